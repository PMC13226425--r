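test_that("superposition is exact under rigid motion and matches a
           brute-force rotation search", {
  toy <- toy_conformers()
  m <- model_coords(toy$ensIN, 1)
  s0 <- superpose(m, m)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  a <- pi / 2
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  moved <- sweep(m %*% t(R), 2, c(5, -3, 2), `+`)
  s <- superpose(moved, m)
  expect_lt(s$rmsd, 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  # 4-point toy set against the iteratively refined rotation grid
  set.seed(8)
  A <- matrix(rnorm(12), 4, 3)
  B <- matrix(rnorm(12), 4, 3)
  expect_equal(superpose(A, B)$rmsd, brute_rotation_rmsd(A, B),
               tolerance = 1e-6)
  expect_error(superpose(A[1:2, ], B[1:2, ]), ">= 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("per-residue RMSD localizes perturbations and is metric-like", {
  toy <- toy_conformers()
  at <- toy$ensIN$atoms
  base <- toy$ensIN$xyz[1, ]
  ensA <- structure_ensemble(at, base, "A")
  shifted <- base
  idx <- which(at$resno == 13)
  shifted[as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))] <-
    shifted[as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))] +
    rep(c(1, 0, 0), each = 1, times = length(idx))
  ensB <- structure_ensemble(at, shifted, "B")
  out <- per_residue_rmsd(ensA, ensB, selection = "heavy",
                          fit_residues = setdiff(1:25, 13))
  expect_equal(out$rmsd[out$resno == 13], 1.0, tolerance = 1e-9)
  expect_true(all(out$rmsd[out$resno != 13] < 1e-9))
  # symmetric in the two inputs
  rev <- per_residue_rmsd(ensB, ensA, selection = "heavy",
                          fit_residues = setdiff(1:25, 13))
  expect_equal(out$rmsd, rev$rmsd, tolerance = 1e-9)
  # identical ensemble of models: zero everywhere
  ens2 <- structure_ensemble(at, rbind(base, base, base), "AA")
  spread <- per_residue_rmsd(ens2, selection = "backbone")
  expect_true(all(spread$rmsd < 1e-12))
})

test_that("dihedrals follow the IUPAC convention and an independent
           vector-algebra oracle", {
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 0)
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0)), 180)
  # constructed geometries against an acos/sign oracle
  oracle <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- pracma::cross(b1, b2); n2 <- pracma::cross(b2, b3)
    ang <- acos(max(-1, min(1, sum(n1 * n2) /
                              sqrt(sum(n1^2) * sum(n2^2))))) * 180 / pi
    if (sum(pracma::cross(n1, n2) * b2) < 0) -ang else ang
  }
  set.seed(5)
  for (k in 1:25) {
    p <- lapply(1:4, function(i) rnorm(3))
    expect_equal(dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                 oracle(p[[1]], p[[2]], p[[3]], p[[4]]), tolerance = 1e-6)
  }
})

test_that("phi/psi are undefined at termini and chain breaks", {
  toy <- toy_conformers()
  pp <- phi_psi(toy$ensIN, 1)
  expect_true(is.na(pp$phi[pp$resno == 1]))
  expect_true(is.na(pp$psi[pp$resno == 25]))
  # internal residues of the strands have defined angles
  expect_true(all(is.finite(pp$phi[pp$resno %in% 2:9])))
  # residues 10/16 face the gap between the strands across the turn
  expect_true(all(is.finite(pp$psi[pp$resno %in% 2:9])))
})

test_that("circular difference handles wraparound and period", {
  expect_equal(circular_difference(179, -179), 2)
  expect_equal(circular_difference(84, -70), 154)
  for (x in c(-350, -170, 0, 45, 359)) {
    expect_equal(circular_difference(x, x), 0)
    expect_equal(circular_difference(x + 720, x - 360),
                 circular_difference(x, x))
  }
  set.seed(2)
  a <- runif(50, -720, 720); b <- runif(50, -720, 720); k <- sample(-3:3, 50, TRUE)
  expect_equal(circular_difference(a + 360 * k, b), circular_difference(a, b))
  expect_true(all(circular_difference(a, b) >= 0 &
                    circular_difference(a, b) <= 180))
})
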