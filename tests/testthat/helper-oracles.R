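# Independent oracle implementations used to cross-check the package.
# These are written from the closed forms directly and share no code with
# the implementation under test.

fc800 <- field_context(800.13)

# independent Lorentzian-sum spectral density (times in seconds)
oracle_J <- function(omega, tau_c, S2, amp2 = 0, tau2 = 0) {
  out <- S2 * tau_c / (1 + (omega * tau_c)^2)
  if (amp2 > 0 && tau2 > 0) out <- out + amp2 * tau2 / (1 + (omega * tau2)^2)
  (2 / 5) * out
}

# independent back-calculation of R1/R2/NOE for the rigid model from raw
# physical constants (not via field_context)
oracle_rates_rigid <- function(S2, tau_c, mhz = 800.13, rnh = 1.02e-10,
                               csa = -160e-6) {
  gammaH <- 2.6752218744e8
  gratio <- -9.8656
  wH <- 2 * pi * mhz * 1e6
  wN <- wH / abs(gratio)
  dd <- 1e-7 * 1.054571817e-34 * gammaH * (gammaH / abs(gratio)) / rnh^3
  cc <- wN * csa / sqrt(3)
  Jf <- function(w) oracle_J(w, tau_c, S2)
  R1 <- dd^2 / 4 * (Jf(wH - wN) + 3 * Jf(wN) + 6 * Jf(wH + wN)) +
    cc^2 * Jf(wN)
  R2 <- dd^2 / 8 * (4 * Jf(0) + Jf(wH - wN) + 3 * Jf(wN) + 6 * Jf(wH) +
                      6 * Jf(wH + wN)) + cc^2 / 6 * (4 * Jf(0) + 3 * Jf(wN))
  NOE <- 1 + dd^2 / 4 * gratio * (6 * Jf(wH + wN) - Jf(wH - wN)) / R1
  list(R1 = R1, R2 = R2, NOE = NOE)
}

# noiseless relaxation record for given motional parameters
record_from_params <- function(params, tau_c_ns, field = fc800,
                               frac_err = 0.02, noe_err = 0.02,
                               residue_id = 1L) {
  r <- back_calculate_rates(params, tau_c_ns * 1e-9, field)
  data.frame(residue_id = residue_id,
             R1 = r$R1, R1_err = frac_err * r$R1,
             R2 = r$R2, R2_err = frac_err * r$R2,
             NOE = r$NOE, NOE_err = noe_err)
}

# add Gaussian noise to a noiseless record using its own error columns
noisy_record <- function(rec, seed) {
  set.seed(seed)
  rec$R1 <- rec$R1 + rnorm(nrow(rec), 0, rec$R1_err)
  rec$R2 <- rec$R2 + rnorm(nrow(rec), 0, rec$R2_err)
  rec$NOE <- rec$NOE + rnorm(nrow(rec), 0, rec$NOE_err)
  rec
}

# brute-force best-fit RMSD via iteratively refined grid search over
# rotation vectors (axis-angle); independent of the Kabsch path
brute_rotation_rmsd <- function(mobile, reference) {
  rotmat <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  score <- function(v) {
    R <- rotmat(v)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  # coarse scan over many rotations, then refine the best few basins
  # with successively finer local grids
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(97)
  starts <- matrix(runif(3 * 3000, -pi, pi), ncol = 3)
  coarse <- apply(starts, 1, score)
  refine <- function(centre) {
    width <- 0.6
    best <- c(score(centre), centre)
    for (level in 1:10) {
      g <- seq(-width, width, length.out = 7)
      for (x in g) for (y in g) for (z in g) {
        v <- centre + c(x, y, z)
        s <- score(v)
        if (s < best[1]) best <- c(s, v)
      }
      centre <- best[2:4]
      width <- width / 3
    }
    best[1]
  }
  min(vapply(order(coarse)[1:3], function(i) refine(starts[i, ]),
             numeric(1)))
}

# toy hairpin ensembles shared by several geometry tests
toy_conformers <- function(seed = 3) gen_two_conformer_ensemble(seed = seed)
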