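# rigid-core-only records at a single tau_c (the configuration the
# R2/R1-ratio fit assumes)
rigid_records <- function(n = 80, tau_c_ns = 6.6, S2 = 0.9) {
  do.call(rbind, lapply(1:n, function(i)
    record_from_params(motional_params(1, S2 = S2), tau_c_ns,
                       residue_id = i)))
}

test_that("per-residue tau_c inverts forward-calculated ratios", {
  for (tc in c(6.6, 3.0)) {
    r <- back_calculate_rates(motional_params(1, S2 = 1), tc * 1e-9, fc800)
    expect_equal(residue_tauc(r$R1, r$R2, fc800), tc, tolerance = 1e-3)
  }
  # exchange inflates R2 and therefore the apparent tau
  r <- back_calculate_rates(motional_params(1, S2 = 1), 6.6e-9, fc800)
  expect_gt(residue_tauc(r$R1, r$R2 + 10, fc800), 6.6)
  # tau_c is strictly increasing in the observed ratio
  taus <- vapply(seq(2, 12, by = 2), function(k)
    residue_tauc(r$R1, r$R1 * k, fc800), numeric(1))
  expect_true(all(diff(taus) > 0))
  expect_warning(out <- residue_tauc(1, 1000, fc800), "outside")
  expect_true(is.na(out))
})

test_that("isotropic fit recovers tau_c on perfect data and filters by NOE", {
  rec <- rigid_records()
  fit <- fit_isotropic(rec, fc800)
  expect_s3_class(fit, "diffusion_model")
  expect_equal(fit$tau_c, 6.6, tolerance = 1e-4)
  expect_lt(fit$chi2, 1e-8)
  expect_equal(fit$n_residues, 80L)
  # one residue pushed below the NOE cutoff drops out, exactly one
  rec2 <- rec
  rec2$NOE[7] <- 0.5
  expect_equal(fit_isotropic(rec2, fc800)$n_residues, 79L)
  expect_error(fit_isotropic(rec[1:4, ], fc800), "usable residues")
})

test_that("isotropic fit is unbiased under noise and brackets tau_c,i", {
  taus <- vapply(1:100, function(s)
    fit_isotropic(noisy_record(rigid_records(n = 40), seed = s),
                  fc800)$tau_c, numeric(1))
  se <- sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - 6.6), 2 * se + 1e-3)
  # fitted tau_c lies within the per-residue tau range actually used
  rec <- noisy_record(rigid_records(n = 40), seed = 1)
  fit <- fit_isotropic(rec, fc800)
  tci <- mapply(residue_tauc, rec$R1, rec$R2, MoreArgs = list(field = fc800))
  expect_gte(fit$tau_c, min(tci, na.rm = TRUE))
  expect_lte(fit$tau_c, max(tci, na.rm = TRUE))
})

test_that("axial tensor fit recovers isotropic and anisotropic truths", {
  set.seed(42)
  n <- 60
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  # anisotropic truth: D_ratio = 1.5, known axis
  D_iso <- 1 / (6 * 6.6e-9)
  Dperp <- 3 * D_iso / 3.5
  Dpar <- 1.5 * Dperp
  th0 <- 40 * pi / 180; ph0 <- 60 * pi / 180
  u0 <- c(sin(th0) * cos(ph0), sin(th0) * sin(ph0), cos(th0))
  ratios <- igdyn:::axial_ratio(as.numeric(v %*% u0), Dperp, Dpar, fc800)
  rec <- data.frame(residue_id = 1:n, R1 = 1.3, R1_err = 0.013,
                    R2 = 1.3 * ratios, R2_err = 0.013 * ratios,
                    NOE = 0.85, NOE_err = 0.02)
  ax <- fit_axial(rec, v, fc800)
  expect_equal(ax$D_ratio, 1.5, tolerance = 0.02)
  uf <- with(list(a = ax$axis_polar_angles * pi / 180),
             c(sin(a[1]) * cos(a[2]), sin(a[1]) * sin(a[2]), cos(a[1])))
  expect_lt(acos(min(1, abs(sum(uf * u0)))) * 180 / pi, 5)
  # permuting residue order leaves chi2 unchanged
  perm <- sample(n)
  ax_p <- fit_axial(rec[perm, ], v[perm, ], fc800)
  expect_equal(ax_p$chi2, ax$chi2, tolerance = 1e-6)
  # isotropic truth: fitted anisotropy collapses to 1
  riso <- igdyn:::rigid_ratio(6.6e-9, fc800)
  rec_iso <- data.frame(residue_id = 1:n, R1 = 1.3, R1_err = 0.013,
                        R2 = 1.3 * riso, R2_err = 0.013 * riso,
                        NOE = 0.85, NOE_err = 0.02)
  ax_iso <- fit_axial(rec_iso, v, fc800)
  expect_gt(ax_iso$D_ratio, 0.95)
  expect_lt(ax_iso$D_ratio, 1.05)
})

test_that("sphere/axial F comparison follows the stated formula", {
  mk <- function(kind, chi2, n, p) structure(
    list(kind = kind, chi2 = chi2, n_residues = n, n_params = p),
    class = "diffusion_model")
  eq <- compare_diffusion_models(mk("sphere", 5, 80, 1L), mk("axial", 5, 80, 4L))
  expect_equal(eq$F, 0)
  expect_equal(eq$p, 1)
  # published chi2 pair evaluated through the formula
  cmp <- compare_diffusion_models(mk("sphere", 19.2, 80, 1L),
                                  mk("axial", 18.6, 80, 4L))
  expect_equal(cmp$F, ((19.2 - 18.6) / 3) / (18.6 / 76))
  expect_gt(cmp$p, 0.05)
  # scale invariance of F
  cmp2 <- compare_diffusion_models(mk("sphere", 38.4, 80, 1L),
                                   mk("axial", 37.2, 80, 4L))
  expect_equal(cmp2$F, cmp$F)
  expect_warning(z <- compare_diffusion_models(mk("sphere", 3, 80, 1L),
                                               mk("axial", 0, 80, 4L)),
                 "p = 0")
  expect_equal(z$p, 0)
})

test_that("inertia axes reproduce rod and sphere limits and are
           invariant under rigid motion", {
  rod <- structure_ensemble(
    data.frame(chain = "A", resno = 1:100, resname = "ALA", atom = "CA",
               element = "C"),
    as.numeric(t(cbind(seq(0, 99), 0, 0))))
  ax <- inertia_axes(rod)
  expect_equal(ax$axis_ratios[1:2], c(1, 1), tolerance = 1e-9)
  expect_lt(ax$axis_ratios[3], 1e-9)
  i <- seq_len(400) - 0.5
  ph <- acos(1 - 2 * i / 400); th <- pi * (1 + sqrt(5)) * i
  pts <- 10 * cbind(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph))
  sph <- structure_ensemble(
    data.frame(chain = "A", resno = seq_len(400), resname = "ALA",
               atom = "CA", element = "C"), as.numeric(t(pts)))
  expect_equal(inertia_axes(sph)$axis_ratios, rep(1, 3), tolerance = 0.01)
  # rigid rotation + translation leaves the ratios untouched
  a <- pi / 5
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  pts2 <- sweep(pts %*% t(R), 2, c(10, -4, 2), `+`)
  sph2 <- structure_ensemble(sph$atoms, as.numeric(t(pts2)))
  expect_equal(inertia_axes(sph2)$axis_ratios, inertia_axes(sph)$axis_ratios,
               tolerance = 1e-9)
  expect_error(inertia_axes(sph, residue_range = 1000), "empty")
})
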