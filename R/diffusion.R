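# Global rotational diffusion from R2/R1 ratios.
#
# For a rigid N-H vector (S2 = 1, Rex = 0) the R2/R1 ratio depends only on
# the tumbling of the molecule, so per-residue ratios of residues without
# fast internal motion (heteronuclear NOE above a cutoff) report on the
# global diffusion tensor.

# rigid-limit R2/R1 ratio at correlation time tau_s (seconds)
rigid_ratio <- function(tau_s, field) {
  p <- motional_params(1, S2 = 1)
  vapply(tau_s, function(tc) {
    r <- back_calculate_rates(p, tc, field)
    r$R2 / r$R1
  }, numeric(1))
}

#' Per-residue apparent correlation time from an R2/R1 ratio
#'
#' Inverts the rigid-limit (S2 = 1, Rex = 0) R2/R1 curve for the observed
#' ratio; the root is bracketed in \[0.1, 50\] ns, where the rigid ratio is
#' strictly increasing in tau.
#'
#' @param R1,R2 observed rates in s^-1.
#' @param field a [field_context].
#' @return apparent tau_c in ns, or `NA` (with a warning) when the ratio
#'   falls outside the achievable range.
#' @export
residue_tauc <- function(R1, R2, field) {
  if (!is.finite(R1) || !is.finite(R2) || R1 <= 0 || R2 <= 0)
    return(NA_real_)
  obs <- R2 / R1
  lo <- 0.1e-9; hi <- 50e-9
  flo <- rigid_ratio(lo, field) - obs
  fhi <- rigid_ratio(hi, field) - obs
  if (flo * fhi > 0) {
    warning(sprintf("R2/R1 = %.3f outside achievable range; residue excluded",
                    obs))
    return(NA_real_)
  }
  root <- stats::uniroot(function(t) rigid_ratio(t, field) - obs,
                         lower = lo, upper = hi, tol = 1e-15)$root
  root * 1e9
}

# filter records entering diffusion fits: R1/R2 present, NOE above cutoff
diffusion_subset <- function(records, noe_cutoff) {
  ok <- is.finite(records$R1) & is.finite(records$R2) &
    is.finite(records$NOE) & records$NOE > noe_cutoff
  records[ok, , drop = FALSE]
}

# observed ratios and first-order propagated uncertainties
ratio_obs <- function(records) {
  r <- records$R2 / records$R1
  s1 <- records$R1_err; s2 <- records$R2_err
  s1[!is.finite(s1)] <- 0; s2[!is.finite(s2)] <- 0
  sr <- r * sqrt((s1 / records$R1)^2 + (s2 / records$R2)^2)
  sr[sr <= 0] <- stats::median(sr[sr > 0], na.rm = TRUE)
  if (all(!is.finite(sr)) || all(sr <= 0)) sr <- rep(1, length(r))
  list(ratio = r, sigma = sr)
}

#' Fit an isotropic (spherical) diffusion model to R2/R1 ratios
#'
#' One-parameter chi-square minimization of observed versus rigid-limit
#' R2/R1 ratios over all residues with heteronuclear NOE above the cutoff.
#' The chi-square uses error-propagated ratio uncertainties; the
#' uncertainty on tau_c comes from the curvature of the chi-square surface
#' at the minimum.
#'
#' @param records relaxation record data frame (columns `residue_id`,
#'   `R1`, `R1_err`, `R2`, `R2_err`, `NOE`, `NOE_err`).
#' @param field a [field_context].
#' @param noe_cutoff residues with NOE at or below this value are excluded
#'   (default 0.6).
#' @return object of class `diffusion_model` with `kind = "sphere"`,
#'   `tau_c` and `tau_c_err` (ns), `chi2`, `n_residues`, `n_params = 1`.
#' @export
fit_isotropic <- function(records, field, noe_cutoff = 0.6) {
  use <- diffusion_subset(records, noe_cutoff)
  if (nrow(use) < 5)
    stop("only ", nrow(use), " usable residues after NOE filtering; >= 5 needed")
  ro <- ratio_obs(use)
  chi2_of <- function(tau_ns)
    sum(((ro$ratio - rigid_ratio(tau_ns * 1e-9, field)) / ro$sigma)^2)
  opt <- stats::optimize(chi2_of, interval = c(0.5, 30), tol = 1e-8)
  tau <- opt$minimum
  # curvature of chi2 at the minimum -> sigma_tau = sqrt(2 / chi2'')
  h <- 1e-3
  curv <- (chi2_of(tau + h) - 2 * opt$objective + chi2_of(tau - h)) / h^2
  tau_err <- if (is.finite(curv) && curv > 0) sqrt(2 / curv) else NA_real_
  structure(list(kind = "sphere", tau_c = tau, tau_c_err = tau_err,
                 chi2 = opt$objective, n_residues = nrow(use), n_params = 1L,
                 residue_id = use$residue_id),
            class = "diffusion_model")
}

#' @export
print.diffusion_model <- function(x, ...) {
  if (x$kind == "sphere") {
    cat(sprintf("<diffusion_model sphere> tau_c = %.3f +- %.3f ns, chi2 = %.3g (n = %d)\n",
                x$tau_c, x$tau_c_err, x$chi2, x$n_residues))
  } else {
    cat(sprintf("<diffusion_model axial> D_iso = %.3e s^-1, D_par/D_perp = %.3f\n",
                x$D_iso, x$D_ratio))
    cat(sprintf("  axis (theta, phi) = (%.1f, %.1f) deg, tau_c = %.3f ns, chi2 = %.3g (n = %d)\n",
                x$axis_polar_angles[1], x$axis_polar_angles[2],
                x$tau_c, x$chi2, x$n_residues))
  }
  invisible(x)
}

# axially symmetric rigid spectral density: three-exponential form with
# tau_k^-1 = {6 Dperp, 5 Dperp + Dpar, 2 Dperp + 4 Dpar} and amplitudes
# A_k(theta) = {(3 cos^2 - 1)^2 / 4, 3 sin^2 cos^2, (3/4) sin^4}
axial_J <- function(omega, cos_theta, Dperp, Dpar) {
  c2 <- cos_theta^2; s2 <- 1 - c2
  A <- c((3 * c2 - 1)^2 / 4, 3 * s2 * c2, 0.75 * s2^2)
  tk <- 1 / c(6 * Dperp, 5 * Dperp + Dpar, 2 * Dperp + 4 * Dpar)
  out <- 0
  for (k in 1:3) out <- out + A[k] * tk[k] / (1 + (omega * tk[k])^2)
  0.4 * out
}

axial_ratio <- function(cos_theta, Dperp, Dpar, field) {
  wH <- field$omega_H; wN <- field$omega_N
  vapply(cos_theta, function(ct) {
    w <- c(0, wN, wH - wN, wH, wH + wN)
    J <- vapply(w, axial_J, numeric(1), cos_theta = ct,
                Dperp = Dperp, Dpar = Dpar)
    R1 <- field$d2 / 4 * (J[3] + 3 * J[2] + 6 * J[5]) + field$c2 * J[2]
    R2 <- field$d2 / 8 * (4 * J[1] + J[3] + 3 * J[2] + 6 * J[4] + 6 * J[5]) +
      field$c2 / 6 * (4 * J[1] + 3 * J[2])
    R2 / R1
  }, numeric(1))
}

#' Fit an axially symmetric diffusion tensor to R2/R1 ratios
#'
#' Four-parameter fit (D_iso, D_par/D_perp and the polar angles of the
#' unique axis).  The search uses the quadric local-diffusion
#' approximation -- the apparent local diffusion coefficient
#' D_i = 1/(6 tau_c,i) of residue i depends on its N-H orientation n_i as
#' n_i' Q n_i with Q = (Tr(D) I - D)/2, which is linear in the tensor for
#' a fixed axis and therefore solvable in closed form on an orientation
#' grid -- and the solution is then refined against, and the final
#' chi-square reported from, the full three-exponential axially symmetric
#' spectral density.
#'
#' @param records relaxation record data frame.
#' @param nh_vectors matrix (one row per record row) of N-H bond unit
#'   vectors in the molecular frame; rows with non-finite vectors are
#'   dropped with a notice.
#' @param field a [field_context].
#' @param noe_cutoff NOE filter as in [fit_isotropic].
#' @return object of class `diffusion_model` with `kind = "axial"`,
#'   `D_iso`, `D_ratio`, `axis_polar_angles` (degrees), equivalent
#'   `tau_c = 1/(6 D_iso)` in ns, `chi2` (full-form, over ratios),
#'   `n_residues`, `n_params = 4`.
#' @export
fit_axial <- function(records, nh_vectors, field, noe_cutoff = 0.6) {
  stopifnot(nrow(records) == nrow(nh_vectors), ncol(nh_vectors) == 3)
  keep <- is.finite(records$R1) & is.finite(records$R2) &
    is.finite(records$NOE) & records$NOE > noe_cutoff
  vec_ok <- apply(is.finite(nh_vectors), 1, all)
  if (any(keep & !vec_ok))
    message(sum(keep & !vec_ok), " residue(s) dropped: missing amide N-H vector")
  keep <- keep & vec_ok
  use <- records[keep, , drop = FALSE]
  nh <- nh_vectors[keep, , drop = FALSE]
  if (nrow(use) < 6) stop("too few residues (", nrow(use), ") for an axial fit")
  nh <- nh / sqrt(rowSums(nh^2))
  ro <- ratio_obs(use)
  # observed local diffusion coefficients with propagated uncertainties
  tci <- mapply(residue_tauc, use$R1, use$R2, MoreArgs = list(field = field))
  if (any(!is.finite(tci))) {
    use <- use[is.finite(tci), , drop = FALSE]
    nh <- nh[is.finite(tci), , drop = FALSE]
    ro <- ratio_obs(use)
    tci <- tci[is.finite(tci)]
  }
  Di <- 1 / (6 * tci * 1e-9)
  # sigma_D via the numeric slope of the tau(ratio) inversion
  dtau <- vapply(seq_along(tci), function(i) {
    eps <- 1e-3 * ro$ratio[i]
    t2 <- tryCatch(stats::uniroot(function(t) rigid_ratio(t, field) -
                                    (ro$ratio[i] + eps),
                                  lower = 0.1e-9, upper = 50e-9,
                                  tol = 1e-15)$root * 1e9,
                   error = function(e) NA_real_)
    abs(t2 - tci[i]) / eps
  }, numeric(1))
  sD <- abs(dtau * ro$sigma) / (6 * tci^2 * 1e-9)   # |dD/dtau| * sigma_tau
  sD[!is.finite(sD) | sD <= 0] <- stats::median(sD[is.finite(sD) & sD > 0])

  # stage 1: closed-form weighted LS of D_loc = a - b (n.u)^2 on an axis grid
  grid <- expand.grid(theta = seq(0.05, pi / 2, length.out = 13),
                      phi = seq(0, pi, length.out = 13))
  best <- NULL
  w <- 1 / sD^2
  for (g in seq_len(nrow(grid))) {
    u <- c(sin(grid$theta[g]) * cos(grid$phi[g]),
           sin(grid$theta[g]) * sin(grid$phi[g]),
           cos(grid$theta[g]))
    x <- (nh %*% u)^2
    X <- cbind(1, -x)
    XtW <- t(X * w)
    ab <- tryCatch(solve(XtW %*% X, XtW %*% Di), error = function(e) NULL)
    if (is.null(ab)) next
    res <- Di - X %*% ab
    chi2 <- sum(w * res^2)
    if (is.null(best) || chi2 < best$chi2)
      best <- list(chi2 = chi2, a = ab[1], b = ab[2],
                   theta = grid$theta[g], phi = grid$phi[g])
  }
  # a = (Dperp + Dpar)/2, b = (Dpar - Dperp)/2
  Dperp0 <- best$a - best$b
  Dpar0 <- best$a + best$b
  if (Dperp0 <= 0) Dperp0 <- best$a
  if (Dpar0 <= 0) Dpar0 <- best$a

  # stage 2: refine against the full axially symmetric form, chi2 on ratios
  chi2_full <- function(par) {
    Dperp <- exp(par[1]); Dpar <- exp(par[2])
    u <- c(sin(par[3]) * cos(par[4]), sin(par[3]) * sin(par[4]), cos(par[3]))
    ct <- as.numeric(nh %*% u)
    calc <- axial_ratio(ct, Dperp, Dpar, field)
    sum(((ro$ratio - calc) / ro$sigma)^2)
  }
  start <- c(log(Dperp0), log(Dpar0), best$theta, best$phi)
  opt <- stats::nlminb(start, chi2_full)
  Dperp <- exp(opt$par[1]); Dpar <- exp(opt$par[2])
  theta <- opt$par[3] %% pi; phi <- opt$par[4] %% (2 * pi)
  D_iso <- (2 * Dperp + Dpar) / 3
  structure(list(kind = "axial", D_iso = D_iso, D_ratio = Dpar / Dperp,
                 axis_polar_angles = c(theta, phi) * 180 / pi,
                 tau_c = 1 / (6 * D_iso) * 1e9,
                 chi2 = opt$objective, n_residues = nrow(use), n_params = 4L,
                 residue_id = use$residue_id),
            class = "diffusion_model")
}

#' F-test comparison of spherical versus axially symmetric diffusion
#'
#' \deqn{F = \frac{(\chi^2_{sph} - \chi^2_{ax})/(4-1)}{\chi^2_{ax}/(n-4)}}
#' with the p-value from the F distribution with (3, n-4) degrees of
#' freedom; n is the number of residues in the (shared) fit.
#'
#' @param sphere,axial `diffusion_model` objects fitted to the same
#'   residue set.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
compare_diffusion_models <- function(sphere, axial) {
  stopifnot(sphere$kind == "sphere", axial$kind == "axial",
            axial$n_params > sphere$n_params)
  n <- axial$n_residues
  df1 <- axial$n_params - sphere$n_params
  df2 <- n - axial$n_params
  if (axial$chi2 == 0 && sphere$chi2 > 0) {
    warning("axial chi2 is zero with nonzero sphere chi2; reporting p = 0")
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  }
  Fv <- if (sphere$chi2 == axial$chi2) 0 else
    ((sphere$chi2 - axial$chi2) / df1) / (axial$chi2 / df2)
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  list(F = Fv, p = p, df1 = df1, df2 = df2)
}

# standard atomic masses for the elements seen in protein heavy atoms
element_mass <- function(elements) {
  m <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
         H = 1.008)
  out <- unname(m[elements])
  out[is.na(out)] <- 12.011
  out
}

#' Principal axes of the inertia tensor of a structure
#'
#' Mass-weighted inertia tensor over heavy atoms (hydrogens excluded,
#' element masses) of one model, optionally restricted to a residue range.
#' Reports the principal moments sorted in descending order and the
#' relative moments normalized so the largest equals 1.00 (the convention
#' in which a rod reads 1.00:1.00:0.00 and a sphere 1.00:1.00:1.00), plus
#' the equivalent uniform-ellipsoid semi-axis ratios derived from
#' a^2 proportional to (Ib + Ic - Ia) (cyclic).
#'
#' @param ensemble a `structure_ensemble` (see [read_pdb_ensemble]).
#' @param model_index 1-based model number (default 1, the representative).
#' @param residue_range optional integer vector of residue numbers to use.
#' @return object of class `principal_axes` with `moments`, `axis_ratios`,
#'   `semiaxis_ratios` and `axes` (eigenvector matrix, columns ordered as
#'   `moments`).
#' @export
inertia_axes <- function(ensemble, model_index = 1, residue_range = NULL) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  at <- ensemble$atoms
  sel <- at$element != "H"
  if (!is.null(residue_range)) sel <- sel & at$resno %in% residue_range
  if (!any(sel)) stop("empty atom selection for inertia tensor")
  xyz <- model_coords(ensemble, model_index)[sel, , drop = FALSE]
  m <- element_mass(at$element[sel])
  com <- colSums(xyz * m) / sum(m)
  r <- sweep(xyz, 2, com)
  Ixx <- sum(m * (r[, 2]^2 + r[, 3]^2))
  Iyy <- sum(m * (r[, 1]^2 + r[, 3]^2))
  Izz <- sum(m * (r[, 1]^2 + r[, 2]^2))
  Ixy <- -sum(m * r[, 1] * r[, 2])
  Ixz <- -sum(m * r[, 1] * r[, 3])
  Iyz <- -sum(m * r[, 2] * r[, 3])
  I <- matrix(c(Ixx, Ixy, Ixz, Ixy, Iyy, Iyz, Ixz, Iyz, Izz), 3, 3)
  e <- eigen(I, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  mom <- e$values[ord]
  semi2 <- c(mom[2] + mom[3] - mom[1],
             mom[1] + mom[3] - mom[2],
             mom[1] + mom[2] - mom[3])
  semi2[semi2 < 0] <- 0
  semi <- sort(sqrt(semi2), decreasing = TRUE)
  structure(list(moments = mom,
                 axis_ratios = mom / mom[1],
                 semiaxis_ratios = semi / semi[1],
                 axes = e$vectors[, ord]),
            class = "principal_axes")
}

#' @export
print.principal_axes <- function(x, ...) {
  cat(sprintf("<principal_axes> relative moments %.2f : %.2f : %.2f\n",
              x$axis_ratios[1], x$axis_ratios[2], x$axis_ratios[3]))
  cat(sprintf("  ellipsoid semi-axes %.2f : %.2f : %.2f\n",
              x$semiaxis_ratios[1], x$semiaxis_ratios[2], x$semiaxis_ratios[3]))
  invisible(x)
}
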