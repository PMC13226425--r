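#' Fit a mono-exponential decay to a peak-volume series
#'
#' Fits V(t) = V0 * exp(-R * t) to a relaxation decay series by nonlinear
#' least squares (Levenberg-Marquardt).  The fit is performed in the
#' nonlinear form, not log-linearized, which matches the behaviour of the
#' curve fitting in typical NMR analysis software and weights noisy
#' long-delay points sensibly.  V0 is initialized from the first point and
#' R from a two-point log estimate.
#'
#' @param delays numeric vector of relaxation delays in seconds (>= 3
#'   distinct values).
#' @param volumes numeric vector of peak volumes (arbitrary units), same
#'   length as `delays`.
#' @return list with `rate` (s^-1), `rate_err` (standard error from the
#'   fit covariance), `v0`, `ok` (logical).  On non-convergence or a
#'   non-positive fitted rate the result has `ok = FALSE` and `NA` values
#'   rather than raising, so one bad residue does not abort a batch.
#' @examples
#' t1_delays <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.8, 1.2, 1.5)
#' fit_exponential(t1_delays, 100 * exp(-2 * t1_delays))$rate
#' @export
fit_exponential <- function(delays, volumes) {
  stopifnot(length(delays) == length(volumes))
  usable <- is.finite(delays) & is.finite(volumes)
  delays <- delays[usable]; volumes <- volumes[usable]
  fail <- list(rate = NA_real_, rate_err = NA_real_, v0 = NA_real_, ok = FALSE)
  if (length(unique(delays)) < 3) return(fail)
  ord <- order(delays)
  delays <- delays[ord]; volumes <- volumes[ord]
  v0_init <- volumes[1]
  # two-point log estimate for the initial rate; fall back to 1/t_max
  r_init <- NA_real_
  n <- length(delays)
  if (volumes[1] > 0 && volumes[n] > 0 && volumes[n] < volumes[1])
    r_init <- log(volumes[1] / volumes[n]) / (delays[n] - delays[1])
  if (!is.finite(r_init) || r_init <= 0) r_init <- 1 / max(delays)
  dat <- data.frame(t = delays, v = volumes)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ v0 * exp(-r * t), data = dat,
                      start = list(v0 = v0_init, r = r_init),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- stats::coef(fit)
  if (!is.finite(cf[["r"]]) || cf[["r"]] <= 0) return(fail)
  se <- tryCatch(summary(fit)$coefficients["r", "Std. Error"],
                 error = function(e) NA_real_)
  list(rate = unname(cf[["r"]]), rate_err = unname(se),
       v0 = unname(cf[["v0"]]), ok = TRUE)
}

#' Heteronuclear NOE from saturated/reference peak volumes
#'
#' NOE = V(sat)/V(ref); the uncertainty is the absolute difference between
#' the values from the original experiment and a single repeat, the
#' replicate-difference convention used when only one duplicate is
#' available.
#'
#' @param sat_volume,ref_volume peak volumes with and without 1H saturation.
#' @param sat_volume_rep,ref_volume_rep the same from the repeated
#'   experiment; omit both to get `noe_err = NA`.
#' @return list with `noe`, `noe_err`, `ok`.  A zero reference volume is a
#'   flagged failure (`ok = FALSE`), not an exception.
#' @examples
#' compute_hetnoe(-300, 1000, -280, 1000)
#' @export
compute_hetnoe <- function(sat_volume, ref_volume,
                           sat_volume_rep = NA, ref_volume_rep = NA) {
  if (!is.finite(ref_volume) || ref_volume == 0)
    return(list(noe = NA_real_, noe_err = NA_real_, ok = FALSE))
  noe <- sat_volume / ref_volume
  err <- NA_real_
  if (is.finite(sat_volume_rep) && is.finite(ref_volume_rep)) {
    if (ref_volume_rep == 0)
      return(list(noe = NA_real_, noe_err = NA_real_, ok = FALSE))
    err <- abs(noe - sat_volume_rep / ref_volume_rep)
  }
  list(noe = noe, noe_err = err, ok = TRUE)
}

#' Convert a decay table to a per-residue relaxation record table
#'
#' Takes a long-format decay table (columns `residue_id`, `delay_s`,
#' `volume`, `experiment_tag` with tags `t1`, `t2`, `noe_sat`, `noe_ref`,
#' `noe_sat_rep`, `noe_ref_rep`) and produces one relaxation record per
#' residue: R1 and R2 with exponential-fit standard errors, and the
#' heteronuclear NOE with the replicate-difference error.  Residues with
#' fewer than 3 usable decay points, failed fits or zero NOE reference
#' volumes get `NA` in the affected fields; nothing is imputed.
#'
#' @param decays data frame as described above (see [read_decay_table]).
#' @return data frame with columns `residue_id`, `R1`, `R1_err`, `R2`,
#'   `R2_err`, `NOE`, `NOE_err`.
#' @export
fit_decay_table <- function(decays) {
  stopifnot(all(c("residue_id", "delay_s", "volume", "experiment_tag") %in%
                  names(decays)))
  ids <- sort(unique(decays$residue_id))
  one <- function(id) {
    d <- decays[decays$residue_id == id, ]
    rec <- data.frame(residue_id = id, R1 = NA_real_, R1_err = NA_real_,
                      R2 = NA_real_, R2_err = NA_real_,
                      NOE = NA_real_, NOE_err = NA_real_)
    for (tag in c("t1", "t2")) {
      s <- d[d$experiment_tag == tag, ]
      if (nrow(s) >= 3) {
        f <- fit_exponential(s$delay_s, s$volume)
        if (f$ok) {
          if (tag == "t1") { rec$R1 <- f$rate; rec$R1_err <- f$rate_err }
          else             { rec$R2 <- f$rate; rec$R2_err <- f$rate_err }
        }
      }
    }
    vol1 <- function(tag) {
      v <- d$volume[d$experiment_tag == tag]
      if (length(v) >= 1) v[1] else NA_real_
    }
    sat <- vol1("noe_sat"); ref <- vol1("noe_ref")
    if (is.finite(sat) && is.finite(ref)) {
      h <- compute_hetnoe(sat, ref, vol1("noe_sat_rep"), vol1("noe_ref_rep"))
      if (h$ok) { rec$NOE <- h$noe; rec$NOE_err <- h$noe_err }
    }
    rec
  }
  do.call(rbind, lapply(ids, one))
}
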