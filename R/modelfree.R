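# Per-residue Lipari-Szabo model-free fitting.
#
# Each residue contributes three observables (R1, R2, NOE) fitted at a
# fixed global tau_c with one of five motional models.  Model complexity
# is gated by an F-statistic (models 1 -> 2/3) and by Monte-Carlo
# critical chi-square values (all models; the only route into the
# zero-degree-of-freedom models 4 and 5).

# run expr with a local RNG stream, restoring the caller's stream after
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% 2147483647))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# deterministic per-residue substream so batch results do not depend on
# processing order
residue_seed <- function(master_seed, residue_id, salt = 0L) {
  (as.numeric(master_seed) * 1000003 + as.numeric(residue_id) * 7919 +
     as.numeric(salt) * 104729) %% 2147483647
}

mf_n_params <- c(1L, 2L, 2L, 3L, 3L)

# unvalidated constructor for optimizer-internal use; the bounded search
# space guarantees validity
new_mp <- function(model_id, S2, tau_e = 0, R_ex = 0, S2_f = 1, tau_i = 0) {
  structure(list(model_id = as.integer(model_id), S2 = S2, tau_e = tau_e,
                 R_ex = R_ex, S2_f = S2_f, tau_i = tau_i),
            class = "motional_params")
}

# map a free-parameter vector to motional_params.  Internal times are in
# ns so all free parameters share a comparable scale for the optimizer.
# Model 5 is parameterized as (S2f, S2s, tau_i) with S2 = S2f * S2s so
# the constraint S2 <= S2f holds by construction.
mf_make_params <- function(model_id, par) {
  switch(model_id,
         new_mp(1, S2 = par[1]),
         new_mp(2, S2 = par[1], R_ex = par[2]),
         new_mp(3, S2 = par[1], tau_e = par[2] * 1e-9),
         new_mp(4, S2 = par[1], tau_e = par[2] * 1e-9, R_ex = par[3]),
         new_mp(5, S2 = par[1] * par[2], S2_f = par[1],
                tau_i = par[3] * 1e-9))
}

mf_bounds <- function(model_id) {
  switch(model_id,
         list(lo = 0, hi = 1),
         list(lo = c(0, 0), hi = c(1, 50)),
         list(lo = c(0, 0), hi = c(1, 10)),
         list(lo = c(0, 0, 0), hi = c(1, 10, 50)),
         list(lo = c(0, 0, 0), hi = c(1, 1, 10)))
}

mf_starts <- function(model_id) {
  g <- function(...) as.matrix(expand.grid(...))
  switch(model_id,
         matrix(c(0.5, 0.85), ncol = 1),
         g(S2 = c(0.5, 0.7, 0.9), Rex = c(0.5, 5, 15)),
         g(S2 = c(0.2, 0.5, 0.8, 0.95), te = c(0.02, 0.2, 2)),
         g(S2 = c(0.4, 0.7, 0.9), te = c(0.05, 1), Rex = c(1, 8)),
         g(S2f = c(0.5, 0.8, 0.95), S2s = c(0.2, 0.5, 0.8),
           ti = c(0.3, 1, 3)))
}

mf_chi2 <- function(par, model_id, obs, sigma, tau_c_s, field) {
  p <- mf_make_params(model_id, par)
  calc <- back_calculate_rates(p, tau_c_s, field)
  val <- sum(((obs - c(calc$R1, calc$R2, calc$NOE)) / sigma)^2)
  # the NOE is undefined where all spectral densities vanish (R1 = 0);
  # treat such corners of parameter space as arbitrarily bad fits
  if (!is.finite(val)) 1e12 else val
}

#' Fit one motional model to a residue's relaxation data
#'
#' Minimizes chi2 = sum(((obs - calc)/sigma)^2) over R1, R2 and NOE at
#' fixed global tau_c, with bounded parameters (S2, S2f in \[0,1\];
#' tau_e, tau_i in \[0, 10 ns\]; Rex in \[0, 50 s^-1\]) and a multi-start
#' grid to avoid local minima.
#'
#' @param record one-row data frame (or list) with `R1`, `R1_err`, `R2`,
#'   `R2_err`, `NOE`, `NOE_err` and optionally `residue_id`.
#' @param tau_c global correlation time in ns.
#' @param model_id motional model 1..5.
#' @param field a [field_context].
#' @param start optional numeric start vector; when supplied the
#'   multi-start grid is skipped (used by the Monte-Carlo refits).
#' @return object of class `model_fit`: `residue_id`, `model_id`, `par`
#'   (free-parameter vector), `params` ([motional_params]), `chi2`,
#'   `n_params`.
#' @export
fit_model <- function(record, tau_c, model_id, field, start = NULL) {
  stopifnot(model_id %in% 1:5)
  obs <- c(record$R1, record$R2, record$NOE)
  sigma <- c(record$R1_err, record$R2_err, record$NOE_err)
  if (any(!is.finite(obs)))
    stop("residue ", record$residue_id %||% "?",
         ": R1, R2 and NOE must all be present")
  sigma[!is.finite(sigma) | sigma <= 0] <- pmax(abs(obs), 1)[
    !is.finite(sigma) | sigma <= 0] * 0.02
  tau_c_s <- tau_c * 1e-9
  b <- mf_bounds(model_id)
  if (model_id == 1 && is.null(start)) {
    opt <- stats::optimize(function(s2)
      mf_chi2(s2, 1L, obs, sigma, tau_c_s, field), interval = c(0, 1),
      tol = 1e-10)
    best <- list(par = opt$minimum, objective = opt$objective)
  } else {
    starts <- if (!is.null(start)) matrix(start, nrow = 1) else
      mf_starts(model_id)
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- stats::nlminb(pmin(pmax(starts[i, ], b$lo), b$hi),
                         mf_chi2, model_id = model_id, obs = obs,
                         sigma = sigma, tau_c_s = tau_c_s, field = field,
                         lower = b$lo, upper = b$hi,
                         control = list(iter.max = 500, rel.tol = 1e-12))
      if (is.null(best) || o$objective < best$objective) best <- o
    }
    if (is.null(start)) {
      # polish the multi-start winner once more from its own optimum
      o <- stats::nlminb(best$par, mf_chi2, model_id = model_id, obs = obs,
                         sigma = sigma, tau_c_s = tau_c_s, field = field,
                         lower = b$lo, upper = b$hi,
                         control = list(iter.max = 500, rel.tol = 1e-13))
      if (o$objective < best$objective) best <- o
    }
  }
  structure(list(residue_id = record$residue_id %||% NA_integer_,
                 model_id = as.integer(model_id),
                 par = as.numeric(best$par),
                 params = mf_make_params(model_id, as.numeric(best$par)),
                 chi2 = best$objective,
                 n_params = mf_n_params[model_id]),
            class = "model_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' F-test for nested motional models
#'
#' \deqn{F = \frac{(\chi^2_s - \chi^2_c)/(p_c - p_s)}{\chi^2_c/(n_{obs} - p_c)}}
#' with p from the F distribution with (p_c - p_s, n_obs - p_c) degrees of
#' freedom.  With three observables the 1 -> 2 and 1 -> 3 comparisons have
#' (1, 1) degrees of freedom.
#'
#' @param chi2_simple,chi2_complex chi-square of the nested fits.
#' @param n_obs number of observables (default 3: R1, R2, NOE).
#' @param p_simple,p_complex numbers of fitted parameters.
#' @return list with `F` and `p`.
#' @export
ftest_nested <- function(chi2_simple, chi2_complex, n_obs = 3,
                         p_simple, p_complex) {
  stopifnot(p_complex > p_simple, chi2_simple >= 0, chi2_complex >= 0,
            n_obs > p_complex)
  if (chi2_complex == 0) {
    if (chi2_simple == 0) return(list(F = 0, p = 1))
    warning("complex-model chi2 is zero; reporting p = 0")
    return(list(F = Inf, p = 0))
  }
  df1 <- p_complex - p_simple
  df2 <- n_obs - p_complex
  Fv <- ((chi2_simple - chi2_complex) / df1) / (chi2_complex / df2)
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Monte-Carlo critical chi-square for a motional model
#'
#' Simulates `n_sim` synthetic (R1, R2, NOE) triples from the rates
#' back-calculated at the best-fit parameters plus Gaussian noise with the
#' experimental uncertainties, refits the same model to each (starting
#' from the best-fit parameters) and returns the confidence-level
#' empirical quantile (nearest-rank) of the refit chi-square distribution.
#' The refit parameter spread doubles as the Monte-Carlo parameter
#' uncertainty.
#'
#' @param record_sigmas numeric length-3 vector of experimental sigmas for
#'   (R1, R2, NOE).
#' @param model_id motional model 1..5.
#' @param best_fit a `model_fit` for that model.
#' @param tau_c global correlation time in ns.
#' @param field a [field_context].
#' @param n_sim number of simulations (>= 100).
#' @param confidence quantile level (default 0.95).
#' @param seed integer seed; the same seed reproduces the result exactly.
#' @return list with `chi2_critical`, `param_sd` (per-parameter Monte-Carlo
#'   standard deviations) and `chi2_sim` (the simulated distribution).
#' @export
critical_chi2 <- function(record_sigmas, model_id, best_fit, tau_c, field,
                          n_sim = 500, confidence = 0.95, seed = 1) {
  stopifnot(n_sim >= 100, length(record_sigmas) == 3)
  true_rates <- back_calculate_rates(best_fit$params, tau_c * 1e-9, field)
  mu <- c(true_rates$R1, true_rates$R2, true_rates$NOE)
  with_seed(seed, {
    chi2s <- numeric(n_sim)
    pars <- matrix(NA_real_, n_sim, length(best_fit$par))
    for (i in seq_len(n_sim)) {
      obs <- mu + stats::rnorm(3, 0, record_sigmas)
      rec <- list(residue_id = best_fit$residue_id,
                  R1 = obs[1], R1_err = record_sigmas[1],
                  R2 = obs[2], R2_err = record_sigmas[2],
                  NOE = obs[3], NOE_err = record_sigmas[3])
      f <- fit_model(rec, tau_c, model_id, field, start = best_fit$par)
      chi2s[i] <- f$chi2
      pars[i, ] <- f$par
    }
    k <- min(n_sim, max(1L, ceiling(confidence * n_sim)))
    list(chi2_critical = sort(chi2s)[k],
         param_sd = apply(pars, 2, stats::sd),
         chi2_sim = chi2s)
  })
}

#' Select a motional model for one residue
#'
#' Implements the two-tier selection scheme: model 1 is the baseline;
#' models 2 and 3 displace it only if the nested F-test gives p < 0.05
#' (when both pass, the lower chi-square wins, ties going to model 2).  A
#' model is "satisfactory" when its chi-square is below its Monte-Carlo
#' critical chi-square.  Models 4 and 5 are considered only when none of
#' models 1-3 is satisfactory, and are accepted only when their own
#' chi-square beats their critical value.  If no model is satisfactory the
#' best-chi-square fit is returned flagged unsatisfactory.
#'
#' @param record one-row data frame with R1/R2/NOE and errors.
#' @param tau_c global correlation time in ns.
#' @param field a [field_context].
#' @param n_sim Monte-Carlo sample size for critical chi-squares.
#' @param confidence critical-quantile level.
#' @param seed master seed; each residue derives its own substream from
#'   `residue_id`, so batch results are independent of processing order.
#' @return `model_fit` with extra fields `chi2_critical`, `param_sd`,
#'   `satisfactory` and `decision_path`.
#' @export
select_model <- function(record, tau_c, field, n_sim = 500,
                         confidence = 0.95, seed = 1) {
  rid <- record$residue_id %||% 0L
  sig <- c(record$R1_err, record$R2_err, record$NOE_err)
  sig[!is.finite(sig) | sig <= 0] <-
    pmax(abs(c(record$R1, record$R2, record$NOE)), 1)[
      !is.finite(sig) | sig <= 0] * 0.02
  crit_of <- function(fit)
    critical_chi2(sig, fit$model_id, fit, tau_c, field, n_sim = n_sim,
                  confidence = confidence,
                  seed = residue_seed(seed, rid, fit$model_id))
  fits <- list(fit_model(record, tau_c, 1L, field),
               fit_model(record, tau_c, 2L, field),
               fit_model(record, tau_c, 3L, field))
  path <- character()
  cand <- fits[[1]]
  if (fits[[1]]$chi2 < 1e-6) {
    # model 1 already fits to numerical precision: a finite F-statistic
    # cannot justify extra parameters on an effectively perfect fit
    path <- c(path, "m1 chi2 at numerical zero")
  } else {
    ft2 <- ftest_nested(fits[[1]]$chi2, fits[[2]]$chi2, 3, 1, 2)
    ft3 <- ftest_nested(fits[[1]]$chi2, fits[[3]]$chi2, 3, 1, 2)
    path <- c(path, sprintf("F1>2 p=%.3g", ft2$p),
              sprintf("F1>3 p=%.3g", ft3$p))
    if (ft2$p < 0.05 && ft3$p < 0.05) {
      cand <- if (fits[[3]]$chi2 < fits[[2]]$chi2) fits[[3]] else fits[[2]]
    } else if (ft2$p < 0.05) cand <- fits[[2]]
    else if (ft3$p < 0.05) cand <- fits[[3]]
  }
  path <- c(path, sprintf("candidate m%d", cand$model_id))

  finish <- function(fit, crit, sat) {
    fit$chi2_critical <- crit$chi2_critical
    fit$param_sd <- crit$param_sd
    fit$satisfactory <- sat
    fit$decision_path <- paste(path, collapse = "; ")
    fit
  }
  crit_cand <- crit_of(cand)
  if (cand$chi2 < crit_cand$chi2_critical) {
    path <- c(path, sprintf("m%d satisfactory (chi2 %.3g < crit %.3g)",
                            cand$model_id, cand$chi2, crit_cand$chi2_critical))
    return(finish(cand, crit_cand, TRUE))
  }
  # The F-test gates entry into models 2/3: a complex model that did not
  # earn significance stays unavailable even if its chi2 would pass its
  # critical value.  The critical values of all three simple models still
  # decide whether models 4/5 may be considered at all.
  crits <- vector("list", 3)
  crits[[cand$model_id]] <- crit_cand
  for (m in 1:3) if (is.null(crits[[m]])) crits[[m]] <- crit_of(fits[[m]])
  sat13 <- vapply(1:3, function(m)
    fits[[m]]$chi2 < crits[[m]]$chi2_critical, logical(1))
  if (any(sat13)) {
    path <- c(path, sprintf("m%d not satisfactory but models 1-3 not all
                            unsatisfactory; keeping candidate",
                            cand$model_id))
    path <- gsub("\\s+", " ", path)
    return(finish(cand, crit_cand, FALSE))
  }
  path <- c(path, "models 1-3 unsatisfactory; trying 4/5")
  f4 <- fit_model(record, tau_c, 4L, field)
  f5 <- fit_model(record, tau_c, 5L, field)
  c4 <- crit_of(f4); c5 <- crit_of(f5)
  ok4 <- f4$chi2 < c4$chi2_critical
  ok5 <- f5$chi2 < c5$chi2_critical
  if (ok4 && (!ok5 || f4$chi2 <= f5$chi2)) {
    path <- c(path, "m4 accepted")
    return(finish(f4, c4, TRUE))
  }
  if (ok5) {
    path <- c(path, "m5 accepted")
    return(finish(f5, c5, TRUE))
  }
  # nothing satisfactory: best chi2 across everything, flagged
  all_fits <- c(fits, list(f4, f5))
  all_crits <- c(crits, list(c4, c5))
  best <- which.min(vapply(all_fits, `[[`, numeric(1), "chi2"))
  path <- c(path, sprintf("no model satisfactory; best m%d flagged",
                          all_fits[[best]]$model_id))
  finish(all_fits[[best]], all_crits[[best]], FALSE)
}

#' Model-free analysis of a relaxation table
#'
#' Runs [select_model] for every residue with complete R1/R2/NOE data and
#' collects the results in the standard output layout.  Residues with a
#' missing observable are skipped with a notice.
#'
#' @param records relaxation record data frame.
#' @param tau_c global correlation time in ns.
#' @param field a [field_context].
#' @param n_sim,confidence,seed passed to [select_model].
#' @return data frame with columns `residue_id`, `model`, `S2`, `S2_err`,
#'   `te_ps`, `te_err`, `Rex`, `Rex_err`, `S2f`, `S2f_err`, `ti_ns`,
#'   `ti_err`, `chi2`, `chi2_crit`, `satisfactory`, `decision_path`.
#' @export
fit_modelfree_table <- function(records, tau_c, field, n_sim = 500,
                                confidence = 0.95, seed = 1) {
  rows <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    if (any(!is.finite(c(rec$R1, rec$R2, rec$NOE)))) {
      message("residue ", rec$residue_id, " skipped: incomplete observables")
      next
    }
    f <- select_model(rec, tau_c, field, n_sim = n_sim,
                      confidence = confidence, seed = seed)
    p <- f$params
    sd_of <- function(k) if (k <= length(f$param_sd)) f$param_sd[k] else NA_real_
    # map parameter-vector sd onto named fields by model
    S2_err <- te_err <- Rex_err <- S2f_err <- ti_err <- NA_real_
    if (f$model_id == 1) S2_err <- sd_of(1)
    if (f$model_id == 2) { S2_err <- sd_of(1); Rex_err <- sd_of(2) }
    if (f$model_id == 3) { S2_err <- sd_of(1); te_err <- sd_of(2) * 1e3 }
    if (f$model_id == 4) { S2_err <- sd_of(1); te_err <- sd_of(2) * 1e3
                           Rex_err <- sd_of(3) }
    if (f$model_id == 5) { S2f_err <- sd_of(1); ti_err <- sd_of(3)
                           S2_err <- NA_real_ }
    rows[[length(rows) + 1]] <- data.frame(
      residue_id = rec$residue_id, model = f$model_id,
      S2 = p$S2, S2_err = S2_err,
      te_ps = if (f$model_id %in% c(3, 4)) p$tau_e * 1e12 else NA_real_,
      te_err = te_err,
      Rex = if (f$model_id %in% c(2, 4)) p$R_ex else NA_real_,
      Rex_err = Rex_err,
      S2f = if (f$model_id == 5) p$S2_f else NA_real_,
      S2f_err = S2f_err,
      ti_ns = if (f$model_id == 5) p$tau_i * 1e9 else NA_real_,
      ti_err = ti_err,
      chi2 = f$chi2, chi2_crit = f$chi2_critical,
      satisfactory = f$satisfactory,
      decision_path = f$decision_path,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
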