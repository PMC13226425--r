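#' Field context for backbone amide 15N relaxation
#'
#' Collects the spectrometer- and spin-pair-dependent constants needed to
#' back-calculate 15N R1, R2 and the 1H-15N NOE: the two Larmor
#' frequencies, the squared dipolar coupling constant for the N-H pair and
#' the squared CSA constant for the 15N chemical-shift anisotropy.
#'
#' The dipolar constant is \eqn{d = (\mu_0/4\pi)\,\hbar\,\gamma_H\gamma_N /
#' r_{NH}^3} and the CSA constant \eqn{c = \omega_N\,\Delta\sigma/\sqrt{3}};
#' both enter the rate expressions squared.  The defaults (rNH = 1.02
#' Angstrom, 15N CSA = -160 ppm, gammaH/gammaN = -9.8656) are the values in
#' common use for backbone amides; recovered motional parameters shift by a
#' few percent under alternative conventions (e.g. rNH = 1.04, CSA = -172
#' ppm), so all are overridable.
#'
#' @param proton_frequency_MHz 1H Larmor frequency in MHz (default 800.13).
#' @param r_NH N-H bond length in Angstrom.
#' @param delta_sigma 15N chemical-shift anisotropy in ppm (signed).
#' @param gamma_ratio signed ratio gammaH/gammaN (dimensionless).
#'
#' @return An object of class `field_context`: a list with elements
#'   `proton_frequency`, `omega_H`, `omega_N` (rad/s, magnitudes),
#'   `gamma_ratio`, `r_NH`, `delta_sigma`, `d2` and `c2` (s^-2).
#' @examples
#' fc <- field_context(800.13)
#' fc$omega_N / fc$omega_H   # = 1 / |gammaH/gammaN|
#' @export
field_context <- function(proton_frequency_MHz = 800.13,
                          r_NH = 1.02,
                          delta_sigma = -160,
                          gamma_ratio = -9.8656) {
  stopifnot(is.finite(proton_frequency_MHz), proton_frequency_MHz > 0,
            is.finite(r_NH), r_NH > 0, is.finite(delta_sigma),
            is.finite(gamma_ratio), gamma_ratio != 0)
  mu0_over_4pi <- 1e-7        # T m / A
  hbar <- 1.054571817e-34     # J s
  gamma_H <- 2.6752218744e8   # rad s^-1 T^-1
  gamma_N <- gamma_H / gamma_ratio       # signed, negative by default
  omega_H <- 2 * pi * proton_frequency_MHz * 1e6
  omega_N <- omega_H / abs(gamma_ratio)  # magnitude
  r_m <- r_NH * 1e-10
  d <- mu0_over_4pi * hbar * gamma_H * abs(gamma_N) / r_m^3
  c_csa <- omega_N * delta_sigma * 1e-6 / sqrt(3)
  structure(list(proton_frequency = proton_frequency_MHz,
                 omega_H = omega_H, omega_N = omega_N,
                 gamma_ratio = gamma_ratio,
                 r_NH = r_NH, delta_sigma = delta_sigma,
                 d2 = d^2, c2 = c_csa^2),
            class = "field_context")
}

#' @export
print.field_context <- function(x, ...) {
  cat(sprintf("<field_context> 1H %.2f MHz | rNH %.3f A | CSA %.1f ppm | gH/gN %.4f\n",
              x$proton_frequency, x$r_NH, x$delta_sigma, x$gamma_ratio))
  cat(sprintf("  d2 = %.4e s^-2, c2 = %.4e s^-2\n", x$d2, x$c2))
  invisible(x)
}

#' Lipari-Szabo motional parameters
#'
#' Container for the per-residue parameters of the five standard motional
#' models used in model-free analysis of amide 15N relaxation:
#' \describe{
#'   \item{model 1}{order parameter S2 only}
#'   \item{model 2}{S2 + exchange contribution Rex to R2}
#'   \item{model 3}{S2 + internal correlation time tau_e}
#'   \item{model 4}{S2 + tau_e + Rex}
#'   \item{model 5}{extended two-timescale form: fast order parameter S2f
#'     (fast motion taken as infinitely fast), slow order parameter
#'     S2 = S2f * S2s, and internal time tau_i for the slow component}
#' }
#' Parameters not belonging to the chosen model must be left at their
#' defaults; supplying them is an error.
#'
#' @param model_id integer 1..5.
#' @param S2 generalized order parameter in \[0, 1\].
#' @param tau_e internal correlation time in seconds (models 3, 4).
#' @param R_ex exchange contribution in s^-1 (models 2, 4).
#' @param S2_f fast-motion order parameter in \[0, 1\] (model 5).
#' @param tau_i slow internal correlation time in seconds (model 5).
#' @return An object of class `motional_params`.
#' @examples
#' motional_params(2, S2 = 0.85, R_ex = 5)
#' @export
motional_params <- function(model_id, S2, tau_e = 0, R_ex = 0,
                            S2_f = 1, tau_i = 0) {
  stopifnot(model_id %in% 1:5,
            is.finite(S2), S2 >= 0, S2 <= 1,
            is.finite(tau_e), tau_e >= 0,
            is.finite(R_ex), R_ex >= 0,
            is.finite(S2_f), S2_f >= 0, S2_f <= 1,
            is.finite(tau_i), tau_i >= 0)
  if (model_id %in% c(1, 2) && tau_e != 0)
    stop("tau_e is not a parameter of model ", model_id)
  if (model_id %in% c(1, 3, 5) && R_ex != 0)
    stop("R_ex is not a parameter of model ", model_id)
  if (model_id != 5 && (S2_f != 1 || tau_i != 0))
    stop("S2_f/tau_i are parameters of model 5 only")
  if (model_id == 5 && S2 > S2_f)
    stop("model 5 requires S2 <= S2_f")
  structure(list(model_id = as.integer(model_id), S2 = S2, tau_e = tau_e,
                 R_ex = R_ex, S2_f = S2_f, tau_i = tau_i),
            class = "motional_params")
}

#' Model-free spectral density
#'
#' Evaluates the Lipari-Szabo spectral density J(omega) with the 2/5
#' normalization folded in.  Models 1 and 2 use the single-Lorentzian
#' rigid-amplitude form; models 3 and 4 add the (1 - S2) internal term with
#' 1/tau' = 1/tau_c + 1/tau_e; model 5 uses the extended two-timescale form
#' with amplitude (S2f - S2) and 1/tau' = 1/tau_c + 1/tau_i:
#' \deqn{J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_c}{1+(\omega\tau_c)^2} +
#'   \frac{A\,\tau'}{1+(\omega\tau')^2}\right]}
#' with A = 1 - S2 (models 3, 4), A = S2f - S2 (model 5), A = 0 otherwise.
#'
#' @param params a [motional_params] object.
#' @param tau_c global rotational correlation time in seconds (> 0).
#' @param omega angular frequency in rad/s (vectorized, >= 0).
#' @return J(omega) in s/rad, same length as `omega`.
#' @examples
#' p <- motional_params(1, S2 = 1)
#' spectral_density(p, tau_c = 2.5e-9, omega = 0)  # 0.4 * 2.5 ns = 1 ns
#' @export
spectral_density <- function(params, tau_c, omega) {
  stopifnot(inherits(params, "motional_params"))
  if (!is.finite(tau_c) || tau_c <= 0) stop("tau_c must be finite and > 0")
  if (any(!is.finite(omega)) || any(omega < 0))
    stop("omega must be finite and >= 0")
  J <- 0.4 * params$S2 * tau_c / (1 + (omega * tau_c)^2)
  if (params$model_id %in% c(3, 4) && params$tau_e > 0) {
    tp <- 1 / (1 / tau_c + 1 / params$tau_e)
    J <- J + 0.4 * (1 - params$S2) * tp / (1 + (omega * tp)^2)
  } else if (params$model_id == 5 && params$tau_i > 0) {
    tp <- 1 / (1 / tau_c + 1 / params$tau_i)
    J <- J + 0.4 * (params$S2_f - params$S2) * tp / (1 + (omega * tp)^2)
  }
  J
}

#' Back-calculate 15N relaxation rates from motional parameters
#'
#' Standard dipolar + CSA expressions for an amide 15N spin relaxed by the
#' attached proton:
#' \deqn{R_1 = \tfrac{d^2}{4}[J(\omega_H-\omega_N) + 3J(\omega_N) +
#'       6J(\omega_H+\omega_N)] + c^2 J(\omega_N)}
#' \deqn{R_2 = \tfrac{d^2}{8}[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N) +
#'       6J(\omega_H) + 6J(\omega_H+\omega_N)] +
#'       \tfrac{c^2}{6}[4J(0) + 3J(\omega_N)] + R_{ex}}
#' \deqn{NOE = 1 + \tfrac{d^2}{4}\,\frac{\gamma_H}{\gamma_N}\,\frac{1}{R_1}
#'       [6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)]}
#'
#' @param params a [motional_params] object.
#' @param tau_c global correlation time in seconds.
#' @param field a [field_context].
#' @return list with elements `R1`, `R2` (s^-1) and `NOE` (dimensionless).
#' @examples
#' fc <- field_context(800.13)
#' back_calculate_rates(motional_params(1, S2 = 0.85), 6.6e-9, fc)
#' @export
back_calculate_rates <- function(params, tau_c, field) {
  stopifnot(inherits(field, "field_context"))
  wH <- field$omega_H; wN <- field$omega_N
  w <- c(0, wN, wH - wN, wH, wH + wN)
  J <- spectral_density(params, tau_c, w)
  J0 <- J[1]; JN <- J[2]; Jm <- J[3]; JH <- J[4]; Jp <- J[5]
  d2 <- field$d2; c2 <- field$c2
  R1 <- d2 / 4 * (Jm + 3 * JN + 6 * Jp) + c2 * JN
  R2 <- d2 / 8 * (4 * J0 + Jm + 3 * JN + 6 * JH + 6 * Jp) +
    c2 / 6 * (4 * J0 + 3 * JN) + params$R_ex
  NOE <- 1 + d2 / 4 * field$gamma_ratio * (6 * Jp - Jm) / R1
  list(R1 = R1, R2 = R2, NOE = NOE)
}
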