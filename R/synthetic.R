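# Synthetic-data generators.
#
# Every input the analysis pipeline consumes can be generated here with
# the statistical structure the analysis assumes, so every stage is
# testable offline.  All generators take an explicit seed, use a local
# RNG stream and are bit-reproducible; observables always come with a
# ground-truth table read only at assertion time in recovery tests.

#' Generate a noisy mono-exponential decay series
#'
#' volumes = v0 * exp(-rate * t) * (1 + eps), eps ~ Normal(0, noise_frac).
#'
#' @param rate decay rate in s^-1 (> 0).
#' @param delays relaxation delays in seconds.
#' @param v0 initial volume (default 100).
#' @param noise_frac multiplicative Gaussian noise sigma (default 0).
#' @param seed integer seed.
#' @return data frame with `delay_s`, `volume`.
#' @export
gen_decay <- function(rate, delays, v0 = 100, noise_frac = 0, seed = 1) {
  stopifnot(rate > 0, all(is.finite(delays)), noise_frac >= 0)
  with_seed(seed, {
    eps <- stats::rnorm(length(delays), 0, noise_frac)
    data.frame(delay_s = delays, volume = v0 * exp(-rate * delays) * (1 + eps))
  })
}

#' Synthetic per-residue motional profile of a small rigid domain
#'
#' Describes the study conditions the relaxation generator emulates: a
#' rigid core (S2 about 0.85), highly mobile termini whose fast
#' large-amplitude motion produces negative heteronuclear NOEs at 800
#' MHz, and an exchange-broadened loop carrying Rex of several s^-1.
#' Defaults mimic a ~100-residue IgI domain tumbling at 6.6 ns with
#' disordered tails (residues 1-6 and 96-102) and an exchanging EF-loop
#' (residues 73-77); rate noise is 2 percent, NOE noise 0.02 absolute.
#' Termini use S2 = 0.15 with tau_e = 400 ps, which at 800 MHz puts their
#' back-calculated NOE below zero (a longer tau_e of about 1 ns would
#' leave the NOE positive at this field).
#'
#' @param n_residues chain length.
#' @param core_S2_mean,core_S2_sd Gaussian S2 for core residues.
#' @param termini_ranges list of residue-number vectors for the tails.
#' @param termini_S2,termini_tau_e tail parameters (tau_e in seconds).
#' @param rex_range residue numbers of the exchange-broadened loop.
#' @param rex_S2_mean,rex_S2_sd loop S2 distribution.
#' @param rex_limits uniform range of loop Rex in s^-1.
#' @param tau_c global correlation time in ns.
#' @param field_MHz 1H frequency.
#' @param noise_rate_frac fractional sigma for R1 and R2.
#' @param noise_noe_abs absolute sigma for the NOE.
#' @return list of class `synthetic_profile`.
#' @export
synthetic_profile <- function(n_residues = 102,
                              core_S2_mean = 0.85, core_S2_sd = 0.03,
                              termini_ranges = list(1:6, 96:102),
                              termini_S2 = 0.15, termini_tau_e = 0.4e-9,
                              rex_range = 73:77,
                              rex_S2_mean = 0.80, rex_S2_sd = 0.02,
                              rex_limits = c(3, 10),
                              tau_c = 6.6, field_MHz = 800.13,
                              noise_rate_frac = 0.02, noise_noe_abs = 0.02) {
  ranges <- unlist(termini_ranges)
  stopifnot(all(ranges >= 1), all(ranges <= n_residues),
            all(rex_range >= 1), all(rex_range <= n_residues),
            noise_rate_frac >= 0, noise_noe_abs >= 0, tau_c > 0)
  structure(as.list(environment()), class = "synthetic_profile")
}

#' Generate a synthetic relaxation dataset with ground truth
#'
#' Draws per-residue motional parameters region by region from a
#' [synthetic_profile], back-calculates R1/R2/NOE through the model-free
#' spectral densities, adds noise, and returns the observed records next
#' to the generating truth.
#'
#' @param profile a [synthetic_profile].
#' @param seed integer seed.
#' @return list with `records` (relaxation record data frame with the
#'   true noise sigmas as the error columns) and `truth` (per-residue
#'   `region`, `model`, `S2`, `tau_e`, `Rex` and noiseless rates).
#' @export
gen_relaxation_dataset <- function(profile, seed = 1) {
  stopifnot(inherits(profile, "synthetic_profile"))
  fc <- field_context(profile$field_MHz)
  tc_s <- profile$tau_c * 1e-9
  termini <- unlist(profile$termini_ranges)
  with_seed(seed, {
    n <- profile$n_residues
    truth <- data.frame(residue_id = 1:n, region = "core", model = 1L,
                        S2 = NA_real_, tau_e = 0, Rex = 0,
                        R1_true = NA_real_, R2_true = NA_real_,
                        NOE_true = NA_real_, stringsAsFactors = FALSE)
    rec <- data.frame(residue_id = 1:n, R1 = NA_real_, R1_err = NA_real_,
                      R2 = NA_real_, R2_err = NA_real_,
                      NOE = NA_real_, NOE_err = NA_real_)
    for (i in 1:n) {
      if (i %in% termini) {
        truth$region[i] <- "terminus"; truth$model[i] <- 3L
        truth$S2[i] <- profile$termini_S2
        truth$tau_e[i] <- profile$termini_tau_e
        p <- motional_params(3, S2 = truth$S2[i], tau_e = truth$tau_e[i])
      } else if (i %in% profile$rex_range) {
        truth$region[i] <- "rex_loop"; truth$model[i] <- 2L
        truth$S2[i] <- min(1, max(0, stats::rnorm(1, profile$rex_S2_mean,
                                                  profile$rex_S2_sd)))
        truth$Rex[i] <- stats::runif(1, profile$rex_limits[1],
                                     profile$rex_limits[2])
        p <- motional_params(2, S2 = truth$S2[i], R_ex = truth$Rex[i])
      } else {
        truth$S2[i] <- min(1, max(0, stats::rnorm(1, profile$core_S2_mean,
                                                  profile$core_S2_sd)))
        p <- motional_params(1, S2 = truth$S2[i])
      }
      r <- back_calculate_rates(p, tc_s, fc)
      truth$R1_true[i] <- r$R1; truth$R2_true[i] <- r$R2
      truth$NOE_true[i] <- r$NOE
      rec$R1_err[i] <- profile$noise_rate_frac * r$R1
      rec$R2_err[i] <- profile$noise_rate_frac * r$R2
      rec$NOE_err[i] <- profile$noise_noe_abs
      rec$R1[i] <- r$R1 + stats::rnorm(1, 0, rec$R1_err[i])
      rec$R2[i] <- r$R2 + stats::rnorm(1, 0, rec$R2_err[i])
      rec$NOE[i] <- r$NOE + stats::rnorm(1, 0, rec$NOE_err[i])
    }
    list(records = rec, truth = truth)
  })
}

# one residue of the toy scaffold: idealized local frame around a CA
toy_residue_atoms <- function(resno, ca, flip = 1) {
  offs <- rbind(N = c(-1.2, 0.5 * flip, 0),
                CA = c(0, 0, 0),
                C = c(1.2, 0.5 * flip, 0),
                O = c(1.2, 1.7 * flip, 0),
                H = c(-1.2, 1.45 * flip, 0.2),
                HA = c(0, -0.7 * flip, 0.8))
  data.frame(chain = "A", resno = resno, resname = "ALA",
             atom = rownames(offs),
             element = substr(rownames(offs), 1, 1),
             x = ca[1] + offs[, 1], y = ca[2] + offs[, 2],
             z = ca[3] + offs[, 3], stringsAsFactors = FALSE)
}

# CA trace of the toy hairpin; loop_sign bends the 5-residue loop toward
# (-1) or away from (+1) the first strand
toy_ca_trace <- function(loop_sign) {
  ca <- matrix(NA_real_, 25, 3)
  for (i in 1:10) ca[i, ] <- c(3.5 * (i - 1), 0, 0)
  for (i in 16:25) ca[i, ] <- c(3.5 * (25 - i), 8, 0)
  for (i in 11:15) {
    t <- (i - 10) / 6
    w <- sin(pi * t)
    ca[i, ] <- c(33.5 + 4 * w, 8 * t + loop_sign * 2.8 * w, 0)
  }
  ca
}

#' Generate a toy two-conformer ensemble with conformer-specific restraints
#'
#' Builds a polyalanine-like hairpin scaffold (25 residues: two strands
#' and a 5-residue loop, residues 11-15) whose loop sits near the first
#' strand in the IN conformer and bulges toward the second strand in the
#' OUT conformer; the central loop CA moves by well over 2 Angstrom
#' between the two.  Proton-pair distance restraints are derived from the
#' ideal (first-model) coordinates with upper bounds = true distance +
#' 0.2 Angstrom: the conformer-specific sets are chosen so each is
#' satisfied only in its own ensemble at the 0.3 Angstrom tolerance, and
#' the shared set is satisfied in both.  Remaining models carry small
#' Gaussian coordinate jitter so the non-loop ensemble spread stays below
#' 0.1 Angstrom.
#'
#' @param seed integer seed.
#' @param n_models models per ensemble (default 5).
#' @param jitter coordinate jitter sigma in Angstrom for models 2..n.
#' @return list with `ensIN`, `ensOUT` (`structure_ensemble`),
#'   `shared_restraints`, `in_restraints`, `out_restraints` (restraint
#'   data frames with `tag` set), and `loop_residues`.
#' @export
gen_two_conformer_ensemble <- function(seed = 1, n_models = 5,
                                       jitter = 0.02) {
  build <- function(loop_sign) {
    ca <- toy_ca_trace(loop_sign)
    rows <- do.call(rbind, lapply(1:25, function(i)
      toy_residue_atoms(i, ca[i, ], flip = if (i >= 16) -1 else 1)))
    rows
  }
  atIN <- build(-1)
  atOUT <- build(+1)
  to_ens <- function(at, id, seed_off) {
    base <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
    with_seed(seed + seed_off, {
      xyz <- matrix(NA_real_, n_models, length(base))
      xyz[1, ] <- base
      if (n_models > 1)
        for (m in 2:n_models)
          xyz[m, ] <- base + stats::rnorm(length(base), 0, jitter)
      structure_ensemble(at[, c("chain", "resno", "resname", "atom",
                                "element")], xyz, source_id = id)
    })
  }
  ensIN <- to_ens(atIN, "toyIN", 101)
  ensOUT <- to_ens(atOUT, "toyOUT", 202)
  # candidate HA-HA pairs between loop and strand residues, measured on
  # the ideal models
  dist_of <- function(at, r1, r2) {
    a <- which(at$resno == r1 & at$atom == "HA")
    b <- which(at$resno == r2 & at$atom == "HA")
    sqrt(sum((as.numeric(at[a, c("x", "y", "z")]) -
                as.numeric(at[b, c("x", "y", "z")]))^2))
  }
  loop <- 11:15
  strands <- c(1:10, 16:25)
  cand <- rbind(expand.grid(res1 = loop, res2 = strands),
                # cross-strand pairs: untouched by the loop flip, so
                # their distances agree between conformers (shared set)
                data.frame(res1 = 1:10, res2 = 25:16))
  cand$d_in <- mapply(dist_of, cand$res1, cand$res2,
                      MoreArgs = list(at = atIN))
  cand$d_out <- mapply(dist_of, cand$res1, cand$res2,
                       MoreArgs = list(at = atOUT))
  mk <- function(rows, upper, tag) {
    if (!nrow(rows)) stop("toy construction produced no ", tag, " restraints")
    data.frame(res1 = rows$res1, atom1 = "HA", res2 = rows$res2,
               atom2 = "HA", upper_A = round(upper, 2), tag = tag,
               stringsAsFactors = FALSE)
  }
  sel_in <- cand[cand$d_in < 7 & cand$d_out > cand$d_in + 0.8, ]
  sel_in <- sel_in[order(sel_in$d_in), ][seq_len(min(6, nrow(sel_in))), ]
  sel_out <- cand[cand$d_out < 7 & cand$d_in > cand$d_out + 0.8, ]
  sel_out <- sel_out[order(sel_out$d_out), ][seq_len(min(6, nrow(sel_out))), ]
  shared <- cand[abs(cand$d_in - cand$d_out) < 0.05 &
                   pmin(cand$d_in, cand$d_out) < 10, ]
  shared <- shared[seq_len(min(6, nrow(shared))), ]
  list(ensIN = ensIN, ensOUT = ensOUT,
       shared_restraints = mk(shared, pmax(shared$d_in, shared$d_out) + 0.2,
                              "shared"),
       in_restraints = mk(sel_in, sel_in$d_in + 0.2, "IN"),
       out_restraints = mk(sel_out, sel_out$d_out + 0.2, "OUT"),
       loop_residues = loop)
}

#' Generate a synthetic proline Cbeta/Cgamma shift table
#'
#' Draws Cbeta - Cgamma differences from the trans (4.51 +- 1.37 ppm) and
#' cis (9.64 +- 1.62 ppm) Normal populations.
#'
#' @param n_trans,n_cis numbers of prolines per class (>= 0).
#' @param seed integer seed.
#' @return list with `shifts` (rows `residue_number`, `residue_name`,
#'   `atom_name`, `ppm`: one CB and one CG row per proline) and `truth`
#'   (`residue_number`, `isomer`).
#' @export
gen_shift_table <- function(n_trans, n_cis, seed = 1) {
  stopifnot(n_trans >= 0, n_cis >= 0)
  n <- n_trans + n_cis
  empty <- data.frame(residue_number = integer(), residue_name = character(),
                      atom_name = character(), ppm = numeric(),
                      stringsAsFactors = FALSE)
  if (n == 0) return(list(shifts = empty,
                          truth = data.frame(residue_number = integer(),
                                             isomer = character())))
  with_seed(seed, {
    isomer <- sample(c(rep("trans", n_trans), rep("cis", n_cis)))
    cb <- stats::rnorm(n, 31.8, 0.5)
    delta <- ifelse(isomer == "trans", stats::rnorm(n, 4.51, 1.37),
                    stats::rnorm(n, 9.64, 1.62))
    shifts <- rbind(
      data.frame(residue_number = 1:n, residue_name = "PRO",
                 atom_name = "CB", ppm = cb, stringsAsFactors = FALSE),
      data.frame(residue_number = 1:n, residue_name = "PRO",
                 atom_name = "CG", ppm = cb - delta, stringsAsFactors = FALSE))
    shifts <- shifts[order(shifts$residue_number), ]
    rownames(shifts) <- NULL
    list(shifts = shifts,
         truth = data.frame(residue_number = 1:n, isomer = isomer,
                            stringsAsFactors = FALSE))
  })
}
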