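#' Model parameters for arrest laws and telomere shortening
#'
#' Bundles every constant of the senescence model: the three
#' shortest-telomere-dependent arrest laws (non-terminal arrest `nta`,
#' terminal senescence of type-A and of type-B cells), the hard length
#' thresholds below which arrest is certain, the geometric exit
#' probabilities of arrest sequences, the telomere-independent accidental
#' death probability, the replication overhang and the long-cycle duration
#' threshold.
#'
#' Each arrest law has the form
#' \deqn{p(\ell) = \min(1, b e^{-a \ell}) \textrm{ for } \ell > \ell_{min},
#'       \qquad p(\ell) = 1 \textrm{ for } \ell \le \ell_{min},}
#' where \eqn{\ell} is the length (bp) of the shortest telomere of the cell
#' after replication.  Defaults are the values fitted on telomerase-negative
#' single-cell microfluidics data.
#'
#' @param a_nta,b_nta rate (1/bp) and scale of the non-terminal-arrest law.
#' @param a_sen_A,b_sen_A rate and scale of the type-A senescence-onset law.
#' @param a_sen_B,b_sen_B rate and scale of the type-B senescence-onset law
#'   (`a_sen_B = 0` makes it independent of telomere length).
#' @param l_min_A,l_min_B hard thresholds (bp): at or below them senescence
#'   onset is certain for type A / type B cells.
#' @param p_accident per-division probability of telomere-independent
#'   (accidental) death, applied to every daughter cell.
#' @param p_repair per-cycle probability that a non-terminal arrest sequence
#'   ends (repair or adaptation), returning the cell to normal cycles.
#' @param p_death per-cycle probability that a senescent cell's arrest
#'   sequence ends in death; the number of consecutive senescent cycles is
#'   geometric with this success probability.
#' @param h replication overhang (bp): the fixed amount removed from exactly
#'   one telomere per chromosome per division.
#' @param D duration threshold (minutes) separating normal from abnormally
#'   long cell cycles.
#'
#' @return An object of class `law_params` (a validated named list).
#' @examples
#' p <- law_params()
#' p$l_min_A            # 27 bp
#' arrest_probability(p$a_nta, p$b_nta, 0, l = 50)
#' @export
law_params <- function(a_nta = 0.02, b_nta = 0.44,
                       a_sen_A = 0.19, b_sen_A = 0.73,
                       a_sen_B = 0, b_sen_B = 0.12,
                       l_min_A = 27, l_min_B = 0,
                       p_accident = 4.3e-3,
                       p_repair = 0.65,
                       p_death = 0.58,
                       h = 7, D = 180) {
  p <- list(a_nta = a_nta, b_nta = b_nta,
            a_sen_A = a_sen_A, b_sen_A = b_sen_A,
            a_sen_B = a_sen_B, b_sen_B = b_sen_B,
            l_min_A = l_min_A, l_min_B = l_min_B,
            p_accident = p_accident, p_repair = p_repair,
            p_death = p_death, h = h, D = D)
  validate_law_params(p)
  structure(p, class = "law_params")
}

validate_law_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("law_params: `", nm, "` must be a single finite number")
    if (p[[nm]] < 0) stop("law_params: `", nm, "` must be non-negative")
  }
  for (nm in c("p_accident", "p_repair", "p_death")) {
    if (p[[nm]] > 1) stop("law_params: `", nm, "` must lie in [0, 1]")
  }
  if (p$D <= 0) stop("law_params: `D` must be positive")
  invisible(p)
}

#' @export
print.law_params <- function(x, ...) {
  cat("Senescence model parameters\n")
  cat(sprintf("  nta law:    p(l) = min(1, %.3g exp(-%.3g l))\n", x$b_nta, x$a_nta))
  cat(sprintf("  sen-A law:  p(l) = min(1, %.3g exp(-%.3g l)), 1 for l <= %g bp\n",
              x$b_sen_A, x$a_sen_A, x$l_min_A))
  cat(sprintf("  sen-B law:  p(l) = min(1, %.3g exp(-%.3g l)), 1 for l <= %g bp\n",
              x$b_sen_B, x$a_sen_B, x$l_min_B))
  cat(sprintf("  p_accident = %.4g, p_repair = %.3g, p_death = %.3g\n",
              x$p_accident, x$p_repair, x$p_death))
  cat(sprintf("  overhang h = %g bp, long-cycle threshold D = %g min\n", x$h, x$D))
  invisible(x)
}

#' Serial-dilution population experiment configuration
#'
#' Describes the daily saturation--dilution culture protocol: `N_init`
#' founder cells, growth frozen when the living count reaches
#' `N_sat = r_sat * N_init`, and dilution every 24 h down to `N_dil` cells
#' sampled uniformly without replacement.
#'
#' @param n_init number of founder cells seeded at telomerase inactivation
#'   (and re-seeded at each dilution through `n_dil`).
#' @param r_sat saturation ratio; the culture stops dividing at
#'   `n_sat = r_sat * n_init` cells until the next dilution.
#' @param n_dil cells kept at each dilution (defaults to `n_init`).
#' @param n_days number of 24-h culture days to simulate.
#' @param ancestry_bins number of equal-sized founder bins (by founder
#'   shortest telomere) used for ancestry tracking.
#' @return An object of class `experiment_config`.
#' @examples
#' experiment_config(n_init = 300, r_sat = 1000, n_days = 8)
#' @export
experiment_config <- function(n_init = 300, r_sat = 1000, n_dil = n_init,
                              n_days = 10, ancestry_bins = 10) {
  stopifnot(n_init >= 1, r_sat > 1, n_dil >= 1, n_days >= 1, ancestry_bins >= 1)
  n_sat <- r_sat * n_init
  if (n_dil > n_sat) stop("experiment_config: n_dil must not exceed n_sat")
  structure(list(n_init = as.integer(n_init), r_sat = r_sat,
                 n_dil = as.integer(n_dil), n_sat = as.integer(round(n_sat)),
                 n_days = as.integer(n_days),
                 dilution_period_h = 24,
                 ancestry_bins = as.integer(ancestry_bins)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Population experiment: N_init = %d, N_sat = %d (r_sat = %g), N_dil = %d\n",
              x$n_init, x$n_sat, x$r_sat, x$n_dil))
  cat(sprintf("  %d days, dilution every %g h, %d ancestry bins\n",
              x$n_days, x$dilution_period_h, x$ancestry_bins))
  invisible(x)
}
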