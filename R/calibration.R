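#' Specification of a calibration fit
#'
#' Defines the ten free parameters inferred from lineage data — the three
#' arrest-law pairs (`a_nta`, `b_nta`, `a_sen_A`, `b_sen_A`, `a_sen_B`,
#' `b_sen_B`), the two hard thresholds (`l_min_A`, `l_min_B`) and the two
#' initial-distribution dilation parameters (`l_0`, `l_1`) — with their
#' box bounds and the simulation effort per candidate evaluation.
#'
#' @param n_lineages simulated lineages per candidate evaluation.  The
#'   default is deliberately large: on this rugged, simulation-noisy
#'   landscape, high-fidelity evaluations prevent noise-induced false
#'   minima far more effectively than averaging repeats of small batches.
#' @param n_repeats independent repeats per candidate; the cost is averaged
#'   over repeats.
#' @param budget maximum number of cost evaluations for the optimizer.
#' @param lambda CMA-ES population size.  The default 14 is larger than
#'   Hansen's `4 + floor(3 log n)` rule: on this rugged simulation-noisy
#'   landscape, bigger populations escape the threshold-mimicking local
#'   minima far more reliably.
#' @param sigma0 initial CMA-ES step size in normalized [0, 1] coordinates.
#' @param seed seed for the whole fit (bit-for-bit reproducible).
#' @param rate_upper upper bound for the law rate/scale parameters (`a`,
#'   `b`); probabilities-scale quantities, bounded in `[0, rate_upper]`.
#' @param length_upper upper bound (bp) for `l_min_A`, `l_min_B`, `l_1`.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(n_lineages = 600, n_repeats = 1, budget = 3000,
                     lambda = 14, sigma0 = 0.3, seed = 1,
                     rate_upper = 1, length_upper = 200) {
  stopifnot(n_lineages >= 1, n_repeats >= 1, budget >= 10)
  structure(list(n_lineages = as.integer(n_lineages),
                 n_repeats = as.integer(n_repeats),
                 budget = as.integer(budget), lambda = lambda,
                 sigma0 = sigma0, seed = as.integer(seed),
                 rate_upper = rate_upper, length_upper = length_upper),
            class = "fit_spec")
}

.free_param_names <- c("a_nta", "b_nta", "a_sen_A", "b_sen_A",
                       "a_sen_B", "b_sen_B", "l_min_A", "l_min_B",
                       "l_0", "l_1")

#' Distance between two sets of arrest-generation curves
#'
#' The calibration cost: for each curve category (`nta`, `sen_A`, `sen_B`,
#' `sen`), both sorted generation curves are resampled by quantile onto a
#' common rank grid and compared by mean squared difference; a
#' squared-difference penalty on the observed type-B proportion (carried
#' as an attribute by [arrest_generation_curves()]) is added.  A category
#' empty in the target is skipped with a warning; a category empty in the
#' simulation (the candidate produces no such events) is scored against a
#' zero curve.  Deterministic given its inputs, and pluggable: any
#' function of `(simulated, target)` can replace it in
#' [fit_parameters()].
#'
#' @param simulated,target curve sets from [arrest_generation_curves()].
#' @param n_grid number of rank-grid points.
#' @param prop_weight weight of the type-B-proportion penalty (a
#'   proportion error of 0.1 then costs as much as a uniform curve error
#'   of `sqrt(prop_weight)/10` generations).
#' @return Non-negative scalar.
#' @export
curve_cost <- function(simulated, target, n_grid = 50, prop_weight = 1000) {
  probs <- (seq_len(n_grid) - 0.5) / n_grid
  total <- 0
  for (cat in c("nta", "sen_A", "sen_B", "sen")) {
    tg <- target[[cat]]
    if (!length(tg)) {
      warning("curve_cost: target category `", cat, "` is empty; skipped",
              call. = FALSE)
      next
    }
    sm <- simulated[[cat]]
    if (!length(sm)) sm <- 0
    qt <- stats::quantile(tg, probs, names = FALSE, type = 7)
    qs <- stats::quantile(sm, probs, names = FALSE, type = 7)
    total <- total + mean((qs - qt)^2)
  }
  pb_s <- attr(simulated, "prop_B"); pb_t <- attr(target, "prop_B")
  if (!is.null(pb_s) && !is.null(pb_t))
    total <- total + prop_weight * (pb_s - pb_t)^2
  total
}

#' Fit the arrest laws to arrest-generation curves by CMA-ES
#'
#' Infers the ten free model parameters from target arrest-generation
#' curves (experimental, or synthetic with known ground truth for
#' parameter-recovery validation).  Each CMA-ES candidate is evaluated by
#' simulating `n_repeats` batches of `n_lineages` lineages under the
#' candidate parameters and averaging `cost_fn` between the simulated and
#' target curves.  The search runs in normalized [0, 1] coordinates mapped
#' onto the parameter bounds; the exponential-rate coordinates (`a_nta`,
#' `a_sen_A`, `a_sen_B`) are cube-warped (`x = upper * z^3`) because their
#' effective scale is far below their bound — with telomere lengths of
#' tens to hundreds of bp, any rate above ~0.1/bp behaves as a hard
#' threshold, and a linear parameterization wastes most of the search
#' space on that degenerate regime.  Thresholds are optimized on a
#' continuous scale and rounded to integer bp in the returned estimate.
#'
#' Note an intrinsic identifiability limit of fitting to duration-derived
#' curves alone: jointly raising the left-dilation `l_0` (and thus every
#' cell's shortest-telomere trajectory) while rescaling the law scales
#' `b` by the matching exponential factor leaves all arrest-generation
#' distributions almost unchanged, so the absolute positions of `l_min_A`
#' and `l_0` are mutually constrained only through second-order shape
#' effects of the initial-length order statistics.  Telomere-length
#' measurements, which anchor the initial distribution independently, are
#' what breaks this degeneracy in practice.
#'
#' @param target curve set from [arrest_generation_curves()].
#' @param spec a [fit_spec()].
#' @param params baseline [law_params()] supplying the non-fitted
#'   constants (`p_accident`, `p_repair`, `p_death`, `h`, `D`).
#' @param dist base [initial_distribution()]; its `l_0`, `l_1` are
#'   replaced by each candidate's values.
#' @param bank a [duration_bank()].
#' @param cost_fn cost function of `(simulated, target)`; defaults to
#'   [curve_cost()].
#' @param max_generations lineage safety cap per simulation.
#' @return List with `par` (named vector of the ten fitted parameters,
#'   thresholds rounded to integer bp), `value` (best cost), `trace`
#'   (best-so-far cost per generation, non-increasing), `n_evals` and
#'   `converged`.
#' @export
fit_parameters <- function(target, spec = fit_spec(),
                           params = law_params(),
                           dist = initial_distribution(),
                           bank = synthetic_duration_bank(),
                           cost_fn = curve_cost,
                           max_generations = 200L) {
  stopifnot(inherits(spec, "fit_spec"))
  if (!length(target$sen)) stop("fit_parameters: target has no senescence curve")
  lw <- rep(0, 10)
  up <- c(rep(spec$rate_upper, 6),
          spec$length_upper, spec$length_upper,
          min(spec$length_upper, dist$l_mode - dist$l_inf - 1),
          spec$length_upper)
  names(lw) <- names(up) <- .free_param_names

  rate_idx <- c(1L, 3L, 5L)   # a_nta, a_sen_A, a_sen_B: cube-warped
  to_params <- function(z) {
    z[rate_idx] <- z[rate_idx]^3
    x <- lw + z * (up - lw)
    names(x) <- .free_param_names
    x
  }
  objective <- function(z) {
    x <- to_params(z)
    cand_params <- update_params(params,
      a_nta = x[["a_nta"]], b_nta = x[["b_nta"]],
      a_sen_A = x[["a_sen_A"]], b_sen_A = x[["b_sen_A"]],
      a_sen_B = x[["a_sen_B"]], b_sen_B = x[["b_sen_B"]],
      l_min_A = x[["l_min_A"]], l_min_B = x[["l_min_B"]])
    cand_dist <- update_distribution(dist, l_0 = x[["l_0"]], l_1 = x[["l_1"]])
    costs <- vapply(seq_len(spec$n_repeats), function(r) {
      recs <- simulate_lineages(spec$n_lineages, cand_params, cand_dist,
                                bank, max_generations)
      suppressWarnings(cost_fn(arrest_generation_curves(recs), target))
    }, numeric(1))
    mean(costs)
  }

  set.seed(spec$seed)
  res <- cma_es(objective, rep(0.5, 10), spec$sigma0, lower = 0, upper = 1,
                budget = spec$budget, lambda = spec$lambda)
  par <- to_params(res$par)
  par[c("l_min_A", "l_min_B")] <- round(par[c("l_min_A", "l_min_B")])
  list(par = par, value = res$value, trace = res$trace,
       n_evals = res$n_evals, converged = res$converged)
}
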