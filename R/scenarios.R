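#' @keywords internal
#' Rebuild an initial distribution with some transform parameters replaced.
update_distribution <- function(dist, l_trans = dist$l_trans,
                                l_0 = dist$l_0, l_1 = dist$l_1) {
  initial_distribution(l_inf = dist$l_inf, l_mode = dist$l_mode,
                       l_sup = dist$l_sup, l_trans = l_trans,
                       l_0 = l_0, l_1 = l_1,
                       concentration = dist$concentration,
                       base_sample = dist$base_sample)
}

#' @keywords internal
#' Rebuild law parameters with some entries replaced.
update_params <- function(params, ...) {
  do.call(law_params, utils::modifyList(unclass(params), list(...)))
}

# Paired-seed replicate runner shared by the scans: replicate i of every
# condition starts from seed `seed + i`, so conditions are coupled (same
# founder quantiles, same early dynamics) and condition differences
# isolate the parameter effect.
.run_conditions <- function(conditions, config, bank, n_replicates, seed,
                            stop_frac = 0.5) {
  n_cond <- length(conditions)
  hsl <- matrix(NA_real_, n_replicates, n_cond)
  telo <- array(NA_real_, c(n_replicates, n_cond, config$n_days))
  for (i in seq_len(n_replicates)) {
    for (j in seq_len(n_cond)) {
      set.seed(seed + i)
      run <- run_population_experiment(
        config, conditions[[j]]$params, conditions[[j]]$dist, bank,
        stop_below = stop_frac * config$n_sat)
      hsl[i, j] <- as.numeric(compute_hsl(run$end_counts, config$n_sat))
      telo[i, j, seq_len(run$n_days_run)] <- run$snapshots$telo_mean
    }
  }
  list(hsl = hsl, telo = telo)
}

#' Translation scan of the initial telomere-length distribution
#'
#' Shifts the whole initial telomere-length distribution by each `delta`
#' (signed bp, added to `l_trans`) and measures the effect on the
#' half-saturation time (HSL) of daily-diluted populations.  Replicates
#' are paired by seed across conditions, and `delta = 0` (the unshifted
#' control) is always included, so the reported `delta_hsl_h` is the mean
#' paired HSL difference against control.
#'
#' @param deltas signed translations in bp.
#' @param config an [experiment_config()].
#' @param params a [law_params()].
#' @param dist the control [initial_distribution()].
#' @param bank a [duration_bank()].
#' @param n_replicates paired replicates per condition (>= 3).
#' @param seed base seed; replicate `i` of every condition uses
#'   `seed + i`.
#' @return List with `table` (one row per delta: `delta`, `mean_hsl_h`,
#'   `sd_hsl_h`, `delta_hsl_h`, `n_censored`), `hsl` (replicate x condition
#'   matrix) and `telo_mean` (condition x day matrix of day-wise mean
#'   telomere length, averaged over replicates).
#' @export
run_translation_scan <- function(deltas, config = experiment_config(),
                                 params = law_params(),
                                 dist = initial_distribution(),
                                 bank = synthetic_duration_bank(),
                                 n_replicates = 10, seed = 1) {
  if (n_replicates < 3) stop("run_translation_scan: need >= 3 replicates")
  deltas <- sort(unique(c(0, deltas)))
  conds <- lapply(deltas, function(d)
    list(params = params,
         dist = update_distribution(dist, l_trans = dist$l_trans + d)))
  res <- .run_conditions(conds, config, bank, n_replicates, seed)
  .scan_table(deltas, "delta", res, control = which(deltas == 0))
}

#' Left-tail (shortest-telomere) dilation scan
#'
#' Varies only the left-dilation parameter `l_0`, i.e. the distribution of
#' the shortest initial telomere lengths, leaving the mode and the right
#' half of the distribution untouched.  Same paired-seed protocol as
#' [run_translation_scan()]; the control condition is the distribution's
#' own `l_0`.
#'
#' @param l0_values values of `l_0` (bp); each must be below
#'   `l_mode - l_inf`.
#' @inheritParams run_translation_scan
#' @return As [run_translation_scan()], with column `l_0`.
#' @export
run_left_tail_scan <- function(l0_values, config = experiment_config(),
                               params = law_params(),
                               dist = initial_distribution(),
                               bank = synthetic_duration_bank(),
                               n_replicates = 10, seed = 1) {
  if (n_replicates < 3) stop("run_left_tail_scan: need >= 3 replicates")
  l0_values <- sort(unique(c(dist$l_0, l0_values)))
  conds <- lapply(l0_values, function(v)
    list(params = params, dist = update_distribution(dist, l_0 = v)))
  res <- .run_conditions(conds, config, bank, n_replicates, seed)
  .scan_table(l0_values, "l_0", res, control = which(l0_values == dist$l_0))
}

#' Telomere-independent mortality scan
#'
#' Multiplies the constant accidental-death probability `p_accident` and
#' measures either the population half-saturation time (HSL) per mortality
#' level (`mode = "population"`), or the median generation of senescence
#' onset over simulated single-cell lineage experiments
#' (`mode = "lineage"`, mirroring the microfluidics setting; the rad51
#' deletion scenario corresponds to a mortality of 5.4% with experiments
#' of 11 lineages each).
#'
#' @param multipliers multiplicative factors applied to `p_accident`
#'   (multiplier 1 is always included as control).
#' @param mode `"population"` or `"lineage"`.
#' @param n_lineages lineages per virtual experiment (lineage mode).
#' @param n_experiments virtual experiments per level (lineage mode).
#' @inheritParams run_translation_scan
#' @return Population mode: as [run_translation_scan()] with columns
#'   `multiplier` and `p_accident`.  Lineage mode: data frame with one row
#'   per level: `multiplier`, `p_accident`, `median_onset_gen` (median over
#'   experiments of the per-experiment median senescence-onset generation),
#'   `q025`, `q975`.
#' @export
run_mortality_scan <- function(multipliers, config = experiment_config(),
                               params = law_params(),
                               dist = initial_distribution(),
                               bank = synthetic_duration_bank(),
                               mode = c("population", "lineage"),
                               n_replicates = 10, n_lineages = 11,
                               n_experiments = 100, seed = 1) {
  mode <- match.arg(mode)
  multipliers <- sort(unique(c(1, multipliers)))
  if (any(multipliers * params$p_accident > 1))
    stop("run_mortality_scan: multiplier * p_accident exceeds 1")
  if (mode == "population") {
    conds <- lapply(multipliers, function(m)
      list(params = update_params(params, p_accident = m * params$p_accident),
           dist = dist))
    res <- .run_conditions(conds, config, bank, n_replicates, seed)
    out <- .scan_table(multipliers, "multiplier", res,
                       control = which(multipliers == 1))
    out$table$p_accident <- multipliers * params$p_accident
    return(out)
  }
  rows <- lapply(seq_along(multipliers), function(k) {
    pk <- update_params(params, p_accident = multipliers[k] * params$p_accident)
    med <- vapply(seq_len(n_experiments), function(i) {
      set.seed(seed + i)
      recs <- simulate_lineages(n_lineages, pk, dist, bank)
      stats::median(recs$gen_sen, na.rm = TRUE)
    }, numeric(1))
    data.frame(multiplier = multipliers[k],
               p_accident = multipliers[k] * params$p_accident,
               median_onset_gen = stats::median(med, na.rm = TRUE),
               q025 = stats::quantile(med, 0.025, na.rm = TRUE, names = FALSE),
               q975 = stats::quantile(med, 0.975, na.rm = TRUE, names = FALSE))
  })
  do.call(rbind, rows)
}

# Assemble the scan output table from paired HSL matrices.
.scan_table <- function(values, value_name, res, control) {
  d_hsl <- res$hsl - res$hsl[, control]
  tab <- data.frame(
    value = values,
    mean_hsl_h = colMeans(res$hsl, na.rm = TRUE),
    sd_hsl_h = apply(res$hsl, 2, stats::sd, na.rm = TRUE),
    delta_hsl_h = colMeans(d_hsl, na.rm = TRUE),
    n_censored = colSums(is.na(res$hsl)))
  names(tab)[1] <- value_name
  telo_mean <- apply(res$telo, c(2, 3), mean, na.rm = TRUE)
  rownames(telo_mean) <- values
  list(table = tab, hsl = res$hsl, telo_mean = telo_mean)
}
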