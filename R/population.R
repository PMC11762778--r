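#' Summarize a cell population
#'
#' Computes the per-timepoint aggregates tracked across a population
#' experiment: living count, type and cycle-type composition, telomere
#' mean and statistical mode (over all `32 * count` telomeres; ties go to
#' the smallest length, since the mode is the experimentally measurable
#' proxy compared across days), shortest-telomere statistics (mean, min and
#' max of the per-cell minima), the generational-age mean/variance/95%
#' band, and — when a founder ancestry map is supplied — the proportion of
#' cells descending from each founder bin.
#'
#' @param cells list with `telo` (`32 x n` integer matrix), `type`
#'   (1 = A, 2 = B), `cyc` (1 = nor, 2 = nta, 3 = sen), `gen`, `anc`
#'   (founder index), as carried by [run_population_experiment()].
#' @param time_h time of the snapshot in hours.
#' @param ancestry optional integer vector mapping founder index to
#'   ancestry bin (1..`ancestry_bins`).
#' @return A one-row data frame; ancestry proportions, when requested, are
#'   attached as the `"ancestry"` attribute.
#' @export
summarize_population <- function(cells, time_h, ancestry = NULL) {
  n <- length(cells$type)
  if (n == 0L) {
    out <- data.frame(time_h = time_h, count = 0L,
                      frac_A = NA_real_, frac_B = NA_real_,
                      frac_nor = NA_real_, frac_nta = NA_real_, frac_sen = NA_real_,
                      telo_mean = NA_real_, telo_mode = NA_real_,
                      shortest_mean = NA_real_, shortest_min = NA_real_,
                      shortest_max = NA_real_,
                      gen_mean = NA_real_, gen_var = NA_real_,
                      gen_q025 = NA_real_, gen_q975 = NA_real_)
    return(out)
  }
  telo <- cells$telo
  # per-cell shortest telomere: fold pmin over the 32 ends
  mins <- telo[1L, ]
  for (j in 2L:32L) mins <- pmin(mins, telo[j, ])
  tab <- tabulate(as.integer(telo) + 1L)   # counts for lengths 0, 1, 2, ...
  mode_bp <- which.max(tab) - 1L           # which.max -> first max: smallest wins
  out <- data.frame(
    time_h = time_h, count = n,
    frac_A = mean(cells$type == 1L), frac_B = mean(cells$type == 2L),
    frac_nor = mean(cells$cyc == 1L), frac_nta = mean(cells$cyc == 2L),
    frac_sen = mean(cells$cyc == 3L),
    telo_mean = mean(telo), telo_mode = as.numeric(mode_bp),
    shortest_mean = mean(mins), shortest_min = min(mins),
    shortest_max = max(mins),
    gen_mean = mean(cells$gen),
    gen_var = if (n > 1) stats::var(cells$gen) else 0,
    gen_q025 = stats::quantile(cells$gen, 0.025, names = FALSE),
    gen_q975 = stats::quantile(cells$gen, 0.975, names = FALSE))
  if (!is.null(ancestry)) {
    bins <- tabulate(ancestry[cells$anc], nbins = max(ancestry))
    attr(out, "ancestry") <- bins / n
  }
  out
}

#' Run a daily saturation--dilution population experiment
#'
#' Simulates a competing population of telomerase-negative cells from
#' telomerase inactivation: `n_init` founder type-A cells with i.i.d.
#' telomeres divide in continuous time (each cell divides at its birth
#' time plus its sampled cycle duration; both daughters are kept and get
#' independent fates and durations).  As soon as the living count reaches
#' `n_sat = r_sat * n_init`, divisions are frozen — cells keep their
#' remaining cycle time — until the next dilution.  Every 24 h the
#' culture is diluted: `n_dil` cells are sampled uniformly without
#' replacement (all cells are kept if fewer remain), and frozen cells
#' resume their cycles.  Dead cells are removed immediately.
#'
#' Founders are assigned once, at time 0, to `ancestry_bins` equal-sized
#' bins by ranking their shortest telomere, enabling the ancestry-decile
#' composition tracking.
#'
#' @param config an [experiment_config()].
#' @param params a [law_params()].
#' @param dist an [initial_distribution()].
#' @param bank a [duration_bank()].
#' @param stop_below optional count: stop simulating further days once the
#'   end-of-day (pre-dilution) count falls below this value (the day that
#'   crosses it is still recorded).  Useful to stop once the
#'   half-saturation time is bracketed.  Default 0 (run all days).
#' @return An object of class `population_run`: list with
#'   * `snapshots`: one row per day (pre-dilution) from
#'     [summarize_population()];
#'   * `hourly`: data frame `time_h`, `count` (living cells each hour);
#'   * `onsets`: data frame `time_h`, `day`, `type` (`"A"`/`"B"`, ground
#'     truth), `shortest_bp` — one row per senescence onset;
#'   * `end_counts`: pre-dilution count per simulated day;
#'   * `ancestry`: matrix (day x bin) of ancestry proportions;
#'   * `extinct`, `n_days_run`, `config`.
#' @examples
#' \donttest{
#' set.seed(1)
#' run <- run_population_experiment(
#'   experiment_config(n_init = 50, r_sat = 100, n_days = 4),
#'   law_params(), initial_distribution(), synthetic_duration_bank())
#' run$snapshots[, c("time_h", "count", "frac_sen")]
#' }
#' @export
run_population_experiment <- function(config = experiment_config(),
                                      params = law_params(),
                                      dist = initial_distribution(),
                                      bank = synthetic_duration_bank(),
                                      stop_below = 0) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(params, "law_params"),
            inherits(dist, "initial_distribution"),
            inherits(bank, "duration_bank"))
  n_init <- config$n_init
  state <- list(
    telo = matrix(sample_initial_lengths(32L * n_init, dist), nrow = 32L),
    type = rep(1L, n_init), cyc = rep(1L, n_init),
    gen = rep(0L, n_init), anc = seq_len(n_init))
  state$div_time <- sample_cycle_duration(bank, "A", "nor", n = n_init)

  # founder ancestry bins by shortest telomere (bin 1 = shortest founders)
  fmins <- state$telo[1L, ]
  for (j in 2L:32L) fmins <- pmin(fmins, state$telo[j, ])
  ancestry <- as.integer(ceiling(rank(fmins, ties.method = "first") /
                                   (n_init / config$ancestry_bins)))
  ancestry <- pmin(ancestry, config$ancestry_bins)

  day_min <- 24 * 60
  snapshots <- vector("list", config$n_days)
  onsets <- vector("list", config$n_days)
  hourly <- vector("list", config$n_days)
  anc_prop <- matrix(NA_real_, config$n_days, config$ancestry_bins)
  end_counts <- rep(NA_real_, config$n_days)
  extinct <- FALSE
  days_run <- 0L

  for (day in seq_len(config$n_days)) {
    res <- cpp_run_day(state$telo, state$type, state$cyc, state$gen,
                       state$anc, state$div_time,
                       (day - 1) * day_min, day * day_min,
                       config$n_sat, unclass(params),
                       bank[c("nor_A", "nor_B", "nta", "sen")])
    state <- list(telo = res$telo, type = res$type, cyc = res$cyc,
                  gen = res$gen, anc = res$anc, div_time = res$div_time)
    days_run <- day
    hourly[[day]] <- data.frame(time_h = res$hour_time / 60,
                                count = res$hour_count)
    if (length(res$onset_time)) {
      onsets[[day]] <- data.frame(time_h = res$onset_time / 60, day = day,
                                  type = c("A", "B")[res$onset_type],
                                  shortest_bp = res$onset_shortest)
    }
    n_end <- length(state$type)
    end_counts[day] <- n_end
    snap <- summarize_population(state, time_h = day * 24, ancestry = ancestry)
    snapshots[[day]] <- snap
    if (!is.null(attr(snap, "ancestry"))) anc_prop[day, ] <- attr(snap, "ancestry")
    if (n_end == 0L) { extinct <- TRUE; break }
    # dilution: uniform sample without replacement, then resume paused cells
    if (n_end > config$n_dil) {
      keep <- sample.int(n_end, config$n_dil)
      state <- list(telo = state$telo[, keep, drop = FALSE],
                    type = state$type[keep], cyc = state$cyc[keep],
                    gen = state$gen[keep], anc = state$anc[keep],
                    div_time = state$div_time[keep])
    }
    if (isTRUE(res$frozen)) {
      state$div_time <- day * day_min + pmax(state$div_time - res$t_freeze, 0)
    }
    if (n_end < stop_below) break
  }

  structure(list(
    snapshots = do.call(rbind, snapshots[seq_len(days_run)]),
    hourly = do.call(rbind, hourly[seq_len(days_run)]),
    onsets = if (length(ons <- Filter(Negate(is.null), onsets[seq_len(days_run)])))
      do.call(rbind, ons)
    else data.frame(time_h = numeric(), day = integer(),
                    type = character(), shortest_bp = numeric()),
    end_counts = end_counts[seq_len(days_run)],
    ancestry = anc_prop[seq_len(days_run), , drop = FALSE],
    extinct = extinct, n_days_run = days_run,
    config = config), class = "population_run")
}

#' @export
print.population_run <- function(x, ...) {
  cat(sprintf("Population run: %d day(s), N_init = %d, N_sat = %d%s\n",
              x$n_days_run, x$config$n_init, x$config$n_sat,
              if (x$extinct) " (extinct)" else ""))
  print(x$snapshots[, c("time_h", "count", "frac_B", "frac_sen",
                        "telo_mode", "shortest_mean")], row.names = FALSE)
  invisible(x)
}

#' Half-saturation-limit time (HSL)
#'
#' The population-level summary of senescence rate: the time at which the
#' end-of-day (pre-dilution) cell count first falls to half the saturation
#' number, linearly interpolated between the last day with count at or
#' above `n_sat / 2` and the first day below it.
#'
#' @param end_counts pre-dilution counts, one per day (day 1 first).
#' @param n_sat saturation count.
#' @param times_h times of the counts in hours (defaults to 24, 48, ...).
#' @return HSL in hours.  `NA` with attribute `censored = "right"` if the
#'   count never falls below half saturation within the recorded days (the
#'   true HSL exceeds the last recorded time); if even day 1 is below half
#'   saturation the first recorded time is returned with attribute
#'   `censored = "left"`.
#' @examples
#' compute_hsl(c(1, 1, 1, 0.8, 0.3) * 1000, n_sat = 1000)  # 110.4 h
#' @export
compute_hsl <- function(end_counts, n_sat, times_h = 24 * seq_along(end_counts)) {
  stopifnot(length(end_counts) == length(times_h))
  half <- n_sat / 2
  below <- which(end_counts < half)
  if (!length(below)) {
    out <- NA_real_
    attr(out, "censored") <- "right"
    return(out)
  }
  i <- below[1]
  if (i == 1L) {
    out <- times_h[1]
    attr(out, "censored") <- "left"
    return(out)
  }
  c_prev <- end_counts[i - 1]; c_next <- end_counts[i]
  times_h[i - 1] + (times_h[i] - times_h[i - 1]) *
    (c_prev - half) / (c_prev - c_next)
}

#' Convert simulated cell counts to OD600 for display
#'
#' Population experiments are simulated at reduced scale; for plotting
#' against experimental growth curves the counts are rescaled linearly so
#' that the post-dilution count `n_init` corresponds to the inoculation
#' density of the standard assay, OD600 = 0.0125 (about 3.75e5 cells/ml).
#' Display convenience only — nothing in the simulation depends on it.
#'
#' @param count simulated cell count(s).
#' @param n_init founder count of the simulation.
#' @param od_init optical density at inoculation.
#' @return OD600 value(s).
#' @examples
#' count_to_od600(300000, n_init = 300)   # saturation of an r_sat = 1000 run: 12.5
#' @export
count_to_od600 <- function(count, n_init, od_init = 0.0125) {
  count / n_init * od_init
}
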