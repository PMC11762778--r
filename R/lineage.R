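#' Simulate one single-cell lineage (microfluidics setting)
#'
#' Reproduces the mother-machine observation scheme: starting from one
#' founder cell of type A with i.i.d. telomeres, the cell divides, one of
#' the two daughters is picked uniformly at random and tracked, its fate is
#' drawn from the arrest laws on its post-shortening shortest telomere, and
#' a cycle duration is sampled from the bank.  Generation 0 is the founder
#' cell at telomerase inactivation; it completes one cycle before the first
#' division, so fates are first evaluated on generation-1 daughters.  The
#' lineage ends at cell death (senescent or accidental) or at the safety
#' cap `max_generations`.
#'
#' @param params a [law_params()].
#' @param dist an [initial_distribution()].
#' @param bank a [duration_bank()].
#' @param max_generations safety cap; reaching it flags the record as
#'   truncated (a sign of immortal parameter settings).
#' @return A `lineage_record`: list with `cycles` (data frame of
#'   `generation`, `cycle_type` (ground truth), `type` (ground truth),
#'   `duration_min`, `shortest_bp`), `gen_first_nta`, `gen_sen`,
#'   `gen_death`, `death_cause` (`"senescence"`, `"accident"` or
#'   `"truncated"`), `observed_type` (`"A"`/`"B"`, from durations only),
#'   `is_M` and `truncated`.
#' @examples
#' set.seed(42)
#' rec <- simulate_lineage(law_params(), initial_distribution(),
#'                         synthetic_duration_bank())
#' rec$gen_death; rec$observed_type
#' @export
simulate_lineage <- function(params = law_params(),
                             dist = initial_distribution(),
                             bank = synthetic_duration_bank(),
                             max_generations = 200L) {
  L <- sample_initial_matrix(dist)
  type <- "A"; cycle <- "nor"
  gen <- 0L
  n <- max_generations + 1L
  g_col <- integer(n); ct_col <- character(n); ty_col <- character(n)
  du_col <- numeric(n); sh_col <- integer(n)
  gen_first_nta <- NA_integer_; gen_sen <- NA_integer_
  death_cause <- "truncated"
  i <- 0L
  repeat {
    # the current cell completes one cycle of its current type
    i <- i + 1L
    g_col[i] <- gen; ct_col[i] <- cycle; ty_col[i] <- type
    du_col[i] <- sample_cycle_duration(bank, type, cycle)
    sh_col[i] <- min(L)
    if (gen >= max_generations) break
    # division: track one daughter uniformly at random
    daughters <- divide_telomeres(L, params$h)
    L <- if (stats::runif(1) < 0.5) daughters$daughter1 else daughters$daughter2
    fate <- next_cell_fate(type, cycle, params = params, l = min(L))
    if (!fate$alive) { death_cause <- fate$death_cause; break }
    type <- fate$type; cycle <- fate$cycle
    gen <- gen + 1L
    if (cycle == "nta" && is.na(gen_first_nta)) gen_first_nta <- gen
    if (cycle == "sen" && is.na(gen_sen)) gen_sen <- gen
  }
  cycles <- data.frame(generation = g_col[seq_len(i)],
                       cycle_type = ct_col[seq_len(i)],
                       type = ty_col[seq_len(i)],
                       duration_min = du_col[seq_len(i)],
                       shortest_bp = sh_col[seq_len(i)],
                       stringsAsFactors = FALSE)
  rec <- list(cycles = cycles,
              gen_first_nta = gen_first_nta,
              gen_sen = gen_sen,
              gen_death = cycles$generation[i],
              death_cause = death_cause,
              truncated = death_cause == "truncated")
  cls <- classify_lineage(rec, D = params$D)
  rec$observed_type <- cls$observed_type
  rec$is_M <- cls$is_M
  class(rec) <- "lineage_record"
  rec
}

#' Classify a lineage from its cycle durations
#'
#' Mirrors the experimental classification, which sees only durations: a
#' cycle is "long" when its duration is at least `D` minutes.  A lineage is
#' observed type B iff at least one long cycle is later followed by a
#' normal (short) cycle — i.e. a non-terminal arrest is visible.  Otherwise
#' it is observed type A.  A lineage is flagged `is_M` when it is observed
#' type A although its ground truth contains an nta cycle: a type-B cell
#' whose first arrest sequence ran directly into death, experimentally
#' indistinguishable from type A.
#'
#' @param record a `lineage_record` (or any list with a `cycles` data frame
#'   holding `duration_min` and `cycle_type`).
#' @param D long-cycle duration threshold (minutes).
#' @return List with `observed_type` and `is_M`.
#' @export
classify_lineage <- function(record, D = 180) {
  dur <- record$cycles$duration_min
  long <- dur >= D
  observed_B <- FALSE
  if (length(dur) > 1L) {
    # a long cycle strictly before some later normal cycle
    last_normal <- max(c(0L, which(!long)))
    observed_B <- any(long[seq_len(max(0L, last_normal - 1L))])
  }
  has_nta <- any(record$cycles$cycle_type == "nta")
  list(observed_type = if (observed_B) "B" else "A",
       is_M = !observed_B && has_nta)
}

#' Simulate a batch of lineages
#'
#' Fast path over the compiled engine: simulates `n` independent lineages
#' and returns one row per lineage.  Statistically equivalent to repeated
#' [simulate_lineage()] calls (the pure-R reference path), which is
#' asserted by the package's tests.
#'
#' @inheritParams simulate_lineage
#' @param n number of lineages.
#' @return A data frame with one row per lineage: `gen_first_nta`,
#'   `gen_sen`, `gen_death`, `death_cause`, `observed_type`, `is_M`,
#'   `truncated`.
#' @examples
#' set.seed(1)
#' recs <- simulate_lineages(200, law_params(), initial_distribution(),
#'                           synthetic_duration_bank())
#' mean(recs$observed_type == "B")
#' @export
simulate_lineages <- function(n, params = law_params(),
                              dist = initial_distribution(),
                              bank = synthetic_duration_bank(),
                              max_generations = 200L) {
  founders <- matrix(sample_initial_lengths(32L * n, dist), nrow = 32L)
  res <- cpp_simulate_lineages(founders, unclass(params),
                               bank[c("nor_A", "nor_B", "nta", "sen")],
                               as.integer(max_generations))
  data.frame(
    gen_first_nta = ifelse(res$gen_first_nta < 0, NA_integer_, res$gen_first_nta),
    gen_sen = ifelse(res$gen_sen < 0, NA_integer_, res$gen_sen),
    gen_death = res$gen_death,
    death_cause = c("senescence", "accident", "truncated")[res$death_cause],
    observed_type = c("A", "B")[res$observed_type],
    is_M = res$is_M,
    truncated = res$death_cause == 3L,
    stringsAsFactors = FALSE)
}

#' Arrest-generation curves of a batch of lineages
#'
#' The summary used both for visual comparison with microfluidics data and
#' as the calibration target: for each of four categories — generation of
#' the first non-terminal arrest (`nta`), generation of the first senescent
#' cycle among observed type-A lineages (`sen_A`), among observed type-B
#' lineages (`sen_B`), and among all lineages (`sen`) — the ascending
#' sorted vector of generations (lineages ordered by that value, i.e. the
#' x-axis is lineage rank).  Categories use the observed (duration-based)
#' classification, so misclassified type-M lineages contribute to `sen_A`.
#'
#' @param records a data frame as returned by [simulate_lineages()] (or a
#'   list of `lineage_record`s).
#' @return List of four sorted numeric vectors: `nta`, `sen_A`, `sen_B`,
#'   `sen`.  Empty categories give empty vectors.
#' @export
arrest_generation_curves <- function(records) {
  if (!is.data.frame(records)) {
    records <- data.frame(
      gen_first_nta = vapply(records, function(r) as.integer(r$gen_first_nta), 1L),
      gen_sen = vapply(records, function(r) as.integer(r$gen_sen), 1L),
      observed_type = vapply(records, function(r) r$observed_type, ""),
      stringsAsFactors = FALSE)
  }
  if (nrow(records) == 0) stop("arrest_generation_curves: no records")
  sen_all <- records$gen_sen
  curves <- list(
    nta = sort(records$gen_first_nta[!is.na(records$gen_first_nta)]),
    sen_A = sort(sen_all[!is.na(sen_all) & records$observed_type == "A"]),
    sen_B = sort(sen_all[!is.na(sen_all) & records$observed_type == "B"]),
    sen = sort(sen_all[!is.na(sen_all)]))
  attr(curves, "n_lineages") <- nrow(records)
  attr(curves, "prop_B") <- mean(records$observed_type == "B")
  curves
}
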