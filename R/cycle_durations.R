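#' Cell-cycle-duration bank
#'
#' Cycle durations are resampled uniformly from four empirical subdatasets
#' keyed by (type, cycle type): normal cycles of type-A cells, normal
#' cycles of type-B cells, non-terminal arrest cycles and senescent cycles
#' (the latter two pooled across types).  The partition is defined by the
#' long-cycle threshold `D`: every normal duration is `< D`, every arrest
#' duration is `>= D`.
#'
#' @param nor_A,nor_B,nta,sen numeric vectors of durations (minutes).
#' @param D long-cycle threshold in minutes (default 180).
#' @return An object of class `duration_bank`.
#' @seealso [synthetic_duration_bank()], [read_duration_bank()],
#'   [sample_cycle_duration()]
#' @export
duration_bank <- function(nor_A, nor_B, nta, sen, D = 180) {
  bank <- list(nor_A = as.numeric(nor_A), nor_B = as.numeric(nor_B),
               nta = as.numeric(nta), sen = as.numeric(sen))
  for (nm in names(bank)) {
    if (length(bank[[nm]]) == 0)
      stop("duration_bank: category `", nm, "` is empty")
    if (anyNA(bank[[nm]]) || any(bank[[nm]] <= 0))
      stop("duration_bank: category `", nm, "` has missing or non-positive durations")
  }
  for (nm in c("nor_A", "nor_B")) {
    bad <- which(bank[[nm]] >= D)
    if (length(bad))
      stop(sprintf("duration_bank: normal-cycle duration %g min in `%s` (row %d) is >= D = %g",
                   bank[[nm]][bad[1]], nm, bad[1], D))
  }
  for (nm in c("nta", "sen")) {
    bad <- which(bank[[nm]] < D)
    if (length(bad))
      stop(sprintf("duration_bank: arrest-cycle duration %g min in `%s` (row %d) is < D = %g",
                   bank[[nm]][bad[1]], nm, bad[1], D))
  }
  structure(c(bank, list(D = D)), class = "duration_bank")
}

#' @export
print.duration_bank <- function(x, ...) {
  cat("Cell-cycle duration bank (minutes), long-cycle threshold D =", x$D, "\n")
  for (nm in c("nor_A", "nor_B", "nta", "sen"))
    cat(sprintf("  %-6s n = %5d, median = %6.1f, range [%g, %g]\n",
                nm, length(x[[nm]]), stats::median(x[[nm]]),
                min(x[[nm]]), max(x[[nm]])))
  invisible(x)
}

#' Synthetic stand-in duration bank
#'
#' Emulates the shapes of the four microfluidics duration subdatasets:
#' normal cycles are log-normal-shaped around 90 min (type A) and slightly
#' longer for type B, truncated below the long-cycle threshold `D`; arrest
#' cycles (non-terminal and senescent) are `D` plus a heavy-right-tailed
#' log-normal, truncated at `max_arrest`.  Values are frozen samples: the
#' bank is generated once (seeded by the caller's RNG state) and then
#' resampled uniformly during simulations.
#'
#' @param n samples per category.
#' @param median_nor_A,median_nor_B median normal-cycle duration (minutes)
#'   for type A and type B cells.
#' @param sdlog_nor log-scale SD of normal cycles.
#' @param median_arrest_excess median excess duration of arrest cycles
#'   above `D` (minutes).
#' @param sdlog_arrest log-scale SD of arrest-cycle excess (heavy tail).
#' @param max_arrest upper truncation of arrest durations (minutes).
#' @param D long-cycle threshold (minutes).
#' @return A [duration_bank()].
#' @examples
#' set.seed(7)
#' bank <- synthetic_duration_bank()
#' mean(bank$nor_A)    # close to 90 min
#' @export
synthetic_duration_bank <- function(n = 500,
                                    median_nor_A = 90, median_nor_B = 100,
                                    sdlog_nor = 0.18,
                                    median_arrest_excess = 120,
                                    sdlog_arrest = 0.9,
                                    max_arrest = 1000, D = 180) {
  rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
    p_lo <- stats::plnorm(lo, meanlog, sdlog)
    p_hi <- stats::plnorm(hi, meanlog, sdlog)
    stats::qlnorm(p_lo + (p_hi - p_lo) * stats::runif(n), meanlog, sdlog)
  }
  # truncate below D with headroom so rounding cannot reach the threshold
  nor_A <- rtrunc_lnorm(n, log(median_nor_A), sdlog_nor, 0, D - 0.5)
  nor_B <- rtrunc_lnorm(n, log(median_nor_B), sdlog_nor, 0, D - 0.5)
  nta <- D + rtrunc_lnorm(n, log(median_arrest_excess), sdlog_arrest,
                          0, max_arrest - D)
  sen <- D + rtrunc_lnorm(n, log(median_arrest_excess), sdlog_arrest,
                          0, max_arrest - D)
  duration_bank(round(nor_A, 1), round(nor_B, 1), round(nta, 1),
                round(sen, 1), D = D)
}

#' Read a duration bank from CSV
#'
#' Expected columns: `cell_type` (`A`, `B` or `any`), `cycle_type`
#' (`nor`, `nta` or `sen`) and `duration_minutes`.  Arrest categories
#' (`nta`, `sen`) are pooled across types, so their `cell_type` is
#' conventionally `any`.
#'
#' @param path CSV file path.
#' @param D long-cycle threshold (minutes).
#' @return A [duration_bank()].
#' @export
read_duration_bank <- function(path, D = 180) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_type", "cycle_type", "duration_minutes")
  if (!all(need %in% names(df)))
    stop("read_duration_bank: file must have columns ", paste(need, collapse = ", "))
  pick <- function(type, cycle) {
    sel <- df$cycle_type == cycle &
      (cycle != "nor" | df$cell_type %in% c(type, "any"))
    df$duration_minutes[sel]
  }
  duration_bank(nor_A = pick("A", "nor"), nor_B = pick("B", "nor"),
                nta = df$duration_minutes[df$cycle_type == "nta"],
                sen = df$duration_minutes[df$cycle_type == "sen"], D = D)
}

#' Write a duration bank to CSV
#'
#' @param bank a [duration_bank()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_duration_bank <- function(bank, path) {
  stopifnot(inherits(bank, "duration_bank"))
  df <- rbind(
    data.frame(cell_type = "A", cycle_type = "nor", duration_minutes = bank$nor_A),
    data.frame(cell_type = "B", cycle_type = "nor", duration_minutes = bank$nor_B),
    data.frame(cell_type = "any", cycle_type = "nta", duration_minutes = bank$nta),
    data.frame(cell_type = "any", cycle_type = "sen", duration_minutes = bank$sen))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sample one cycle duration
#'
#' Uniform draw from the bank category matching the cell's type and cycle
#' type (`nta` and `sen` durations are pooled across types).
#'
#' @param bank a [duration_bank()].
#' @param type `"A"` or `"B"`.
#' @param cycle `"nor"`, `"nta"` or `"sen"`.
#' @param n number of draws.
#' @return Duration(s) in minutes.
#' @export
sample_cycle_duration <- function(bank, type, cycle, n = 1L) {
  stopifnot(inherits(bank, "duration_bank"))
  cycle <- match.arg(cycle, c("nor", "nta", "sen"))
  pool <- if (cycle == "nor") {
    type <- match.arg(type, c("A", "B"))
    if (type == "A") bank$nor_A else bank$nor_B
  } else bank[[cycle]]
  pool[pmax(1L, ceiling(stats::runif(n) * length(pool)))]
}
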