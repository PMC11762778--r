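#' Generate synthetic fixture datasets
#'
#' Writes deterministic, seed-stamped stand-ins for the data the model
#' consumes: samples of initial (telomerase-positive equilibrium) telomere
#' lengths, cycle-duration banks, and pseudo-experimental lineage datasets
#' with known ground-truth parameters for calibration-recovery tests.
#' Every fixture comes with a JSON manifest recording the kind, seed,
#' counts and true parameters, enabling closed-loop tests.  The same seed
#' always reproduces byte-identical files.
#'
#' @param kind `"initial_lengths"`, `"duration_bank"` or
#'   `"lineage_targets"`.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed.
#' @param n number of lengths / durations per category / lineages.
#' @param params a [law_params()]: the generating truth for
#'   `lineage_targets` (recorded in the manifest).
#' @param dist an [initial_distribution()].
#' @param bank_args arguments passed to [synthetic_duration_bank()].
#' @return Named character vector of the files written (invisibly).
#' @export
generate_fixture_dataset <- function(kind = c("initial_lengths",
                                              "duration_bank",
                                              "lineage_targets"),
                                     out_dir, seed = 1, n = NULL,
                                     params = law_params(),
                                     dist = initial_distribution(),
                                     bank_args = list()) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  manifest <- list(kind = kind, seed = seed)
  files <- character(0)

  if (kind == "initial_lengths") {
    if (is.null(n)) n <- 5000L
    u <- stats::runif(n)
    lengths <- round(dist$l_inf +
                       (dist$l_sup - dist$l_inf) *
                         stats::qbeta(u, dist$shape1, dist$shape2))
    path <- file.path(out_dir, "initial_lengths.txt")
    writeLines(as.character(lengths), path)
    files["lengths"] <- path
    manifest$n <- n
    manifest$base <- list(l_inf = dist$l_inf, l_mode = dist$l_mode,
                          l_sup = dist$l_sup,
                          concentration = dist$concentration)
  } else if (kind == "duration_bank") {
    if (!is.null(n)) bank_args$n <- n
    bank <- do.call(synthetic_duration_bank, bank_args)
    path <- file.path(out_dir, "duration_bank.csv")
    write_duration_bank(bank, path)
    files["bank"] <- path
    manifest$n_per_category <- length(bank$nor_A)
    manifest$D <- bank$D
  } else {
    if (is.null(n)) n <- 2000L
    bank <- do.call(synthetic_duration_bank, bank_args)
    recs <- simulate_lineages(n, params, dist, bank)
    path <- file.path(out_dir, "lineage_targets.csv")
    utils::write.csv(recs, path, row.names = FALSE, quote = FALSE)
    bank_path <- file.path(out_dir, "duration_bank.csv")
    write_duration_bank(bank, bank_path)
    files["lineages"] <- path
    files["bank"] <- bank_path
    manifest$n_lineages <- n
    manifest$true_params <- unclass(params)
    manifest$dist <- list(l_inf = dist$l_inf, l_mode = dist$l_mode,
                          l_sup = dist$l_sup, l_trans = dist$l_trans,
                          l_0 = dist$l_0, l_1 = dist$l_1)
    manifest$prop_B_observed <- mean(recs$observed_type == "B")
    manifest$prop_M <- mean(recs$is_M)
  }

  manifest_path <- file.path(out_dir, paste0(kind, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files["manifest"] <- manifest_path
  invisible(files)
}
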