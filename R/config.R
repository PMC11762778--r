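#' Load a simulation configuration from YAML
#'
#' Reads a flat YAML file keyed by the model's standard symbols and
#' resolves it into validated parameter objects.  Every key is optional;
#' missing keys take the fitted defaults, so an empty file yields the
#' default model.  Unknown keys and out-of-range values raise descriptive
#' errors.
#'
#' Recognised keys:
#' * arrest/shortening constants: `a_nta`, `b_nta`, `a_sen_A`, `b_sen_A`,
#'   `a_sen_B`, `b_sen_B`, `l_min_A`, `l_min_B`, `p_accident`, `p_repair`,
#'   `p_death`, `h`, `D`;
#' * initial distribution: `l_inf`, `l_mode`, `l_sup`, `l_trans`, `l_0`,
#'   `l_1`, `concentration`, `initial_sample_file` (plain text, one bp per
#'   line);
#' * population protocol: `n_init`, `r_sat`, `n_dil`, `n_days`,
#'   `ancestry_bins`;
#' * duration bank: `bank_file` (CSV) or any `bank_*` argument of
#'   [synthetic_duration_bank()] (e.g. `bank_n`, `bank_median_nor_A`);
#' * `seed`: global seed; sub-streams (bank synthesis, founder draws,
#'   dynamics) all descend from it via `set.seed()` at each entry point.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return List with `params` ([law_params()]), `dist`
#'   ([initial_distribution()]), `experiment` ([experiment_config()]),
#'   `bank` ([duration_bank()]), `seed`, and `resolved` (the fully
#'   resolved flat key/value list, suitable for [save_config()]).
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()

  law_keys <- names(formals(law_params))
  dist_keys <- c("l_inf", "l_mode", "l_sup", "l_trans", "l_0", "l_1",
                 "concentration", "initial_sample_file")
  exp_keys <- c("n_init", "r_sat", "n_dil", "n_days", "ancestry_bins")
  bank_syn_keys <- paste0("bank_", names(formals(synthetic_duration_bank)))
  other_keys <- c("bank_file", "seed")
  known <- c(law_keys, dist_keys, exp_keys, bank_syn_keys, other_keys)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "))

  params <- do.call(law_params, raw[intersect(names(raw), law_keys)])

  dist_args <- raw[intersect(names(raw), setdiff(dist_keys, "initial_sample_file"))]
  if (!is.null(raw$initial_sample_file))
    dist_args$base_sample <- read_length_sample(raw$initial_sample_file)
  dist <- do.call(initial_distribution, dist_args)

  experiment <- do.call(experiment_config, raw[intersect(names(raw), exp_keys)])

  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  if (!is.null(raw$bank_file)) {
    bank <- read_duration_bank(raw$bank_file, D = params$D)
  } else {
    bank_args <- raw[intersect(names(raw), bank_syn_keys)]
    names(bank_args) <- sub("^bank_", "", names(bank_args))
    bank_args$D <- params$D
    set.seed(seed)
    bank <- do.call(synthetic_duration_bank, bank_args)
  }

  resolved <- c(unclass(params),
                list(l_inf = dist$l_inf, l_mode = dist$l_mode,
                     l_sup = dist$l_sup, l_trans = dist$l_trans,
                     l_0 = dist$l_0, l_1 = dist$l_1,
                     concentration = dist$concentration,
                     n_init = experiment$n_init, r_sat = experiment$r_sat,
                     n_dil = experiment$n_dil, n_days = experiment$n_days,
                     ancestry_bins = experiment$ancestry_bins,
                     seed = seed))
  for (k in c("initial_sample_file", "bank_file", bank_syn_keys))
    if (!is.null(raw[[k]])) resolved[[k]] <- raw[[k]]

  list(params = params, dist = dist, experiment = experiment,
       bank = bank, seed = seed, resolved = resolved)
}

#' Save a resolved configuration back to YAML
#'
#' @param resolved the `resolved` element of [load_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(resolved, path) {
  yaml::write_yaml(resolved, path)
  invisible(path)
}
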