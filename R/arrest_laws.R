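#' Evaluate a shortest-telomere arrest law
#'
#' All arrest laws of the model share the form
#' `p(l) = min(1, b * exp(-a * l))` for `l > l_min` and `p(l) = 1` for
#' `l <= l_min`, where `l` is the length of the shortest telomere in the
#' cell after replication.
#'
#' @param a rate (1/bp), non-negative.
#' @param b scale, non-negative.
#' @param l_min hard threshold (bp); at or below it the probability is 1.
#' @param l shortest-telomere length(s), bp (vectorised).
#' @return Probability vector, same length as `l`.
#' @examples
#' p <- law_params()
#' arrest_probability(p$a_sen_A, p$b_sen_A, p$l_min_A, 27)   # 1: at threshold
#' arrest_probability(p$a_sen_B, p$b_sen_B, p$l_min_B, 150)  # 0.12: flat law
#' @export
arrest_probability <- function(a, b, l_min, l) {
  if (!is.numeric(a) || !is.numeric(b) || a < 0 || b < 0)
    stop("arrest_probability: a and b must be non-negative")
  ifelse(l <= l_min, 1, pmin(1, b * exp(-a * l)))
}

#' Cell state constructor
#'
#' The per-cell state tracked by the simulators: telomere matrix `L`,
#' ground-truth type `T` (`"A"` or `"B"`), cycle type `C`
#' (`"nor"`, `"nta"` or `"sen"`), current cycle duration `tau` (minutes)
#' and bookkeeping (generation since telomerase inactivation, birth time,
#' founder index, arrest-history flags).
#'
#' @param L `2 x 16` telomere matrix.
#' @param type `"A"` or `"B"`.
#' @param cycle `"nor"`, `"nta"` or `"sen"`.
#' @param tau cycle duration in minutes (`NA` until sampled).
#' @param generation generation index (0 = telomerase inactivation).
#' @param birth_time birth time in minutes.
#' @param ancestor founder index.
#' @param ever_nta has this cell's lineage (since generation 0) experienced
#'   a non-terminal arrest?  Type A implies `FALSE`.
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(L, type = "A", cycle = "nor", tau = NA_real_,
                       generation = 0L, birth_time = 0, ancestor = 1L,
                       ever_nta = FALSE) {
  L <- as_telomere_matrix(L)
  type <- match.arg(type, c("A", "B"))
  cycle <- match.arg(cycle, c("nor", "nta", "sen"))
  if (type == "A" && ever_nta)
    stop("cell_state: a type-A cell cannot have experienced an nta cycle")
  if (type == "A" && cycle == "nta")
    stop("cell_state: an nta cycle implies type B")
  structure(list(L = L, type = type, cycle = cycle, tau = tau,
                 generation = as.integer(generation),
                 birth_time = birth_time, ancestor = as.integer(ancestor),
                 ever_nta = ever_nta),
            class = "cell_state")
}

# Onset checks applied to a daughter whose mother (or the daughter itself,
# after repair) is in a normal cycle.  Type A: terminal senescence first
# (threshold l_min_A), then first nta (switching the type to B).  Type B:
# senescence by the flat type-B law, else a new nta.
.onset_checks <- function(type, l, params) {
  if (type == "A") {
    if (stats::runif(1) < arrest_probability(params$a_sen_A, params$b_sen_A,
                                             params$l_min_A, l))
      return(list(alive = TRUE, type = "A", cycle = "sen", onset = TRUE))
    if (stats::runif(1) < arrest_probability(params$a_nta, params$b_nta, -Inf, l))
      return(list(alive = TRUE, type = "B", cycle = "nta", onset = FALSE))
    list(alive = TRUE, type = "A", cycle = "nor", onset = FALSE)
  } else {
    if (stats::runif(1) < arrest_probability(params$a_sen_B, params$b_sen_B,
                                             params$l_min_B, l))
      return(list(alive = TRUE, type = "B", cycle = "sen", onset = TRUE))
    if (stats::runif(1) < arrest_probability(params$a_nta, params$b_nta, -Inf, l))
      return(list(alive = TRUE, type = "B", cycle = "nta", onset = FALSE))
    list(alive = TRUE, type = "B", cycle = "nor", onset = FALSE)
  }
}

#' Determine the fate of one daughter cell
#'
#' Applies the per-division transition kernel to a daughter whose telomeres
#' have already been shortened, given its mother's type and cycle type.
#' Events are evaluated in a fixed order on `l = min(daughter_L)`:
#'
#' 1. accidental (telomere-independent) death with `p_accident`;
#' 2. a senescent mother transmits senescence: the daughter is senescent
#'    and the arrest sequence terminates in death with `p_death` per
#'    completed senescent cycle (drawn independently for each daughter);
#' 3. a non-terminally-arrested mother's daughter exits the arrest sequence
#'    with `p_repair` (repair or adaptation); an exiting daughter is
#'    immediately subject to the type-B onset checks of step 4, so an nta
#'    sequence can run directly into senescence with no intervening normal
#'    cycle (such lineages are observationally misclassified as type A);
#'    otherwise it remains in `nta`;
#' 4. a normally cycling mother's daughter undergoes the onset checks:
#'    type A enters terminal senescence with `p_sen,A(l)` (certain at or
#'    below `l_min_A = 27` bp), else becomes type B via a first
#'    non-terminal arrest with `p_nta(l)`, else stays `(A, nor)`; type B
#'    enters senescence with the flat `p_sen,B(l)`, else a new nta with
#'    `p_nta(l)`, else stays `(B, nor)`.
#'
#' @param mother_type,mother_cycle the mother's type and cycle type.
#' @param daughter_L the daughter's (post-shortening) telomere matrix, or a
#'   pre-computed shortest length via `l`.
#' @param params a [law_params()].
#' @param l optional shortcut: the daughter's shortest telomere length.
#' @return A list with `alive` (logical), `type`, `cycle`, `onset`
#'   (did this division start a terminal senescent sequence?) and, when
#'   dead, `death_cause` (`"accident"` or `"senescence"`).
#' @examples
#' p <- law_params(p_accident = 0)
#' set.seed(1)
#' next_cell_fate("A", "nor", params = p, l = 25)  # below 27 bp: senescent
#' @export
next_cell_fate <- function(mother_type, mother_cycle, daughter_L = NULL,
                           params = law_params(), l = NULL) {
  mother_type <- match.arg(mother_type, c("A", "B"))
  mother_cycle <- match.arg(mother_cycle, c("nor", "nta", "sen"))
  if (is.null(l)) {
    daughter_L <- as_telomere_matrix(daughter_L)
    l <- min(daughter_L)
  }
  if (mother_type == "A" && mother_cycle == "nta")
    stop("next_cell_fate: an nta mother must be type B")

  if (stats::runif(1) < params$p_accident)
    return(list(alive = FALSE, type = mother_type, cycle = mother_cycle,
                onset = FALSE, death_cause = "accident"))

  if (mother_cycle == "sen") {
    if (stats::runif(1) < params$p_death)
      return(list(alive = FALSE, type = mother_type, cycle = "sen",
                  onset = FALSE, death_cause = "senescence"))
    return(list(alive = TRUE, type = mother_type, cycle = "sen",
                onset = FALSE))
  }

  if (mother_cycle == "nta") {
    if (stats::runif(1) < params$p_repair)
      return(.onset_checks("B", l, params))
    return(list(alive = TRUE, type = "B", cycle = "nta", onset = FALSE))
  }

  .onset_checks(mother_type, l, params)
}
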