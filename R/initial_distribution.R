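#' Initial telomere-length distribution
#'
#' Describes the distribution `f_init` from which all 32 telomeres of every
#' founder cell are drawn i.i.d. at telomerase inactivation.  The base
#' distribution stands in for the telomerase-positive equilibrium length
#' distribution: either a smooth parametric unimodal density on
#' `[l_inf, l_sup]` with mode `l_mode` (a scaled Beta density, sampled by
#' inverse CDF), or a user-supplied empirical sample of lengths.
#'
#' The base distribution is then modified by two mode-preserving dilations
#' and a translation:
#' * the left segment `[l_inf, l_mode]` is mapped linearly onto
#'   `[l_inf + l_0, l_mode]`,
#' * the right segment `[l_mode, l_sup]` is mapped linearly onto
#'   `[l_mode, l_mode + l_1]`,
#' * then `l_trans` (signed, bp) is added everywhere.
#'
#' The mode is invariant under the dilations (before translation).  Lengths
#' are rounded to integer bp and clamped at zero.
#'
#' @param l_inf,l_mode,l_sup support minimum, mode and support maximum of
#'   the base distribution (bp); defaults 100, 300, 500.
#' @param l_trans signed translation of the whole distribution (bp).
#' @param l_0 left-dilation parameter (bp): the left support endpoint moves
#'   to `l_inf + l_0`.  Must satisfy `l_0 < l_mode - l_inf`.
#' @param l_1 right-dilation parameter (bp): the right support endpoint
#'   moves to `l_mode + l_1`.
#' @param concentration shape concentration of the parametric base density;
#'   larger values give a tighter peak around the mode.  With the default 4
#'   and a centred mode the base density is Beta(3, 3) rescaled to the
#'   support (SD about 76 bp on the default support).
#' @param base_sample optional numeric vector of lengths (bp) replacing the
#'   parametric base distribution (e.g. read with [read_length_sample()]).
#'   When supplied, `l_inf`/`l_mode`/`l_sup` default to its minimum, its
#'   most frequent value and its maximum.
#' @return An object of class `initial_distribution`.
#' @examples
#' d <- initial_distribution()                   # fitted dilation defaults
#' transform_length(c(100, 300, 500), d)         # support maps to [140, 358]
#' d0 <- initial_distribution(l_0 = 0, l_1 = 200, l_trans = 0)  # identity
#' @export
initial_distribution <- function(l_inf = 100, l_mode = 300, l_sup = 500,
                                 l_trans = 0, l_0 = 40, l_1 = 58,
                                 concentration = 4, base_sample = NULL) {
  if (!is.null(base_sample)) {
    base_sample <- as.numeric(base_sample)
    if (length(base_sample) < 1L || anyNA(base_sample) || any(base_sample < 0))
      stop("initial_distribution: base_sample must be non-negative lengths")
    if (missing(l_inf)) l_inf <- min(base_sample)
    if (missing(l_sup)) l_sup <- max(base_sample)
    if (missing(l_mode)) {
      tab <- table(round(base_sample))
      l_mode <- as.numeric(names(tab)[which.max(tab)])
    }
    base_sample <- sort(base_sample)
  }
  if (!(l_inf <= l_mode && l_mode <= l_sup))
    stop("initial_distribution: need l_inf <= l_mode <= l_sup")
  if (l_mode > l_inf && l_0 >= l_mode - l_inf)
    stop("initial_distribution: l_0 >= l_mode - l_inf collapses or inverts ",
         "the left segment")
  if (l_1 < 0) stop("initial_distribution: l_1 must be non-negative")
  if (concentration <= 0) stop("initial_distribution: concentration must be positive")
  span <- l_sup - l_inf
  m <- if (span > 0) (l_mode - l_inf) / span else 0.5
  structure(list(l_inf = l_inf, l_mode = l_mode, l_sup = l_sup,
                 l_trans = l_trans, l_0 = l_0, l_1 = l_1,
                 concentration = concentration,
                 shape1 = 1 + concentration * m,
                 shape2 = 1 + concentration * (1 - m),
                 base_sample = base_sample),
            class = "initial_distribution")
}

#' @export
print.initial_distribution <- function(x, ...) {
  base <- if (is.null(x$base_sample))
    sprintf("parametric Beta(%.2f, %.2f) on [%g, %g], mode %g",
            x$shape1, x$shape2, x$l_inf, x$l_sup, x$l_mode)
  else
    sprintf("empirical sample (n = %d) on [%g, %g], mode %g",
            length(x$base_sample), x$l_inf, x$l_sup, x$l_mode)
  cat("Initial telomere-length distribution\n  base: ", base, "\n", sep = "")
  cat(sprintf("  dilation l_0 = %g, l_1 = %g; translation l_trans = %g bp\n",
              x$l_0, x$l_1, x$l_trans))
  cat(sprintf("  transformed support [%g, %g]\n",
              max(0, round(x$l_inf + x$l_0 + x$l_trans)),
              max(0, round(x$l_mode + x$l_1 + x$l_trans))))
  invisible(x)
}

#' Apply the mode-preserving dilation and translation to lengths
#'
#' The piecewise-linear map described in [initial_distribution()]: the left
#' segment of the support is dilated by `l_0`, the right segment by `l_1`
#' (both preserving the mode), then the translation `l_trans` is added.
#' Results are rounded to the nearest integer bp and clamped at zero.
#'
#' @param x numeric vector of base lengths in `[l_inf, l_sup]`.
#' @param dist an [initial_distribution()].
#' @return Integer vector of transformed lengths (bp).
#' @examples
#' d <- initial_distribution(l_0 = 40, l_1 = 58)
#' transform_length(c(100, 300, 500), d)   # 140 300 358
#' @export
transform_length <- function(x, dist) {
  stopifnot(inherits(dist, "initial_distribution"))
  if (any(x < dist$l_inf - 1e-9 | x > dist$l_sup + 1e-9))
    stop("transform_length: x must lie within [l_inf, l_sup]")
  left_span <- dist$l_mode - dist$l_inf
  right_span <- dist$l_sup - dist$l_mode
  y <- numeric(length(x))
  left <- x <= dist$l_mode
  if (left_span > 0) {
    y[left] <- dist$l_inf + dist$l_0 +
      (x[left] - dist$l_inf) * (left_span - dist$l_0) / left_span
  } else {
    y[left] <- dist$l_mode
  }
  if (right_span > 0) {
    y[!left] <- dist$l_mode + (x[!left] - dist$l_mode) * dist$l_1 / right_span
  } else {
    y[!left] <- dist$l_mode
  }
  y <- y + dist$l_trans
  as.integer(pmax(0, round(y)))
}

#' Draw i.i.d. initial telomere lengths from the transformed distribution
#'
#' Inverse-CDF sampling: a uniform draw is mapped through the base
#' distribution's quantile function (parametric Beta quantile, or the
#' empirical quantile of a supplied sample) and then through
#' [transform_length()].  Because the transform is applied after the
#' uniform draw, runs with the same seed and different `l_trans` are
#' coupled: every sampled length shifts by exactly the translation.
#'
#' @param n number of lengths to draw.
#' @param dist an [initial_distribution()].
#' @return Integer vector of `n` lengths (bp).
#' @export
sample_initial_lengths <- function(n, dist) {
  stopifnot(inherits(dist, "initial_distribution"))
  u <- stats::runif(n)
  if (is.null(dist$base_sample)) {
    base <- dist$l_inf +
      (dist$l_sup - dist$l_inf) * stats::qbeta(u, dist$shape1, dist$shape2)
  } else {
    m <- length(dist$base_sample)
    base <- dist$base_sample[pmax(1L, ceiling(u * m))]
  }
  transform_length(base, dist)
}

#' Draw the full telomere matrix of one founder cell
#'
#' All `2 x 16 = 32` telomeres are i.i.d. from the transformed initial
#' distribution (rows = the two ends of each chromosome, columns = the 16
#' chromosomes of haploid *S. cerevisiae*).
#'
#' @inheritParams sample_initial_lengths
#' @return A `2 x 16` integer matrix of lengths (bp).
#' @examples
#' set.seed(1)
#' L <- sample_initial_matrix(initial_distribution())
#' dim(L)       # 2 16
#' min(L)       # the founder's shortest telomere
#' @export
sample_initial_matrix <- function(dist) {
  matrix(sample_initial_lengths(32L, dist), nrow = 2L, ncol = 16L)
}

#' Read a plain-text sample of telomere lengths
#'
#' One length (bp) per line; used to replace the parametric base
#' distribution by measured or externally simulated telomerase-positive
#' equilibrium lengths.
#'
#' @param path file path.
#' @return Numeric vector of lengths.
#' @export
read_length_sample <- function(path) {
  x <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  if (length(x) == 0) stop("read_length_sample: no lengths in ", path)
  if (any(x < 0)) stop("read_length_sample: negative length in ", path)
  x
}
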