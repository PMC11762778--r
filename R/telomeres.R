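#' Validate a telomere matrix
#'
#' A haploid cell carries 16 chromosomes, each with two telomeric ends:
#' lengths are stored as a `2 x 16` non-negative integer matrix (rows = the
#' two ends, columns = chromosomes).
#'
#' @param L matrix to validate.
#' @return `L`, invisibly, as an integer matrix.
#' @export
as_telomere_matrix <- function(L) {
  if (!is.matrix(L) || !identical(dim(L), c(2L, 16L)))
    stop("telomere matrix must be 2 x 16 (two ends of each of 16 chromosomes)")
  if (anyNA(L) || any(L < 0))
    stop("telomere lengths must be non-negative and non-missing")
  storage.mode(L) <- "integer"
  invisible(L)
}

#' Divide a cell's telomeres between two daughters
#'
#' Implements the coupled asymmetric shortening rule of telomere
#' replication.  For each chromosome, exactly one of the two telomeric ends
#' is shortened by the overhang `h` in each daughter, and the end shortened
#' in one daughter is the end left at the parental length in the other:
#' with a fair Bernoulli draw `B_j` per chromosome `j`,
#' daughter 1 gets `(l1 - h*B_j, l2 - h*(1 - B_j))` and daughter 2 gets the
#' complementary `(l1 - h*(1 - B_j), l2 - h*B_j)`.  Chromosomes are
#' mutually independent; lengths clamp at zero.
#'
#' @param parent `2 x 16` telomere matrix of the mother cell.
#' @param h overhang (bp), a single non-negative number.
#' @return A list with integer matrices `daughter1` and `daughter2`.
#' @examples
#' L <- matrix(100L, 2, 16)
#' set.seed(1)
#' d <- divide_telomeres(L, h = 7)
#' # per chromosome, total shortening across both daughters is 2 h:
#' all(colSums(d$daughter1) + colSums(d$daughter2) == 2 * colSums(L) - 2 * 7)
#' @export
divide_telomeres <- function(parent, h = 7) {
  parent <- as_telomere_matrix(parent)
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < 0)
    stop("divide_telomeres: h must be a single non-negative number")
  b <- stats::runif(16L) < 0.5
  cut1 <- rbind(h * b, h * !b)       # which end loses h in daughter 1
  d1 <- pmax(parent - cut1, 0)
  d2 <- pmax(parent - (h - cut1), 0) # complementary ends in daughter 2
  storage.mode(d1) <- "integer"
  storage.mode(d2) <- "integer"
  list(daughter1 = d1, daughter2 = d2)
}
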