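#' Convert raw expression levels to a relative expression profile
#'
#' A relative expression profile rescales a gene's raw expression vector to
#' proportions of its total expression, so that only the pattern across
#' samples — not overall expression magnitude — enters the distance
#' computations.
#'
#' @param raw numeric vector of non-negative, finite raw expression levels
#'   over `n >= 1` samples; at least one entry must be positive.
#' @return Numeric vector of the same length with entries in `[0, 1]`
#'   summing to 1.
#' @examples
#' to_relative(c(10, 30, 60))   # 0.1 0.3 0.6
#' @seealso [combined_relative()], [genomewide_relative()]
#' @export
to_relative <- function(raw) {
  if (!is.numeric(raw) || length(raw) < 1L)
    stop("'raw' must be a non-empty numeric vector")
  if (any(!is.finite(raw))) stop("expression values must be finite")
  if (any(raw < 0)) stop("expression values must be non-negative")
  total <- sum(raw)
  if (total == 0)
    stop("zero-expression vector: relative profile is undefined")
  raw / total
}

#' Combined relative profile of a duplicate pair
#'
#' The combined profile treats the two duplicate copies as a single locus:
#' by default the raw expression vectors are summed and the pooled vector is
#' normalised (`method = "raw-sum"`), so the copy with higher total
#' expression contributes proportionally more.  `method = "relative-mean"`
#' instead averages the two copies' individual relative profiles with equal
#' weight.  The two definitions agree exactly when the copies have equal
#' total expression and differ otherwise.
#'
#' @param raw_copy1,raw_copy2 raw expression vectors of the two copies, same
#'   length.
#' @param method pooling rule, see Details.
#' @return Relative profile of the pair, entries summing to 1.
#' @examples
#' combined_relative(c(10, 0), c(0, 10))   # 0.5 0.5
#' @export
combined_relative <- function(raw_copy1, raw_copy2,
                              method = c("raw-sum", "relative-mean")) {
  method <- match.arg(method)
  if (length(raw_copy1) != length(raw_copy2))
    stop("duplicate copies have different numbers of samples (",
         length(raw_copy1), " vs ", length(raw_copy2), ")")
  if (method == "raw-sum") {
    to_relative(raw_copy1 + raw_copy2)
  } else {
    (to_relative(raw_copy1) + to_relative(raw_copy2)) / 2
  }
}

#' Genome-wide relative expression (single-sample data)
#'
#' With a single expression measurement per gene (`n = 1`) the per-gene
#' normalisation is degenerate: every profile would be exactly 1 and every
#' distance 0.  In that case each gene's value is instead expressed as a
#' proportion of the table-wide expression total, giving cross-species
#' comparable scalar profiles.
#'
#' @param table an [expression_table()] with exactly one sample column.
#' @return Named numeric vector: one proportion per gene, summing to 1.
#' @export
genomewide_relative <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  if (ncol(table$values) != 1L)
    stop("genomewide_relative() applies only to single-sample tables")
  total <- sum(table$values)
  if (total == 0) stop("expression table total is zero")
  stats::setNames(table$values[, 1L] / total, table$genes)
}

## Row-normalise a whole table; rows with zero total become NA rows and are
## reported in the "zero_genes" attribute for the caller's drop policy.
relative_matrix <- function(table) {
  v <- table$values
  totals <- rowSums(v)
  out <- v / totals
  zero <- totals == 0
  out[zero, ] <- NA_real_
  attr(out, "zero_genes") <- table$genes[zero]
  out
}
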