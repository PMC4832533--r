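#' Euclidean distance between two relative expression profiles
#'
#' The number of samples sets the dimensionality of the space in which
#' profiles live.  For profiles that are proportion vectors (n > 1 samples)
#' the distance lies in `[0, sqrt(2)]`, the maximum being attained only by
#' profiles with disjoint support.
#'
#' @param p,q numeric vectors of equal length.
#' @return Non-negative scalar `sqrt(sum((p - q)^2))`.
#' @examples
#' profile_distance(c(1, 0), c(0, 1))          # sqrt(2)
#' profile_distance(c(0.5, 0.5), c(0.8, 0.2))  # sqrt(0.18)
#' @export
profile_distance <- function(p, q) {
  if (length(p) != length(q))
    stop("profiles have different dimensions (", length(p), " vs ",
         length(q), ")")
  sqrt(sum((p - q)^2))
}

## Relative profiles for both species, dispatching on the n = 1 special
## case (genome-wide normalisation) vs the standard per-gene normalisation.
## Returns per-species lookup matrices (genes x n) with zero-total genes NA.
profile_lookup <- function(expr) {
  if (ncol(expr$values) == 1L) {
    rel <- genomewide_relative(expr)
    m <- matrix(rel, ncol = 1L, dimnames = list(names(rel), expr$samples))
    attr(m, "zero_genes") <- expr$genes[expr$values[, 1L] == 0]
    attr(m, "single_sample_total") <- sum(expr$values)
    m
  } else {
    relative_matrix(expr)
  }
}

#' Per-triplet expression divergence from the ancestor
#'
#' For each duplicate triplet, computes the Euclidean distances between the
#' relative profile of each copy and that of the ancestral gene, and between
#' the combined pair profile and the ancestral profile.  Triplets containing
#' a gene with zero total expression are dropped with a warning (their
#' relative profiles are undefined); the dropped IDs are recorded in the
#' `dropped` attribute of the result.
#'
#' @param triplets data frame with columns `copy1`, `copy2`, `ancestor`
#'   (see [read_triplet_table()]); copies must resolve in `expr1`, ancestors
#'   in `expr2`.
#' @param expr1,expr2 [expression_table()]s for species 1 (the species
#'   carrying the duplicates) and species 2 (carrying the ancestral
#'   single-copy genes); must have the same number of samples.
#' @param combine pooling rule for the combined pair profile, see
#'   [combined_relative()].
#' @return Data frame with the triplet IDs and columns `E_copy1_A`,
#'   `E_copy2_A`, `E_combined_A`; attribute `dropped` lists triplets
#'   removed under the zero-expression policy.
#' @export
triplet_distances <- function(triplets, expr1, expr2,
                              combine = c("raw-sum", "relative-mean")) {
  combine <- match.arg(combine)
  stopifnot(inherits(expr1, "expression_table"),
            inherits(expr2, "expression_table"))
  n <- ncol(expr1$values)
  if (ncol(expr2$values) != n)
    stop("the two expression tables must have the same number of samples (",
         n, " vs ", ncol(expr2$values), ")")
  check_resolvable(c(triplets$copy1, triplets$copy2), expr1,
                   c(triplets$ancestor), expr2, what = "triplet")
  rel1 <- profile_lookup(expr1)
  rel2 <- profile_lookup(expr2)

  zero1 <- attr(rel1, "zero_genes")
  zero2 <- attr(rel2, "zero_genes")
  has_zero <- triplets$copy1 %in% zero1 | triplets$copy2 %in% zero1 |
    triplets$ancestor %in% zero2
  dropped <- triplets[has_zero, , drop = FALSE]
  if (nrow(dropped))
    warning(nrow(dropped), " triplet(s) dropped: member gene(s) with zero ",
            "total expression (",
            paste(utils::head(unique(unlist(dropped)), 6L), collapse = ", "),
            if (length(unique(unlist(dropped))) > 6L) ", ..." else "", ")")
  kept <- triplets[!has_zero, , drop = FALSE]

  e1 <- e2 <- ec <- numeric(nrow(kept))
  raw1 <- expr1$values
  tot1 <- attr(rel1, "single_sample_total")  # non-NULL only when n = 1
  for (i in seq_len(nrow(kept))) {
    a <- rel2[kept$ancestor[i], ]
    p1 <- rel1[kept$copy1[i], ]
    p2 <- rel1[kept$copy2[i], ]
    comb <- if (n == 1L) {
      # genome-wide normalisation: the pooled pair as proportion of the
      # species-1 expression total (raw-sum is the only meaningful pooling)
      (raw1[kept$copy1[i], 1L] + raw1[kept$copy2[i], 1L]) / tot1
    } else {
      combined_relative(raw1[kept$copy1[i], ], raw1[kept$copy2[i], ],
                        method = combine)
    }
    e1[i] <- profile_distance(p1, a)
    e2[i] <- profile_distance(p2, a)
    ec[i] <- profile_distance(comb, a)
  }
  out <- data.frame(kept, E_copy1_A = e1, E_copy2_A = e2, E_combined_A = ec,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dropped") <- dropped
  out
}

#' Expression divergence between single-copy orthologs
#'
#' One Euclidean distance per ortholog pair, between the species-1 and
#' species-2 relative profiles.  This distribution calibrates the
#' expression-divergence cutoff (see [estimate_cutoffs()]).  Pairs with a
#' zero-expression member are dropped with a warning.
#'
#' @param pairs data frame with columns `s1`, `s2`
#'   (see [read_ortholog_table()]).
#' @inheritParams triplet_distances
#' @return Numeric vector of distances in file order (attribute `dropped`
#'   lists removed pairs).
#' @export
ortholog_distances <- function(pairs, expr1, expr2) {
  stopifnot(inherits(expr1, "expression_table"),
            inherits(expr2, "expression_table"))
  if (ncol(expr1$values) != ncol(expr2$values))
    stop("the two expression tables must have the same number of samples")
  check_resolvable(pairs$s1, expr1, pairs$s2, expr2, what = "ortholog")
  rel1 <- profile_lookup(expr1)
  rel2 <- profile_lookup(expr2)
  has_zero <- pairs$s1 %in% attr(rel1, "zero_genes") |
    pairs$s2 %in% attr(rel2, "zero_genes")
  dropped <- pairs[has_zero, , drop = FALSE]
  if (nrow(dropped))
    warning(nrow(dropped), " ortholog pair(s) dropped: zero total expression")
  kept <- pairs[!has_zero, , drop = FALSE]
  if (nrow(kept) == 0L)
    stop("no ortholog pairs survive filtering: divergence cutoff cannot ",
         "be estimated")
  d <- vapply(seq_len(nrow(kept)), function(i)
    profile_distance(rel1[kept$s1[i], ], rel2[kept$s2[i], ]), numeric(1L))
  attr(d, "dropped") <- dropped
  d
}

check_resolvable <- function(ids1, expr1, ids2, expr2, what) {
  miss1 <- setdiff(ids1, expr1$genes)
  miss2 <- setdiff(ids2, expr2$genes)
  if (length(miss1) || length(miss2))
    stop(what, " table references gene(s) absent from the expression ",
         "tables: ",
         paste(utils::head(c(miss1, miss2), 10L), collapse = ", "),
         if (length(c(miss1, miss2)) > 10L) ", ..." else "",
         "\n(use skip_missing = TRUE to drop them instead)")
  invisible(TRUE)
}

#' Calibrate expression-divergence cutoffs from ortholog distances
#'
#' Single-copy orthologs evolve without the relaxed constraint that follows
#' duplication, so the spread of their expression distances measures how far
#' apart two profiles can drift while the gene keeps its ancestral role.
#' The default cutoff is the median of the ortholog-distance distribution
#' plus its semi-interquartile range, SIQR = (Q3 - Q1)/2 — a robust
#' location-plus-half-spread threshold that is insensitive to distribution
#' shape and outliers.  Five candidate cutoffs, median + k * SIQR for
#' k in {0, 0.5, 1, 1.5, 2}, bracket the default for sensitivity analysis.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param d numeric vector of ortholog expression distances (non-empty).
#' @param user_ediv optional user-supplied cutoff overriding the default.
#' @return Object of class `ediv_cutoffs`: a list with elements `median`,
#'   `siqr`, `default`, `candidates` (length 5), `chosen` and `source`
#'   (`"default"` or `"user"`).
#' @examples
#' estimate_cutoffs(c(0.1, 0.2, 0.3, 0.4, 0.5))
#' @export
estimate_cutoffs <- function(d, user_ediv = NULL) {
  if (!is.numeric(d) || length(d) == 0L)
    stop("ortholog distance vector is empty: cannot estimate cutoff")
  if (any(!is.finite(d)) || any(d < 0))
    stop("ortholog distances must be finite and non-negative")
  if (!is.null(user_ediv)) {
    if (!is.numeric(user_ediv) || length(user_ediv) != 1L ||
        !is.finite(user_ediv) || user_ediv < 0)
      stop("'user_ediv' must be a single non-negative number")
  }
  q <- unname(stats::quantile(d, c(0.25, 0.5, 0.75), type = 7))
  siqr <- (q[3L] - q[1L]) / 2
  candidates <- q[2L] + c(0, 0.5, 1, 1.5, 2) * siqr
  default <- q[2L] + siqr
  structure(list(median = q[2L], siqr = siqr, default = default,
                 candidates = candidates,
                 chosen = if (is.null(user_ediv)) default else user_ediv,
                 source = if (is.null(user_ediv)) "default" else "user",
                 n_orthologs = length(d)),
            class = "ediv_cutoffs")
}

#' @export
print.ediv_cutoffs <- function(x, ...) {
  cat(sprintf("Expression-divergence cutoff (from %d ortholog distances)\n",
              x$n_orthologs))
  cat(sprintf("  median = %.6f, SIQR = %.6f\n", x$median, x$siqr))
  cat(sprintf("  chosen E_div = %.6f (%s)\n", x$chosen, x$source))
  cat("  candidates:", paste(sprintf("%.6f", x$candidates), collapse = " "),
      "\n")
  invisible(x)
}
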