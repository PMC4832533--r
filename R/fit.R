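#' Classify the retention mechanisms of duplicate gene pairs
#'
#' The main entry point of the package.  Given a table of duplicate gene
#' pairs in species 1 with their ancestral single-copy genes in a sister
#' species 2, a table of single-copy orthologs between the two species, and
#' an expression table for each species over the same matched samples, this
#' function:
#' \enumerate{
#'   \item converts raw expression to relative profiles (proportions of each
#'     gene's total expression; with a single sample, proportions of the
#'     table-wide total);
#'   \item computes Euclidean distances from each duplicate copy and from
#'     the combined pair profile to the ancestral profile, and between the
#'     profiles of every ortholog pair;
#'   \item calibrates the expression-divergence cutoff from the ortholog
#'     distance distribution (default: median + SIQR; see
#'     [estimate_cutoffs()]) unless `ediv` is supplied;
#'   \item classifies each pair as conservation, neofunctionalization,
#'     subfunctionalization or specialization (see [classify_mechanism()])
#'     and tabulates counts across five candidate cutoffs.
#' }
#'
#' @param duplicates duplicate-triplet table: a path (see
#'   [read_triplet_table()]) or a data frame with columns `copy1`, `copy2`,
#'   `ancestor`.
#' @param orthologs single-copy ortholog table: a path (see
#'   [read_ortholog_table()]) or a data frame with columns `s1`, `s2`.
#' @param expr1,expr2 expression tables for species 1 (carrying the
#'   duplicates) and species 2 (carrying the ancestral genes): paths,
#'   numeric matrices with gene row names, or [expression_table()]s.  Both
#'   must cover the same `n >= 1` ordered samples.
#' @param oriented logical; `TRUE` if `copy1` is the parent copy (the copy
#'   retaining the ancestral locus) and `copy2` the child copy produced by
#'   the duplication.  Classification is identical; oriented mode only
#'   relabels the diverged copy as P/C and splits the neofunctionalization
#'   counts by which copy diverged.
#' @param ediv optional user-specified expression-divergence cutoff; when
#'   `NULL` (default) the cutoff is calibrated from the orthologs.
#' @param combine pooling rule for the combined pair profile
#'   (see [combined_relative()]).
#' @param skip_missing if `TRUE`, triplets or ortholog pairs referencing
#'   genes absent from the expression tables are dropped with a warning
#'   instead of raising an error.
#' @return An object of class `dupclass`: a list with elements
#'   \describe{
#'     \item{results}{per-pair calls at the chosen cutoff (IDs, the three
#'       distances, `Ediv`, `mechanism`, `diverged_copy`);}
#'     \item{counts}{mechanism counts at each candidate cutoff;}
#'     \item{cutoffs}{the [estimate_cutoffs()] object;}
#'     \item{ortholog_distances}{the calibration distances;}
#'     \item{dropped}{triplets/pairs removed (missing IDs or zero
#'       expression);}
#'     \item{oriented, combine, n_samples, call}{run metadata.}
#'   }
#' @examples
#' sim <- simulate_duplicates(n_per_mechanism = 10, n_orthologs = 50,
#'                            seed = 1)
#' fit <- classify_duplicates(sim$triplets, sim$orthologs,
#'                            sim$expr1, sim$expr2)
#' fit
#' table(fit$results$mechanism)
#' @seealso [plot.dupclass()], [predict.dupclass()], [run_pipeline()]
#' @export
classify_duplicates <- function(duplicates, orthologs, expr1, expr2,
                                oriented = FALSE, ediv = NULL,
                                combine = c("raw-sum", "relative-mean"),
                                skip_missing = FALSE) {
  combine <- match.arg(combine)
  cl <- match.call()

  if (is.character(duplicates) && length(duplicates) == 1L)
    duplicates <- read_triplet_table(duplicates, oriented = oriented)
  if (is.character(orthologs) && length(orthologs) == 1L)
    orthologs <- read_ortholog_table(orthologs)
  expr1 <- as_expression_table(expr1, species = "species1")
  expr2 <- as_expression_table(expr2, species = "species2")
  check_triplet_frame(duplicates)
  check_pair_frame(orthologs)
  if (ncol(expr1$values) != ncol(expr2$values))
    stop("expression tables disagree on the number of samples (",
         ncol(expr1$values), " vs ", ncol(expr2$values), ")")
  if (nrow(duplicates) == 0L) stop("duplicate table is empty")
  if (nrow(orthologs) == 0L && is.null(ediv))
    stop("ortholog table is empty and no 'ediv' was supplied: the ",
         "divergence cutoff cannot be estimated")

  dropped <- list()
  if (skip_missing) {
    keep <- duplicates$copy1 %in% expr1$genes &
      duplicates$copy2 %in% expr1$genes &
      duplicates$ancestor %in% expr2$genes
    dropped$missing_triplets <- duplicates[!keep, , drop = FALSE]
    if (any(!keep)) {
      warning(sum(!keep), " triplet(s) dropped: unresolvable gene IDs")
      duplicates <- duplicates[keep, , drop = FALSE]
      if (nrow(duplicates) == 0L)
        stop("all triplets reference genes absent from the expression tables")
    }
    keep <- orthologs$s1 %in% expr1$genes & orthologs$s2 %in% expr2$genes
    dropped$missing_orthologs <- orthologs[!keep, , drop = FALSE]
    if (any(!keep)) {
      warning(sum(!keep), " ortholog pair(s) dropped: unresolvable gene IDs")
      orthologs <- orthologs[keep, , drop = FALSE]
    }
  }

  records <- triplet_distances(duplicates, expr1, expr2, combine = combine)
  dropped$zero_expression_triplets <- attr(records, "dropped")
  if (nrow(records) == 0L)
    stop("no triplets survive the zero-expression filter")

  if (nrow(orthologs) > 0L) {
    od <- ortholog_distances(orthologs, expr1, expr2)
    dropped$zero_expression_orthologs <- attr(od, "dropped")
    cutoffs <- estimate_cutoffs(as.numeric(od), user_ediv = ediv)
  } else {
    od <- numeric(0)
    cutoffs <- structure(list(median = NA_real_, siqr = NA_real_,
                              default = NA_real_, candidates = ediv,
                              chosen = ediv, source = "user",
                              n_orthologs = 0L),
                         class = "ediv_cutoffs")
  }

  cls <- classify_all(records, cutoffs, oriented = oriented)
  structure(list(results = cls$results, counts = cls$counts,
                 cutoffs = cutoffs,
                 ortholog_distances = as.numeric(od),
                 dropped = dropped, oriented = oriented, combine = combine,
                 n_samples = ncol(expr1$values), call = cl),
            class = "dupclass")
}

check_triplet_frame <- function(x) {
  if (!is.data.frame(x) ||
      !all(c("copy1", "copy2", "ancestor") %in% names(x)))
    stop("'duplicates' must be a path or a data frame with columns ",
         "'copy1', 'copy2', 'ancestor'")
  if (any(x$copy1 == x$copy2))
    stop("triplet with copy1 == copy2 at row ",
         which(x$copy1 == x$copy2)[1L])
  invisible(x)
}

check_pair_frame <- function(x) {
  if (!is.data.frame(x) || !all(c("s1", "s2") %in% names(x)))
    stop("'orthologs' must be a path or a data frame with columns ",
         "'s1', 's2'")
  invisible(x)
}

#' @export
print.dupclass <- function(x, ...) {
  cat("Duplicate-gene retention mechanism classification\n")
  cat(sprintf("  %d duplicate pair(s) over %d sample(s), %s mode\n",
              nrow(x$results), x$n_samples,
              if (x$oriented) "oriented (parent/child)" else
                "generalized (D1/D2)"))
  cat(sprintf("  E_div = %.6f (%s; ortholog median %.6f, SIQR %.6f)\n",
              x$cutoffs$chosen, x$cutoffs$source, x$cutoffs$median,
              x$cutoffs$siqr))
  tab <- table(factor(x$results$mechanism, levels = MECHANISMS))
  for (m in MECHANISMS)
    cat(sprintf("  %-22s %d\n", m, tab[[m]]))
  invisible(x)
}

#' Summary of a duplicate-classification fit
#'
#' @param object a [classify_duplicates()] fit.
#' @param ... unused.
#' @return A `summary.dupclass` object: mechanism counts at the chosen
#'   cutoff and across candidates, cutoff calibration, and drop accounting.
#' @export
summary.dupclass <- function(object, ...) {
  n_dropped <- sum(vapply(object$dropped, NROW, integer(1L)))
  structure(list(n_pairs = nrow(object$results),
                 n_samples = object$n_samples,
                 oriented = object$oriented,
                 cutoffs = object$cutoffs,
                 mechanism_table =
                   table(factor(object$results$mechanism,
                                levels = MECHANISMS)),
                 diverged_table = table(object$results$diverged_copy),
                 counts = object$counts,
                 n_dropped = n_dropped),
            class = "summary.dupclass")
}

#' @export
print.summary.dupclass <- function(x, ...) {
  cat(sprintf(
    "Classification of %d duplicate pair(s) (%d sample(s), %s mode)\n",
    x$n_pairs, x$n_samples,
    if (x$oriented) "oriented" else "generalized"))
  print(x$cutoffs)
  cat("Mechanism calls at chosen E_div:\n")
  print(x$mechanism_table)
  cat("Diverged copy:\n")
  print(x$diverged_table)
  cat("Counts across candidate cutoffs:\n")
  print(x$counts, row.names = FALSE)
  if (x$n_dropped > 0L)
    cat(sprintf("%d triplet(s)/pair(s) dropped before classification\n",
                x$n_dropped))
  invisible(x)
}

#' Re-classify a fit at a different divergence cutoff
#'
#' Classification is a deterministic function of the stored distances, so
#' alternative cutoffs can be explored without recomputing profiles or
#' distances.
#'
#' @param object a [classify_duplicates()] fit.
#' @param ediv cutoff to classify at; defaults to the fit's chosen cutoff
#'   (returning the fitted calls).
#' @param ... unused.
#' @return The per-pair results data frame at `ediv`.
#' @export
predict.dupclass <- function(object, ediv = NULL, ...) {
  if (is.null(ediv)) return(object$results)
  cutoffs <- object$cutoffs
  cutoffs$chosen <- ediv
  cutoffs$source <- "user"
  rec <- object$results[setdiff(names(object$results),
                                c("Ediv", "mechanism", "diverged_copy"))]
  classify_all(rec, cutoffs, oriented = object$oriented)$results
}
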