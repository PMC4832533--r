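#' Construct an expression table
#'
#' An expression table holds raw, non-negative expression levels for one
#' species as a genes-by-samples matrix.  Values are unit-agnostic: RPKM,
#' TPM, microarray intensities or any other non-negative quantification are
#' acceptable, provided the two species' tables were produced comparably and
#' share the same ordered set of samples.
#'
#' @param values numeric matrix, genes in rows, samples in columns; all
#'   entries finite and `>= 0`.  Row names are the gene identifiers and must
#'   be unique; column names are the sample labels.
#' @param species free-text label for the species the table belongs to.
#' @return An object of class `expression_table`: a list with elements
#'   `values` (the validated matrix), `genes`, `samples` and `species`.
#' @examples
#' m <- matrix(c(10, 0, 5, 0, 10, 5), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' expression_table(m, species = "spA")
#' @export
expression_table <- function(values, species = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (ncol(values) < 1L)
    stop("expression table must have at least one sample column")
  if (is.null(rownames(values)))
    stop("expression table must have gene identifiers as row names")
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  structure(list(values = values,
                 genes = rownames(values),
                 samples = colnames(values),
                 species = as.character(species)[1L]),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("Expression table%s: %d genes x %d sample%s\n",
              if (nzchar(x$species)) paste0(" [", x$species, "]") else "",
              length(x$genes), length(x$samples),
              if (length(x$samples) == 1L) "" else "s"))
  invisible(x)
}

#' @export
dim.expression_table <- function(x) dim(x$values)

## coerce path / matrix / data.frame inputs into an expression_table
as_expression_table <- function(x, species = "") {
  if (inherits(x, "expression_table")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(read_expression_table(x, species_label = species))
  if (is.data.frame(x)) x <- as.matrix(x)
  expression_table(x, species = species)
}

#' Read a tab-delimited expression table
#'
#' The file must have a header row (first field names the gene-ID column,
#' remaining fields are sample labels), one row per gene, the gene identifier
#' in the first column and one numeric expression column per sample.
#'
#' @param path path to a tab-separated text file.
#' @param species_label label stored in the returned table; defaults to the
#'   file name.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path, species_label = basename(path)) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", blank.lines.skip = TRUE)
  if (ncol(raw) < 2L)
    stop("expression table '", path, "' has no sample columns")
  genes <- raw[[1L]]
  num <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw) - 1L,
                dimnames = list(genes, colnames(raw)[-1L]))
  for (j in seq_len(ncol(num))) {
    col <- raw[[j + 1L]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !is.na(col) & nzchar(trimws(col)))
    if (length(bad))
      stop(sprintf(
        "malformed numeric value '%s' in '%s', row %d (gene '%s'), column '%s'",
        col[bad[1L]], path, bad[1L], genes[bad[1L]], colnames(num)[j]))
    num[, j] <- v
  }
  if (anyNA(num))
    stop("missing expression value(s) in '", path, "'")
  expression_table(num, species = species_label)
}

#' Write an expression table to a tab-delimited file
#'
#' Inverse of [read_expression_table()]: gene IDs in the first column
#' (header `gene`), one column per sample.  Values are written with full
#' double precision so a write/read round trip is exact.
#'
#' @param table an [expression_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path) {
  stopifnot(inherits(table, "expression_table"))
  df <- data.frame(gene = table$genes,
                   format(table$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", table$samples)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## shared reader for headerless n-column ID tables
read_id_table <- function(path, n_fields, what, col_names, header = FALSE) {
  if (!file.exists(path)) stop(what, " table not found: ", path)
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- as.data.frame(rep(list(character(0)), n_fields))
    names(out) <- col_names
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  len <- lengths(fields)
  if (any(len != n_fields))
    stop(sprintf("%s table '%s': row %d has %d field(s), expected %d",
                 what, path, which(len != n_fields)[1L],
                 len[len != n_fields][1L], n_fields))
  out <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(out) <- col_names
  out[] <- lapply(out, trimws)
  out
}

#' Read a duplicate-gene triplet table
#'
#' Each row maps one duplicate gene pair in species 1 to its ancestral
#' single-copy gene in species 2: three tab-separated identifiers
#' `copy1 <TAB> copy2 <TAB> ancestor`, no header by default.  When
#' `oriented = TRUE` the first column is taken to be the parent copy (the
#' copy at the ancestral locus) and the second the child copy (the new copy
#' created by the duplication); otherwise the copies are unordered
#' duplicates D1/D2.
#'
#' @param path path to a tab-separated text file.
#' @param oriented logical; is column 1 the parent and column 2 the child?
#' @param header logical; skip a header row.
#' @return A data frame with columns `copy1`, `copy2`, `ancestor` and
#'   attribute `oriented`.
#' @export
read_triplet_table <- function(path, oriented = FALSE, header = FALSE) {
  out <- read_id_table(path, 3L, "duplicate triplet",
                       c("copy1", "copy2", "ancestor"), header = header)
  same <- out$copy1 == out$copy2
  if (any(same))
    stop("triplet table '", path, "': copy1 equals copy2 in row ",
         which(same)[1L], " ('", out$copy1[which(same)[1L]], "')")
  attr(out, "oriented") <- isTRUE(oriented)
  out
}

#' Read a single-copy ortholog table
#'
#' Each row pairs a species-1 gene with its single-copy ortholog in
#' species 2: two tab-separated identifiers, no header by default.
#'
#' @inheritParams read_triplet_table
#' @return A data frame with columns `s1` and `s2`, in file order.
#' @export
read_ortholog_table <- function(path, header = FALSE) {
  read_id_table(path, 2L, "ortholog", c("s1", "s2"), header = header)
}

#' Write the per-pair classification table
#'
#' One row per classified duplicate pair: the three gene identifiers, the
#' three Euclidean distances (6 decimal places), the cutoff used, the
#' mechanism call and which copy diverged.
#'
#' @param results data frame of per-triplet calls, as found in the
#'   `results` element of a [classify_duplicates()] fit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_classification_table <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("no classification results to write")
  out <- results
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(v) sprintf("%.6f", v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the cutoff-sensitivity counts table
#'
#' One row per candidate expression-divergence cutoff, one count column per
#' mechanism (in oriented mode neofunctionalization is split into
#' parent-diverged and child-diverged columns).  Each row's counts sum to
#' the number of classified duplicate pairs.
#'
#' @param counts data frame of mechanism counts, as found in the `counts`
#'   element of a [classify_duplicates()] fit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  if (!is.data.frame(counts) || nrow(counts) == 0L)
    stop("no classification counts to write")
  out <- counts
  out$Ediv <- sprintf("%.6f", out$Ediv)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
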