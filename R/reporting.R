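#' Plot the expression-distance distributions and the divergence cutoff
#'
#' Kernel-density view of every distance distribution the classification
#' rests on, with a labelled vertical line at the chosen cutoff.  In
#' generalized mode three curves are drawn: the pooled copy--ancestor
#' distances (E_D1,A + E_D2,A), the combined-pair distances (E_D1+D2,A) and
#' the ortholog distances (E_S1,S2).  In oriented mode the copy distances
#' are split into parent (E_P,A) and child (E_C,A) curves, four in total.
#' Densities use a Gaussian kernel with the standard plug-in bandwidth,
#' evaluated on the distance support (from 0 to `sqrt(2)` for multi-sample
#' profiles) so no mass is smeared below zero; groups with too few distinct
#' values for a density fall back to rug marks.
#'
#' @param x a [classify_duplicates()] fit.
#' @param main plot title.
#' @param lwd line width for the density curves.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dupclass <- function(x, main = "Expression divergence distributions",
                          lwd = 2, ...) {
  r <- x$results
  if (x$oriented) {
    groups <- list("E[list(P, A)]" = r$E_copy1_A,
                   "E[list(C, A)]" = r$E_copy2_A,
                   "E[list(P + C, A)]" = r$E_combined_A,
                   "E[list(S1, S2)]" = x$ortholog_distances)
  } else {
    groups <- list("E[list(D1, A)] + E[list(D2, A)]" =
                     c(r$E_copy1_A, r$E_copy2_A),
                   "E[list(D1 + D2, A)]" = r$E_combined_A,
                   "E[list(S1, S2)]" = x$ortholog_distances)
  }
  groups <- groups[vapply(groups, length, integer(1L)) > 0L]
  upper <- if (x$n_samples > 1L) sqrt(2) else
    max(unlist(groups), x$cutoffs$chosen, na.rm = TRUE) * 1.05
  dens <- lapply(groups, function(v) {
    if (length(v) >= 2L && stats::sd(v) > 0)
      stats::density(v, from = 0, to = upper)
    else NULL
  })
  ymax <- max(c(vapply(dens[!vapply(dens, is.null, logical(1L))],
                       function(d) max(d$y), numeric(1L)), 1))
  cols <- grDevices::hcl.colors(max(length(groups), 3L), "Dark 3")
  graphics::plot(NA, xlim = c(0, upper), ylim = c(0, ymax * 1.05),
                 xlab = "Euclidean distance between relative profiles",
                 ylab = "Density", main = main, ...)
  for (i in seq_along(groups)) {
    if (is.null(dens[[i]]))
      graphics::rug(groups[[i]], col = cols[i], lwd = lwd)
    else
      graphics::lines(dens[[i]], col = cols[i], lwd = lwd)
  }
  graphics::abline(v = x$cutoffs$chosen, lty = 2, lwd = lwd,
                   col = "grey30")
  graphics::mtext(substitute(E[div] == v,
                             list(v = signif(x$cutoffs$chosen, 4))),
                  side = 3, at = x$cutoffs$chosen, cex = 0.9)
  graphics::legend("topright",
                   legend = sapply(names(groups),
                                   function(s) parse(text = s)[[1L]]),
                   col = cols[seq_along(groups)], lwd = lwd, bty = "n")
  invisible(x)
}

#' Run the full classification pipeline and write all outputs
#'
#' Reads the four input tables, fits the classifier and writes one figure
#' and two tables — `<prefix>.classes.tsv` (per-pair calls),
#' `<prefix>.counts.tsv` (counts per candidate cutoff) and
#' `<prefix>.distances.<ext>` (the distance-distribution figure) — plus a
#' run log `<prefix>.log` recording input sizes, drops and the chosen
#' cutoff.
#'
#' @inheritParams classify_duplicates
#' @param out_prefix path prefix for the output files.
#' @param fig_format figure device: `"pdf"`, `"png"` or `"svg"`.
#' @param quiet suppress the log messages on the console.
#' @return The [classify_duplicates()] fit, invisibly, with an
#'   `output_files` attribute naming the files written.
#' @export
run_pipeline <- function(duplicates, orthologs, expr1, expr2, out_prefix,
                         oriented = FALSE, ediv = NULL,
                         combine = c("raw-sum", "relative-mean"),
                         skip_missing = FALSE,
                         fig_format = c("pdf", "png", "svg"),
                         quiet = FALSE) {
  combine <- match.arg(combine)
  fig_format <- match.arg(fig_format)
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  fit <- withCallingHandlers(
    classify_duplicates(duplicates, orthologs, expr1, expr2,
                        oriented = oriented, ediv = ediv, combine = combine,
                        skip_missing = skip_missing),
    warning = function(w) {
      note("warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  files <- c(classes = paste0(out_prefix, ".classes.tsv"),
             counts = paste0(out_prefix, ".counts.tsv"),
             figure = paste0(out_prefix, ".distances.", fig_format),
             log = paste0(out_prefix, ".log"))

  note("classified %d duplicate pair(s) over %d sample(s) (%s mode)",
       nrow(fit$results), fit$n_samples,
       if (oriented) "oriented" else "generalized")
  note("ortholog pairs used for calibration: %d", fit$cutoffs$n_orthologs)
  n_drop <- sum(vapply(fit$dropped, NROW, integer(1L)))
  note("dropped before classification: %d", n_drop)
  note("E_div = %.6f (%s)", fit$cutoffs$chosen, fit$cutoffs$source)

  write_classification_table(fit$results, files[["classes"]])
  write_counts_table(fit$counts, files[["counts"]])
  switch(fig_format,
         pdf = grDevices::pdf(files[["figure"]], width = 7, height = 5),
         png = grDevices::png(files[["figure"]], width = 7, height = 5,
                              units = "in", res = 150),
         svg = grDevices::svg(files[["figure"]], width = 7, height = 5))
  tryCatch(plot(fit), finally = grDevices::dev.off())
  for (f in files[c("classes", "counts", "figure")])
    note("wrote %s", f)
  writeLines(log_lines, files[["log"]])
  invisible(structure(fit, output_files = files))
}
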