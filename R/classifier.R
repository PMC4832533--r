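#' Retention mechanism labels
#'
#' The four long-term duplicate retention mechanisms, in the order used by
#' all count tables.
#' @export
MECHANISMS <- c("conservation", "neofunctionalization",
                "subfunctionalization", "specialization")

#' Classify duplicate pairs from their expression distances
#'
#' Applies the phylogenetic classification rules to each triplet's three
#' distances at cutoff `ediv`:
#' \itemize{
#'   \item conservation: both copies within `ediv` of the ancestor;
#'   \item neofunctionalization: exactly one copy diverged beyond `ediv`;
#'   \item subfunctionalization: both copies diverged but the combined pair
#'     profile is within `ediv` of the ancestor (ancestral expression
#'     partitioned between the copies);
#'   \item specialization: both copies and the combined profile all diverged.
#' }
#' A distance exactly equal to `ediv` counts as \emph{not} diverged (the
#' conservation rule uses `<=`).  The four rules partition the space of
#' finite distance records, so exactly one mechanism fires per record.
#'
#' @param e_copy1_a,e_copy2_a,e_combined_a numeric vectors of distances
#'   (recycled to a common length): each copy vs the ancestor, and the
#'   combined pair profile vs the ancestor.
#' @param ediv non-negative scalar expression-divergence cutoff.
#' @return Data frame with columns `mechanism` (one of [MECHANISMS]) and
#'   `diverged_copy` (`"copy1"`, `"copy2"`, `"both"` or `"neither"`).
#' @examples
#' classify_mechanism(0.5, 0.1, 0.3, ediv = 0.2)  # neofunctionalization
#' @export
classify_mechanism <- function(e_copy1_a, e_copy2_a, e_combined_a, ediv) {
  if (!is.numeric(ediv) || length(ediv) != 1L || !is.finite(ediv) ||
      ediv < 0)
    stop("'ediv' must be a single non-negative number")
  m <- max(length(e_copy1_a), length(e_copy2_a), length(e_combined_a))
  e1 <- rep_len(e_copy1_a, m)
  e2 <- rep_len(e_copy2_a, m)
  ec <- rep_len(e_combined_a, m)
  if (any(!is.finite(c(e1, e2, ec))) || any(c(e1, e2, ec) < 0))
    stop("distances must be finite and non-negative")
  d1 <- e1 > ediv
  d2 <- e2 > ediv
  dc <- ec > ediv
  mechanism <- ifelse(!d1 & !d2, "conservation",
               ifelse(xor(d1, d2), "neofunctionalization",
               ifelse(!dc, "subfunctionalization", "specialization")))
  diverged <- ifelse(!d1 & !d2, "neither",
              ifelse(d1 & d2, "both",
              ifelse(d1, "copy1", "copy2")))
  data.frame(mechanism = mechanism, diverged_copy = diverged,
             stringsAsFactors = FALSE)
}

#' Classify all triplets and tabulate counts across candidate cutoffs
#'
#' Per-triplet calls are made at the chosen cutoff; the counts table
#' re-classifies every triplet at each of the five candidate cutoffs (plus
#' the chosen cutoff as an extra row when it was user-supplied and not among
#' the candidates), giving the sensitivity view of how calls shift with
#' `E_div`.  In oriented (parent/child) mode the neofunctionalization count
#' is split by which copy diverged.
#'
#' @param records data frame from [triplet_distances()] (non-empty).
#' @param cutoffs an `ediv_cutoffs` object from [estimate_cutoffs()].
#' @param oriented logical; if `TRUE`, copy1 is the parent (P) and copy2 the
#'   child (C), and `diverged_copy` is reported as `P`/`C`; otherwise copies
#'   are unordered duplicates reported as `D1`/`D2`.
#' @return List with `results` (per-triplet calls at the chosen cutoff, with
#'   the distances and `Ediv` column) and `counts` (one row per candidate
#'   cutoff, one count column per mechanism).
#' @export
classify_all <- function(records, cutoffs, oriented = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("no distance records to classify")
  stopifnot(inherits(cutoffs, "ediv_cutoffs"))

  labels <- if (oriented) c(copy1 = "P", copy2 = "C") else
    c(copy1 = "D1", copy2 = "D2")
  cls <- classify_mechanism(records$E_copy1_A, records$E_copy2_A,
                            records$E_combined_A, cutoffs$chosen)
  dv <- cls$diverged_copy
  dv[dv == "copy1"] <- labels[["copy1"]]
  dv[dv == "copy2"] <- labels[["copy2"]]
  results <- data.frame(records, Ediv = cutoffs$chosen,
                        mechanism = cls$mechanism, diverged_copy = dv,
                        stringsAsFactors = FALSE, row.names = NULL)

  grid <- cutoffs$candidates
  if (cutoffs$source == "user" && !cutoffs$chosen %in% grid)
    grid <- sort(c(grid, cutoffs$chosen))
  counts <- count_mechanisms(records, grid, oriented)
  list(results = results, counts = counts)
}

## mechanism counts at each cutoff in `grid`
count_mechanisms <- function(records, grid, oriented = FALSE) {
  cols <- if (oriented)
    c("conservation", "neofunctionalization_P", "neofunctionalization_C",
      "subfunctionalization", "specialization")
  else MECHANISMS
  rows <- lapply(grid, function(ed) {
    cls <- classify_mechanism(records$E_copy1_A, records$E_copy2_A,
                              records$E_combined_A, ed)
    key <- cls$mechanism
    if (oriented) {
      neo <- key == "neofunctionalization"
      key[neo] <- ifelse(cls$diverged_copy[neo] == "copy1",
                         "neofunctionalization_P", "neofunctionalization_C")
    }
    vapply(cols, function(k) sum(key == k), integer(1L))
  })
  out <- data.frame(Ediv = grid, do.call(rbind, rows),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
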