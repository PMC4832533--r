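#' Simulate a ground-truth-labelled duplicate-gene dataset
#'
#' Generates the four input tables the classifier consumes — two expression
#' tables, a duplicate-triplet table and a single-copy ortholog table —
#' together with the true retention mechanism of every triplet, so the whole
#' pipeline can be validated against known answers.
#'
#' @details
#' The generative model realises each mechanism's definition directly:
#' \itemize{
#'   \item Every ancestral relative profile is drawn from a symmetric
#'     Dirichlet over the `n_samples` samples (concentration
#'     `concentration`).  The triplet ancestor's species-2 profile is the
#'     ancestral profile itself.
#'   \item Ortholog pairs: each species' copy is the ancestral profile with
#'     one multiplicative log-normal perturbation of scale `ortholog_noise`
#'     (renormalised), so the S1--S2 distance carries two independent
#'     divergence doses — the calibration target for the cutoff.
#'   \item conservation: both copies are the ancestral profile perturbed at
#'     scale `duplicate_noise`.
#'   \item neofunctionalization: one copy (chosen at random) is conserved as
#'     above; the other is an independent Dirichlet draw.
#'   \item subfunctionalization: the samples are split into two complementary
#'     non-empty subsets; copy 1 carries the ancestor's raw expression on one
#'     subset (zero elsewhere), copy 2 the complement, sharing one total so
#'     the raw sum reconstructs the ancestral profile exactly at
#'     `duplicate_noise = 0`.
#'   \item specialization: both copies are independent Dirichlet draws.
#' }
#' Every component whose ground-truth label says "diverged" (the novel copy
#' in neofunctionalization, both restricted profiles in
#' subfunctionalization, and both copies plus the pooled profile in
#' specialization) is rejection-sampled until its distance from the ancestor
#' exceeds twice `ortholog_noise`, so the labels are realisable rather than
#' merely intended.  Raw tables are obtained by scaling profiles with
#' log-normal totals (meanlog `log(1000)`, sdlog 0.5).
#'
#' @param n_samples number of samples (tissues/conditions) per species,
#'   `>= 2` (subfunctionalization needs at least two samples to partition).
#' @param n_per_mechanism number of duplicate triplets generated under each
#'   of the four mechanisms.
#' @param n_orthologs number of single-copy ortholog pairs for cutoff
#'   calibration.
#' @param ortholog_noise perturbation scale (log-normal sigma) applied per
#'   species branch to ortholog profiles.
#' @param duplicate_noise perturbation scale applied to duplicate copies
#'   around their mechanism-specific target profile.
#' @param seed integer seed; the simulation is fully deterministic given the
#'   seed (recorded in the output `config`).
#' @param concentration symmetric Dirichlet concentration for ancestral
#'   profiles; the default 10 yields moderately even profiles typical of
#'   broadly expressed genes.
#' @return Object of class `dup_simulation`: list with `expr1`, `expr2`
#'   ([expression_table()]s), `triplets` (columns `copy1`, `copy2`,
#'   `ancestor`), `truth` (the triplets plus their true `mechanism`),
#'   `orthologs` (columns `s1`, `s2`) and `config`.
#' @examples
#' sim <- simulate_duplicates(n_per_mechanism = 5, n_orthologs = 20, seed = 1)
#' sim$truth$mechanism
#' @export
simulate_duplicates <- function(n_samples = 6, n_per_mechanism = 100,
                                n_orthologs = 500, ortholog_noise = 0.05,
                                duplicate_noise = 0.05, seed = NULL,
                                concentration = 10) {
  if (n_samples < 2L)
    stop("'n_samples' must be >= 2 (subfunctionalization requires a ",
         "partition of the samples)")
  if (n_per_mechanism < 1L || n_orthologs < 1L)
    stop("'n_per_mechanism' and 'n_orthologs' must be >= 1")
  if (!is.finite(ortholog_noise) || ortholog_noise < 0 ||
      !is.finite(duplicate_noise) || duplicate_noise < 0)
    stop("noise scales must be finite and >= 0")
  if (!is.null(seed)) set.seed(seed)

  rdirichlet <- function() {
    repeat {
      g <- stats::rgamma(n_samples, shape = concentration)
      if (sum(g) > 0) return(g / sum(g))
    }
  }
  perturb <- function(p, sigma) {
    if (sigma == 0) return(p)
    q <- p * exp(stats::rnorm(length(p), 0, sigma))
    q / sum(q)
  }
  rtotal <- function() stats::rlnorm(1L, meanlog = log(1000), sdlog = 0.5)
  far <- 2 * ortholog_noise   # realizability margin for "diverged" labels

  n_trip <- 4L * n_per_mechanism
  mech <- rep(MECHANISMS, each = n_per_mechanism)
  samples <- sprintf("sample%d", seq_len(n_samples))
  rows1 <- list(); rows2 <- list()   # named raw expression vectors

  copy1_id <- sprintf("dup%04d.1", seq_len(n_trip))
  copy2_id <- sprintf("dup%04d.2", seq_len(n_trip))
  anc_id <- sprintf("anc%04d", seq_len(n_trip))
  for (i in seq_len(n_trip)) {
    a <- rdirichlet()
    if (mech[i] == "conservation") {
      p1 <- perturb(a, duplicate_noise)
      p2 <- perturb(a, duplicate_noise)
      raw1 <- p1 * rtotal(); raw2 <- p2 * rtotal()
    } else if (mech[i] == "neofunctionalization") {
      cons <- perturb(a, duplicate_noise)
      repeat {
        novel <- rdirichlet()
        if (profile_distance(novel, a) > far) break
      }
      if (stats::runif(1L) < 0.5) { p1 <- cons; p2 <- novel }
      else { p1 <- novel; p2 <- cons }
      raw1 <- p1 * rtotal(); raw2 <- p2 * rtotal()
    } else if (mech[i] == "subfunctionalization") {
      repeat {
        k <- sample.int(n_samples - 1L, 1L)
        in1 <- seq_len(n_samples) %in% sample.int(n_samples, k)
        r1 <- a * in1; r2 <- a * !in1
        if (profile_distance(r1 / sum(r1), a) > far &&
            profile_distance(r2 / sum(r2), a) > far) break
      }
      tot <- rtotal()   # shared so the raw sum reconstructs the ancestor
      raw1 <- tot * r1 * exp(stats::rnorm(n_samples, 0, duplicate_noise))
      raw2 <- tot * r2 * exp(stats::rnorm(n_samples, 0, duplicate_noise))
    } else {  # specialization
      repeat {
        p1 <- rdirichlet(); p2 <- rdirichlet()
        t1 <- rtotal(); t2 <- rtotal()
        comb <- (p1 * t1 + p2 * t2) / (t1 + t2)
        if (profile_distance(p1, a) > far &&
            profile_distance(p2, a) > far &&
            profile_distance(comb, a) > far) break
      }
      raw1 <- p1 * t1; raw2 <- p2 * t2
    }
    rows1[[copy1_id[i]]] <- raw1
    rows1[[copy2_id[i]]] <- raw2
    rows2[[anc_id[i]]] <- a * rtotal()
  }

  s1_id <- sprintf("org%04d_s1", seq_len(n_orthologs))
  s2_id <- sprintf("org%04d_s2", seq_len(n_orthologs))
  for (i in seq_len(n_orthologs)) {
    b <- rdirichlet()
    rows1[[s1_id[i]]] <- perturb(b, ortholog_noise) * rtotal()
    rows2[[s2_id[i]]] <- perturb(b, ortholog_noise) * rtotal()
  }

  mk <- function(rows, species) {
    m <- do.call(rbind, rows)
    dimnames(m) <- list(names(rows), samples)
    expression_table(m, species = species)
  }
  triplets <- data.frame(copy1 = copy1_id, copy2 = copy2_id,
                         ancestor = anc_id, stringsAsFactors = FALSE)
  structure(list(
    expr1 = mk(rows1, "species1"),
    expr2 = mk(rows2, "species2"),
    triplets = triplets,
    truth = data.frame(triplets, mechanism = mech, stringsAsFactors = FALSE),
    orthologs = data.frame(s1 = s1_id, s2 = s2_id, stringsAsFactors = FALSE),
    config = list(n_samples = n_samples, n_per_mechanism = n_per_mechanism,
                  n_orthologs = n_orthologs, ortholog_noise = ortholog_noise,
                  duplicate_noise = duplicate_noise, seed = seed,
                  concentration = concentration)),
    class = "dup_simulation")
}

#' @export
print.dup_simulation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "Simulated duplicate-gene dataset: %d triplets (%d per mechanism), ",
    "%d ortholog pairs, %d samples\n"),
    nrow(x$triplets), cfg$n_per_mechanism, nrow(x$orthologs),
    cfg$n_samples))
  cat(sprintf("  ortholog_noise = %g, duplicate_noise = %g, seed = %s\n",
              cfg$ortholog_noise, cfg$duplicate_noise,
              if (is.null(cfg$seed)) "none" else cfg$seed))
  invisible(x)
}

#' Write a simulated dataset as the four classifier input files
#'
#' Writes `expr1.tsv`, `expr2.tsv` (headered expression tables),
#' `duplicates.tsv`, `orthologs.tsv` (headerless ID tables) and `truth.tsv`
#' (triplets with their true mechanism) into `dir`.
#'
#' @param sim a `dup_simulation` from [simulate_duplicates()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "dup_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expr1 = file.path(dir, "expr1.tsv"),
             expr2 = file.path(dir, "expr2.tsv"),
             duplicates = file.path(dir, "duplicates.tsv"),
             orthologs = file.path(dir, "orthologs.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_table(sim$expr1, paths[["expr1"]])
  write_expression_table(sim$expr2, paths[["expr2"]])
  utils::write.table(sim$triplets, paths[["duplicates"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$orthologs, paths[["orthologs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(paths)
}

#' Confusion matrix and accuracy of mechanism recovery
#'
#' Compares predicted mechanism calls against ground-truth labels, aligned
#' by position.
#'
#' @param truth character vector of true mechanisms, or a data frame with a
#'   `mechanism` column (e.g. the `truth` element of a simulation).
#' @param predicted character vector of predicted mechanisms, a results data
#'   frame with a `mechanism` column, or a [classify_duplicates()] fit.
#' @return List with `confusion` (4 x 4 table, truth in rows, prediction in
#'   columns, both ordered as [MECHANISMS]) and `accuracy` in `[0, 1]`.
#' @export
evaluate_recovery <- function(truth, predicted) {
  if (is.data.frame(truth)) truth <- truth$mechanism
  if (inherits(predicted, "dupclass")) predicted <- predicted$results
  if (is.data.frame(predicted)) predicted <- predicted$mechanism
  if (length(truth) != length(predicted))
    stop("truth and prediction have different lengths (", length(truth),
         " vs ", length(predicted), ")")
  bad <- setdiff(unique(c(truth, predicted)), MECHANISMS)
  if (length(bad))
    stop("unknown mechanism label(s): ", paste(bad, collapse = ", "))
  tf <- factor(truth, levels = MECHANISMS)
  pf <- factor(predicted, levels = MECHANISMS)
  confusion <- table(truth = tf, predicted = pf)
  list(confusion = confusion,
       accuracy = sum(diag(confusion)) / length(truth))
}
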