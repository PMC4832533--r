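# Small in-code fixtures shared across test files.

expr_mat <- function(..., samples = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  colnames(m) <- samples
  m
}

# the hand-worked two-sample triplet: ancestor (5,5), copies (10,0)/(0,10)
worked_tables <- function() {
  e1 <- expression_table(expr_mat(p = c(10, 0), c = c(0, 10),
                                  o1 = c(3, 1), o2 = c(1, 1)),
                         species = "sp1")
  e2 <- expression_table(expr_mat(anc = c(5, 5),
                                  o1c = c(6, 2), o2c = c(2, 2)),
                         species = "sp2")
  list(expr1 = e1, expr2 = e2,
       triplets = data.frame(copy1 = "p", copy2 = "c", ancestor = "anc",
                             stringsAsFactors = FALSE),
       orthologs = data.frame(s1 = c("o1", "o2"), s2 = c("o1c", "o2c"),
                              stringsAsFactors = FALSE))
}

# independent straight-line restatement of the classification rules, used
# as an oracle: deliberately written as nested if/else over scalars
oracle_classify <- function(e1, e2, ec, ediv) {
  if (e1 <= ediv && e2 <= ediv) "conservation"
  else if (e1 > ediv && e2 <= ediv) "neofunctionalization"
  else if (e1 <= ediv && e2 > ediv) "neofunctionalization"
  else if (ec <= ediv) "subfunctionalization"
  else "specialization"
}

random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(E_copy1_A = runif(n, 0, sqrt(2)),
             E_copy2_A = runif(n, 0, sqrt(2)),
             E_combined_A = runif(n, 0, sqrt(2)))
}
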