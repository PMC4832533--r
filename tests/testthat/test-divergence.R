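test_that("Euclidean profile distance matches hand computations", {
  expect_equal(profile_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_equal(profile_distance(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(profile_distance(c(0.5, 0.5), c(0.8, 0.2)), sqrt(0.18))
  expect_error(profile_distance(c(1, 0), c(1, 0, 0)), "dimensions")
})

test_that("profile distance is a metric bounded by sqrt(2) on profiles", {
  set.seed(3)
  rprof <- function() to_relative(rexp(5))
  for (i in 1:100) {
    p <- rprof(); q <- rprof(); r <- rprof()
    dpq <- profile_distance(p, q)
    expect_gte(dpq, 0)
    expect_equal(dpq, profile_distance(q, p))
    expect_equal(profile_distance(p, p), 0)
    expect_lte(dpq, profile_distance(p, r) + profile_distance(r, q) + 1e-12)
    expect_lte(dpq, sqrt(2))
  }
})

test_that("triplet distances reproduce the worked example", {
  w <- worked_tables()
  rec <- triplet_distances(w$triplets, w$expr1, w$expr2)
  # ancestor (5,5) -> (.5,.5); copies (10,0)/(0,10) -> (1,0)/(0,1);
  # pooled raw (10,10) -> (.5,.5) recovers the ancestor exactly
  expect_equal(rec$E_copy1_A, sqrt(0.5), tolerance = 1e-12)
  expect_equal(rec$E_copy2_A, sqrt(0.5), tolerance = 1e-12)
  expect_equal(rec$E_combined_A, 0)

  # identical relative profiles at different scales -> all zeros
  e1 <- expression_table(expr_mat(c1 = c(8, 0), c2 = c(4, 0)), "sp1")
  e2 <- expression_table(expr_mat(anc = c(10, 0)), "sp2")
  tr <- data.frame(copy1 = "c1", copy2 = "c2", ancestor = "anc")
  rec2 <- triplet_distances(tr, e1, e2)
  expect_equal(unlist(rec2[c("E_copy1_A", "E_copy2_A", "E_combined_A")]),
               c(E_copy1_A = 0, E_copy2_A = 0, E_combined_A = 0))
})

test_that("equal-total copies give a combined distance within the convex bound", {
  set.seed(21)
  for (i in 1:25) {
    a <- to_relative(rexp(4))
    x <- to_relative(rexp(4)) * 50   # equal totals by construction
    y <- to_relative(rexp(4)) * 50
    e1 <- expression_table(rbind(c1 = x, c2 = y), "sp1")
    colnames(e1$values) <- paste0("s", 1:4)
    e2 <- expression_table(rbind(anc = a * 10), "sp2")
    colnames(e2$values) <- paste0("s", 1:4)
    rec <- triplet_distances(data.frame(copy1 = "c1", copy2 = "c2",
                                        ancestor = "anc"),
                             expression_table(e1$values, "sp1"),
                             expression_table(e2$values, "sp2"))
    expect_gte(rec$E_combined_A, 0)
    expect_lte(rec$E_combined_A,
               (rec$E_copy1_A + rec$E_copy2_A) / 2 + 1e-12)
  }
})

test_that("zero-expression members are dropped with a warning", {
  e1 <- expression_table(expr_mat(c1 = c(1, 1), c2 = c(0, 0),
                                  c3 = c(2, 1), c4 = c(1, 2)), "sp1")
  e2 <- expression_table(expr_mat(a1 = c(1, 1), a2 = c(1, 3)), "sp2")
  tr <- data.frame(copy1 = c("c1", "c3"), copy2 = c("c2", "c4"),
                   ancestor = c("a1", "a2"))
  expect_warning(rec <- triplet_distances(tr, e1, e2), "zero")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$copy1, "c3")
  expect_equal(attr(rec, "dropped")$copy2, "c2")

  # unresolvable IDs are a hard error naming the offenders
  tr$ancestor[1] <- "nope"
  expect_error(triplet_distances(tr, e1, e2), "nope")
})

test_that("ortholog distances match per-pair recomputation", {
  set.seed(5)
  n <- 20
  m1 <- matrix(rexp(n * 3), n, dimnames = list(paste0("a", 1:n), NULL))
  m2 <- matrix(rexp(n * 3), n, dimnames = list(paste0("b", 1:n), NULL))
  e1 <- expression_table(m1, "sp1"); e2 <- expression_table(m2, "sp2")
  pairs <- data.frame(s1 = paste0("a", 1:n), s2 = paste0("b", 1:n))
  d <- ortholog_distances(pairs, e1, e2)
  manual <- sapply(1:n, function(i)
    sqrt(sum((m1[i, ] / sum(m1[i, ]) - m2[i, ] / sum(m2[i, ]))^2)))
  expect_equal(as.numeric(d), manual)

  # identical profiles -> zeros; disjoint support -> sqrt(2)
  ident <- expression_table(m1, "sp2")
  pairs2 <- data.frame(s1 = paste0("a", 1:n), s2 = paste0("a", 1:n))
  expect_equal(as.numeric(ortholog_distances(pairs2, e1, ident)), rep(0, n))
})

test_that("cutoff estimation follows median + k*SIQR with type-7 quartiles", {
  cs <- estimate_cutoffs(c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(cs$median, 0.3)
  expect_equal(cs$siqr, 0.1)
  expect_equal(cs$default, 0.4)
  expect_equal(cs$candidates, c(0.30, 0.35, 0.40, 0.45, 0.50))
  expect_equal(cs$chosen, 0.4)
  expect_equal(cs$source, "default")

  # degenerate constant distribution
  flat <- estimate_cutoffs(c(0.2, 0.2, 0.2))
  expect_equal(flat$siqr, 0)
  expect_equal(flat$default, 0.2)

  # user override keeps the candidate grid
  user <- estimate_cutoffs(c(0.1, 0.2, 0.3, 0.4, 0.5), user_ediv = 0.25)
  expect_equal(user$chosen, 0.25)
  expect_equal(user$source, "user")
  expect_equal(user$candidates, cs$candidates)

  expect_error(estimate_cutoffs(numeric(0)), "empty")
  expect_error(estimate_cutoffs(c(0.1, 0.2), user_ediv = -1),
               "non-negative")
})

test_that("cutoff estimation is permutation invariant", {
  set.seed(9)
  d <- rexp(101, 10)
  base <- estimate_cutoffs(d)
  for (i in 1:10) {
    perm <- estimate_cutoffs(sample(d))
    expect_equal(perm$median, base$median)
    expect_equal(perm$siqr, base$siqr)
    expect_equal(perm$candidates, base$candidates)
  }
})
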