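test_that("the four rules assign the expected mechanisms", {
  cases <- list(
    list(d = c(0.1, 0.15, 0.05), ediv = 0.2,
         mech = "conservation", div = "neither"),
    list(d = c(0.5, 0.1, 0.3), ediv = 0.2,
         mech = "neofunctionalization", div = "copy1"),
    list(d = c(0.1414214, 0.7071068, 0.4), ediv = 0.2,
         mech = "neofunctionalization", div = "copy2"),
    list(d = c(0.7071068, 0.7071068, 0.0), ediv = 0.2,
         mech = "subfunctionalization", div = "both"),
    list(d = c(0.9, 0.8, 0.6), ediv = 0.2,
         mech = "specialization", div = "both"))
  for (cs in cases) {
    got <- classify_mechanism(cs$d[1], cs$d[2], cs$d[3], cs$ediv)
    expect_equal(got$mechanism, cs$mech)
    expect_equal(got$diverged_copy, cs$div)
  }
})

test_that("a distance exactly at the cutoff counts as not diverged", {
  expect_equal(classify_mechanism(0.2, 0.2, 0.5, 0.2)$mechanism,
               "conservation")
  expect_equal(classify_mechanism(0.2 + 1e-12, 0.2, 0.5, 0.2)$mechanism,
               "neofunctionalization")
  expect_equal(classify_mechanism(0.3, 0.3, 0.3, 0.3)$mechanism,
               "conservation")
})

test_that("rules are exhaustive, exclusive, and agree with the oracle", {
  rec <- random_records(10000, seed = 101)
  for (ediv in c(0, 0.1, 0.35, 0.7, 1.2)) {
    got <- classify_mechanism(rec$E_copy1_A, rec$E_copy2_A,
                              rec$E_combined_A, ediv)
    expect_true(all(got$mechanism %in% MECHANISMS))
    want <- mapply(oracle_classify, rec$E_copy1_A, rec$E_copy2_A,
                   rec$E_combined_A, ediv)
    expect_identical(got$mechanism, unname(want))
    # diverged_copy is consistent with the mechanism
    expect_true(all((got$mechanism == "conservation") ==
                      (got$diverged_copy == "neither")))
    expect_true(all((got$mechanism == "neofunctionalization") ==
                      (got$diverged_copy %in% c("copy1", "copy2"))))
    expect_true(all((got$mechanism %in%
                       c("subfunctionalization", "specialization")) ==
                      (got$diverged_copy == "both")))
  }
})

test_that("conservation grows and specialization shrinks as the cutoff rises", {
  rec <- random_records(2000, seed = 55)
  grid <- seq(0, sqrt(2), length.out = 50)
  counts <- count_series <- t(sapply(grid, function(ed) {
    m <- classify_mechanism(rec$E_copy1_A, rec$E_copy2_A,
                            rec$E_combined_A, ed)$mechanism
    c(cons = sum(m == "conservation"), spec = sum(m == "specialization"))
  }))
  expect_true(all(diff(counts[, "cons"]) >= 0))
  expect_true(all(diff(counts[, "spec"]) <= 0))
})

test_that("swapping copy labels preserves mechanism counts and flips divergence", {
  rec <- random_records(500, seed = 77)
  cutoffs <- estimate_cutoffs(runif(50, 0, 0.8))
  swapped <- data.frame(E_copy1_A = rec$E_copy2_A,
                        E_copy2_A = rec$E_copy1_A,
                        E_combined_A = rec$E_combined_A)
  a <- classify_all(rec, cutoffs)
  b <- classify_all(swapped, cutoffs)
  expect_identical(a$results$mechanism, b$results$mechanism)
  expect_identical(a$counts, b$counts)
  flip <- c(D1 = "D2", D2 = "D1", both = "both", neither = "neither")
  expect_identical(unname(flip[a$results$diverged_copy]),
                   b$results$diverged_copy)
})

test_that("counts tables cover the candidate grid and sum to the records", {
  rec <- random_records(200, seed = 13)
  cutoffs <- estimate_cutoffs(runif(40, 0, 1))
  out <- classify_all(rec, cutoffs)
  expect_equal(out$counts$Ediv, cutoffs$candidates)
  expect_equal(unname(rowSums(out$counts[, -1])), rep(200L, 5L))
  expect_equal(unique(out$results$Ediv), cutoffs$chosen)

  # user cutoff off the grid appears as a sixth row
  user <- estimate_cutoffs(runif(40, 0, 1), user_ediv = 0.123)
  out_u <- classify_all(rec, user)
  expect_equal(nrow(out_u$counts), 6L)
  expect_true(0.123 %in% out_u$counts$Ediv)

  # oriented mode splits neofunctionalization by the diverged copy
  out_o <- classify_all(rec, cutoffs, oriented = TRUE)
  expect_true(all(c("neofunctionalization_P", "neofunctionalization_C")
                  %in% names(out_o$counts)))
  expect_equal(unname(rowSums(out_o$counts[, -1])), rep(200L, 5L))
  expect_equal(out_o$counts$neofunctionalization_P +
                 out_o$counts$neofunctionalization_C,
               out$counts$neofunctionalization)
  expect_true(all(out_o$results$diverged_copy %in%
                    c("P", "C", "both", "neither")))
  expect_error(classify_all(rec[0, ], cutoffs), "no distance records")
})

test_that("limit cutoffs collapse the calls as expected", {
  rec <- random_records(300, seed = 31)
  rec[] <- lapply(rec, function(v) pmax(v, 1e-6))  # strictly positive
  at0 <- classify_mechanism(rec$E_copy1_A, rec$E_copy2_A,
                            rec$E_combined_A, 0)$mechanism
  expect_false(any(at0 == "conservation"))
  atmax <- classify_mechanism(rec$E_copy1_A, rec$E_copy2_A,
                              rec$E_combined_A, sqrt(2))$mechanism
  expect_true(all(atmax == "conservation"))
})
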