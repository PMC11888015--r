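test_that("instrument totals are sums/counts with strict validation", {
  expect_identical(discern_total(rep(1, 16)), 16L)
  expect_identical(discern_total(rep(5, 16)), 80L)
  expect_identical(discern_total(c(rep(2, 8), rep(4, 8))), 48L)
  expect_error(discern_total(rep(3, 15)), class = "wq_validation_error")
  expect_error(discern_total(c(rep(3, 15), 6)), class = "wq_validation_error")

  expect_identical(jama_total(c(TRUE, TRUE, TRUE, TRUE)), 4L)
  expect_identical(jama_total(c(FALSE, FALSE, FALSE, FALSE)), 0L)
  expect_identical(jama_total(c(TRUE, FALSE, TRUE, FALSE)), 2L)
  expect_error(jama_total(c(TRUE, TRUE)), class = "wq_validation_error")

  expect_identical(content_total(rep(2, 6)), 12L)
  expect_identical(content_total(rep(0, 6)), 0L)
  expect_identical(content_total(c(2, 2, 1, 2, 0, 1)), 8L)
  expect_error(content_total(c(2, 2, 1, 2, 0, 3)), class = "wq_validation_error")
})

test_that("quality bands partition [16, 80] with the documented boundaries", {
  expect_identical(classify_discern_band(42), "fair")
  expect_identical(classify_discern_band(20), "very poor")
  expect_identical(classify_discern_band(78), "excellent")
  expect_identical(classify_discern_band(50.5), "fair")
  # boundary pairs from the band definition
  expect_identical(classify_discern_band(c(26, 27, 38, 39, 50, 51, 62, 63, 75, 76, 80)),
                   c("very poor", "poor", "poor", "fair", "fair", "good",
                     "good", "excellent", "excellent", "excellent", "excellent"))
  expect_error(classify_discern_band(15.9), class = "wq_range_error")
  expect_error(classify_discern_band(80.1), class = "wq_range_error")
  # every real in range maps to exactly one band
  grid <- seq(16, 80, by = 0.25)
  bands <- classify_discern_band(grid)
  expect_true(all(bands %in% c("very poor", "poor", "fair", "good", "excellent")))
  expect_false(anyNA(bands))
})

test_that("DISCERN adjudication applies the 5-point rule with means", {
  r <- function(total) make_rating("w1", "Rx", discern_items_with_total(total))
  a <- adjudicate_discern(r(40), r(43))
  expect_equal(a$total, 41.5)
  expect_identical(a$n_raters_used, 2L)
  # exactly 5 apart triggers the third rater; mean of all three
  b <- adjudicate_discern(r(40), r(45), r(44))
  expect_equal(b$total, 43.0)
  expect_identical(b$n_raters_used, 3L)
  expect_identical(b$band, "fair")
  expect_error(adjudicate_discern(r(40), r(46)),
               regexp = "w1", class = "wq_adjudication_required")
  # unneeded third rating is ignored with a note
  expect_message(cc <- adjudicate_discern(r(40), r(43), r(80)))
  expect_equal(cc$total, 41.5)
  # gap of 4 never consults a third rater
  d <- adjudicate_discern(r(40), r(44))
  expect_identical(d$n_raters_used, 2L)
})

test_that("adjudication is symmetric and idempotent", {
  set.seed(202)
  for (i in 1:200) {
    t1 <- sample(16:80, 1); t2 <- sample(16:80, 1)
    r1 <- make_rating("w", "R1", discern_items_with_total(t1))
    r2 <- make_rating("w", "R2", discern_items_with_total(t2))
    r3 <- make_rating("w", "R3", discern_items_with_total(sample(16:80, 1)))
    need3 <- abs(t1 - t2) >= 5
    a <- suppressMessages(adjudicate_discern(r1, r2, if (need3) r3))
    b <- suppressMessages(adjudicate_discern(r2, r1, if (need3) r3))
    expect_equal(a$total, b$total)
    expect_identical(a$band, b$band)
    expect_true(a$total >= 16 && a$total <= 80)
  }
  same <- make_rating("w", "R1", discern_items_with_total(57))
  id <- adjudicate_discern(same, same)
  expect_equal(id$total, 57)
  expect_identical(id$n_raters_used, 2L)
})

test_that("item adjudication: agreement, majority, and all-differ rules", {
  expect_identical(adjudicate_items(c(1, 0, 1, 0), c(1, 0, 1, 0)), c(1, 0, 1, 0))
  expect_identical(adjudicate_items(c(1, 0, 1, 0), c(1, 1, 1, 0), c(1, 1, 1, 0)),
                   c(1, 1, 1, 0))
  # three-way disagreement on a 0/1/2 item: the third rater decides
  expect_identical(adjudicate_items(c(0, 2), c(2, 2), c(1, 2)), c(1, 2))
  expect_error(adjudicate_items(c(1, 0, 1, 0), c(1, 1, 0, 0)),
               regexp = "2, 3", class = "wq_unresolved_disagreement")
  expect_error(adjudicate_items(c(1, 0), c(1, 0, 1)), class = "wq_validation_error")
  # adjudicated content values always stay in instrument range
  set.seed(303)
  for (i in 1:100) {
    v1 <- sample(0:2, 6, replace = TRUE)
    v2 <- sample(0:2, 6, replace = TRUE)
    v3 <- sample(0:2, 6, replace = TRUE)
    out <- adjudicate_items(v1, v2, v3)
    expect_true(all(out %in% 0:2))
    expect_identical(adjudicate_items(v2, v1, v3)[v1 == v2], out[v1 == v2])
  }
})

test_that("corpus adjudication produces one bounded row per analyzed site", {
  g <- generate_corpus(synthetic_config(n_sites = 30, seed = 5))
  adj <- adjudicate_corpus(g$corpus)
  expect_equal(nrow(adj), 30)
  expect_true(all(adj$discern_total >= 16 & adj$discern_total <= 80))
  expect_true(all(adj$jama_total %in% 0:4))
  expect_true(all(adj$content_total %in% 0:12))
  expect_true(all(adj$discern_raters %in% c(2L, 3L)))
  # three-rater sites are exactly the generator's forced-disagreement sites
  expect_identical(sort(adj$id[adj$discern_raters == 3]),
                   sort(g$truth$id[g$truth$forced_disagreement]))
})
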