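test_that("creatinine adjustment divides urinary analytes per subject", {
  expect_equal(creatinine_adjust(matrix(5), 2), matrix(2.5))
  m <- matrix(rlnorm(12), 4, 3)
  expect_equal(creatinine_adjust(m, rep(1, 4)), m)
  ones <- matrix(1, 3, 2)
  expect_equal(creatinine_adjust(ones, c(1, 2, 4)),
               matrix(c(1, 0.5, 0.25), 3, 2))
  # serum columns untouched
  adj <- creatinine_adjust(ones, c(2, 2, 2), urinary = c(TRUE, FALSE))
  expect_equal(adj[, 1], rep(0.5, 3))
  expect_equal(adj[, 2], rep(1, 3))
})

test_that("missing or non-positive creatinine is rejected with subject ids", {
  m <- matrix(1, 2, 2, dimnames = list(c("A", "B"), NULL))
  expect_error(creatinine_adjust(m, c(1, 0)), "B")
  expect_error(creatinine_adjust(m, c(NA, 1)), "A")
})

test_that("molar and plain sums follow their formulas", {
  expect_equal(molar_sum(cbind(c(10), c(20)), molar_masses = c(10, 10)), 3)
  expect_equal(molar_sum(cbind(1:2, 3:4, 5:6), mode = "plain"), c(9, 12))
  expect_error(molar_sum(matrix(1:3, ncol = 1)), "at least 2")
  expect_error(molar_sum(cbind(a = 1, b = 2), molar_masses = c(1, NA)), "b")
  expect_error(molar_sum(cbind(1, 2), molar_masses = c(1, -1)), "positive")
})

test_that("detection filter drops below-threshold chemicals, honors keep", {
  nd <- matrix(FALSE, 100, 3, dimnames = list(NULL, c("A", "B", "C")))
  nd[1:26, 2] <- TRUE   # B detected in 74/100
  nd[1:50, 3] <- TRUE   # C detected in 50/100
  panel <- make_panel(matrix(rlnorm(300), 100, 3,
                             dimnames = list(NULL, c("A", "B", "C"))),
                      nondetect = nd)
  expect_message(kept <- detection_filter(panel, 0.75), "B, C")
  expect_equal(colnames(kept$values), "A")

  kept2 <- suppressMessages(detection_filter(panel, 0.75, keep = c("B", "C")))
  expect_equal(colnames(kept2$values), c("A", "B", "C"))

  clean <- make_panel(matrix(rlnorm(300), 100, 3))
  expect_identical(detection_filter(clean, 0.75)$values, clean$values)
})

test_that("detection filter is idempotent and rejects empty mixtures", {
  nd <- cbind(c(rep(TRUE, 40), rep(FALSE, 60)), rep(FALSE, 100))
  panel <- make_panel(matrix(rlnorm(200), 100, 2), nondetect = nd)
  once <- suppressMessages(detection_filter(panel, 0.75))
  twice <- suppressMessages(detection_filter(once, 0.75))
  expect_identical(once$values, twice$values)

  nd_all <- matrix(TRUE, 10, 2)
  bad <- make_panel(matrix(rlnorm(20), 10, 2), nondetect = nd_all)
  expect_error(detection_filter(bad, 0.75), "empty mixture")
})

test_that("nondetect substitution uses LOD/sqrt(2)", {
  v <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "A"))
  nd <- matrix(c(TRUE, FALSE, FALSE, FALSE), 4, 1)
  panel <- make_panel(v, nondetect = nd)
  panel$lod <- c(A = 1.5)
  out <- impute_nondetects(panel)
  expect_equal(out$values[1, 1], 1.5 / sqrt(2))
  expect_equal(out$values[2:4, 1], c(2, 3, 4), ignore_attr = TRUE)
})

test_that("decile scoring matches the uniform-grid example", {
  qm <- quantile_score(matrix(1:20, ncol = 1), K = 10)
  expect_equal(qm$scores[, 1], rep(0:9, each = 2), ignore_attr = TRUE)
})

test_that("quantile scores are invariant to strictly monotone transforms", {
  withr::with_seed(21, {
    x <- rlnorm(101)
    base <- quantile_score(matrix(x, ncol = 1), K = 10)$scores
    for (f in list(function(z) z^3, log, function(z) 5 * z + 2,
                   function(z) z / (1 + z))) {
      expect_identical(quantile_score(matrix(f(x), ncol = 1), K = 10)$scores,
                       base)
    }
  })
})

test_that("bin occupancy is n/K up to rounding at n = 678", {
  withr::with_seed(22, x <- rlnorm(678))
  qm <- quantile_score(cbind(x), K = 10)
  counts <- tabulate(qm$scores + 1L, 10)
  expect_true(all(counts %in% c(67, 68)))
  expect_equal(sum(counts), 678)
})

test_that("scores span 0..K-1 and breakpoints re-score new data", {
  withr::with_seed(23, x <- rlnorm(200))
  qm <- quantile_score(cbind(x), K = 10)
  expect_equal(min(qm$scores), 0L)
  expect_equal(max(qm$scores), 9L)
  new <- matrix(c(min(x) - 1, median(x), max(x) + 1), ncol = 1)
  rescored <- quantile_score(new, K = 10, breakpoints = qm$breakpoints)
  expect_equal(rescored$scores[1, 1], 0L, ignore_attr = TRUE)
  expect_equal(rescored$scores[3, 1], 9L, ignore_attr = TRUE)
})

test_that("heavy ties collapse breakpoints with a warning, scores in range", {
  x <- c(rep(1, 80), rep(2, 20))
  expect_warning(qm <- quantile_score(cbind(x), K = 10), "ties")
  expect_true(all(qm$scores >= 0 & qm$scores <= 9))
  expect_true(all(qm$scores[x == 1] < qm$scores[x == 2]))
})

test_that("preprocess_panel chains substitution, adjustment and scoring", {
  coh <- simulate_cohort(n = 120, seed = 31)
  qm <- preprocess_panel(coh$exposures, K = 10)
  expect_s3_class(qm, "quantile_matrix")
  expect_equal(ncol(qm$scores), 26)
  expect_equal(nrow(qm$scores), 120)
  expect_true(all(qm$scores >= 0 & qm$scores <= 9))
  # creatinine adjustment must change urinary ranks relative to raw scoring
  raw <- quantile_score(impute_nondetects(coh$exposures), K = 10)
  urinary <- coh$exposures$chemicals$matrix == "urine"
  expect_false(identical(qm$scores[, urinary], raw$scores[, urinary]))
  expect_identical(qm$scores[, !urinary], raw$scores[, !urinary])
})
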