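test_that("the reduction target is mean minus one SD", {
  idx <- with_mean_sd(rnorm(200), 2.24, 0.50)
  expect_equal(target_value(idx), 1.74, tolerance = 1e-12)
  idx2 <- with_mean_sd(rnorm(50), 10, 1)
  expect_equal(target_value(idx2), 9, tolerance = 1e-12)
  expect_equal(target_value(drop(scale(rnorm(40)))), -1, tolerance = 1e-12)
  expect_error(target_value(rep(2, 10)), "distinct")
})

# toy decomposition: 4 chemicals over 3 classes, both sexes
toy_decomp <- function(n = 10, seed = 80, weights = NULL) {
  withr::with_seed(seed, {
    S <- matrix(sample(0:9, n * 4, replace = TRUE), n, 4,
                dimnames = list(NULL, c("A", "B", "C", "D")))
    sex <- rep(c(0, 1), length.out = n)
  })
  classes <- c(A = "plasticizer", B = "phenol", C = "pfas",
               D = "persistent_chlorinated")
  weights <- weights %||% rep(1 / 8, 8)
  list(d = class_contributions(S, weights, sex, classes), S = S, sex = sex,
       weights = weights)
}

test_that("class contributions decompose the index exactly", {
  td <- toy_decomp(n = 25, seed = 81)
  idx <- compute_index(td$S, td$weights, td$sex)
  expect_equal(rowSums(td$d$contributions), idx, tolerance = 1e-10)
  ok <- idx > 0
  expect_equal(rowSums(td$d$fractions[ok, , drop = FALSE]), rep(1, sum(ok)),
               tolerance = 1e-10)
})

test_that("pure-PFAS weights give persistent fraction one", {
  w <- rep(0, 52)
  chems <- chemical_table()
  w[which(chems$chemical == "PFOA")] <- 0.5        # boy block
  w[26 + which(chems$chemical == "PFOA")] <- 0.5   # girl block
  toy <- make_toy_scores(12, 26, seed = 82)
  colnames(toy$S) <- chems$chemical
  d <- class_contributions(toy$S, w, toy$sex,
                           setNames(chems$class, chems$chemical))
  expect_equal(d$persistent_fraction, rep(1, 12), tolerance = 1e-12)
})

test_that("uniform weights and equal scores split by class size", {
  chems <- chemical_table()
  S <- matrix(7L, 9, 26, dimnames = list(NULL, chems$chemical))
  sex <- rep(c(0, 1, 1), 3)
  d <- class_contributions(S, rep(1 / 52, 52), sex,
                           setNames(chems$class, chems$chemical))
  expect_equal(d$persistent_fraction, rep(10 / 26, 9), tolerance = 1e-12)
})

test_that("unmapped chemicals are rejected by name", {
  S <- matrix(1L, 5, 2, dimnames = list(NULL, c("A", "Mystery")))
  expect_error(
    class_contributions(S, rep(0.25, 4), rep(0, 5), c(A = "phenol")),
    "Mystery")
})

test_that("scenario arithmetic scales class contributions", {
  td <- toy_decomp(n = 20, seed = 83)
  idx <- td$d$index
  expect_equal(apply_scenario(td$d, c(plasticizer = 1)), idx)
  all_zero <- setNames(rep(0, length(td$d$class_levels)), td$d$class_levels)
  expect_equal(apply_scenario(td$d, all_zero), rep(0, 20))
  pers <- rowSums(td$d$contributions[, c("pfas", "persistent_chlorinated")])
  nonpers <- idx - pers
  adj <- apply_scenario(td$d, c(plasticizer = 0.3, phenol = 0.3))
  expect_equal(adj, pers + 0.3 * nonpers, tolerance = 1e-12)
  expect_error(apply_scenario(td$d, c(plasticizer = 1.2)), "\\[0, 1\\]")
  expect_error(apply_scenario(td$d, c(nope = 0.5)), "nope")
})

test_that("fraction below target counts strictly", {
  expect_equal(fraction_below_target(c(1, 2, 3), 2), 1 / 3)
  expect_equal(fraction_below_target(c(0, 0.5), 2), 1)
  expect_equal(fraction_below_target(c(2, 2, 2), 2), 0)  # strict inequality
  expect_error(fraction_below_target(numeric(0), 1), "empty")
})

test_that("below-target fractions are monotone in every retain multiplier", {
  td <- toy_decomp(n = 10, seed = 84)
  tgt <- target_value(td$d$index)
  grid <- seq(0, 1, by = 0.25)
  for (cls in td$d$class_levels) {
    fr <- vapply(grid, function(r) {
      fraction_below_target(apply_scenario(td$d, setNames(r, cls)), tgt)
    }, numeric(1))
    expect_true(all(diff(fr) <= 1e-12))  # nonincreasing in retention
  }
  # and jointly, over a two-class grid
  for (r1 in grid) {
    fr2 <- vapply(grid, function(r2) {
      fraction_below_target(
        apply_scenario(td$d, c(plasticizer = r1, pfas = r2)), tgt)
    }, numeric(1))
    expect_true(all(diff(fr2) <= 1e-12))
  }
})

test_that("eliminating a superset of classes never performs worse", {
  td <- toy_decomp(n = 10, seed = 85)
  tgt <- target_value(td$d$index)
  cls <- td$d$class_levels
  subsets <- unlist(lapply(seq_along(cls), function(k)
    combn(cls, k, simplify = FALSE)), recursive = FALSE)
  frac_of <- function(sub) {
    fraction_below_target(
      apply_scenario(td$d, setNames(rep(0, length(sub)), sub)), tgt)
  }
  fr <- vapply(subsets, frac_of, numeric(1))
  for (i in seq_along(subsets)) for (j in seq_along(subsets)) {
    if (all(subsets[[i]] %in% subsets[[j]])) {
      expect_gte(fr[j] + 1e-12, fr[i])
    }
  }
})

test_that("the scenario battery reports coherent fractions and histograms", {
  coh <- simulate_cohort(n = 150, seed = 86)
  qm <- preprocess_panel(coh$exposures)
  w <- weight_set(rep(1 / 52, 52), chemical_table()$chemical)
  d <- class_contributions(qm, w, coh$sex)
  b <- scenario_battery(d)
  expect_equal(b$summary$fraction_below[b$summary$scenario == "baseline"],
               fraction_below_target(d$index, b$target))
  expect_true(all(colSums(b$histograms$counts) == 150))
  # eliminating plasticizers+phenols retains no more weight than
  # plasticizers alone, so its below-target fraction is at least as large
  fr <- setNames(b$summary$fraction_below, b$summary$scenario)
  expect_gte(fr[["eliminate_plasticizers_phenols"]],
             fr[["eliminate_plasticizers"]])
  expect_gte(fr[["eliminate_plasticizers_shortlived"]],
             fr[["eliminate_plasticizers"]])
  expect_gte(fr[["cut70_nonpersistent"]], fr[["baseline"]])
})
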