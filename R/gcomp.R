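#' Center and scale an exposure metric
#'
#' Standardizes a per-subject metric (e.g. the WQS index or a nutrition
#' index) to mean 0 and SD 1, retaining the center and scale so
#' counterfactual levels can be translated between the standardized and raw
#' scales.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @param name Metric label.
#' @return An `exposure_metric`: list with `name`, `values` (scaled), `raw`,
#'   `center`, `scale`.
#' @export
#' @examples
#' m <- scale_metric(c(1, 2, 3))
#' m$values
scale_metric <- function(values, name = "metric") {
  if (length(unique(values)) < 2L) {
    stop_wqs("metric has fewer than 2 distinct values; cannot scale")
  }
  center <- mean(values)
  scale <- sd(values)
  if (scale == 0) stop_wqs("metric has zero variance")
  structure(
    list(name = name, values = (values - center) / scale, raw = values,
         center = center, scale = scale),
    class = "exposure_metric"
  )
}

#' @export
print.exposure_metric <- function(x, ...) {
  cat("<exposure_metric> ", x$name, ": center ", signif(x$center, 4),
      ", scale ", signif(x$scale, 4), ", n = ", length(x$values), "\n",
      sep = "")
  invisible(x)
}

#' Raw metric value of a counterfactual shift of k SDs
#'
#' Translates a standardized counterfactual setting into the raw metric
#' scale: `center + k * scale`.  For a nutrition index with mean 66.8 and SD
#' 14.0, a one-SD improvement is 80.8; for a WQS index with mean 2.24 and SD
#' 0.50, one SD below the mean is 1.74.
#'
#' @param center Metric mean.
#' @param scale Metric SD (> 0).
#' @param k Number of SDs (sign gives the direction).
#' @return `center + k * scale`.
#' @export
#' @examples
#' counterfactual_shift(66.8, 14.0, +1)
counterfactual_shift <- function(center, scale, k) {
  if (scale <= 0) stop_wqs("`scale` must be > 0")
  center + k * scale
}

#' Marginal counterfactual effect by g-computation
#'
#' Fits a linear outcome model on the observed data (metric, sex stratum,
#' their interaction unless disabled, and covariates), then for each of two
#' counterfactual settings sets every subject's metric to that level,
#' predicts, and averages within each reporting stratum (boys, girls,
#' overall).  The marginal effect is the difference of the two averages
#' (second level minus first); percentile confidence intervals come from a
#' subject-level nonparametric bootstrap that repeats the whole procedure.
#'
#' @param y Outcome vector.
#' @param metric Per-subject metric, raw or standardized (levels must be on
#'   the same scale).
#' @param covariates Numeric covariate data.frame (may be NULL).
#' @param sex Binary stratum vector (1 = girl).
#' @param levels Length-2 numeric: the reference ("what is") and
#'   counterfactual ("what if") metric settings.
#' @param n_boot Bootstrap replicates (default 200); 0 gives point estimates
#'   only.
#' @param interaction Include the metric-by-stratum interaction (default
#'   TRUE)?  Without it the marginal difference is exactly
#'   `coefficient * (levels[2] - levels[1])` in every stratum.
#' @param seed Integer seed for the bootstrap.
#' @return A `gcomp_result`: data.frames `marginal_means` (level x stratum)
#'   and `difference` (per stratum), each with bootstrap 2.5/97.5 percentile
#'   bounds when `n_boot > 0`, plus the fitted model.
#' @export
gcomp_marginal <- function(y, metric, covariates = NULL, sex,
                           levels, n_boot = 200, interaction = TRUE,
                           seed = NULL) {
  assert_binary_sex(sex)
  if (length(levels) != 2L || !is.numeric(levels)) {
    stop_wqs("`levels` must be two numeric metric settings")
  }
  Z <- covariate_matrix(covariates, length(y))
  n <- length(y)
  stopifnot(length(metric) == n, length(sex) == n, nrow(Z) %in% c(0L, n))
  span <- range(metric)
  s <- sd(metric)
  out_of_range <- levels < span[1] - s | levels > span[2] + s
  if (any(out_of_range)) {
    warning("counterfactual level(s) ",
            paste(signif(levels[out_of_range], 4), collapse = ", "),
            " lie more than 1 SD outside the observed metric range; ",
            "the positivity assumption is doubtful there", call. = FALSE)
  }

  point <- gcomp_once(y, metric, Z, sex, levels, interaction)

  boots <- NULL
  if (n_boot > 0) {
    local_seed(seed)
    boots <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      for (attempt in 1:10) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(sex[idx])) == 2L) break
      }
      boots[[b]] <- gcomp_once(y[idx], metric[idx], Z[idx, , drop = FALSE],
                               sex[idx], levels, interaction)
    }
  }

  strata <- c("boy", "girl", "overall")
  mm <- expand.grid(level = levels, stratum = strata,
                    stringsAsFactors = FALSE)
  mm$mean <- as.vector(point$means)
  diff_df <- data.frame(stratum = strata, difference = point$diff,
                        stringsAsFactors = FALSE)
  if (!is.null(boots)) {
    bm <- vapply(boots, function(b) as.vector(b$means),
                 numeric(length(mm$mean)))
    mm$q2.5 <- apply(bm, 1L, quantile, 0.025, names = FALSE)
    mm$q97.5 <- apply(bm, 1L, quantile, 0.975, names = FALSE)
    bd <- vapply(boots, function(b) b$diff, numeric(3L))
    diff_df$q2.5 <- apply(bd, 1L, quantile, 0.025, names = FALSE)
    diff_df$q97.5 <- apply(bd, 1L, quantile, 0.975, names = FALSE)
  }
  structure(
    list(levels = levels, marginal_means = mm, difference = diff_df,
         n_boot = n_boot, seed = seed, interaction = interaction,
         model = point$fit),
    class = "gcomp_result"
  )
}

# one g-computation pass: fit, predict under both levels, average, difference
gcomp_once <- function(y, metric, Z, sex, levels, interaction) {
  D <- cbind(`(Intercept)` = 1, metric = metric, Female = sex)
  if (interaction) D <- cbind(D, `metric:Female` = metric * sex)
  if (ncol(Z)) D <- cbind(D, Z)
  fit <- lm.fit(D, y)
  if (fit$rank < ncol(D)) stop_wqs("rank-deficient g-computation model")
  cf <- fit$coefficients
  predict_at <- function(L) {
    Dc <- D
    Dc[, "metric"] <- L
    if (interaction) Dc[, "metric:Female"] <- L * sex
    drop(Dc %*% cf)
  }
  p1 <- predict_at(levels[1]); p2 <- predict_at(levels[2])
  boys <- sex == 0
  means <- rbind(c(mean(p1[boys]), mean(p1[!boys]), mean(p1)),
                 c(mean(p2[boys]), mean(p2[!boys]), mean(p2)))
  list(means = means, diff = means[2L, ] - means[1L, ], fit = cf)
}

#' @export
print.gcomp_result <- function(x, ...) {
  cat("<gcomp_result> counterfactual levels ", signif(x$levels[1], 4), " -> ",
      signif(x$levels[2], 4), "\n", sep = "")
  cat("Marginal means:\n"); print(x$marginal_means, digits = 4)
  cat("Differences (what-if minus what-is):\n")
  print(x$difference, digits = 3)
  invisible(x)
}
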