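#' Random training/holdout split of a cohort
#'
#' Simple random split without replacement: `floor(fraction * n)` subjects
#' form the training set (weight estimation), the rest the holdout
#' (hypothesis testing).  If either part would lack a sex stratum the split
#' is redrawn with a derived seed (up to 10 attempts, logged), then rejected.
#'
#' @param cohort A `wqs_cohort`, or a bare sex vector.
#' @param fraction Training share in (0, 1); default 0.4.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `holdout` (disjoint,
#'   exhaustive).
#' @export
#' @examples
#' sp <- split_cohort(rep(c(0, 1), 339), fraction = 0.4, seed = 1)
#' lengths(sp)
split_cohort <- function(cohort, fraction = 0.4, seed = NULL) {
  sex <- if (inherits(cohort, "wqs_cohort")) cohort$sex else cohort
  assert_binary_sex(sex)
  if (fraction <= 0 || fraction >= 1) stop_wqs("`fraction` must be in (0, 1)")
  n <- length(sex)
  n_train <- floor(fraction * n)
  if (n_train < 1L || n_train >= n) stop_wqs("split leaves an empty part")
  local_seed(seed)
  for (attempt in 1:10) {
    train <- sort(sample.int(n, n_train))
    holdout <- setdiff(seq_len(n), train)
    if (length(unique(sex[train])) == 2L &&
        length(unique(sex[holdout])) == 2L) {
      return(list(train = train, holdout = holdout))
    }
    message("split_cohort: stratum empty on attempt ", attempt, ", resampling")
  }
  stop_wqs("could not produce a split with both sex strata in both parts")
}

#' Repeated-holdout estimation of the stratified WQS model
#'
#' The generalizability procedure: the exposure panel is decile-scored once
#' (breakpoints frozen from the full sample); then for each of `n_repeats`
#' random 40/60 splits, a bootstrap ensemble of `n_boot` constrained fits on
#' the training part yields averaged weights, the frozen-weight index is
#' computed on the holdout part, and the linear index model is fit there.
#' The distribution of coefficients and weights across repeats summarizes
#' uncertainty.
#'
#' @param cohort A `wqs_cohort`.
#' @param n_repeats Number of random splits (default 100).
#' @param n_boot Bootstrap fits per split (default 100).
#' @param fraction Training share (default 0.4).
#' @param direction Sign constraint for the reference slope
#'   (default `"negative"`, adverse mixture).
#' @param K Quantile bins (default 10).
#' @param min_detect Detection filter threshold (default 0.75).
#' @param ensemble_mode Weight averaging mode, see [ensemble_weights()].
#' @param n_restart Optimizer restarts per bootstrap fit.
#' @param seed Master seed; per-repeat seeds are derived deterministically so
#'   any single repeat can be reproduced in isolation.
#' @param verbose Emit per-repeat progress messages?
#' @return A `holdout_ensemble`: per-repeat weight matrix, coefficient
#'   matrix, split seeds, failure count and settings.
#' @export
run_repeated_holdout <- function(cohort, n_repeats = 100, n_boot = 100,
                                 fraction = 0.4,
                                 direction = c("negative", "positive"),
                                 K = 10, min_detect = 0.75,
                                 ensemble_mode = c("mean", "signal_weighted"),
                                 n_restart = 3, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(cohort, "wqs_cohort"), n_repeats >= 1, n_boot >= 1)
  direction <- match.arg(direction)
  ensemble_mode <- match.arg(ensemble_mode)
  qm <- preprocess_panel(cohort$exposures, K = K, min_detect = min_detect)
  S <- qm$scores
  Z <- covariate_matrix(cohort$covariates)
  sex <- cohort$sex
  y <- cohort$outcome
  c <- ncol(S)
  seeds <- derive_seeds(seed, n_repeats)

  weights <- matrix(NA_real_, n_repeats, 2L * c)
  colnames(weights) <- c(paste0("boy:", colnames(S)),
                         paste0("girl:", colnames(S)))
  coefs <- NULL
  failed <- logical(n_repeats)

  for (r in seq_len(n_repeats)) {
    res <- tryCatch({
      rs <- derive_seeds(seeds[[r]], n_boot + 1L)
      sp <- split_cohort(sex, fraction, seed = rs[[n_boot + 1L]])
      fits <- lapply(seq_len(n_boot), function(b) {
        fit_single_bootstrap(S[sp$train, , drop = FALSE],
                             as.data.frame(Z[sp$train, , drop = FALSE]),
                             sex[sp$train], y[sp$train],
                             direction = direction, seed = rs[[b]],
                             n_restart = n_restart)
      })
      n_conv <- sum(vapply(fits, function(f) isTRUE(f$converged), logical(1)))
      if (verbose && n_conv < n_boot) {
        message("repeat ", r, ": ", n_boot - n_conv,
                " unconverged bootstrap fit(s) excluded")
      }
      w <- ensemble_weights(fits, mode = ensemble_mode)
      idx_hold <- compute_index(S[sp$holdout, , drop = FALSE], w, sex[sp$holdout])
      im <- fit_index_model(idx_hold,
                            as.data.frame(Z[sp$holdout, , drop = FALSE]),
                            sex[sp$holdout], y[sp$holdout])
      list(w = w, cf = setNames(im$coefficients$estimate,
                                im$coefficients$term))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[r] <- TRUE
      if (verbose) message("repeat ", r, " failed: ", conditionMessage(res))
      next
    }
    weights[r, ] <- res$w
    if (is.null(coefs)) {
      coefs <- matrix(NA_real_, n_repeats, length(res$cf),
                      dimnames = list(NULL, names(res$cf)))
    }
    coefs[r, ] <- res$cf
    if (verbose) message("repeat ", r, "/", n_repeats, " done")
  }
  if (all(failed)) stop_wqs("every holdout repeat failed")
  structure(
    list(weights = weights, coefficients = coefs, failed = failed,
         n_repeats = n_repeats, n_boot = n_boot, fraction = fraction,
         direction = direction, ensemble_mode = ensemble_mode, K = K,
         seed = seed, threshold = equi_weight_threshold(c, 2),
         chemicals = qm$chemicals, breakpoints = qm$breakpoints),
    class = "holdout_ensemble"
  )
}

#' @export
print.holdout_ensemble <- function(x, ...) {
  ok <- sum(!x$failed)
  cat("<holdout_ensemble> ", ok, "/", x$n_repeats, " repeats (",
      x$n_boot, " bootstraps each, ", round(100 * x$fraction),
      "/", round(100 * (1 - x$fraction)), " split)\n", sep = "")
  b1 <- x$coefficients[!x$failed, "WQS"]
  cat("  mean boys' slope: ", signif(mean(b1), 3), " (SD ",
      signif(sd(b1), 3), ")\n", sep = "")
  invisible(x)
}

#' Summarize a repeated-holdout ensemble
#'
#' Parameter summaries across repeats (mean, SD reported as the standard
#' error, 2.5/97.5 percentiles, fraction of negative estimates) and weight
#' summaries (mean, 2.5/25/50/75/97.5 percentiles, fraction of repeats above
#' the equi-weight threshold).
#'
#' @param ensemble A `holdout_ensemble`.
#' @param threshold Weight cutoff; defaults to the ensemble's `1/(2c)`.
#' @return An `ensemble_summary`: list with data.frames `parameters` and
#'   `weights`.
#' @export
summarize_ensemble <- function(ensemble, threshold = NULL) {
  stopifnot(inherits(ensemble, "holdout_ensemble"))
  threshold <- threshold %||% ensemble$threshold
  ok <- !ensemble$failed
  if (!any(ok)) stop_wqs("empty ensemble")
  cf <- ensemble$coefficients[ok, , drop = FALSE]
  parameters <- data.frame(
    term = colnames(cf),
    mean = colMeans(cf),
    std_error = apply(cf, 2L, sd),
    q2.5 = apply(cf, 2L, quantile, 0.025, names = FALSE),
    q97.5 = apply(cf, 2L, quantile, 0.975, names = FALSE),
    frac_negative = colMeans(cf < 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  wm <- ensemble$weights[ok, , drop = FALSE]
  nm <- colnames(wm)
  weights <- data.frame(
    stratum = sub(":.*$", "", nm),
    chemical = sub("^[^:]*:", "", nm),
    mean = colMeans(wm),
    q2.5 = apply(wm, 2L, quantile, 0.025, names = FALSE),
    q25 = apply(wm, 2L, quantile, 0.25, names = FALSE),
    q50 = apply(wm, 2L, quantile, 0.5, names = FALSE),
    q75 = apply(wm, 2L, quantile, 0.75, names = FALSE),
    q97.5 = apply(wm, 2L, quantile, 0.975, names = FALSE),
    frac_above_threshold = colMeans(wm > threshold),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(parameters = parameters, weights = weights,
                 threshold = threshold, n_repeats = sum(ok)),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("<ensemble_summary> over", x$n_repeats, "holdout repeats\n")
  cat("Parameters:\n")
  print(x$parameters, digits = 3)
  cat("\nWeights above the", signif(x$threshold, 3), "guideline:\n")
  above <- x$weights[x$weights$mean > x$threshold,
                     c("stratum", "chemical", "mean", "frac_above_threshold")]
  print(above[order(-above$mean), ], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Mean ensemble weights as a weight set
#'
#' Extracts the across-repeat mean weight vector (renormalized to the
#' simplex) for downstream use: index construction, g-computation
#' ("conditioning on the average weights") and scenario analysis.
#'
#' @param ensemble A `holdout_ensemble`.
#' @return A [weight_set()].
#' @export
mean_ensemble_weights <- function(ensemble) {
  stopifnot(inherits(ensemble, "holdout_ensemble"))
  w <- colMeans(ensemble$weights[!ensemble$failed, , drop = FALSE])
  w <- renormalize_blocks(w)
  structure(w, class = "weight_set",
            threshold = ensemble$threshold)
}
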