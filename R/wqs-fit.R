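#' Equi-weight guideline threshold for index weights
#'
#' In an equi-weighted index of `c` components across `n_strata` strata every
#' weight equals `1/(n_strata * c)`; estimated mean weights above this value
#' flag components of concern (for 26 chemicals in 2 sex strata the cutoff is
#' 1/52, about 0.019).
#'
#' @param c Number of mixture components per stratum (>= 1).
#' @param n_strata Number of strata sharing the simplex (>= 1).
#' @return The threshold `1 / (n_strata * c)`.
#' @export
#' @examples
#' equi_weight_threshold(26, 2)
equi_weight_threshold <- function(c, n_strata = 2) {
  stopifnot(c >= 1, n_strata >= 1)
  1 / (n_strata * c)
}

#' Construct and validate a stratified weight set
#'
#' A weight set holds the `2c` nonnegative weights of the stratified index
#' (boy block then girl block) on a single simplex.
#'
#' @param w Numeric vector of length `2c`, nonnegative, summing to 1 within
#'   `1e-8`.
#' @param chemicals Optional chemical names (length `c`) used to name the
#'   entries `boy:<chem>` / `girl:<chem>`.
#' @return A named numeric vector of class `weight_set` with attribute
#'   `threshold = 1/(2c)`.
#' @export
weight_set <- function(w, chemicals = NULL) {
  if (length(w) %% 2L != 0L) stop_wqs("weight vector length must be even")
  c <- length(w) / 2L
  if (any(w < -1e-12)) stop_wqs("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-8) {
    stop_wqs("weights must sum to 1 within 1e-8 (got ", format(sum(w)), ")")
  }
  w <- pmax(w, 0)
  if (!is.null(chemicals)) {
    stopifnot(length(chemicals) == c)
    names(w) <- c(paste0("boy:", chemicals), paste0("girl:", chemicals))
  }
  structure(w, class = "weight_set", threshold = equi_weight_threshold(c, 2))
}

#' Compute the stratified weighted quantile sum index
#'
#' Each subject's index is the weighted sum of their quantile scores using
#' only their own stratum's weight block:
#' `index_i = sum_j w[s(i), j] * q[i, j]`, with `s(i)` the boy block for
#' `sex = 0` and the girl block for `sex = 1`.
#'
#' @param q A `quantile_matrix` or score matrix (subjects x chemicals).
#' @param weights Length-`2c` weight vector (boy block first).
#' @param sex Binary vector (1 = girl).
#' @return Numeric index vector.
#' @export
#' @examples
#' q <- matrix(9L, 2, 26)
#' compute_index(q, rep(1 / 52, 52), c(0, 1))
compute_index <- function(q, weights, sex) {
  S <- quantile_scores(q)
  assert_binary_sex(sex)
  c <- ncol(S)
  if (length(weights) != 2L * c) {
    stop_wqs("`weights` must have length ", 2L * c, " (2 strata x ", c,
             " chemicals); got ", length(weights))
  }
  if (nrow(S) != length(sex)) stop_wqs("`q` and `sex` sizes disagree")
  wb <- weights[seq_len(c)]
  wg <- weights[c + seq_len(c)]
  drop((1 - sex) * (S %*% wb) + sex * (S %*% wg))
}

# rescale each sex block of a 2c weight vector to mass 1/2
renormalize_blocks <- function(w) {
  c <- length(w) / 2L
  b <- seq_len(c)
  w[b] <- 0.5 * w[b] / sum(w[b])
  w[c + b] <- 0.5 * w[c + b] / sum(w[c + b])
  w
}

# covariate data.frame -> plain numeric matrix (n x 0 when absent)
covariate_matrix <- function(covariates, n = NROW(covariates)) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  covariates <- as.data.frame(covariates)
  if (!all(vapply(covariates, is.numeric, logical(1)))) {
    stop_wqs("covariates must be numeric")
  }
  as.matrix(covariates)
}

# Core constrained fit on prepared matrices.  Minimizes the profiled RSS over
# the softmax-parameterized simplex weights and the box-constrained reference
# slope beta1, with quasi-Newton (L-BFGS-B) restarts from random logits.
wqs_fit_internal <- function(S, x, Z, y, direction = c("negative", "positive"),
                             n_restart = 3, maxit = 500, factr = 1e9) {
  direction <- match.arg(direction)
  c <- ncol(S)
  npar <- 2L * c + 1L
  lower <- c(rep(-20, 2L * c), if (direction == "negative") -Inf else 0)
  upper <- c(rep(20, 2L * c), if (direction == "negative") 0 else Inf)
  storage.mode(S) <- "double"

  # slope start: OLS slope of y on the equi-weighted index, clipped to the
  # allowed sign (small magnitude fallback when the data trend the other way)
  W0 <- rowMeans(S) / 2  # equi-weighted (1/(2c)) index
  b_ols <- tryCatch(coef(lm.fit(cbind(1, W0, x, x * W0, Z), y))[2L],
                    error = function(e) 0)
  sgn <- if (direction == "negative") -1 else 1
  b_start <- if (is.finite(b_ols) && sign(b_ols) == sgn) b_ols else sgn * 0.1

  best <- NULL
  for (r in seq_len(n_restart)) {
    theta0 <- if (r == 1L) rep(0, 2L * c) else rnorm(2L * c, 0, 0.5)
    par0 <- c(theta0, b_start)
    fit <- tryCatch(
      stats::optim(par0, fn = wqs_obj_cpp, gr = wqs_grad_cpp,
                   Q = S, x = x, Z = Z, y = y,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = maxit, factr = factr)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e29) {
    return(list(converged = FALSE))
  }
  prof <- wqs_profile_cpp(best$par, S, x, Z, y)
  if (!prof$ok) return(list(converged = FALSE))
  gamma <- drop(prof$gamma)
  phi <- if (length(gamma) > 3L) gamma[-(1:3)] else numeric(0)
  names(phi) <- colnames(Z)
  w <- drop(prof$weights)
  names(w) <- c(paste0("boy:", colnames(S)), paste0("girl:", colnames(S)))
  # conditional t-statistic for beta1 treating the fitted index as fixed
  Wfit <- compute_index(S, w, x)
  t1 <- beta1_tstat(Wfit, x, Z, y)
  list(weights = w, beta0 = gamma[1L], beta1 = prof$beta1, beta2 = gamma[2L],
       beta12 = gamma[3L], phi = phi, rss = prof$rss,
       converged = best$convergence == 0, beta1_t = t1)
}

beta1_tstat <- function(W, x, Z, y) {
  D <- cbind(1, W, x, x * W, Z)
  fit <- tryCatch(lm.fit(D, y), error = function(e) NULL)
  if (is.null(fit) || fit$rank < ncol(D)) return(NA_real_)
  rdf <- length(y) - fit$rank
  s2 <- sum(fit$residuals^2) / rdf
  XtXinv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
  se <- sqrt(s2 * XtXinv[2L, 2L])
  unname(fit$coefficients[2L] / se)
}

#' Fit the constrained WQS model on one bootstrap resample
#'
#' Draws a bootstrap sample of subjects (with replacement, redrawn up to 10
#' times if a sex stratum is absent) and jointly estimates the 52 weights
#' and the model coefficients by minimizing the residual sum of squares of
#' the outcome on `{WQS(w), sex, sex*WQS(w), covariates}`, with the
#' reference slope sign-constrained to `direction`.  The weights are
#' nonnegative and sum to 1, with each sex block holding mass 1/2; fixing
#' the block masses identifies the slope magnitudes, which would otherwise
#' trade off freely against the split of weight between the blocks.
#'
#' @param q `quantile_matrix` or score matrix.
#' @param covariates Numeric covariate data.frame (may be NULL).
#' @param sex Binary vector (1 = girl).
#' @param y Outcome vector.
#' @param direction Sign constraint on the reference (boys) slope.
#' @param seed Integer seed for the resample and restarts.
#' @param n_restart Random optimizer restarts (default 3).
#' @param resample Set `FALSE` to fit on the data as given (no bootstrap).
#' @return A `wqs_boot_fit`: weights, coefficients (`beta0`, `beta1`,
#'   `beta2`, `beta12`, `phi`), `rss`, `converged`, `beta1_t` and `seed`.
#' @export
fit_single_bootstrap <- function(q, covariates, sex, y,
                                 direction = c("negative", "positive"),
                                 seed = NULL, n_restart = 3, resample = TRUE) {
  direction <- match.arg(direction)
  S <- quantile_scores(q)
  assert_binary_sex(sex)
  Z <- covariate_matrix(covariates, length(y))
  n <- length(y)
  if (n < 2L * ncol(S) + ncol(Z) + 3L) {
    stop_wqs("need at least ", 2L * ncol(S) + ncol(Z) + 3L,
             " complete cases; got ", n)
  }
  local_seed(seed)
  idx <- seq_len(n)
  if (resample) {
    for (attempt in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(sex[idx])) == 2L) break
    }
  }
  fit <- wqs_fit_internal(S[idx, , drop = FALSE], sex[idx],
                          Z[idx, , drop = FALSE], y[idx],
                          direction = direction, n_restart = n_restart)
  fit$seed <- seed
  fit$direction <- direction
  class(fit) <- "wqs_boot_fit"
  fit
}

#' Average bootstrap weight vectors into an ensemble weight set
#'
#' Combines the converged fits of a bootstrap ensemble: `mean` mode takes the
#' arithmetic mean of the weight vectors (renormalized onto the simplex);
#' `signal_weighted` mode weights each fit by the absolute t-statistic of its
#' index slope, emphasizing resamples with a stronger mixture signal.
#'
#' @param fits List of `wqs_boot_fit` objects.
#' @param mode `"mean"` (default) or `"signal_weighted"`.
#' @return A [weight_set()].
#' @export
ensemble_weights <- function(fits, mode = c("mean", "signal_weighted")) {
  mode <- match.arg(mode)
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv)) stop_wqs("no converged bootstrap fits to average")
  Wm <- do.call(rbind, lapply(conv, `[[`, "weights"))
  if (mode == "mean") {
    w <- colMeans(Wm)
  } else {
    a <- abs(vapply(conv, function(f) f$beta1_t %||% NA_real_, numeric(1)))
    a[!is.finite(a)] <- 0
    if (sum(a) == 0) a <- rep(1, length(conv))
    w <- colSums(Wm * a) / sum(a)
  }
  w <- renormalize_blocks(w)
  names(w) <- colnames(Wm)
  structure(w, class = "weight_set",
            threshold = equi_weight_threshold(ncol(Wm) / 2L, 2))
}

#' Fit the linear index model with frozen weights
#'
#' Ordinary least squares of the outcome on `{index, Female, index:Female,
#' covariates}`, the hypothesis-testing step of WQS regression: the index is
#' held fixed (weights frozen from the estimation step) so standard linear
#' model inference applies.
#'
#' @param index Numeric index vector.
#' @param covariates Numeric covariate data.frame (may be NULL).
#' @param sex Binary vector (1 = girl).
#' @param y Outcome.
#' @return A `wqs_index_fit`: `coefficients` data.frame (term, estimate,
#'   std_error) with terms `(Intercept)`, `WQS`, `Female`, the covariates and
#'   `WQS:Female`, plus the underlying `lm` fit.
#' @export
fit_index_model <- function(index, covariates, sex, y) {
  assert_binary_sex(sex)
  df <- data.frame(.y = y, WQS = index, Female = sex)
  if (!is.null(covariates) && NCOL(covariates) > 0L) {
    df <- cbind(df, as.data.frame(covariates))
  }
  covs <- setdiff(names(df), c(".y", "WQS", "Female"))
  rhs <- paste(c("WQS", "Female", covs, "WQS:Female"), collapse = " + ")
  fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop_wqs("rank-deficient design; collinear term(s): ",
             paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  coefficients <- data.frame(
    term = rownames(sm), estimate = sm[, 1L], std_error = sm[, 2L],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(coefficients = coefficients, fit = fit),
            class = "wqs_index_fit")
}

#' @export
print.wqs_index_fit <- function(x, ...) {
  cat("<wqs_index_fit> stratified-interaction index model\n")
  print(x$coefficients, digits = 3)
  cat("boys' slope:", signif(stratum_slope(x, "boy"), 3),
      "; girls' slope:", signif(stratum_slope(x, "girl"), 3), "\n")
  invisible(x)
}

#' Stratum-specific index slope
#'
#' In the interaction parameterization the reference stratum (boys) has slope
#' `beta1` and the comparison stratum (girls) has slope `beta1 + beta12`; the
#' girls' slope is always reported as that sum, never as a free parameter.
#'
#' @param coefs A `wqs_index_fit`, its `coefficients` data.frame, or a named
#'   vector containing `WQS` and `WQS:Female`.
#' @param stratum `"boy"` or `"girl"`.
#' @return The slope (outcome units per index unit).
#' @export
#' @examples
#' stratum_slope(c(WQS = -2.13, `WQS:Female` = 1.98), "girl")
stratum_slope <- function(coefs, stratum = c("boy", "girl")) {
  stratum <- match.arg(stratum)
  if (inherits(coefs, "wqs_index_fit")) coefs <- coefs$coefficients
  if (is.data.frame(coefs)) {
    v <- setNames(coefs$estimate, coefs$term)
  } else {
    v <- coefs
  }
  if (!all(c("WQS", "WQS:Female") %in% names(v))) {
    stop_wqs("coefficients must contain `WQS` and `WQS:Female`")
  }
  b1 <- unname(v[["WQS"]])
  if (stratum == "boy") b1 else b1 + unname(v[["WQS:Female"]])
}
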