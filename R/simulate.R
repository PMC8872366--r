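#' Simulate a block-correlated lognormal exposure panel
#'
#' Draws subject-by-chemical concentrations from a Gaussian copula with a
#' two-level block-exchangeable correlation structure on the log scale:
#' chemicals within the same class correlate at `rho_within`, chemicals in
#' different classes at `rho_between`.  Marginals are lognormal with the
#' per-chemical location/scale from `chems`.  Values below each chemical's
#' detection-rate quantile (its limit of detection, LOD) are flagged
#' nondetect; the raw draws are retained so substitution policy is applied
#' downstream.  A per-subject urinary creatinine is drawn from a lognormal
#' matched to the requested mean/SD.
#'
#' @param n Number of subjects (>= 1).
#' @param chems Chemical specification, see [chemical_table()].
#' @param rho_within,rho_between Within-/between-class log-scale correlations;
#'   both in `[0, 1)` with `rho_between <= rho_within`.
#' @param creatinine_mean,creatinine_sd Mean and SD (mmol/L) of the creatinine
#'   distribution; defaults match a typical first-trimester urine panel
#'   (10.4 / 4.7).
#' @param seed Integer seed; identical seeds and inputs reproduce the panel
#'   bit-identically.
#' @return An `exposure_panel`: list with `values` (n x chemicals matrix),
#'   `nondetect` (logical matrix), `lod` (per-chemical limit of detection),
#'   `creatinine` (length-n vector) and `chemicals` (the spec table).
#' @export
#' @examples
#' panel <- simulate_exposures(50, seed = 1)
#' dim(panel$values)
simulate_exposures <- function(n, chems = chemical_table(),
                               rho_within = 0.4, rho_between = 0.1,
                               creatinine_mean = 10.4, creatinine_sd = 4.7,
                               seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop_wqs("`n` must be >= 1")
  n <- as.integer(n)
  validate_chemical_table(chems)
  if (rho_within < 0 || rho_within >= 1 || rho_between < 0 || rho_between >= 1) {
    stop_wqs("rho_within and rho_between must lie in [0, 1)")
  }
  if (rho_between > rho_within) {
    stop_wqs("rho_between (", rho_between, ") must not exceed rho_within (",
             rho_within, ")")
  }
  p <- nrow(chems)
  same_class <- outer(chems$class, chems$class, "==")
  R <- matrix(rho_between, p, p)
  R[same_class] <- rho_within
  diag(R) <- 1
  ch <- tryCatch(chol(R), error = function(e) {
    stop_wqs("block correlation matrix is not positive definite for ",
             "rho_within = ", rho_within, ", rho_between = ", rho_between)
  })

  local_seed(seed)
  Zn <- matrix(rnorm(n * p), n, p) %*% ch
  logC <- sweep(sweep(Zn, 2L, chems$log_sd, "*"), 2L, chems$log_mean, "+")
  values <- exp(logC)
  dimnames(values) <- list(sprintf("S%04d", seq_len(n)), chems$chemical)

  # the LOD sits at the (1 - detect_rate) quantile of the marginal, so the
  # nondetect fraction matches 1 - detect_rate in expectation
  lod <- qlnorm(1 - chems$detect_rate, meanlog = chems$log_mean,
                sdlog = chems$log_sd)
  names(lod) <- chems$chemical
  nondetect <- sweep(values, 2L, lod, "<")

  cv2 <- (creatinine_sd / creatinine_mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(creatinine_mean) - sdlog^2 / 2
  creatinine <- rlnorm(n, meanlog, sdlog)

  new_exposure_panel(values, nondetect, lod, creatinine, chems)
}

new_exposure_panel <- function(values, nondetect, lod, creatinine, chemicals) {
  stopifnot(is.matrix(values), identical(dim(values), dim(nondetect)))
  if (any(values[!nondetect] <= 0)) {
    stop_wqs("detected concentrations must be positive")
  }
  structure(
    list(values = values, nondetect = nondetect, lod = lod,
         creatinine = creatinine, chemicals = chemicals),
    class = "exposure_panel"
  )
}

#' @export
print.exposure_panel <- function(x, ...) {
  cat("<exposure_panel> ", nrow(x$values), " subjects x ", ncol(x$values),
      " chemicals\n", sep = "")
  cat("  classes:", paste(sprintf("%s (%d)", names(table(x$chemicals$class)),
                                  table(x$chemicals$class)), collapse = ", "), "\n")
  cat("  nondetect fraction:", signif(mean(x$nondetect), 3), "\n")
  invisible(x)
}

#' Default covariate marginals for the synthetic cohort
#'
#' Marginal distributions of the maternal covariates and child sex used by
#' [simulate_covariates()]: normal mean/SD pairs for the continuous
#' covariates and Bernoulli probabilities for the binary ones.  Defaults
#' reflect a Scandinavian pregnancy-cohort population (nutrition index
#' 66.8 (14.0), energy 1895 (545) kcal, age 31.3 (4.6) y, weight 68.8 (13.5)
#' kg, Raven IQ 114.8 (14.9), 69% college-educated, 11% first-trimester
#' smokers, 51% girls).
#'
#' @return Named list; continuous entries are `c(mean, sd)`, binary entries a
#'   single probability.
#' @export
covariate_defaults <- function() {
  list(MNI = c(66.8, 14.0), Energy = c(1895, 545), MomAge = c(31.3, 4.6),
       MomWeight = c(68.8, 13.5), MomIQ = c(114.8, 14.9),
       MomEduc = 0.69, Smoker = 0.11, Female = 0.51)
}

#' Simulate maternal covariates and child sex
#'
#' Continuous covariates are drawn independently normal and binary ones
#' Bernoulli, with marginals from `params` (see [covariate_defaults()]).
#'
#' @param n Number of subjects (>= 1).
#' @param params Named list of marginal parameters; any subset of the
#'   defaults may be overridden.
#' @param seed Integer seed.
#' @return List with `covariates` (data.frame MNI, Energy, MomAge, MomWeight,
#'   MomIQ, MomEduc, Smoker) and `sex` (0 = boy, 1 = girl).
#' @export
simulate_covariates <- function(n, params = list(), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop_wqs("`n` must be >= 1")
  n <- as.integer(n)
  p <- utils::modifyList(covariate_defaults(), params)
  local_seed(seed)
  covariates <- data.frame(
    MNI = rnorm(n, p$MNI[1], p$MNI[2]),
    Energy = rnorm(n, p$Energy[1], p$Energy[2]),
    MomAge = rnorm(n, p$MomAge[1], p$MomAge[2]),
    MomWeight = rnorm(n, p$MomWeight[1], p$MomWeight[2]),
    MomIQ = rnorm(n, p$MomIQ[1], p$MomIQ[2]),
    MomEduc = rbinom(n, 1L, p$MomEduc),
    Smoker = rbinom(n, 1L, p$Smoker)
  )
  sex <- rbinom(n, 1L, p$Female)
  list(covariates = covariates, sex = sex)
}

#' Ground-truth generating model for synthetic cohorts
#'
#' Bundles the coefficients of the stratified-interaction outcome model
#' `y = beta0 + beta1*WQS + beta2*Female + beta12*Female*WQS + phi'z + e`,
#' the 52 true index weights (26 per sex stratum on one simplex) and the
#' residual SD.  Defaults use cohort-scale coefficient values for a mixture
#' adversely associated with child IQ in boys (slope -2.13) and nearly null
#' in girls (-2.13 + 1.98 = -0.15), with covariate effects dominated by
#' maternal IQ, education and nutrition.
#'
#' @param beta0,beta1,beta2,beta12 Intercept, reference (boys) index slope,
#'   female intercept shift and female slope shift, in IQ points.
#' @param phi Named covariate coefficients (MNI, Energy, MomAge, MomWeight,
#'   MomEduc, MomIQ, Smoker).
#' @param weights 52 nonnegative true weights summing to 1; see
#'   [default_true_weights()].
#' @param sigma Residual SD (IQ points); 0 gives a noiseless model.
#' @return A `true_model` object.
#' @export
true_model <- function(beta0 = 88.7, beta1 = -2.13, beta2 = -0.622,
                       beta12 = 1.98,
                       phi = c(MNI = 0.073, Energy = 0, MomAge = -0.158,
                               MomWeight = -0.098, MomEduc = 4.79,
                               MomIQ = 0.158, Smoker = -2.10),
                       weights = default_true_weights(), sigma = 10) {
  if (sigma < 0) stop_wqs("`sigma` must be nonnegative")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-10) {
    stop_wqs("true weights must be nonnegative and sum to 1 (within 1e-10)")
  }
  if (is.null(names(phi))) stop_wqs("`phi` must be named")
  structure(
    list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta12 = beta12,
         phi = phi, weights = weights, sigma = sigma),
    class = "true_model"
  )
}

#' Sparse default true weights (8 active in boys, 6 in girls)
#'
#' A known sparse support for weight-recovery testing: each sex block carries
#' total mass 1/2 (matching the estimator's block constraint), spread
#' uniformly over eight active boy-stratum chemicals (0.5/8 each) and six
#' active girl-stratum chemicals (0.5/6 each); all other weights are zero.
#' The active sets span all five chemical classes.
#'
#' @param chems Chemical specification table.
#' @param boys,girls Character vectors naming the active chemicals per
#'   stratum.
#' @return Named length-52 numeric vector (`boy:*` block then `girl:*`
#'   block) summing to 1.
#' @export
default_true_weights <- function(chems = chemical_table(),
                                 boys = c("BPF", "TCP", "MBzP", "PFOA",
                                          "triclosan", "MOiNCH", "MEP", "MCiNP"),
                                 girls = c("DPHP", "MEP", "BPF", "BPS",
                                           "PFHxS", "PFUnDA")) {
  stopifnot(all(boys %in% chems$chemical), all(girls %in% chems$chemical))
  w <- setNames(numeric(2L * nrow(chems)),
                c(paste0("boy:", chems$chemical), paste0("girl:", chems$chemical)))
  w[paste0("boy:", boys)] <- 0.5 / length(boys)
  w[paste0("girl:", girls)] <- 0.5 / length(girls)
  w
}

#' Simulate the outcome from the stratified-interaction linear model
#'
#' Computes each subject's true index from the quantile scores and the
#' stratum-specific block of the true weights, then draws
#' `y = beta0 + beta1*WQS + beta2*sex + beta12*sex*WQS + phi'z + e` with
#' Gaussian residuals.
#'
#' @param quantiles A `quantile_matrix` (or plain score matrix).
#' @param covariates Covariate data.frame containing every name in
#'   `truth$phi`.
#' @param sex Binary vector (1 = girl).
#' @param truth A [true_model()].
#' @param seed Integer seed (affects residuals only).
#' @return Numeric outcome vector.
#' @export
simulate_outcome <- function(quantiles, covariates, sex, truth, seed = NULL) {
  scores <- quantile_scores(quantiles)
  assert_binary_sex(sex)
  if (!inherits(truth, "true_model")) stop_wqs("`truth` must be a true_model")
  if (length(truth$weights) != 2L * ncol(scores)) {
    stop_wqs("true weight vector has length ", length(truth$weights),
             "; expected ", 2L * ncol(scores))
  }
  if (nrow(scores) != length(sex) || nrow(covariates) != length(sex)) {
    stop_wqs("dimensions of quantiles, covariates and sex disagree")
  }
  miss <- setdiff(names(truth$phi), names(covariates))
  if (length(miss)) stop_wqs("covariates missing: ", paste(miss, collapse = ", "))
  W <- compute_index(scores, truth$weights, sex)
  Z <- as.matrix(covariates[names(truth$phi)])
  local_seed(seed)
  drop(truth$beta0 + truth$beta1 * W + truth$beta2 * sex +
         truth$beta12 * sex * W + Z %*% truth$phi +
         rnorm(length(sex), 0, truth$sigma))
}

#' Simulate a complete synthetic cohort with known ground truth
#'
#' Generates exposures, covariates and outcome in one call.  The outcome is
#' generated from the decile scores of the *preprocessed* panel
#' (nondetects substituted at LOD/sqrt(2), urinary analytes
#' creatinine-adjusted), i.e. from exactly the exposure representation the
#' analysis pipeline will see.  An optional confounding coefficient tilts the
#' nutrition index against overall log-exposure burden, for g-computation
#' stress tests.
#'
#' @inheritParams simulate_exposures
#' @param truth Generating [true_model()].
#' @param covariate_params Overrides for [covariate_defaults()].
#' @param K Number of quantile bins used for the generating index
#'   (default 10, deciles).
#' @param confound If nonzero, MNI is shifted by `-confound * sd(MNI)` times
#'   the standardized mean log-concentration, inducing exposure-covariate
#'   correlation (default 0: no confounding).
#' @param seed Master seed; child seeds for the three draws are derived
#'   deterministically from it.
#' @return A `wqs_cohort`: list with `exposures` (exposure_panel),
#'   `covariates` (data.frame), `sex`, `outcome` and `truth`.
#' @export
#' @examples
#' coh <- simulate_cohort(n = 120, seed = 7)
#' coh
simulate_cohort <- function(n = 678, truth = true_model(),
                            chems = chemical_table(),
                            rho_within = 0.4, rho_between = 0.1,
                            covariate_params = list(), K = 10,
                            confound = 0, seed = NULL) {
  seeds <- derive_seeds(seed, 3L)
  exposures <- simulate_exposures(n, chems, rho_within, rho_between,
                                  seed = seeds[[1]])
  cv <- simulate_covariates(n, covariate_params, seed = seeds[[2]])
  if (confound != 0) {
    burden <- scale(rowMeans(log(pmax(exposures$values, .Machine$double.eps))))
    cv$covariates$MNI <- cv$covariates$MNI -
      confound * sd(cv$covariates$MNI) * drop(burden)
  }
  qm <- preprocess_panel(exposures, K = K, min_detect = 0)
  outcome <- simulate_outcome(qm, cv$covariates, cv$sex, truth,
                              seed = seeds[[3]])
  new_wqs_cohort(exposures, cv$covariates, cv$sex, outcome, truth)
}

new_wqs_cohort <- function(exposures, covariates, sex, outcome, truth = NULL) {
  n <- length(outcome)
  assert_binary_sex(sex)
  if (nrow(exposures$values) != n || nrow(covariates) != n ||
      length(sex) != n) {
    stop_wqs("cohort components must share one subject count and ordering")
  }
  structure(
    list(exposures = exposures, covariates = covariates, sex = sex,
         outcome = outcome, truth = truth),
    class = "wqs_cohort"
  )
}

#' @export
print.wqs_cohort <- function(x, ...) {
  cat("<wqs_cohort> ", length(x$outcome), " subjects, ",
      ncol(x$exposures$values), " chemicals, ",
      ncol(x$covariates), " covariates\n", sep = "")
  cat("  girls: ", sum(x$sex), " (", round(100 * mean(x$sex)), "%)",
      "; outcome mean (SD): ", round(mean(x$outcome), 1), " (",
      round(sd(x$outcome), 1), ")\n", sep = "")
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}
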