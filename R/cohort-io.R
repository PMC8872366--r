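#' Write a cohort to delimited text files
#'
#' Writes four tab-delimited tables -- `exposures.tsv` (subject_id, one
#' column per chemical, creatinine), `nondetect.tsv` (0/1 flags, written only
#' when any nondetects exist), `covariates.tsv` (subject_id, Female, the
#' covariates) and `outcome.tsv` (subject_id, IQ) -- plus `chemicals.tsv`
#' (the panel specification including LODs) and, when ground truth is
#' attached, a `truth.yml` sidecar.
#'
#' @param cohort A `wqs_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wqs_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- rownames(cohort$exposures$values) %||%
    sprintf("S%04d", seq_along(cohort$outcome))
  tsv <- function(df, file) {
    write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(data.frame(subject_id = ids, cohort$exposures$values,
                 creatinine = cohort$exposures$creatinine,
                 check.names = FALSE), "exposures.tsv")
  if (any(cohort$exposures$nondetect)) {
    tsv(data.frame(subject_id = ids, cohort$exposures$nondetect * 1L,
                   check.names = FALSE), "nondetect.tsv")
  }
  chems <- cohort$exposures$chemicals
  chems$lod <- cohort$exposures$lod[chems$chemical]
  tsv(chems, "chemicals.tsv")
  tsv(data.frame(subject_id = ids, Female = cohort$sex, cohort$covariates,
                 check.names = FALSE), "covariates.tsv")
  tsv(data.frame(subject_id = ids, IQ = cohort$outcome), "outcome.tsv")
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    yaml::write_yaml(
      list(beta0 = tr$beta0, beta1 = tr$beta1, beta2 = tr$beta2,
           beta12 = tr$beta12, phi = as.list(tr$phi),
           weights = as.list(tr$weights), sigma = tr$sigma),
      file.path(dir, "truth.yml"), precision = 15
    )
  }
  invisible(dir)
}

#' Read a cohort from delimited text files
#'
#' Reads the tables written by [write_cohort()] (or equivalently formatted
#' files), aligns subjects by identifier across tables (row order is
#' irrelevant), rejects identifier mismatches listing the orphans, and drops
#' subjects with any missing field (complete-case rule) with a logged count.
#'
#' @param dir Directory containing `exposures.tsv`, `covariates.tsv`,
#'   `outcome.tsv` and optionally `nondetect.tsv`, `chemicals.tsv`,
#'   `truth.yml`.
#' @return A `wqs_cohort`.
#' @export
read_cohort <- function(dir) {
  pth <- function(f) file.path(dir, f)
  for (f in c("exposures.tsv", "covariates.tsv", "outcome.tsv")) {
    if (!file.exists(pth(f))) stop_wqs("missing cohort file: ", pth(f))
  }
  expo <- read.delim(pth("exposures.tsv"), check.names = FALSE)
  covs <- read.delim(pth("covariates.tsv"), check.names = FALSE)
  outc <- read.delim(pth("outcome.tsv"), check.names = FALSE)

  ids <- list(exposures = expo$subject_id, covariates = covs$subject_id,
              outcome = outc$subject_id)
  common <- Reduce(intersect, ids)
  orphans <- unlist(lapply(ids, setdiff, y = common))
  if (length(orphans)) {
    stop_wqs("subject identifiers do not align across tables; orphans: ",
             paste(unique(orphans), collapse = ", "))
  }
  expo <- expo[match(common, expo$subject_id), , drop = FALSE]
  covs <- covs[match(common, covs$subject_id), , drop = FALSE]
  outc <- outc[match(common, outc$subject_id), , drop = FALSE]

  chem_cols <- setdiff(names(expo), c("subject_id", "creatinine"))
  vals <- as.matrix(expo[chem_cols])
  if (!is.numeric(vals)) {
    bad <- chem_cols[!vapply(expo[chem_cols], is.numeric, logical(1))]
    stop_wqs("non-numeric concentration column(s): ",
             paste(bad, collapse = ", "))
  }
  keep <- complete.cases(vals) & complete.cases(covs) &
    complete.cases(outc)
  if (!all(keep)) {
    message("read_cohort: dropping ", sum(!keep),
            " subject(s) with incomplete data")
    vals <- vals[keep, , drop = FALSE]
    expo <- expo[keep, , drop = FALSE]
    covs <- covs[keep, , drop = FALSE]
    outc <- outc[keep, , drop = FALSE]
    common <- common[keep]
  }
  rownames(vals) <- common

  if (file.exists(pth("chemicals.tsv"))) {
    chems <- read.delim(pth("chemicals.tsv"), check.names = FALSE)
    chems <- chems[match(chem_cols, chems$chemical), , drop = FALSE]
  } else {
    chems <- data.frame(chemical = chem_cols, class = NA_character_,
                        matrix = "urine", log_mean = NA_real_,
                        log_sd = NA_real_, detect_rate = 1)
  }
  lod <- if ("lod" %in% names(chems)) setNames(chems$lod, chems$chemical)
         else setNames(rep(NA_real_, length(chem_cols)), chem_cols)

  if (file.exists(pth("nondetect.tsv"))) {
    nd <- read.delim(pth("nondetect.tsv"), check.names = FALSE)
    nd <- nd[match(common, nd$subject_id), chem_cols, drop = FALSE]
    nondetect <- as.matrix(nd) > 0
    nondetect[is.na(nondetect)] <- FALSE
    dimnames(nondetect) <- dimnames(vals)
  } else {
    nondetect <- matrix(FALSE, nrow(vals), ncol(vals),
                        dimnames = dimnames(vals))
  }
  creatinine <- if ("creatinine" %in% names(expo)) expo$creatinine else NULL

  truth <- NULL
  if (file.exists(pth("truth.yml"))) {
    tr <- yaml::read_yaml(pth("truth.yml"))
    truth <- true_model(beta0 = tr$beta0, beta1 = tr$beta1, beta2 = tr$beta2,
                        beta12 = tr$beta12, phi = unlist(tr$phi),
                        weights = unlist(tr$weights), sigma = tr$sigma)
  }
  panel <- new_exposure_panel(vals, nondetect, lod, creatinine, chems)
  sex <- covs$Female
  cov_df <- covs[setdiff(names(covs), c("subject_id", "Female"))]
  outcome_col <- setdiff(names(outc), "subject_id")[1L]
  new_wqs_cohort(panel, cov_df, sex, outc[[outcome_col]], truth)
}
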