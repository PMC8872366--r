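#' Substitute nondetect concentrations at LOD/sqrt(2)
#'
#' Replaces every flagged nondetect value by its chemical's limit of
#' detection divided by sqrt(2), the conventional constant-substitution rule.
#' If a chemical has nondetects but no recorded LOD, the minimum detected
#' concentration is used as the LOD proxy.
#'
#' @param panel An `exposure_panel`.
#' @return The panel with nondetect entries substituted.
#' @export
impute_nondetects <- function(panel) {
  stopifnot(inherits(panel, "exposure_panel"))
  if (!any(panel$nondetect)) return(panel)
  lod <- panel$lod
  for (j in seq_len(ncol(panel$values))) {
    nd <- panel$nondetect[, j]
    if (!any(nd)) next
    l <- lod[j]
    if (is.null(l) || is.na(l) || l <= 0) l <- min(panel$values[!nd, j])
    panel$values[nd, j] <- l / sqrt(2)
  }
  panel
}

#' Adjust urinary concentrations for urine dilution by creatinine
#'
#' Divides each urinary analyte concentration by the subject's creatinine
#' (adjusted level = analyte / creatinine).  Serum and plasma analytes are
#' left unchanged.
#'
#' @param values Numeric subject-by-analyte matrix.
#' @param creatinine Per-subject creatinine (mmol/L), strictly positive.
#' @param urinary Logical vector flagging which columns are urinary
#'   (default: all).
#' @return Matrix with urinary columns divided row-wise by creatinine.
#' @export
#' @examples
#' creatinine_adjust(matrix(1, 3, 2), c(1, 2, 4))
creatinine_adjust <- function(values, creatinine, urinary = NULL) {
  values <- as.matrix(values)
  urinary <- urinary %||% rep(TRUE, ncol(values))
  stopifnot(length(urinary) == ncol(values))
  if (!any(urinary)) return(values)
  bad <- which(is.na(creatinine) | creatinine <= 0)
  if (length(bad)) {
    ids <- rownames(values)[bad] %||% bad
    stop_wqs("urinary analytes present but creatinine is missing or ",
             "non-positive for subject(s): ",
             paste(utils::head(ids, 10), collapse = ", "))
  }
  if (length(creatinine) != nrow(values)) {
    stop_wqs("`creatinine` must have one value per subject")
  }
  values[, urinary] <- values[, urinary, drop = FALSE] / creatinine
  values
}

#' Sum analyte columns into a single component
#'
#' Molar mode divides each analyte by its molar mass (g/mol) before summing,
#' giving a molar-sum component (used for DEHP and DINP metabolite panels);
#' plain mode sums concentrations directly (used for DDT plus its metabolite
#' and for PCB congeners).
#'
#' @param values Matrix with >= 2 analyte columns.
#' @param molar_masses Named or positional masses (g/mol), required in molar
#'   mode.
#' @param mode `"molar"` or `"plain"`.
#' @return Numeric vector, one summed value per subject.
#' @export
#' @examples
#' molar_sum(cbind(a = c(10, 2), b = c(20, 4)), molar_masses = c(10, 10))
#' molar_sum(cbind(a = 1:2, b = 3:4, c = 5:6), mode = "plain")
molar_sum <- function(values, molar_masses = NULL, mode = c("molar", "plain")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (ncol(values) < 2L) {
    stop_wqs("molar_sum needs at least 2 analyte columns; got ", ncol(values))
  }
  if (mode == "plain") return(rowSums(values))
  if (is.null(molar_masses) || length(molar_masses) != ncol(values) ||
      anyNA(molar_masses)) {
    missing <- if (is.null(molar_masses)) colnames(values) %||% seq_len(ncol(values))
               else (colnames(values) %||% seq_len(ncol(values)))[is.na(molar_masses)]
    stop_wqs("molar mode requires a mass for every analyte; missing: ",
             paste(missing, collapse = ", "))
  }
  if (any(molar_masses <= 0)) stop_wqs("molar masses must be positive")
  rowSums(sweep(values, 2L, molar_masses, "/"))
}

#' Drop chemicals detected in too few samples
#'
#' Removes chemicals whose detection fraction falls below `min_rate`
#' (default 75%), except those explicitly kept (summed variables are
#' conventionally exempt).  Dropped names are reported via `message()` and
#' attached as attribute `"dropped"`.
#'
#' @param panel An `exposure_panel`.
#' @param min_rate Minimum detection fraction in `(0, 1]`.
#' @param keep Chemical names retained regardless of detection.
#' @return The filtered `exposure_panel`.
#' @export
detection_filter <- function(panel, min_rate = 0.75, keep = character()) {
  stopifnot(inherits(panel, "exposure_panel"))
  if (min_rate <= 0 || min_rate > 1) stop_wqs("`min_rate` must lie in (0, 1]")
  detected <- 1 - colMeans(panel$nondetect)
  drop <- detected < min_rate & !(colnames(panel$values) %in% keep)
  if (all(drop)) {
    stop_wqs("detection filter at min_rate = ", min_rate,
             " would drop every chemical (empty mixture)")
  }
  if (any(drop)) {
    message("detection_filter: dropping ", sum(drop), " chemical(s): ",
            paste(colnames(panel$values)[drop], collapse = ", "))
    panel$values <- panel$values[, !drop, drop = FALSE]
    panel$nondetect <- panel$nondetect[, !drop, drop = FALSE]
    panel$lod <- panel$lod[!drop]
    panel$chemicals <- panel$chemicals[!drop, , drop = FALSE]
  }
  attr(panel, "dropped") <- names(detected)[drop]
  panel
}

#' Score concentrations into empirical quantile bins
#'
#' Per chemical, the K-1 interior empirical quantiles (type 7) are used as
#' breakpoints and each subject receives the integer bin index 0..K-1 of its
#' concentration (ties at a breakpoint go to the upper bin).  Breakpoints are
#' retained so new data can be scored on the same scale.  Duplicate
#' breakpoints caused by heavy ties are collapsed with a warning; scores then
#' skip some bin values but stay in 0..K-1.
#'
#' @param x An `exposure_panel` or numeric matrix (subjects x chemicals).
#' @param K Number of quantile bins (>= 2; default 10, deciles).
#' @param breakpoints Optional previously computed breakpoint list, used to
#'   re-score new data on frozen cuts.
#' @return A `quantile_matrix`: list with integer `scores`, `K`,
#'   `breakpoints` and (when available) the `chemicals` table.
#' @export
#' @examples
#' qm <- quantile_score(matrix(1:20, ncol = 1), K = 10)
#' qm$scores[, 1]
quantile_score <- function(x, K = 10, breakpoints = NULL) {
  chems <- NULL
  if (inherits(x, "exposure_panel")) {
    chems <- x$chemicals
    x <- x$values
  }
  x <- as.matrix(x)
  if (K < 2) stop_wqs("`K` must be >= 2")
  if (is.null(breakpoints) && nrow(x) < K) {
    stop_wqs("need at least K = ", K, " subjects to estimate quantile cuts")
  }
  cols <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  if (is.null(breakpoints)) {
    breakpoints <- lapply(seq_len(ncol(x)), function(j) {
      bp <- quantile(x[, j], probs = seq_len(K - 1) / K, names = FALSE, type = 7)
      ubp <- unique(bp)
      if (length(ubp) < length(bp)) {
        warning("heavy ties in ", cols[j], ": collapsed ",
                length(bp) - length(ubp), " duplicate breakpoint(s)",
                call. = FALSE)
      }
      ubp
    })
    names(breakpoints) <- cols
  } else {
    if (length(breakpoints) != ncol(x)) {
      stop_wqs("breakpoint list length does not match chemical count")
    }
  }
  scores <- vapply(seq_len(ncol(x)), function(j) {
    findInterval(x[, j], breakpoints[[j]])
  }, integer(nrow(x)))
  dimnames(scores) <- list(rownames(x), cols)
  new_quantile_matrix(scores, K, breakpoints, chems)
}

new_quantile_matrix <- function(scores, K, breakpoints, chemicals = NULL) {
  storage.mode(scores) <- "integer"
  if (any(scores < 0L) || any(scores > K - 1L)) {
    stop_wqs("quantile scores out of range 0..K-1")
  }
  structure(
    list(scores = scores, K = as.integer(K), breakpoints = breakpoints,
         chemicals = chemicals),
    class = "quantile_matrix"
  )
}

#' @export
print.quantile_matrix <- function(x, ...) {
  cat("<quantile_matrix> ", nrow(x$scores), " subjects x ", ncol(x$scores),
      " chemicals, K = ", x$K, "\n", sep = "")
  invisible(x)
}

# Accept either a quantile_matrix or a bare score matrix.
quantile_scores <- function(q) {
  if (inherits(q, "quantile_matrix")) q$scores else as.matrix(q)
}

#' Preprocess an exposure panel into decile scores
#'
#' Applies the standard chain: nondetect substitution at LOD/sqrt(2),
#' creatinine adjustment of urinary analytes, the minimum-detection filter,
#' then quantile scoring.  Breakpoints come from the full sample and are
#' frozen in the result for any later re-scoring.
#'
#' @param panel An `exposure_panel`.
#' @param K Quantile bins (default 10).
#' @param min_detect Minimum detection fraction; `0` disables the filter.
#' @param keep Chemicals exempt from the detection filter.
#' @param adjust_creatinine Divide urinary analytes by creatinine?  Skipped
#'   automatically when the panel carries no creatinine.
#' @return A `quantile_matrix` carrying the (possibly filtered) chemicals
#'   table.
#' @export
preprocess_panel <- function(panel, K = 10, min_detect = 0.75,
                             keep = character(), adjust_creatinine = TRUE) {
  stopifnot(inherits(panel, "exposure_panel"))
  panel <- impute_nondetects(panel)
  if (min_detect > 0) panel <- detection_filter(panel, min_detect, keep)
  if (adjust_creatinine && !is.null(panel$creatinine) &&
      "matrix" %in% names(panel$chemicals)) {
    urinary <- panel$chemicals$matrix == "urine"
    panel$values <- creatinine_adjust(panel$values, panel$creatinine, urinary)
  }
  quantile_score(panel, K = K)
}
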