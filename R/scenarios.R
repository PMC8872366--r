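#' Exposure-reduction target: one SD below the index mean
#'
#' The policy target used throughout the scenario analysis: the sample mean
#' of the index minus its sample SD.
#'
#' @param index Per-subject index vector with at least 2 distinct values.
#' @return `mean(index) - sd(index)`.
#' @export
#' @examples
#' x <- c(1.74, 2.24, 2.74)  # mean 2.24
#' target_value(x)
target_value <- function(index) {
  if (length(unique(index)) < 2L) {
    stop_wqs("index has fewer than 2 distinct values")
  }
  s <- sd(index)
  if (s == 0) stop_wqs("index has zero variance")
  mean(index) - s
}

#' Decompose the index into chemical-class contributions
#'
#' Splits each subject's index exactly into the additive contributions of
#' the five chemical classes, `sum_{j in class} w[s(i), j] * q[i, j]`, plus
#' the per-subject fractions (contributions over the total index).  The
#' persistent group is PFAS plus persistent chlorinated compounds; the
#' non-persistent group is everything else.
#'
#' @param q `quantile_matrix` (carrying its chemicals table) or score matrix.
#' @param weights Length-`2c` stratified weight vector.
#' @param sex Binary vector (1 = girl).
#' @param classes Chemical-to-class map: named character vector, or NULL to
#'   take it from `q`'s chemicals table.
#' @return A `class_decomposition`: list with `contributions` (subjects x
#'   classes), `fractions`, `index`, `classes` and `persistent_fraction`
#'   (per-subject share due to persistent classes).
#' @export
class_contributions <- function(q, weights, sex, classes = NULL) {
  S <- quantile_scores(q)
  assert_binary_sex(sex)
  if (is.null(classes) && inherits(q, "quantile_matrix") &&
      !is.null(q$chemicals)) {
    classes <- setNames(q$chemicals$class, q$chemicals$chemical)
  }
  if (is.null(classes)) stop_wqs("no chemical-to-class map available")
  chems <- colnames(S) %||% names(classes)
  unmapped <- setdiff(chems, names(classes))
  if (length(unmapped)) {
    stop_wqs("chemical(s) without a class: ", paste(unmapped, collapse = ", "))
  }
  cl <- classes[chems]
  c <- ncol(S)
  if (length(weights) != 2L * c) {
    stop_wqs("`weights` must have length ", 2L * c)
  }
  wb <- weights[seq_len(c)]
  wg <- weights[c + seq_len(c)]
  # per-subject, per-chemical contribution using the subject's stratum block
  per_chem <- S * (sex %o% wg) + S * ((1 - sex) %o% wb)
  levels <- intersect(chemical_classes(), unique(cl))
  contributions <- vapply(levels, function(k) {
    rowSums(per_chem[, cl == k, drop = FALSE])
  }, numeric(nrow(S)))
  index <- rowSums(contributions)
  fractions <- contributions / ifelse(index > 0, index, NA_real_)
  pers <- intersect(levels, persistent_classes())
  persistent_fraction <- rowSums(fractions[, pers, drop = FALSE])
  structure(
    list(contributions = contributions, fractions = fractions, index = index,
         classes = cl, class_levels = levels,
         persistent_fraction = persistent_fraction),
    class = "class_decomposition"
  )
}

#' @export
print.class_decomposition <- function(x, ...) {
  cat("<class_decomposition> ", nrow(x$contributions), " subjects, classes: ",
      paste(x$class_levels, collapse = ", "), "\n", sep = "")
  cat("  mean persistent fraction:",
      signif(mean(x$persistent_fraction, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Apply a per-class retention scenario to the index
#'
#' Scales each class contribution by its retention multiplier
#' (`1` untouched, `0` eliminated, `0.30` = retain 30%) and re-sums:
#' `adjusted_i = sum_class retain[class] * contribution_i[class]`.
#' Contributions are scaled directly (quantile designations and weights stay
#' fixed); re-deriving decile scores from reduced concentrations would change
#' the population quantiles and is deliberately not done.
#'
#' @param decomp A [class_contributions()] result.
#' @param retain Named per-class multipliers in `[0, 1]`; unnamed classes
#'   default to 1.
#' @return Adjusted per-subject index vector.
#' @export
apply_scenario <- function(decomp, retain) {
  stopifnot(inherits(decomp, "class_decomposition"))
  if (any(retain < 0 | retain > 1)) {
    stop_wqs("retention multipliers must lie in [0, 1]")
  }
  bad <- setdiff(names(retain), decomp$class_levels)
  if (length(bad)) stop_wqs("unknown class(es): ", paste(bad, collapse = ", "))
  r <- setNames(rep(1, length(decomp$class_levels)), decomp$class_levels)
  r[names(retain)] <- retain
  drop(decomp$contributions %*% r)
}

#' Fraction of subjects strictly below the target
#'
#' @param adjusted Adjusted (or original) index vector.
#' @param target Target value.
#' @return Share of subjects with index strictly below `target`.
#' @export
#' @examples
#' fraction_below_target(c(1, 2, 3), 2)
fraction_below_target <- function(adjusted, target) {
  if (!length(adjusted)) stop_wqs("empty index vector")
  mean(adjusted < target)
}

#' Evaluate the standard battery of exposure-reduction scenarios
#'
#' Runs the named scenarios -- retain 30% of the non-persistent classes
#' (a 70% cut), eliminate the plasticizers, eliminate plasticizers plus other
#' short-lived compounds, eliminate plasticizers plus phenols -- together
#' with any user-supplied retention specs, and reports the fraction of
#' subjects whose adjusted index falls strictly below the target, plus
#' fixed-width histogram data spanning the pooled original/adjusted range.
#'
#' @param decomp A [class_contributions()] result.
#' @param target Target value; defaults to [target_value()] of the
#'   decomposition's index.
#' @param extra Optional named list of additional retention specs (each a
#'   named per-class multiplier vector).
#' @param bins Number of histogram bins (default 30).
#' @return A `scenario_battery`: list with `summary` (scenario,
#'   fraction_below), `adjusted` (matrix of adjusted indices), `histograms`
#'   (shared `breaks`, per-scenario `counts`) and `target`.
#' @export
scenario_battery <- function(decomp, target = NULL, extra = NULL, bins = 30) {
  stopifnot(inherits(decomp, "class_decomposition"))
  target <- target %||% target_value(decomp$index)
  nonpers <- setdiff(decomp$class_levels, persistent_classes())
  specs <- list(
    baseline = setNames(rep(1, 0), character(0)),
    cut70_nonpersistent = setNames(rep(0.30, length(nonpers)), nonpers),
    eliminate_plasticizers = c(plasticizer = 0),
    eliminate_plasticizers_shortlived = c(plasticizer = 0, short_lived = 0),
    eliminate_plasticizers_phenols = c(plasticizer = 0, phenol = 0)
  )
  specs <- c(specs, extra %||% list())
  adjusted <- vapply(specs, function(sp) apply_scenario(decomp, sp),
                     numeric(length(decomp$index)))
  frac <- apply(adjusted, 2L, fraction_below_target, target = target)
  rng <- range(adjusted, decomp$index)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- apply(adjusted, 2L, function(a) {
    tabulate(findInterval(a, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = bins)
  })
  structure(
    list(summary = data.frame(scenario = names(specs), fraction_below = frac,
                              row.names = NULL, stringsAsFactors = FALSE),
         specs = specs, adjusted = adjusted,
         histograms = list(breaks = breaks, counts = counts),
         target = target),
    class = "scenario_battery"
  )
}

#' @export
print.scenario_battery <- function(x, ...) {
  cat("<scenario_battery> target =", signif(x$target, 4), "\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
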