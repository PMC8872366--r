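#' Default chemical panel: 26 endocrine-disrupting chemicals in five classes
#'
#' Returns the specification of the default exposure panel: four phenols, nine
#' plasticizer metabolites, three other short-lived compounds, six PFAS and
#' four persistent chlorinated compounds (the summed variables DDT+DDE and the
#' PCB congener sum appear as single components).  Urinary analytes are
#' measured in urine and subject to creatinine adjustment; PFAS in serum and
#' chlorinated compounds in plasma are not.
#'
#' The lognormal location/scale and detection-rate columns parameterize the
#' synthetic cohort generator; only the ranks of the concentrations matter
#' downstream, so the absolute scales are conventional (roughly ng/mL-sized
#' urinary metabolites and serum PFAS).  Detection rates default to near 100%,
#' as is typical for these biomarkers in pregnancy cohorts.
#'
#' @param detect_rate Optional named numeric vector overriding per-chemical
#'   detection rates (fractions in `[0, 1]`).
#' @return A data.frame with columns `chemical`, `class` (one of `phenol`,
#'   `plasticizer`, `short_lived`, `pfas`, `persistent_chlorinated`), `matrix`
#'   (`urine`, `serum` or `plasma`), `log_mean`, `log_sd`, `detect_rate`.
#' @export
#' @examples
#' chems <- chemical_table()
#' table(chems$class)
chemical_table <- function(detect_rate = NULL) {
  df <- data.frame(
    chemical = c("triclosan", "BPA", "BPF", "BPS",
                 "MEP", "MBP", "MBzP", "DEHP", "DINP", "MHiDP", "MCiNP",
                 "MOiNCH", "DPHP",
                 "TCP", "PBA", "2OHPH",
                 "PFOA", "PFOS", "PFNA", "PFDA", "PFUnDA", "PFHxS",
                 "HCB", "Nonachlor", "DDT_DDE", "PCBsum"),
    class = rep(c("phenol", "plasticizer", "short_lived", "pfas",
                  "persistent_chlorinated"), c(4L, 9L, 3L, 6L, 4L)),
    matrix = rep(c("urine", "serum", "plasma"), c(16L, 6L, 4L)),
    log_mean = c(0.0, 0.5, -0.7, -1.2,
                 4.0, 3.3, 2.6, 4.3, 3.9, 1.1, 0.7, 0.4, 0.5,
                 0.8, 0.1, -0.5,
                 0.5, 1.6, 0.2, -1.0, -1.3, 0.4,
                 2.6, 1.4, 3.1, 4.3),
    log_sd = c(rep(1.0, 4L), rep(0.9, 9L), rep(0.8, 3L),
               rep(0.45, 6L), rep(0.5, 4L)),
    detect_rate = c(0.92, 1, 0.88, 0.90, rep(1, 9L), 0.95, 1, 1,
                    rep(1, 6L), rep(1, 4L)),
    stringsAsFactors = FALSE
  )
  if (!is.null(detect_rate)) {
    bad <- setdiff(names(detect_rate), df$chemical)
    if (length(bad)) stop_wqs("unknown chemicals in `detect_rate`: ",
                              paste(bad, collapse = ", "))
    if (any(detect_rate < 0 | detect_rate > 1)) {
      stop_wqs("`detect_rate` values must lie in [0, 1]")
    }
    df$detect_rate[match(names(detect_rate), df$chemical)] <- detect_rate
  }
  df
}

#' Chemical classes counted as environmentally persistent
#'
#' PFAS and persistent chlorinated compounds have long environmental and
#' biological half-lives and are treated as irreducible in the
#' exposure-reduction scenarios; phenols, plasticizer metabolites and other
#' short-lived compounds form the non-persistent group.
#'
#' @return Character vector of persistent class labels.
#' @export
persistent_classes <- function() c("pfas", "persistent_chlorinated")

chemical_classes <- function() {
  c("phenol", "plasticizer", "short_lived", "pfas", "persistent_chlorinated")
}

validate_chemical_table <- function(chems) {
  need <- c("chemical", "class", "log_mean", "log_sd", "detect_rate")
  if (!is.data.frame(chems) || !all(need %in% names(chems))) {
    stop_wqs("`chems` must be a data.frame with columns ",
             paste(need, collapse = ", "))
  }
  if (anyDuplicated(chems$chemical)) stop_wqs("duplicated chemical names")
  if (!all(chems$class %in% chemical_classes())) {
    stop_wqs("unknown chemical class: ",
             paste(setdiff(chems$class, chemical_classes()), collapse = ", "))
  }
  if (any(chems$detect_rate < 0 | chems$detect_rate > 1)) {
    stop_wqs("detect_rate must lie in [0, 1]")
  }
  invisible(chems)
}
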