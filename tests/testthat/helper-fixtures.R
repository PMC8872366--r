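# Shared fixtures: small panels and cohorts built in code.

# exposure panel straight from a value matrix (all detected, no creatinine)
make_panel <- function(values, classes = NULL, nondetect = NULL,
                       creatinine = NULL, matrix_type = "urine") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("C", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  }
  p <- ncol(values)
  chems <- data.frame(
    chemical = colnames(values),
    class = classes %||% rep("plasticizer", p),
    matrix = rep(matrix_type, length.out = p),
    log_mean = 0, log_sd = 1,
    detect_rate = 1,
    stringsAsFactors = FALSE
  )
  nondetect <- nondetect %||% matrix(FALSE, nrow(values), p,
                                     dimnames = dimnames(values))
  lod <- setNames(rep(NA_real_, p), colnames(values))
  wqsmix:::new_exposure_panel(values, nondetect, lod, creatinine, chems)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small synthetic score matrix + sexes for fit-level tests
make_toy_scores <- function(n, c, seed = 1, K = 10) {
  withr::with_seed(seed, {
    S <- matrix(sample(0:(K - 1), n * c, replace = TRUE), n, c)
    colnames(S) <- paste0("C", seq_len(c))
    sex <- rbinom(n, 1, 0.5)
    list(S = S, sex = sex)
  })
}

# vector rescaled to an exact sample mean and SD
with_mean_sd <- function(x, m, s) {
  drop(scale(x)) * s + m
}
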