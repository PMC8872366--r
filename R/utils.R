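# internal helpers shared across modules

# Set the RNG state locally for the calling function; a NULL seed leaves the
# ambient RNG untouched so callers can manage randomness themselves.
local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}

# Deterministically derive `n` child seeds from a master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  withr::with_seed(as.integer(seed), as.list(sample.int(.Machine$integer.max - 1L, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_wqs <- function(...) stop(..., call. = FALSE)

assert_binary_sex <- function(sex) {
  if (!is.numeric(sex) || anyNA(sex) || !all(sex %in% c(0, 1))) {
    bad <- unique(sex[!(sex %in% c(0, 1))])
    stop_wqs("`sex` must be coded 0 (boy) / 1 (girl); found: ",
             paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(sex)
}

softmax <- function(theta) {
  e <- exp(theta - max(theta))
  e / sum(e)
}
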