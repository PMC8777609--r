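#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible per-unit substream seed from a master seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(master, index, stream = 0L) {
  ((as.numeric(master) * 48271 + as.numeric(index) * 16807 +
      as.numeric(stream) * 69621) %% 2147483629) + 1
}

# Interquartile range reported as a single width Q3 - Q1 (type-7 quartiles),
# matching the "median (IQR)" presentation of clinical tables.
iqr_width <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

stop_hypoburden <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hypoburden_error")))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_hypoburden(sprintf("`%s` must be a single finite number", name),
                    "hypoburden_config_error")
  }
  if (positive && x <= 0) {
    stop_hypoburden(sprintf("`%s` must be > 0", name),
                    "hypoburden_config_error")
  }
  invisible(x)
}
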