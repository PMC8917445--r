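#' Derive a deterministic sub-seed from a root seed
#'
#' All generators in swimkin draw from per-entity substreams so that a subset
#' of the data (one fish, one trial) can be regenerated without re-running the
#' whole simulation. The substream seed is a deterministic hash of the root
#' seed and a string key, kept below 2^31 - 1 so it is always a valid R
#' integer seed.
#'
#' @param seed integer root seed.
#' @param ... components of the substream key (coerced to character and
#'   concatenated with "/").
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

#' Gamma-type speed pulse, unit peak
#'
#' Smooth single-peaked pulse used for simulated fast starts and feeding
#' bouts: `p(t) = (t/rise)^k * exp(k * (1 - t/rise))` with `k = rise/decay`,
#' which peaks at exactly 1 when `t = rise` and decays with time constant
#' `decay`. Zero for `t <= 0`.
#'
#' @param t time since pulse onset, seconds (vector).
#' @param rise time to peak, seconds.
#' @param decay decay time constant, seconds.
#' @return pulse values in `[0, 1]`.
#' @keywords internal
speed_pulse <- function(t, rise, decay) {
  stopifnot(rise > 0, decay > 0)
  k <- rise / decay
  p <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos] / rise
  p[pos] <- tp^k * exp(k * (1 - tp))
  p
}

# centred moving average with shrinking windows at the edges
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  half <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be %s", name, if (strict) "positive" else "non-negative"),
         call. = FALSE)
  }
  invisible(x)
}

assert_dist <- function(x, name) {
  if (!is.list(x) || !all(c("mean", "sd") %in% names(x)) ||
      !is.numeric(x$mean) || !is.numeric(x$sd) || x$sd < 0) {
    stop(sprintf("`%s` must be list(mean=, sd=) with sd >= 0", name), call. = FALSE)
  }
  invisible(x)
}
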