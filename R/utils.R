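`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for reported percentages so that
#' e.g. 36.75 prints as 36.8 rather than going to even.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Small deterministic polynomial hash of a character scalar, used to
# fingerprint bundled fixtures and run manifests. Not cryptographic.
text_checksum <- function(txt) {
  stopifnot(is.character(txt), length(txt) == 1L)
  v <- utf8ToInt(txt)
  m <- 2147483629
  h <- 0
  # process in chunks to keep the interpreted loop short
  mult <- 31
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    for (x in chunk) h <- (h * mult + x) %% m
  }
  sprintf("%010d", h)
}

stop_input <- function(...) stop(..., call. = FALSE)

check_times <- function(times, require_zero_start = FALSE) {
  if (length(times) < 1L || anyNA(times)) stop_input("times must be non-missing")
  if (any(times < 0)) stop_input("times must be non-negative")
  if (is.unsorted(times)) stop_input("times must be ascending")
  if (require_zero_start && times[1] != 0)
    stop_input("time grid must start at 0 (treatment initiation)")
  invisible(times)
}

# Multivariate normal draws via Cholesky; falls back to an eigenvalue
# floor when the covariance is numerically indefinite.
rmvnorm_chol <- function(n, mean, sigma) {
  k <- length(mean)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ei <- eigen(sigma, symmetric = TRUE)
    lam <- pmax(ei$values, max(ei$values, 0) * 1e-10 + 1e-12)
    ch <- t(ei$vectors %*% (t(ei$vectors) * sqrt(lam)))
  }
  z <- matrix(stats::rnorm(n * k), n, k)
  sweep(z %*% ch, 2, mean, "+")
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# deterministic child seeds below 2^31
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483647)
}
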