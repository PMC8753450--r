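# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Otsu's between-class variance threshold on a continuous vector, via a
# fixed-width histogram. Returns the threshold value (bin midpoint).
otsu_threshold <- function(x, n_bins = 128L) {
  x <- x[is.finite(x)]
  stopifnot(length(x) > 1L)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu_t <- sum(p * mids)
  mu0 <- cumsum(p * mids)
  # between-class variance for threshold after bin k
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  mids[which.max(bcv)]
}

stop_clonodyn <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "clonodyn_error")))
}

assert_that <- function(ok, fmt, ..., class = "clonodyn_domain_error") {
  if (!isTRUE(ok)) stop_clonodyn(fmt, ..., class = class)
  invisible(TRUE)
}
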