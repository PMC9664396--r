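# Internal helpers shared across modules.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Separable Gaussian smoothing of a 3-D array; sigma given per axis in voxels.
# Truncated at 3 sigma with edge renormalisation so a constant field is
# preserved exactly.
gaussian_smooth3d <- function(a, sigma_vox) {
  stopifnot(length(dim(a)) == 3L)
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    a <- convolve_axis(a, k, ax)
  }
  a
}

# 1-D convolution of a 3-D array along one axis, kernel length 2r+1,
# renormalised at the edges (equivalent to extending with local mass only).
convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = 1:3, `2` = c(2L, 1L, 3L), `3` = c(3L, 2L, 1L))
  b <- aperm(a, perm)
  db <- dim(b)
  n <- db[1L]
  m <- matrix(b, nrow = n)
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, nrow = n, ncol = ncol(m))
  wsum <- numeric(n)
  for (j in seq_along(k)) {
    off <- j - r - 1L             # source row = target row + off
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
    wsum[ok] <- wsum[ok] + k[j]
  }
  out <- out / wsum
  dim(out) <- db
  aperm(out, order(perm))
}
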