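#' @include AllClasses.R
NULL

## Orthonormal Daubechies 4-tap (D4) analysis filters, in closed form.
.d4h <- local({
  s3 <- sqrt(3)
  c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
})
.d4g <- {
  h <- .d4h
  c(h[4], -h[3], h[2], -h[1])
}

## One periodized analysis step: x (even length) -> list(a, d).
.dwtStep <- function(x) {
  n <- length(x)
  k <- seq(0, n - 2, by = 2)
  idx <- outer(k, 0:3, "+") %% n + 1
  xm <- matrix(x[idx], ncol = 4)
  list(a = drop(xm %*% .d4h), d = drop(xm %*% .d4g))
}

## Inverse of .dwtStep.
.idwtStep <- function(a, d) {
  n <- 2L * length(a)
  out <- numeric(n)
  k <- seq(0, n - 2, by = 2)
  for (m in 0:3) {
    pos <- (k + m) %% n + 1
    out[pos] <- out[pos] + .d4h[m + 1] * a + .d4g[m + 1] * d
  }
  out
}

## Multi-level periodized DWT: returns list(a, d = list(levels coarse->fine)).
.dwt <- function(x, levels) {
  d <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- .dwtStep(a)
    a <- s$a
    d[[levels - l + 1]] <- s$d   # store coarse first, finest last
  }
  list(a = a, d = d)
}

.idwt <- function(w) {
  a <- w$a
  for (l in seq_along(w$d)) a <- .idwtStep(a, w$d[[l]])
  a
}

## Soft-threshold denoising of one trace: universal threshold
## sigma_hat * sqrt(2 log n), sigma_hat = MAD(finest details) / 0.6745.
.waveletDenoiseTrace <- function(x, levels) {
  n <- length(x)
  pad <- (-n) %% 2^levels
  if (pad > 0) {
    reflect <- rev(x)[seq_len(min(pad, n))]
    x <- c(x, reflect, rep(0, max(0, pad - n)))
  }
  w <- .dwt(x, levels)
  fine <- w$d[[length(w$d)]]
  sigma <- stats::median(abs(fine)) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  w$d <- lapply(w$d, function(d) sign(d) * pmax(abs(d) - thr, 0))
  .idwt(w)[seq_len(n)]
}
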