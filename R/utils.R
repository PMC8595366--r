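# Internal numeric/RNG helpers shared across the pipeline.

#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a reproducible per-item seed from a master seed
#'
#' Cohort simulations give every cell its own RNG stream so that cells are
#' reproducible individually and under reordering.  The derivation is a
#' deterministic integer hash of (master seed, index), kept below 2^31.
#'
#' @param master integer master seed.
#' @param index positive integer item index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(master) %% m)
  # two rounds of a multiplicative congruential mix; exact in doubles (< 2^53)
  s <- (s * 48271 + as.numeric(index) * 7919 + 12345) %% m
  s <- (s * 69621 + 1013904223 %% m) %% m
  as.integer(s %% (m - 1) + 1)
}

## Polynomial rolling hash of an R object (via serialization), hex string.
## Used for config fingerprints in run manifests; not cryptographic.
config_hash <- function(x) {
  bytes <- as.numeric(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## Column-wise/row-wise helpers ------------------------------------------------

## 1D Gaussian kernel, truncated at 4 sigma.
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

#' Gaussian-weighted local-linear smoothing of a matrix
#'
#' Smooths a (small) matrix with a Gaussian kernel of the given standard
#' deviation by fitting, at every pixel, a weighted plane to its neighborhood.
#' Unlike plain truncated-kernel convolution this reproduces affine fields
#' exactly, including at the matrix boundary, so a smooth illumination
#' gradient is not attenuated near the field edge.
#'
#' @param m numeric matrix (NAs allowed; they are ignored in the fits).
#' @param sigma kernel standard deviation, in units of matrix cells.
#' @return smoothed matrix, same shape.
#' @export
gaussian_local_linear_smooth <- function(m, sigma) {
  stopifnot(is.matrix(m), sigma > 0)
  nr <- nrow(m); nc <- ncol(m)
  r <- max(1L, ceiling(4 * sigma))
  out <- matrix(NA_real_, nr, nc)
  rows <- row(m); cols <- col(m)
  ok <- is.finite(m)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      i0 <- max(1L, i - r); i1 <- min(nr, i + r)
      j0 <- max(1L, j - r); j1 <- min(nc, j + r)
      sel <- ok[i0:i1, j0:j1, drop = FALSE]
      if (!any(sel)) next
      rr <- rows[i0:i1, j0:j1, drop = FALSE][sel] - i
      cc <- cols[i0:i1, j0:j1, drop = FALSE][sel] - j
      vv <- m[i0:i1, j0:j1, drop = FALSE][sel]
      w <- exp(-(rr^2 + cc^2) / (2 * sigma^2))
      if (length(vv) < 3L) {
        out[i, j] <- sum(w * vv) / sum(w)
      } else {
        fit <- stats::lm.wfit(cbind(1, rr, cc), vv, w)
        out[i, j] <- fit$coefficients[1]
      }
    }
  }
  out
}

## Separable natural-cubic-spline upsampling of a coarse grid to a full field.
## `centers_r`, `centers_c`: full-resolution coordinates of the coarse cells.
spline_upsample <- function(m, centers_r, centers_c, nr, nc) {
  stopifnot(nrow(m) == length(centers_r), ncol(m) == length(centers_c))
  # interpolate along rows for each coarse column
  tmp <- matrix(NA_real_, nr, ncol(m))
  for (j in seq_len(ncol(m))) {
    tmp[, j] <- if (nrow(m) >= 2) {
      stats::spline(centers_r, m[, j], xout = seq_len(nr), method = "natural")$y
    } else rep(m[1, j], nr)
  }
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    out[i, ] <- if (ncol(m) >= 2) {
      stats::spline(centers_c, tmp[i, ], xout = seq_len(nc), method = "natural")$y
    } else rep(tmp[i, 1], nc)
  }
  out
}

## Jaccard index of two logical masks.
#' Jaccard index between two binary masks
#' @param a,b logical matrices of identical shape.
#' @return intersection-over-union in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- a & !is.na(a); b <- b & !is.na(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

## linear interpolation of the crossing time of y(t) = thr between samples
## i and i+1; assumes y[i] and y[i+1] bracket thr.
interp_crossing <- function(t0, t1, y0, y1, thr) {
  if (y1 == y0) return((t0 + t1) / 2)
  t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
}
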