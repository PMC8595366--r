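# Shared fixtures, built in code at test time.

# quiet config with defaults
cfg0 <- polarflip_config()

# a rectangular mask inside a field
rect_mask <- function(nr, nc, r0, r1, c0, c1) {
  m <- matrix(FALSE, nr, nc)
  m[r0:r1, c0:c1] <- TRUE
  m
}

# rasterized disc mask
disc_mask <- function(nr, nc, cr, cc, radius) {
  outer(seq_len(nr), seq_len(nc),
        function(r, c) (r - cr)^2 + (c - cc)^2 <= radius^2)
}

# brute-force oracle for the front/rear 800-px regions: Euclidean distance
# to the given point, ties broken lexicographically by (row, col)
oracle_region <- function(mask, pt, size) {
  px <- which(mask, arr.ind = TRUE)
  d <- sqrt((px[, 1] - pt[1])^2 + (px[, 2] - pt[2])^2)
  key <- order(d, px[, 1], px[, 2])
  sel <- key[seq_len(min(size, nrow(px)))]
  m <- matrix(FALSE, nrow(mask), ncol(mask))
  m[px[sel, , drop = FALSE]] <- TRUE
  m
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of assignments
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  rks <- rank(pooled)
  wobs <- sum(rks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  ws <- apply(idx, 2, function(ii) sum(rks[ii]) - n1 * (n1 + 1) / 2)
  pl <- mean(ws <= wobs); pu <- mean(ws >= wobs)
  min(1, 2 * min(pl, pu))
}

# exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration
oracle_fisher_2x2_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pobs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# exact two-sided Clopper-Pearson bounds by root-finding on the binomial
# tail (enumeration-based; independent of qbeta)
oracle_clopper_pearson <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  lower <- if (k == 0) 0 else
    stats::uniroot(function(p) sum(stats::dbinom(k:n, n, p)) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (k == n) 1 else
    stats::uniroot(function(p) sum(stats::dbinom(0:k, n, p)) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# build a noise-free FRET pair from a mask and an activity image
fret_pair <- function(mask, activity, amplitude = 500) {
  donor <- matrix(0, nrow(mask), ncol(mask))
  donor[mask] <- amplitude
  acceptor <- donor * activity
  acceptor[!mask] <- 0
  list(donor = donor, acceptor = acceptor)
}
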