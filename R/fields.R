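# Internal smooth-field utilities used by the synthetic-cohort generator.
#
# Operator disagreement on lesion boundaries is spatially coherent (whole
# stretches of boundary are pushed in or out), so perturbations are driven by
# Gaussian-smoothed noise fields rather than i.i.d. voxel flips.

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-h, h), sd = sigma)
  k / sum(k)
}

# Convolve along the first dimension of a (d1 x m) matrix using a banded
# kernel matrix with edge renormalisation.
kernel_matrix <- function(d, k) {
  h <- (length(k) - 1L) / 2L
  K <- matrix(0, d, d)
  for (i in seq_len(d)) {
    j <- max(1L, i - h):min(d, i + h)
    w <- k[j - i + h + 1L]
    K[i, j] <- w / sum(w)
  }
  K
}

# Separable 3-D Gaussian smoothing; sigma in voxels per axis.
gaussian_smooth_3d <- function(arr, sigma) {
  d <- dim(arr)
  x <- arr
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    K <- kernel_matrix(d[ax], gaussian_kernel_1d(sigma[ax]))
    perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    if (ax > 1) x <- aperm(x, perm)
    dp <- dim(x)
    x <- array(K %*% matrix(x, nrow = dp[1]), dim = dp)
    if (ax > 1) x <- aperm(x, order(perm))
  }
  x
}

# Standardised (zero-mean, unit-sd) smooth Gaussian random field.
noise_field <- function(dim, sigma) {
  x <- gaussian_smooth_3d(array(stats::rnorm(prod(dim)), dim = dim), sigma)
  x <- x - mean(x)
  x / stats::sd(as.vector(x))
}

# Approximate k-th largest value of a numeric vector via a strided
# subsample (exact for stride 1). Used to pick the field level that gives a
# mask of a prescribed voxel count; the ~0.2% count error at stride 8 is
# far below the deliberate volume jitter between observed masks.
kth_largest <- function(x, k, stride = 8L) {
  n <- length(x)
  if (stride > 1L && n > 4000L) {
    x <- x[seq(1L, n, by = stride)]
    k <- max(1L, as.integer(round(k / stride)))
    n <- length(x)
  }
  k <- min(max(k, 1L), n)
  sort(x, partial = n - k + 1L)[n - k + 1L]
}

# Random rotation matrix (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
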