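stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Centered 2D Fourier transforms
#'
#' Unitary, centered discrete Fourier transforms: DC is at the array center
#' (row `ny/2 + 1`, column `nx/2 + 1` for even dimensions) in both image and
#' k-space, and Parseval's identity holds exactly (`sum(|x|^2) == sum(|X|^2)`).
#'
#' @param x complex or real matrix.
#' @return complex matrix of the same dimension.
#' @keywords internal
#' @name centered-fft
NULL

fftshift2 <- function(x) {
  d <- dim(x)
  i <- c(seq.int(floor(d[1] / 2) + 1L, d[1]), seq_len(floor(d[1] / 2)))
  j <- c(seq.int(floor(d[2] / 2) + 1L, d[2]), seq_len(floor(d[2] / 2)))
  x[i, j, drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  i <- c(seq.int(ceiling(d[1] / 2) + 1L, d[1]), seq_len(ceiling(d[1] / 2)))
  j <- c(seq.int(ceiling(d[2] / 2) + 1L, d[2]), seq_len(ceiling(d[2] / 2)))
  x[i, j, drop = FALSE]
}

#' @rdname centered-fft
ft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname centered-fft
ift2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

# Circular roll of matrix rows by n (positive = content moves down).
roll_rows <- function(x, n) {
  ny <- nrow(x)
  n <- ((n %% ny) + ny) %% ny
  if (n == 0) return(x)
  x[c(seq.int(ny - n + 1L, ny), seq_len(ny - n)), , drop = FALSE]
}

#' Backward bilinear warp
#'
#' Samples `img` at (row + dy, col + dx); coordinates falling outside the
#' grid contribute zero.  `dy`/`dx` may be scalars (pure translation) or
#' matrices matching `img` (dense displacement field).  Complex images are
#' warped component-wise.
#'
#' @param img real or complex matrix.
#' @param dy,dx displacement in pixels along rows / columns.
#' @return warped matrix of the same dimension and mode.
#' @export
warp_bilinear <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  ys <- matrix(seq_len(ny), ny, nx) + dy
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx) + dx
  bilinear_sample(img, ys, xs)
}

# Sample img at arbitrary fractional coordinate matrices (ys, xs); the
# output takes the dimension of the coordinate grids.  Zero outside.
bilinear_sample <- function(img, ys, xs) {
  if (is.complex(img)) {
    return(bilinear_sample(Re(img), ys, xs) +
           1i * bilinear_sample(Im(img), ys, xs))
  }
  ny <- nrow(img); nx <- ncol(img)
  y0 <- floor(ys); x0 <- floor(xs)
  wy <- ys - y0;  wx <- xs - x0

  at <- function(yi, xi) {
    ok <- yi >= 1 & yi <= ny & xi >= 1 & xi <= nx
    v <- numeric(length(yi))
    idx <- (pmin(pmax(xi, 1L), nx) - 1L) * ny + pmin(pmax(yi, 1L), ny)
    v[ok] <- img[idx[ok]]
    v
  }
  v <- (1 - wy) * (1 - wx) * at(y0,     x0) +
       (1 - wy) * wx       * at(y0,     x0 + 1) +
       wy       * (1 - wx) * at(y0 + 1, x0) +
       wy       * wx       * at(y0 + 1, x0 + 1)
  matrix(v, nrow(ys), ncol(ys))
}

# Nearest-neighbour backward warp (for label maps / masks).
warp_nearest <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  ys <- round(matrix(seq_len(ny), ny, nx) + dy)
  xs <- round(matrix(rep(seq_len(nx), each = ny), ny, nx) + dx)
  ok <- ys >= 1 & ys <= ny & xs >= 1 & xs <= nx
  v <- array(vector(mode = typeof(img), 1L), length(ys))
  idx <- (pmin(pmax(xs, 1L), nx) - 1L) * ny + pmin(pmax(ys, 1L), ny)
  v[ok] <- img[idx[ok]]
  matrix(v, ny, nx)
}

# Separable Gaussian smoothing with replicated edges.  sigma in pixels;
# sigma = 0 returns the input unchanged.
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  m <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(seq(-m, m), sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(x, along_rows) {
    if (!along_rows) return(t(smooth_axis(t(x), TRUE)))
    n <- nrow(x)
    xp <- x[c(rep(1L, m), seq_len(n), rep(n, m)), , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k)) {
      out <- out + k[j] * xp[seq.int(j, j + n - 1L), , drop = FALSE]
    }
    out
  }
  smooth_axis(smooth_axis(img, TRUE), FALSE)
}

# Normalised root-mean-square error of `a` against reference `b`,
# optionally restricted to a logical mask.
nrmse <- function(a, b, mask = NULL) {
  if (!is.null(mask)) {
    a <- a[mask]; b <- b[mask]
  }
  sqrt(mean(Mod(a - b)^2)) / sqrt(mean(Mod(b)^2))
}

# Derive a reproducible 32-bit sub-seed from a base seed and a stream id.
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2147483647)
}
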