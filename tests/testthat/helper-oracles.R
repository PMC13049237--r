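# Shared fixtures (memoized: built once per test run) and independent
# oracles used to freeze expected values.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(build)
  .fx[[name]]
}

# Small two-slice phantom with a scar sector in slice 1.
fx_phantom <- function() {
  fixture("phantom2", make_phantom(list(n_slices = 2L,
                                        scar = list(slices = 1L)), seed = 3L))
}

fx_protocol_sms <- function(R = 5L) {
  protocol_params(n_slices = 2L, multiband = 2L, inplane_accel = R,
                  phase_oversampling = 2, matrix = c(64L, 64L))
}

fx_coils <- function(p = fx_protocol_sms()) {
  fixture(paste0("coils_", p$ny_ext),
          make_coil_maps(8L, c(p$ny_ext, p$matrix[2]), seed = 5L))
}

fx_slices <- function(ph = fx_phantom(), p = fx_protocol_sms()) {
  fixture("slices2", list(render_single_shot(ph, 1, p$ti),
                          render_single_shot(ph, 2, p$ti)))
}

# Unit ("body coil") sensitivity array.
unit_coils <- function(ny, nx, nc = 1L) {
  structure(array(1 + 0i, c(ny, nx, nc)), class = "coil_maps")
}

# Harmonic coil maps whose spectra live inside the GRAPPA kernel: the
# world in which GRAPPA interpolation is mathematically exact.
harmonic_coils <- function(ny, nx, R = 5L) {
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  hs <- c(0, 1, 2, 3, 4, 0, 1, 2)
  kxs <- c(0, 0, 0, 0, 0, 1, 1, 1)
  amp <- c(1.1, 0.9 - 0.3i, 0.8 + 0.4i, 1 - 0.2i, 0.7 + 0.7i,
           0.9i, 1.2 - 0.1i, 0.6 + 0.5i)
  coils <- array(0i, c(ny, nx, 8L))
  for (c in 1:8) {
    coils[, , c] <- amp[c] * exp(2i * pi * (hs[c] * yy / ny + kxs[c] * xx / nx))
  }
  structure(coils, class = "coil_maps")
}

# Brute-force oracle for the 8 -> 6 center-of-mass selection rule, written
# directly from the stated procedure and independent of select_images().
oracle_select <- function(coms, n_keep = 6L) {
  n <- nrow(coms)
  dist_to <- function(p) sqrt((coms[, 1] - p[1])^2 + (coms[, 2] - p[2])^2)
  m0 <- c(mean(coms[, 1]), mean(coms[, 2]))
  d0 <- dist_to(m0)
  four <- order(d0, seq_len(n))[1:4]
  m1 <- c(mean(coms[four, 1]), mean(coms[four, 2]))
  d1 <- dist_to(m1)
  sort(order(d1, seq_len(n))[seq_len(n_keep)])
}

# Direct-DFT oracle for the centered unitary 2D transform (O(N^2); tiny
# grids only).  DC at (floor(ny/2)+1, floor(nx/2)+1).
oracle_dft2 <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  cy <- floor(ny / 2); cx <- floor(nx / 2)
  out <- matrix(0i, ny, nx)
  for (ky in 0:(ny - 1)) {
    for (kx in 0:(nx - 1)) {
      s <- 0i
      for (y in 0:(ny - 1)) {
        for (x in 0:(nx - 1)) {
          s <- s + img[y + 1, x + 1] *
            exp(-2i * pi * ((ky - cy) * (y - cy) / ny + (kx - cx) * (x - cx) / nx))
        }
      }
      out[ky + 1, kx + 1] <- s
    }
  }
  out / sqrt(ny * nx)
}

# Time-domain Bloch oracle: iterate the per-TR recursion (RF about x with
# linearly cycled phase, precession + relaxation over TR) for n_tr
# repetitions, then read out at TE.  Independent of the fixed-point solver.
oracle_bssfp_iterate <- function(params, off_res, n_tr = 2000L) {
  T1 <- params$T1; T2 <- params$T2; TR <- params$TR; TE <- params$TE
  a <- params$flip * pi / 180
  M0 <- 1
  E1 <- exp(-TR / T1); E2 <- exp(-TR / T2)
  rx <- function(v, phi) {
    # rotation by `a` about the axis at azimuth phi in the xy-plane
    rz <- function(u, t) c(cos(t) * u[1] - sin(t) * u[2],
                           sin(t) * u[1] + cos(t) * u[2], u[3])
    u <- rz(v, -phi)
    u <- c(u[1], cos(a) * u[2] + sin(a) * u[3], -sin(a) * u[2] + cos(a) * u[3])
    rz(u, phi)
  }
  vapply(off_res, function(f) {
    th <- 2 * pi * f * TR / 1000
    M <- c(0, 0, M0)
    phi <- 0
    for (n in seq_len(n_tr)) {
      Mp <- rx(M, phi)
      # free precession + relaxation over TR
      M <- c(E2 * (cos(th) * Mp[1] - sin(th) * Mp[2]),
             E2 * (sin(th) * Mp[1] + cos(th) * Mp[2]),
             E1 * Mp[3] + M0 * (1 - E1))
      phi <- phi + params$phase_increment
    }
    Mp <- rx(M, phi)                  # readout TR's excitation
    the <- 2 * pi * f * TE / 1000
    mxy_lab <- complex(real = Mp[1], imaginary = Mp[2]) * exp(1i * the) *
      exp(-TE / T2)
    # demodulate at the RF/receiver phase of this TR; the extra
    # increment term moves the TE precession into the effective frame
    mxy_lab * exp(-1i * phi) * exp(-1i * params$phase_increment * TE / TR)
  }, complex(1))
}

# Gaussian-blurred vertical step edge: value 1 for x < x0, 0 beyond,
# blurred with SD sigma_b px.  Closed form via the normal CDF.
erf_edge_image <- function(ny, nx, x0, sigma_b) {
  xx <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  stats::pnorm((x0 - xx) / sigma_b)
}
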