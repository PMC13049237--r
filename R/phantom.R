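#' Default post-contrast tissue parameter table
#'
#' Post-contrast (gadolinium-shortened) T1 values at 1.5 T: scar retains
#' contrast agent and has the shortest T1, blood clears faster than scar,
#' and healthy myocardium has the longest T1 of the three.  `M0` is the
#' equilibrium magnetization in arbitrary signal units; the background has
#' `M0 = 0` by definition.  All values are configurable, the defaults are
#' synthetic choices that produce the bright-scar / nulled-myocardium
#' contrast of late gadolinium enhancement imaging.
#'
#' @return data.frame with columns `name`, `label` (integer code used in
#'   phantom label maps), `T1` (ms) and `M0`.
#' @export
tissue_defaults <- function() {
  data.frame(
    name  = c("background", "blood", "myocardium", "scar"),
    label = c(0L, 1L, 2L, 3L),
    T1    = c(1000, 350, 450, 280),
    M0    = c(0, 1.0, 0.85, 1.0),
    stringsAsFactors = FALSE
  )
}

#' Inversion time that nulls a tissue
#'
#' For the ideal single-inversion signal `M0 (1 - 2 exp(-TI/T1))` the null
#' point is `TI = T1 log(2)`.
#'
#' @param T1 longitudinal relaxation time (ms).
#' @return inversion time in ms.
#' @export
ti_null <- function(T1) T1 * log(2)

#' Inversion-recovery signal
#'
#' Ideal single-inversion closed form `s = M0 (1 - 2 exp(-TI/T1))`:
#' signed longitudinal magnetization at inversion time `TI`, ignoring
#' incomplete recovery between inversions and readout-driven saturation.
#'
#' @param tissue a row of a tissue table (or any list) with fields `T1`
#'   (ms, > 0) and `M0` (>= 0).
#' @param TI inversion time in ms (>= 0); may be a vector.
#' @return signed signal, same length as `TI`.
#' @export
ir_signal <- function(tissue, TI) {
  T1 <- tissue$T1; M0 <- tissue$M0
  if (!is.finite(T1) || T1 <= 0) stopf("invalid parameter: T1 must be > 0 (got %s)", format(T1))
  if (any(!is.finite(TI)) || any(TI < 0)) stopf("invalid parameter: TI must be >= 0")
  M0 * (1 - 2 * exp(-TI / T1))
}

default_phantom_config <- function() {
  list(
    n_slices        = 4L,
    matrix          = c(64L, 64L),          # (ny, nx)
    pixel_spacing   = c(1.48, 1.98),        # (mm along y, mm along x)
    slice_thickness = 8,                    # mm, no gap
    r_blood         = 0.22,                 # fraction of min(ny, nx)
    r_myo           = 0.34,
    taper           = 0.2,                  # apical radius reduction across stack
    center_jitter   = 1.5,                  # px, seeded per-phantom offset
    scar = list(
      slices      = integer(0),             # 1-based slice indices carrying scar
      theta       = c(-60, 10),             # angular sector, degrees in (-180, 180]
      transmural  = 1.0                     # fraction of wall depth from endocardium
    ),
    tissue_table = tissue_defaults()
  )
}

#' Generate a synthetic short-axis cardiac phantom stack
#'
#' Builds a seeded stack of 2D label maps: a circular left-ventricular
#' blood pool surrounded by an annular myocardium, with an optional scar
#' sector (transmural or subendocardial) in configured slices.  Radii taper
#' linearly toward the last (apical) slice.  Ground-truth scar volume is
#' recorded exactly as `sum(scar pixels) * pixel area * slice thickness`.
#'
#' @param config list of phantom parameters; see [default_phantom_config()]
#'   for fields and defaults.  Partial lists are merged over the defaults.
#' @param seed integer seed; the phantom is a pure function of
#'   `(config, seed)`.
#' @return object of class `phantom_stack`: label maps
#'   (`ny x nx x n_slices` integer array, codes per the tissue table),
#'   per-slice scar masks, geometry (centers, radii), tissue table, and
#'   `scar_volume_ml`.
#' @export
make_phantom <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(default_phantom_config(), config)
  ny <- as.integer(cfg$matrix[1]); nx <- as.integer(cfg$matrix[2])
  if (ny < 64L || nx < 64L) stopf("invalid geometry: matrix must be at least 64 x 64")
  ns <- as.integer(cfg$n_slices)
  if (ns < 1L) stopf("invalid geometry: n_slices must be >= 1")

  withr::with_seed(seed, {
    base <- min(ny, nx)
    cy0 <- (ny + 1) / 2 + stats::runif(1, -cfg$center_jitter, cfg$center_jitter)
    cx0 <- (nx + 1) / 2 + stats::runif(1, -cfg$center_jitter, cfg$center_jitter)
    rb0 <- cfg$r_blood * base * stats::runif(1, 0.97, 1.03)
    rm0 <- cfg$r_myo   * base * stats::runif(1, 0.97, 1.03)
    if (rm0 + cfg$center_jitter >= base / 2) {
      stopf("invalid geometry: myocardium radius %.1f px does not fit the %d x %d matrix",
            rm0, ny, nx)
    }

    labels <- array(0L, c(ny, nx, ns))
    scar_mask <- array(FALSE, c(ny, nx, ns))
    centers <- matrix(0, ns, 2)
    radii <- matrix(0, ns, 2, dimnames = list(NULL, c("blood", "myo")))
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(rep(seq_len(nx), each = ny), ny, nx)
    theta <- atan2(yy - cy0, xx - cx0) * 180 / pi  # degrees in (-180, 180]

    scar_sl <- as.integer(cfg$scar$slices)
    if (length(scar_sl) && (min(scar_sl) < 1L || max(scar_sl) > ns)) {
      stopf("invalid geometry: scar slice index out of range 1..%d", ns)
    }
    for (s in seq_len(ns)) {
      sc <- if (ns > 1) 1 - cfg$taper * (s - 1) / (ns - 1) else 1
      rb <- rb0 * sc; rm <- rm0 * sc
      r <- sqrt((yy - cy0)^2 + (xx - cx0)^2)
      lab <- matrix(0L, ny, nx)
      lab[r <= rm] <- 2L
      lab[r <= rb] <- 1L
      if (s %in% scar_sl) {
        depth <- rb + cfg$scar$transmural * (rm - rb)
        in_sector <- theta >= cfg$scar$theta[1] & theta <= cfg$scar$theta[2]
        sm <- lab == 2L & in_sector & r <= depth
        lab[sm] <- 3L
        scar_mask[, , s] <- sm
      }
      labels[, , s] <- lab
      centers[s, ] <- c(cy0, cx0)
      radii[s, ] <- c(rb, rm)
    }
  })

  px_area <- prod(cfg$pixel_spacing)
  vol_ml <- sum(scar_mask) * px_area * cfg$slice_thickness / 1000

  structure(list(
    n_slices = ns, matrix = c(ny, nx),
    pixel_spacing = cfg$pixel_spacing,
    slice_thickness = cfg$slice_thickness,
    labels = labels, scar_mask = scar_mask,
    tissue_table = cfg$tissue_table,
    centers = centers, radii = radii,
    scar_volume_ml = vol_ml,
    config = cfg, seed = seed
  ), class = "phantom_stack")
}

#' @export
print.phantom_stack <- function(x, ...) {
  cat(sprintf("phantom_stack: %d slice(s), %d x %d px (%.2f x %.2f mm), thickness %g mm\n",
              x$n_slices, x$matrix[1], x$matrix[2],
              x$pixel_spacing[1], x$pixel_spacing[2], x$slice_thickness))
  cat(sprintf("  scar volume (ground truth): %.4f mL in %d slice(s)\n",
              x$scar_volume_ml, sum(apply(x$scar_mask, 3, any))))
  invisible(x)
}

#' Generate smooth synthetic coil sensitivity maps
#'
#' `n_coils` complex-valued maps on an `ny x nx` grid: Gaussian amplitude
#' lobes centered on a ring around the FOV plus a small uniform body-coil
#' floor (keeps the root-sum-of-squares strictly positive everywhere), and
#' a slowly varying linear phase per coil.  Maps are bandlimited by
#' construction; the attribute `smoothness_bound` gives an upper bound on
#' the per-pixel finite difference implied by the construction parameters.
#'
#' @param n_coils number of coils (>= 1).
#' @param grid `c(ny, nx)` of the (possibly phase-oversampled) image grid.
#' @param seed integer seed.
#' @param sigma_frac Gaussian lobe width as a fraction of the grid size.
#' @param floor_amp uniform amplitude floor.
#' @return complex array `ny x nx x n_coils` of class `coil_maps`.
#' @export
make_coil_maps <- function(n_coils, grid, seed = 1L,
                           sigma_frac = 0.45, floor_amp = 0.1) {
  n_coils <- as.integer(n_coils)
  if (n_coils < 1L) stopf("invalid parameter: n_coils must be >= 1")
  ny <- as.integer(grid[1]); nx <- as.integer(grid[2])
  sigma <- sigma_frac * max(ny, nx)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(rep(seq_len(nx), each = ny), ny, nx)

  maps <- withr::with_seed(seed, {
    m <- array(0i, c(ny, nx, n_coils))
    ang0 <- stats::runif(1, 0, 2 * pi)
    # per-coil linear phase slopes, radians per pixel
    slopes <- matrix(stats::runif(2 * n_coils, -0.03, 0.03), n_coils, 2)
    phi0 <- stats::runif(n_coils, 0, 2 * pi)
    for (c in seq_len(n_coils)) {
      ang <- ang0 + 2 * pi * (c - 1) / n_coils
      cy <- (ny + 1) / 2 + 0.65 * ny / 2 * sin(ang)
      cx <- (nx + 1) / 2 + 0.65 * nx / 2 * cos(ang)
      amp <- floor_amp + exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sigma^2))
      ph <- slopes[c, 1] * yy + slopes[c, 2] * xx + phi0[c]
      m[, , c] <- amp * exp(1i * ph)
    }
    m
  })
  # |d map| <= |d amp| + max amp * |d phase| per unit pixel step
  bound <- exp(-0.5) / sigma + (1 + floor_amp) * (0.03 * 2)
  structure(maps, class = "coil_maps", smoothness_bound = bound)
}

# Root-sum-of-squares amplitude of a coil map array.
coil_rss <- function(maps) {
  sqrt(apply(Mod(maps)^2, c(1, 2), sum))
}

#' Seeded respiratory motion trace
#'
#' One [motion state][motion_warp()] per repetition: in-plane translation
#' plus a smooth low-frequency warp amplitude.  Regular repetitions draw
#' displacements uniformly in `[-amplitude, amplitude]` per axis;
#' designated outlier repetitions (deep breaths) are placed at magnitude
#' `>= outlier_scale * amplitude` in a random direction.
#'
#' @param n_reps number of repetitions (>= 1).
#' @param amplitude typical translation amplitude in pixels.
#' @param outlier_indices 1-based repetition indices forced to be outliers.
#' @param outlier_scale outlier magnitude as a multiple of `amplitude`.
#' @param deform_frac smooth-warp amplitude as a fraction of `amplitude`.
#' @param seed integer seed.
#' @return list of `n_reps` motion states, each
#'   `list(dx, dy, deform_amplitude)` in pixels.
#' @export
motion_trace <- function(n_reps, amplitude, outlier_indices = integer(0),
                         outlier_scale = 5, deform_frac = 0.2, seed = 1L) {
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stopf("invalid parameter: n_reps must be >= 1")
  outlier_indices <- as.integer(outlier_indices)
  if (length(outlier_indices) &&
      (min(outlier_indices) < 1L || max(outlier_indices) > n_reps)) {
    stopf("outlier index out of range 1..%d", n_reps)
  }
  withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      if (i %in% outlier_indices) {
        mag <- outlier_scale * amplitude * (1 + 0.2 * abs(stats::rnorm(1)))
        ang <- stats::runif(1, 0, 2 * pi)
        dx <- mag * cos(ang); dy <- mag * sin(ang)
      } else {
        dx <- stats::runif(1, -amplitude, amplitude)
        dy <- stats::runif(1, -amplitude, amplitude)
      }
      list(dx = dx, dy = dy,
           deform_amplitude = deform_frac * amplitude * stats::runif(1))
    })
  })
}

identity_motion <- function() list(dx = 0, dy = 0, deform_amplitude = 0)

# Displacement field of a motion state on an ny x nx grid: global
# translation plus one sinusoidal period of smooth deformation.
motion_field <- function(state, ny, nx) {
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  a <- state$deform_amplitude
  list(dy = state$dy + a * sin(2 * pi * xx / nx),
       dx = state$dx + a * sin(2 * pi * yy / ny))
}

#' Apply a motion state to an image
#'
#' Backward warp (linear interpolation, zero boundary) moving the image
#' content by `(dx, dy)` pixels plus the state's smooth sinusoidal
#' deformation.  `nearest = TRUE` uses nearest-neighbour interpolation
#' (label maps, masks).
#'
#' @param img matrix (real, complex, integer or logical).
#' @param state motion state from [motion_trace()].
#' @param nearest use nearest-neighbour interpolation.
#' @return warped matrix.
#' @export
motion_warp <- function(img, state, nearest = FALSE) {
  f <- motion_field(state, nrow(img), ncol(img))
  # content moves BY (dx, dy): backward sampling at -displacement
  if (nearest) warp_nearest(img, -f$dy, -f$dx) else warp_bilinear(img, -f$dy, -f$dx)
}

#' Render one single-shot image of a phantom slice
#'
#' Maps each label to its closed-form inversion-recovery signal at `TI`
#' (or to `M0` for the proton-density-like reference shot of the two-RR
#' PSIR scheme) and applies the repetition's motion state.
#'
#' @param phantom a [make_phantom()] stack.
#' @param slice_idx 1-based slice index.
#' @param TI inversion time (ms); ignored when `reference = TRUE`.
#' @param motion motion state; default identity.
#' @param reference render the no-inversion reference image (signal = M0).
#' @return complex `ny x nx` matrix (zero imaginary part before encoding).
#' @export
render_single_shot <- function(phantom, slice_idx, TI,
                               motion = identity_motion(), reference = FALSE) {
  if (slice_idx < 1 || slice_idx > phantom$n_slices) {
    stopf("slice_idx %d out of range 1..%d", slice_idx, phantom$n_slices)
  }
  tab <- phantom$tissue_table
  sig <- if (reference) {
    tab$M0
  } else {
    vapply(seq_len(nrow(tab)), function(i) ir_signal(tab[i, ], TI), numeric(1))
  }
  lut <- numeric(max(tab$label) + 1L)
  lut[tab$label + 1L] <- sig
  img <- matrix(lut[phantom$labels[, , slice_idx] + 1L],
                phantom$matrix[1], phantom$matrix[2])
  img <- motion_warp(img, motion)
  matrix(complex(real = img), nrow(img), ncol(img))
}
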