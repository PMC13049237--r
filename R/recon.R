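#' Merge interleaved repetitions into a fully sampled calibration k-space
#'
#' T-GRAPPA calibration: the `R` interleaved undersampling patterns shift
#' by one line per repetition, so merging the sampled lines of (at least)
#' `R` consecutive repetitions yields one fully sampled k-space.  Every
#' line is taken from the most recent repetition that sampled it.
#'
#' @param reps list of [encode_sms()] `kspace` objects with a common grid
#'   and acceleration.
#' @return `kspace` object with all lines filled and an all-TRUE mask.
#' @export
build_acs <- function(reps) {
  if (!length(reps)) stopf("no repetitions given")
  R <- reps[[1]]$R
  offsets <- vapply(reps, function(k) k$pe_shift_pattern, integer(1))
  missing <- setdiff(seq_len(R) - 1L, offsets)
  if (length(missing)) {
    stopf("incomplete interleave coverage: missing line offset(s) %s of 0..%d",
          paste(missing, collapse = ", "), R - 1L)
  }
  out <- reps[[1]]
  data <- array(0i, dim(out$data))
  for (k in reps) {
    rows <- which(k$mask)
    data[rows, , ] <- k$data[rows, , ]
  }
  out$data <- data
  out$mask <- rep(TRUE, length(out$mask))
  out$rep_index <- NA_integer_
  out$pe_shift_pattern <- NA_integer_
  out
}

#' Calibrate GRAPPA weights from fully sampled calibration data
#'
#' Standard k-space parallel-imaging calibration: for each gap position
#' `d = 1..R-1` between sampled lines, a linear kernel predicting the
#' missing line of every coil from a `n_ky x n_kx` neighbourhood of
#' sampled lines (all coils as sources) is fit by ridge-regularized least
#' squares over all interior calibration points,
#' `w = argmin ||S w - t||^2 + lambda ||w||^2`.
#'
#' @param acs fully sampled `kspace` object (or complex `ny x nx x nc`
#'   array) used for calibration.
#' @param R acceleration factor the weights will be applied at.
#' @param kernel `c(n_ky_source, n_kx_source)` source points per target;
#'   default 4 sampled lines x 5 readout columns.
#' @param lambda ridge regularization relative to `trace(S^H S)/n_src`.
#' @return object of class `grappa_weights` with one complex
#'   `n_src x n_coils` weight matrix per gap position, kernel geometry,
#'   and a `quality` flag (`"ok"` or `"high_residual"`).
#' @export
calibrate_grappa <- function(acs, R, kernel = c(4L, 5L), lambda = 1e-4) {
  data <- if (is.list(acs)) acs$data else acs
  d <- dim(data)
  ny <- d[1]; nx <- d[2]; nc <- d[3]
  R <- as.integer(R)
  dys <- (seq_len(kernel[1]) - (kernel[1] %/% 2L)) * R      # e.g. (-1,0,1,2)*R
  dxs <- seq_len(kernel[2]) - (kernel[2] %/% 2L + 1L)       # e.g. -2..2
  if (R == 1L) {
    return(structure(list(R = 1L, kernel = kernel, dys = dys, dxs = dxs,
                          weights = list(), lambda = lambda,
                          quality = "ok", resid = 0),
                     class = "grappa_weights"))
  }
  bs <- seq.int(max(1L, 1L - min(dys)), min(ny, ny - max(dys)) - (R - 1L))
  xs <- seq.int(1L - min(dxs), nx - max(dxs))
  if (length(bs) < 1L) {
    stopf("ACS region (%d lines) shorter than the kernel span (%d lines)",
          ny, diff(range(dys)) + R)
  }
  n_src <- length(dys) * length(dxs) * nc
  S <- matrix(0i, length(bs) * length(xs), n_src)
  col <- 0L
  for (c in seq_len(nc)) {
    for (dx in dxs) {
      for (dy in dys) {
        col <- col + 1L
        S[, col] <- as.vector(data[bs + dy, xs + dx, c])
      }
    }
  }
  SH <- Conj(t(S))
  A <- SH %*% S
  reg <- lambda * Re(sum(diag(A))) / n_src
  weights <- vector("list", R - 1L)
  resid <- 0
  for (gap in seq_len(R - 1L)) {
    Tm <- matrix(0i, length(bs) * length(xs), nc)
    for (c in seq_len(nc)) Tm[, c] <- as.vector(data[bs + gap, xs, c])
    w <- tryCatch(
      solve(A + reg * diag(n_src), SH %*% Tm),
      error = function(e) {
        if (lambda <= 0) {
          stopf("singular GRAPPA normal equations; use lambda > 0 (ridge)")
        }
        stop(e)
      })
    weights[[gap]] <- w
    resid <- max(resid, sqrt(sum(Mod(S %*% w - Tm)^2) / sum(Mod(Tm)^2)))
  }
  structure(list(R = R, kernel = kernel, dys = dys, dxs = dxs,
                 weights = weights, lambda = lambda,
                 quality = if (resid > 0.1) "high_residual" else "ok",
                 resid = resid),
            class = "grappa_weights")
}

#' Synthesize missing k-space lines with GRAPPA weights
#'
#' Missing phase-encode lines are predicted coil-by-coil from the sampled
#' neighbourhood using the calibrated kernel; sampled lines are left
#' untouched.  Sources falling outside the k-space grid contribute zero.
#'
#' @param k undersampled `kspace` object (interleave consistent with the
#'   `R` used at calibration).
#' @param w [calibrate_grappa()] weights.
#' @return `kspace` object with every line filled.
#' @export
apply_grappa <- function(k, w) {
  if (all(k$mask)) return(k)
  if (k$R != w$R) stopf("k-space R = %d but weights were calibrated for R = %d", k$R, w$R)
  d <- dim(k$data)
  ny <- d[1]; nx <- d[2]; nc <- d[3]
  R <- w$R
  py <- max(c(-min(w$dys), max(w$dys) + R, 0L))   # row padding
  px <- max(abs(w$dxs))
  padded <- array(0i, c(ny + 2L * py, nx + 2L * px, nc))
  padded[py + seq_len(ny), px + seq_len(nx), ] <- k$data
  full <- k$data
  sampled <- which(k$mask)
  # include one virtual base line below the first sample so that edge lines
  # are synthesized too (out-of-range sources read zero from the padding)
  bases <- c(min(sampled) - R, sampled)
  xs <- seq_len(nx)
  for (gap in seq_len(R - 1L)) {
    ts <- bases + gap
    keep <- ts >= 1L & ts <= ny & !k$mask[pmin(pmax(ts, 1L), ny)]
    ts <- ts[keep]
    if (!length(ts)) next
    bs <- ts - gap
    S <- matrix(0i, length(ts) * nx, nrow(w$weights[[gap]]))
    col <- 0L
    for (c in seq_len(nc)) {
      for (dx in w$dxs) {
        for (dy in w$dys) {
          col <- col + 1L
          S[, col] <- as.vector(padded[py + bs + dy, px + xs + dx, c])
        }
      }
    }
    synth <- S %*% w$weights[[gap]]
    for (c in seq_len(nc)) full[ts, , c] <- matrix(synth[, c], length(ts), nx)
  }
  k$data <- full
  k$mask <- rep(TRUE, ny)
  k
}

#' Inverse Fourier transform and coil combination
#'
#' Per-coil inverse centered FFT followed by a sensitivity-weighted
#' combine `sum(conj(C) I) / sum(|C|^2)`, which recovers the underlying
#' complex image exactly for noiseless data with known maps.  Where the
#' root-sum-of-squares sensitivity falls below `rss_floor` times its
#' maximum the phase is undefined and the root-sum-of-squares magnitude
#' (zero phase) is used instead.
#'
#' @param kfull fully sampled `kspace` object or complex array.
#' @param coils [make_coil_maps()] array on the same grid.
#' @param rss_floor relative sensitivity threshold for the RSS fallback.
#' @return complex image on the extended grid.
#' @export
coil_combine <- function(kfull, coils, rss_floor = 1e-3) {
  data <- if (is.list(kfull)) kfull$data else kfull
  d <- dim(data)
  if (!all(d[1:2] == dim(coils)[1:2]) || d[3] != dim(coils)[3]) {
    stopf("k-space grid %s does not match coil grid %s",
          paste(d, collapse = " x "), paste(dim(coils), collapse = " x "))
  }
  num <- matrix(0i, d[1], d[2])
  den <- matrix(0, d[1], d[2])
  rss2img <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) {
    ic <- ift2c(data[, , c])
    num <- num + Conj(coils[, , c]) * ic
    den <- den + Mod(coils[, , c])^2
    rss2img <- rss2img + Mod(ic)^2
  }
  rss <- sqrt(den)
  low <- rss < rss_floor * max(rss)
  out <- num / pmax(den, .Machine$double.eps)
  out[low] <- sqrt(rss2img[low]) + 0i
  out
}

#' Separate the two slices from the composite extended-FOV image
#'
#' Inverts the CAIPIRINHA placement: slice 1 is the central band of the
#' prescribed FOV; slice 2 is the central band after undoing the half
#' extended-FOV circular shift.  For single-band acquisitions with phase
#' oversampling the composite is simply cropped to the prescribed FOV.
#'
#' @param composite complex image on the `ny_ext x nx` grid.
#' @param params [protocol_params()].
#' @return list with elements `slice_a` and (for multiband 2) `slice_b`,
#'   each `ny x nx`.
#' @export
partition_fov <- function(composite, params) {
  ny <- params$matrix[1]
  ny_ext <- nrow(composite)
  if (ny_ext != params$ny_ext) {
    stopf("composite has %d lines, protocol expects %d", ny_ext, params$ny_ext)
  }
  if (params$multiband == 2L) {
    if (ny_ext != 2L * ny) {
      stopf("multiband 2 partitioning requires ny_ext = 2 ny (got %d, ny = %d)",
            ny_ext, ny)
    }
    list(slice_a = crop_phase_fov(composite, ny),
         slice_b = crop_phase_fov(roll_rows(composite, -ny_ext %/% 2L), ny))
  } else {
    list(slice_a = crop_phase_fov(composite, ny))
  }
}

#' Phase-sensitive inversion-recovery reconstruction
#'
#' Restores the sign of the inverted magnetization using the phase of the
#' no-inversion reference image: `values = |IR| sign(cos(arg IR - arg ref))`.
#' Where the reference magnitude is below `bg_floor` times its maximum the
#' phase reference is meaningless (air) and the sign is forced positive.
#'
#' @param ir_img complex inversion-recovery image.
#' @param ref_img complex reference (proton-density-like) image on the
#'   same grid.
#' @param bg_floor background threshold relative to `max(|ref|)`.
#' @return real signed matrix of class `psir_image`.
#' @export
psir <- function(ir_img, ref_img, bg_floor = 1e-3) {
  if (!all(dim(ir_img) == dim(ref_img))) {
    stopf("IR grid %s does not match reference grid %s",
          paste(dim(ir_img), collapse = " x "),
          paste(dim(ref_img), collapse = " x "))
  }
  s <- ifelse(cos(Arg(ir_img) - Arg(ref_img)) >= 0, 1, -1)
  s[Mod(ref_img) < bg_floor * max(Mod(ref_img))] <- 1
  structure(Mod(ir_img) * s, class = c("psir_image", "matrix", "array"))
}
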