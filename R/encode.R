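#' Acquisition protocol parameters
#'
#' Container for the bSSFP single-shot protocol.  Defaults follow the
#' clinical prescription this package emulates: TR/TE 2.71/1.15 ms, flip
#' 45 degrees, 8 repetitions of each slice, two RR intervals per image
#' (IR shot + reference shot for phase-sensitive reconstruction), and for
#' the SMS arm an in-plane acceleration of 5 with phase oversampling 2 and
#' multiband factor 2 (nominal in-plane acceleration 2.5).
#'
#' @param n_slices slices in the short-axis stack.
#' @param multiband simultaneous-slice factor, 1 or 2.
#' @param n_reps single-shot repetitions per slice.
#' @param rr_per_image RR intervals consumed per image (2 for PSIR).
#' @param inplane_accel prescribed in-plane acceleration factor R.
#' @param phase_oversampling phase-FOV oversampling factor (>= 1).
#' @param matrix `c(ny, nx)` prescribed image matrix.
#' @param fov `c(mm, mm)` field of view.
#' @param tr,te,flip,ti sequence timing (ms) and flip angle (degrees).
#' @param slice_thickness mm.
#' @return list of class `protocol_params`; `ny_ext` is the extended
#'   (oversampled) phase matrix, rounded to an even number of lines.
#' @export
protocol_params <- function(n_slices = 16L, multiband = 2L, n_reps = 8L,
                            rr_per_image = 2L, inplane_accel = 5L,
                            phase_oversampling = 2, matrix = c(64L, 64L),
                            fov = c(380, 380), tr = 2.71, te = 1.15,
                            flip = 45, ti = 450 * log(2),
                            slice_thickness = 8) {
  if (!multiband %in% c(1L, 2L)) stopf("multiband must be 1 or 2")
  if (n_slices %% multiband != 0L) {
    stopf("n_slices (%d) not divisible by multiband (%d)", n_slices, multiband)
  }
  if (inplane_accel < 1 || phase_oversampling < 1) {
    stopf("inplane_accel and phase_oversampling must be >= 1")
  }
  ny <- as.integer(matrix[1])
  ny_ext <- 2L * as.integer(round(ny * phase_oversampling / 2))
  structure(list(
    n_slices = as.integer(n_slices), multiband = as.integer(multiband),
    n_reps = as.integer(n_reps), rr_per_image = as.integer(rr_per_image),
    inplane_accel = inplane_accel, phase_oversampling = phase_oversampling,
    matrix = c(ny, as.integer(matrix[2])), ny_ext = ny_ext,
    fov = fov, tr = tr, te = te, flip = flip, ti = ti,
    slice_thickness = slice_thickness
  ), class = "protocol_params")
}

#' Pair slices for simultaneous excitation
#'
#' For multiband 2 the stack is split in half and slice `i` is excited
#' together with slice `i + n_slices/2`, maximizing the gap (and hence the
#' coil-sensitivity difference) between simultaneously excited slices:
#' a 16-slice stack gives pairs 1-9, 2-10, ..., 8-16.
#'
#' @param n_slices total slices; must be divisible by `multiband`.
#' @param multiband 1 (singletons) or 2 (pairs).
#' @return list of integer vectors (1-based slice indices).
#' @export
slice_pairing <- function(n_slices, multiband) {
  n_slices <- as.integer(n_slices); multiband <- as.integer(multiband)
  if (n_slices %% multiband != 0L) {
    stopf("n_slices (%d) not divisible by multiband (%d)", n_slices, multiband)
  }
  if (multiband == 1L) return(lapply(seq_len(n_slices), identity))
  half <- n_slices %/% 2L
  lapply(seq_len(half), function(i) c(i, i + half))
}

#' Interleaved phase-encode sampling mask
#'
#' T-GRAPPA-style undersampling: repetition `r` (0-based) samples the
#' phase-encode lines whose 0-based index is congruent to `r mod R`, so the
#' union over `R` consecutive repetitions covers every line.
#'
#' @param ny_ext number of phase-encode lines on the extended grid.
#' @param R acceleration factor (>= 1).
#' @param rep_index 0-based repetition index.
#' @return logical vector of length `ny_ext` (TRUE = sampled).
#' @export
sampling_mask <- function(ny_ext, R, rep_index) {
  R <- as.integer(R)
  if (R < 1L) stopf("R must be >= 1")
  (seq_len(ny_ext) - 1L) %% R == rep_index %% R
}

# Place an ny x nx image centrally into an ny_ext x nx grid.
pad_phase_fov <- function(img, ny_ext) {
  ny <- nrow(img)
  if (ny_ext < ny) stopf("extended FOV (%d) smaller than image (%d)", ny_ext, ny)
  out <- matrix(0i, ny_ext, ncol(img))
  off <- (ny_ext - ny) %/% 2L
  out[(off + 1L):(off + ny), ] <- img
  out
}

crop_phase_fov <- function(img, ny) {
  ny_ext <- nrow(img)
  off <- (ny_ext - ny) %/% 2L
  img[(off + 1L):(off + ny), , drop = FALSE]
}

#' Encode one SMS (or single-band) single shot into multi-coil k-space
#'
#' Implements the CAIPIRINHA controlled-aliasing forward model as an
#' in-plane problem on the doubled phase FOV: both slice images are placed
#' into the extended grid, the second slice is circularly shifted by half
#' the extended FOV (the image-domain equivalent of its relative
#' per-line RF phase modulation `exp(i pi m)`, i.e. the difference between
#' the +pi/2 and -pi/2 per-TR phase increments of the two slices), the
#' composite is weighted by each coil sensitivity and Fourier transformed
#' (centered, unitary), and only the phase-encode lines of this
#' repetition's interleave are retained.
#'
#' @param img1 slice-1 complex image on the prescribed `ny x nx` grid.
#' @param img2 slice-2 image, or `NULL` for single-band encoding.
#' @param coils [make_coil_maps()] array on the extended `ny_ext x nx` grid.
#' @param params [protocol_params()].
#' @param rep_index 0-based repetition index (selects the interleave).
#' @return object of class `kspace`: complex array `ny_ext x nx x n_coils`
#'   (zero on unsampled lines), sampling `mask`, `rep_index`,
#'   `pe_shift_pattern`, acceleration `R` and CAIPIRINHA metadata.
#' @export
encode_sms <- function(img1, img2 = NULL, coils, params, rep_index = 0L) {
  ny <- params$matrix[1]; nx <- params$matrix[2]
  ny_ext <- params$ny_ext
  if (!is.null(img1) && !all(dim(img1) == c(ny, nx))) {
    stopf("img1 grid %s does not match prescribed matrix %d x %d",
          paste(dim(img1), collapse = " x "), ny, nx)
  }
  if (!is.null(img2) && !all(dim(img2) == c(ny, nx))) {
    stopf("img2 grid %s does not match prescribed matrix %d x %d",
          paste(dim(img2), collapse = " x "), ny, nx)
  }
  if (!all(dim(coils)[1:2] == c(ny_ext, nx))) {
    stopf("coil grid %s does not match extended grid %d x %d",
          paste(dim(coils)[1:2], collapse = " x "), ny_ext, nx)
  }
  if (is.null(img1)) img1 <- matrix(0i, ny, nx)
  comp <- pad_phase_fov(img1, ny_ext)
  if (!is.null(img2)) {
    if (params$multiband != 2L) stopf("img2 given but multiband is 1")
    comp <- comp + roll_rows(pad_phase_fov(img2, ny_ext), ny_ext %/% 2L)
  }
  n_coils <- dim(coils)[3]
  R <- as.integer(params$inplane_accel)
  mask <- sampling_mask(ny_ext, R, rep_index)
  data <- array(0i, c(ny_ext, nx, n_coils))
  for (c in seq_len(n_coils)) {
    kc <- ft2c(coils[, , c] * comp)
    kc[!mask, ] <- 0i
    data[, , c] <- kc
  }
  structure(list(
    data = data, mask = mask, rep_index = as.integer(rep_index),
    pe_shift_pattern = as.integer(rep_index) %% R, R = R,
    caipi = list(phase_increment_slice1 = pi / 2,
                 phase_increment_slice2 = -pi / 2),
    params = params
  ), class = "kspace")
}

#' Add complex Gaussian noise to sampled k-space lines
#'
#' Independent Gaussian noise of standard deviation `sigma` per real and
#' imaginary component is added to every coil on the sampled lines only;
#' unsampled lines stay exactly zero.  With the package's unitary Fourier
#' convention, white k-space noise of SD `sigma` maps to white image-domain
#' noise of the same SD (per component) at full sampling.
#'
#' @param k a [encode_sms()] `kspace` object.
#' @param sigma noise SD per component (>= 0).
#' @param seed integer seed.
#' @return `kspace` object with noise added.
#' @export
add_noise <- function(k, sigma, seed = 1L) {
  if (sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(k)
  d <- dim(k$data)
  rows <- which(k$mask)
  withr::with_seed(seed, {
    n <- length(rows) * d[2] * d[3]
    noise <- complex(real = stats::rnorm(n, sd = sigma),
                     imaginary = stats::rnorm(n, sd = sigma))
    k$data[rows, , ] <- k$data[rows, , ] + array(noise, c(length(rows), d[2], d[3]))
  })
  k
}
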