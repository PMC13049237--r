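#' Intensity-weighted center of mass
#'
#' Sub-pixel centroid of a non-negative image, in 1-based pixel
#' coordinates `(y, x)`.  Used as a one-point summary of the respiratory
#' motion state of each single-shot image.
#'
#' @param img real matrix with non-negative values and positive total mass.
#' @return numeric `c(y, x)`.
#' @export
center_of_mass <- function(img) {
  if (any(img < 0)) stopf("center_of_mass expects a non-negative (magnitude) image")
  tot <- sum(img)
  if (!is.finite(tot) || tot <= 0) stopf("center_of_mass of an all-zero image is undefined")
  ny <- nrow(img); nx <- ncol(img)
  y <- sum(rowSums(img) * seq_len(ny)) / tot
  x <- sum(colSums(img) * seq_len(nx)) / tot
  c(y = y, x = x)
}

#' Select the most consistent repetitions by center of mass
#'
#' The respiratory outlier-rejection rule applied to the 8 single-shot
#' repetitions of each slice: an initial mean center of mass over all
#' repetitions is refined by averaging the 4 centers closest to it, and
#' the `n_keep` repetitions whose centers are closest to the refined mean
#' are retained (the rest — the most dissimilar motion states — are
#' discarded).  Distances are Euclidean in pixels; ties break toward the
#' lower repetition index.
#'
#' @param coms numeric `n x 2` matrix of `(y, x)` centers (or list of
#'   pairs), one row per repetition.
#' @param n_keep repetitions to retain (default 6 of 8).
#' @return object of class `selection_result`: `coms`, `initial_mean`,
#'   `refined_mean`, sorted `retained` indices and `discarded` indices
#'   (1-based).
#' @export
select_images <- function(coms, n_keep = 6L) {
  if (is.list(coms)) coms <- do.call(rbind, coms)
  coms <- as.matrix(coms)
  n <- nrow(coms)
  if (n < n_keep + 1L) {
    stopf("need at least n_keep + 1 = %d centers, got %d", n_keep + 1L, n)
  }
  initial_mean <- colMeans(coms)
  d0 <- sqrt(rowSums((coms - matrix(initial_mean, n, 2, byrow = TRUE))^2))
  closest4 <- order(d0, seq_len(n))[seq_len(min(4L, n))]
  refined_mean <- colMeans(coms[closest4, , drop = FALSE])
  d1 <- sqrt(rowSums((coms - matrix(refined_mean, n, 2, byrow = TRUE))^2))
  retained <- sort(order(d1, seq_len(n))[seq_len(n_keep)])
  structure(list(
    coms = coms, initial_mean = initial_mean, refined_mean = refined_mean,
    retained = retained, discarded = setdiff(seq_len(n), retained),
    distances = d1
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: retained %s of %d; discarded %s\n",
              paste(x$retained, collapse = ","), nrow(x$coms),
              paste(x$discarded, collapse = ",")))
  invisible(x)
}

zero_field <- function(ny, nx) {
  list(dy = matrix(0, ny, nx), dx = matrix(0, ny, nx))
}

#' Apply a dense deformation field to an image
#'
#' Backward warping with bilinear interpolation and zero boundary:
#' `out(y, x) = img(y + dy(y, x), x + dx(y, x))`.
#'
#' @param img real or complex matrix.
#' @param field list with `dy`, `dx` displacement matrices (pixels).
#' @return warped matrix.
#' @export
warp <- function(img, field) {
  if (!all(dim(img) == dim(field$dy))) {
    stopf("image grid %s does not match field grid %s",
          paste(dim(img), collapse = " x "),
          paste(dim(field$dy), collapse = " x "))
  }
  warp_bilinear(img, field$dy, field$dx)
}

# Bilinear resize to (ny2, nx2), mapping pixel centers proportionally;
# sampling coordinates are clamped to the grid to avoid boundary zeroing.
resize_bilinear <- function(img, ny2, nx2) {
  ny <- nrow(img); nx <- ncol(img)
  ys <- matrix((seq_len(ny2) - 0.5) * ny / ny2 + 0.5, ny2, nx2)
  xs <- matrix(rep((seq_len(nx2) - 0.5) * nx / nx2 + 0.5, each = ny2), ny2, nx2)
  bilinear_sample(img, pmin(pmax(ys, 1), ny), pmin(pmax(xs, 1), nx))
}

#' Non-rigid registration by multi-resolution demons
#'
#' Estimates a dense displacement field mapping `moving` onto `fixed` with
#' a sum-of-squared-differences demons flow: at each level of a Gaussian
#' pyramid the field is updated by the classic demons force
#' `u = diff * grad(fixed) / (|grad(fixed)|^2 + diff^2)`, fluid-smoothed,
#' accumulated, and elastically smoothed (`sigma_field`).  The best field
#' by SSD (including the initial zero field) is returned, so the warped
#' SSD never exceeds the unregistered SSD.  Fully deterministic.
#'
#' @param moving,fixed real matrices on a common grid.
#' @param levels pyramid levels (coarsest is `2^(levels-1)` downsampling).
#' @param sigma_field elastic regularization SD in pixels.
#' @param sigma_fluid update smoothing SD in pixels.
#' @param iterations maximum iterations per level.
#' @param step_cap maximum per-iteration displacement update (pixels).
#' @return list of class `deformation_field`: `dy`, `dx`, final `ssd`,
#'   initial `ssd0` and a `converged` flag (`FALSE` means the iteration
#'   budget was exhausted while still improving).
#' @export
register_nonrigid <- function(moving, fixed, levels = 3L, sigma_field = 2,
                              sigma_fluid = 1, iterations = 50L,
                              step_cap = 2) {
  if (!all(dim(moving) == dim(fixed))) {
    stopf("image grid %s does not match %s",
          paste(dim(moving), collapse = " x "),
          paste(dim(fixed), collapse = " x "))
  }
  scale <- max(abs(fixed), abs(moving), .Machine$double.eps)
  movn <- moving / scale; fixn <- fixed / scale
  ny <- nrow(fixed); nx <- ncol(fixed)
  field <- NULL
  converged <- TRUE
  for (lev in seq.int(levels, 1L)) {
    f <- 2^(lev - 1L)
    nyl <- max(8L, round(ny / f)); nxl <- max(8L, round(nx / f))
    fx <- gaussian_smooth(fixn, f / 2); mv <- gaussian_smooth(movn, f / 2)
    fx <- resize_bilinear(fx, nyl, nxl); mv <- resize_bilinear(mv, nyl, nxl)
    if (is.null(field)) {
      field <- zero_field(nyl, nxl)
    } else {
      ry <- nyl / nrow(field$dy); rx <- nxl / ncol(field$dx)
      field <- list(dy = resize_bilinear(field$dy, nyl, nxl) * ry,
                    dx = resize_bilinear(field$dx, nyl, nxl) * rx)
    }
    gy <- rbind(fx[2, , drop = FALSE] - fx[1, , drop = FALSE],
                (fx[-(1:2), , drop = FALSE] - fx[seq_len(nyl - 2), , drop = FALSE]) / 2,
                fx[nyl, , drop = FALSE] - fx[nyl - 1, , drop = FALSE])
    gx <- cbind(fx[, 2, drop = FALSE] - fx[, 1, drop = FALSE],
                (fx[, -(1:2), drop = FALSE] - fx[, seq_len(nxl - 2), drop = FALSE]) / 2,
                fx[, nxl, drop = FALSE] - fx[, nxl - 1, drop = FALSE])
    g2 <- gy^2 + gx^2
    best <- field
    best_ssd <- sum((warp_bilinear(mv, field$dy, field$dx) - fx)^2)
    for (it in seq_len(iterations)) {
      wm <- warp_bilinear(mv, field$dy, field$dx)
      diff <- fx - wm
      ssd <- sum(diff^2)
      if (ssd < best_ssd) {
        best_ssd <- ssd
        best <- field
      }
      den <- g2 + diff^2
      den[den < 1e-9] <- 1e-9
      uy <- diff * gy / den
      ux <- diff * gx / den
      uy <- pmin(pmax(uy, -step_cap), step_cap)
      ux <- pmin(pmax(ux, -step_cap), step_cap)
      uy <- gaussian_smooth(uy, sigma_fluid)
      ux <- gaussian_smooth(ux, sigma_fluid)
      upd <- max(abs(uy), abs(ux))
      field <- list(dy = gaussian_smooth(field$dy + uy, sigma_field),
                    dx = gaussian_smooth(field$dx + ux, sigma_field))
      if (upd < 0.01) break
      if (it == iterations) converged <- FALSE
    }
    ssd_end <- sum((warp_bilinear(mv, field$dy, field$dx) - fx)^2)
    if (ssd_end <= best_ssd) {
      best <- field
      best_ssd <- ssd_end
    }
    field <- best
  }
  if (!all(dim(field$dy) == c(ny, nx))) {
    ry <- ny / nrow(field$dy); rx <- nx / ncol(field$dx)
    field <- list(dy = resize_bilinear(field$dy, ny, nx) * ry,
                  dx = resize_bilinear(field$dx, ny, nx) * rx)
  }
  ssd0 <- sum((movn - fixn)^2)
  ssd1 <- sum((warp_bilinear(movn, field$dy, field$dx) - fixn)^2)
  if (ssd1 > ssd0) {           # never worse than no registration
    field <- zero_field(ny, nx)
    ssd1 <- ssd0
  }
  structure(list(dy = field$dy, dx = field$dx,
                 ssd = ssd1 * scale^2, ssd0 = ssd0 * scale^2,
                 converged = converged),
            class = "deformation_field")
}

#' Motion-corrected average of a single-shot series
#'
#' The per-slice motion-correction chain: centers of mass are computed on
#' the magnitude images, the [select_images()] rule discards the most
#' dissimilar motion states, the retained images are co-registered
#' non-rigidly onto the reference repetition (the retained image whose
#' center of mass is closest to the refined mean), and the warped images
#' are averaged.  When a signed PSIR series is supplied the motion fields
#' estimated on the magnitude images are re-used to warp and average the
#' PSIR series.
#'
#' @param mag_series list of real non-negative magnitude images, one per
#'   repetition (at least 3).
#' @param psir_series optional list of signed images on the same grid.
#' @param n_keep repetitions to retain.
#' @param reg_config list of arguments passed to [register_nonrigid()].
#' @param register set `FALSE` to skip registration (selection + plain
#'   averaging only; useful as an ablation and for averaging-statistics
#'   checks, since warping interpolation slightly smooths noise).
#' @return list: `final` (averaged image, PSIR if supplied else
#'   magnitude), `selection`, `reference` (repetition index), `fields`
#'   (per retained repetition), `warped` (list of warped averaged-series
#'   images in retained order).
#' @export
moco_average <- function(mag_series, psir_series = NULL, n_keep = 6L,
                         reg_config = list(), register = TRUE) {
  n <- length(mag_series)
  if (n < 3L) stopf("need at least 3 repetitions, got %d", n)
  if (!is.null(psir_series) && length(psir_series) != n) {
    stopf("psir_series length %d does not match magnitude series length %d",
          length(psir_series), n)
  }
  n_keep <- min(n_keep, n - 2L)
  coms <- do.call(rbind, lapply(mag_series, center_of_mass))
  sel <- select_images(coms, n_keep = n_keep)
  ref <- sel$retained[which.min(sel$distances[sel$retained])]
  series <- if (is.null(psir_series)) mag_series else psir_series
  fields <- vector("list", length(sel$retained))
  warped <- vector("list", length(sel$retained))
  for (i in seq_along(sel$retained)) {
    r <- sel$retained[i]
    if (r == ref || !register) {
      fields[[i]] <- c(zero_field(nrow(mag_series[[r]]), ncol(mag_series[[r]])),
                       list(ssd = 0, ssd0 = 0, converged = TRUE))
      warped[[i]] <- series[[r]]
    } else {
      fields[[i]] <- do.call(register_nonrigid,
                             c(list(moving = mag_series[[r]],
                                    fixed = mag_series[[ref]]),
                               reg_config))
      warped[[i]] <- warp(series[[r]], fields[[i]])
    }
  }
  # identical inputs average to themselves exactly (summation would lose
  # the last ulp)
  final <- if (all(vapply(warped[-1], identical, logical(1), warped[[1]]))) {
    warped[[1]]
  } else {
    Reduce(`+`, warped) / length(warped)
  }
  list(final = final, selection = sel, reference = ref,
       fields = fields, warped = warped)
}
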