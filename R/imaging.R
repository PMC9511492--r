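# Hyperspectral cube handling: spectral-class segmentation and ROI sums.

cube_pixel_matrix <- function(cube) {
  d <- dim(cube$intensity)   # (8, ny, nx, nw)
  ny <- d[2]; nx <- d[3]; nw <- d[4]
  m <- matrix(aperm(cube$intensity, c(2, 3, 1, 4)), ny * nx, 8 * nw)
  list(m = m, ny = ny, nx = nx, nw = nw)
}

#' Segment cube pixels into spectral classes
#'
#' Seeded k-means on L2-normalized per-pixel spectra (all polarization
#' combinations concatenated), standing in for a commercial spectral-
#' mapping toolbox. The class with the lowest mean 2910 cm^-1 intensity is
#' relabeled 0 and interpreted as background. If the class mean spectra are
#' statistically indistinguishable (between-class separation below the
#' noise scale), the map is flagged as carrying no structure.
#'
#' @param cube a `hyperspectral_cube`.
#' @param k number of spectral classes (>= 2).
#' @param seed seed for the k-means initialization.
#' @return A list of class `label_map`: `labels` (ny x nx integer matrix,
#'   0 = background), `class_spectra` (class x wavenumber mean spectra,
#'   averaged over polarizations), `counts`, `no_structure` flag.
#' @export
segment_spectral_classes <- function(cube, k, seed = 1) {
  stopifnot(inherits(cube, "hyperspectral_cube"), k >= 2)
  px <- cube_pixel_matrix(cube)
  if (k > nrow(px$m)) stop("k exceeds the number of pixels")
  nrm <- row_norms(px$m)
  nrm[nrm == 0] <- 1
  feat <- px$m / nrm
  km <- with_seed(seed, kmeans(feat, centers = k, nstart = 8,
                               iter.max = 50))
  labels <- matrix(km$cluster, px$ny, px$nx)

  i2910 <- which.min(abs(cube$wavenumber - 2910))
  # raw mean spectra per class, averaged over polarizations
  raw <- px$m  # pixels x (8*nw), polarization fastest within each wavenumber
  class_spectra <- t(vapply(seq_len(k), function(cl) {
    sp <- colMeans(raw[km$cluster == cl, , drop = FALSE])
    colMeans(matrix(sp, 8, px$nw))
  }, numeric(px$nw)))
  peak_by_class <- class_spectra[, i2910]
  background <- which.min(peak_by_class)

  relabel <- integer(k)
  relabel[background] <- 0L
  relabel[-background] <- seq_len(k - 1L)
  labels <- matrix(relabel[km$cluster], px$ny, px$nx)

  # no-structure heuristic: with real spectral classes the cluster split
  # explains a large share of the normalized-feature variance; splitting
  # pure noise in a high-dimensional feature space explains almost none
  no_structure <- (km$betweenss / km$totss) < 0.1

  structure(list(labels = labels,
                 class_spectra = class_spectra[order(relabel), , drop = FALSE],
                 counts = as.integer(table(factor(relabel[km$cluster],
                                                  levels = 0:(k - 1)))),
                 no_structure = no_structure, k = k, seed = seed),
            class = "label_map")
}

#' Sum an ROI into a single spectrum
#'
#' Pixelwise sum of the cube over a mask for one polarization combination;
#' the pixel count is recorded in the spectrum provenance.
#'
#' @param cube a `hyperspectral_cube`.
#' @param mask logical ny x nx matrix (or integer pixel indices into the
#'   ny x nx grid).
#' @param polarization one of [POLARIZATIONS].
#' @return A [spectrum()].
#' @export
sum_roi <- function(cube, mask, polarization) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  polarization <- match.arg(polarization, POLARIZATIONS)
  d <- dim(cube$intensity)
  if (is.logical(mask)) {
    stopifnot(all(dim(mask) == d[2:3]))
    idx <- which(mask)
  } else {
    idx <- as.integer(mask)
    if (any(idx < 1 | idx > d[2] * d[3])) stop("mask indices out of bounds")
  }
  if (!length(idx)) stop("empty ROI mask")
  p <- match(polarization, POLARIZATIONS)
  plane <- matrix(cube$intensity[p, , , ], d[2] * d[3], d[4])
  spectrum(cube$wavenumber, colSums(plane[idx, , drop = FALSE]),
           polarization = polarization,
           provenance = list(pixel_count = length(idx)))
}

#' Rectangular ROI intersected with a segmentation class
#'
#' Emulates drawing an analysis box over a segmented image: the returned
#' mask is the intersection of the box with the pixels of `class_id`.
#'
#' @param label_map a [segment_spectral_classes()] result.
#' @param box `c(x0, x1, y0, y1)` in pixel coordinates (inclusive).
#' @param class_id segmentation class to keep (default: any non-background).
#' @return Logical ny x nx mask.
#' @export
roi_box_mask <- function(label_map, box, class_id = NULL) {
  stopifnot(inherits(label_map, "label_map"), length(box) == 4)
  lab <- label_map$labels
  m <- matrix(FALSE, nrow(lab), ncol(lab))
  xs <- max(1, box[1]):min(ncol(lab), box[2])
  ys <- max(1, box[3]):min(nrow(lab), box[4])
  m[ys, xs] <- TRUE
  if (is.null(class_id)) m & (lab > 0) else m & (lab == class_id)
}

#' Per-polarization ROI susceptibility magnitudes
#'
#' Convenience bridge from a cube ROI to the solver input: sums the ROI for
#' each polarization combination, fits the CH-stretch multipeak model, and
#' extracts `|chi|` at 2910 cm^-1.
#'
#' @param cube a `hyperspectral_cube`.
#' @param mask ROI mask as in [sum_roi()].
#' @param peaks initial peak table (see [ch_stretch_peaks()]).
#' @param window extraction window around 2910, cm^-1.
#' @return Named numeric vector of 8 magnitudes in [POLARIZATIONS] order,
#'   with the ROI pixel count as attribute `pixel_count`.
#' @export
extract_roi_susceptibilities <- function(cube, mask,
                                         peaks = ch_stretch_peaks(),
                                         window = 10) {
  mags <- vapply(POLARIZATIONS, function(p) {
    sp <- sum_roi(cube, mask, p)
    init <- lapply(seq_len(nrow(peaks)), function(q) {
      a0 <- max(sp$intensity[abs(sp$wavenumber - peaks$center[q]) <= 6]) -
        quantile(sp$intensity, 0.05, names = FALSE)
      voigt_peak(peaks$center[q], peaks$gaussian_width[q],
                 peaks$lorentzian_width[q], max(a0, 1e-6))
    })
    fit <- fit_multipeak(sp, init)
    extract_chi_magnitude(fit, 2910, window)
  }, numeric(1))
  pc <- tryCatch(sum(mask != 0), error = function(e) NA_integer_)
  attr(mags, "pixel_count") <- pc
  mags
}
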