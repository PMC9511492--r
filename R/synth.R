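# Synthetic data: training/test sets for the inverse solver and
# polarization-resolved hyperspectral cubes emulating measured sheets.

# run code under a private, seeded RNG without touching global state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sampling ranges for the synthetic training generator
#'
#' Defines the parameter distributions of the forward-model sampler. The
#' hyperpolarizability components are drawn from the positive unit box:
#' the forward map is odd under a global hyperpolarizability sign flip
#' (`chi(phi, -beta) = -chi(phi, beta) = chi(phi + pi, beta)`) and odd in
#' the chiral components under `theta -> pi - theta`, so a sign-symmetric
#' amplitude prior would make the training target a coin flip between
#' equivalent branches. The positive box fixes the sign convention, and
#' together with the in-plane domain `[0, 180)` degrees and the tilt domain
#' `(0, 90)` degrees it makes the inverse map single-valued and continuous
#' (the flipped branch is component-wise negative, far from the sampled
#' family). The tilt domain stops at 90 degrees because a tilt and its
#' supplement are equivalent up to the chiral sign convention, and starts
#' slightly above zero where the signal vanishes identically. See the
#' methods vignette for the identifiability analysis behind these domains.
#'
#' @param beta_zzz range of the dominant achiral component.
#' @param beta_other range of the remaining six components.
#' @param phi_deg in-plane rotation domain of sheet 1, degrees.
#' @param theta_deg tilt domain, degrees.
#' @param coverage range of the two-sheet coverage ratio N.
#' @param delta_phi_deg in-plane offset of sheet 2 relative to sheet 1.
#' @return A list of class `training_ranges`.
#' @export
training_ranges <- function(beta_zzz = c(0, 1), beta_other = c(0, 1),
                            phi_deg = c(0, 180), theta_deg = c(2, 90),
                            coverage = c(0.2, 5), delta_phi_deg = 60) {
  r <- list(beta_zzz = beta_zzz, beta_other = beta_other, phi_deg = phi_deg,
            theta_deg = theta_deg, coverage = coverage,
            delta_phi_deg = delta_phi_deg)
  for (nm in setdiff(names(r), "delta_phi_deg")) {
    v <- r[[nm]]
    if (length(v) != 2 || !all(is.finite(v)) || v[2] <= v[1]) {
      stop("invalid (empty) range for ", nm)
    }
  }
  structure(r, class = "training_ranges")
}

row_norms <- function(m) sqrt(rowSums(m^2))

#' Generate a forward-model-consistent training set
#'
#' Draws random orientations, hyperpolarizabilities and coverage ratios,
#' pushes them through the twist-averaged forward model for two sheets with
#' `phi2 = phi1 + delta_phi`, and stores the unit-normalized 16 signed
#' susceptibilities as inputs together with an 11-value output encoding:
#' the 6 grouped hyperpolarizability terms (unit-normalized), `phi1` and
#' `theta` in radians folded into their base intervals, the coverage ratio
#' `N`, and two binary interval indicators (`phi` in `[pi, 2*pi)`, `theta`
#' in `[pi/2, pi)`). Each row satisfies the round trip: decoding the output
#' and re-running the forward model reproduces the normalized input row.
#'
#' @param n number of samples (>= 1).
#' @param seed integer seed; the generator has no hidden global RNG state.
#' @param ranges a [training_ranges()] object.
#' @param kind `"train"` or `"test"` tag stored with the set.
#' @return A list of class `vsfg_training_set` with elements `inputs`
#'   (n x 16), `outputs` (n x 11), `seed`, `ranges`, `kind`.
#' @export
gen_training_set <- function(n, seed, ranges = training_ranges(),
                             kind = "train") {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive count")
  }
  n <- as.integer(n)
  if (!inherits(ranges, "training_ranges")) ranges <- do.call(training_ranges, ranges)
  with_seed(seed, {
    beta <- cbind(runif(n, ranges$beta_zzz[1], ranges$beta_zzz[2]),
                  matrix(runif(6L * n, ranges$beta_other[1],
                               ranges$beta_other[2]), n, 6))
    phi <- runif(n, ranges$phi_deg[1], ranges$phi_deg[2]) * pi / 180
    theta <- runif(n, ranges$theta_deg[1], ranges$theta_deg[2]) * pi / 180
    N <- runif(n, ranges$coverage[1], ranges$coverage[2])
    dphi <- ranges$delta_phi_deg * pi / 180

    G <- cbind(beta[, 1:4, drop = FALSE],
               beta[, 5] + beta[, 6],
               beta[, 7] - beta[, 6])
    chi1 <- chi_from_grouped(G, phi, theta)
    chi2 <- chi_from_grouped(G, phi + dphi, theta) * N
    X <- cbind(chi1, chi2)
    nrm <- row_norms(X)
    if (any(nrm == 0)) stop("degenerate sample with zero susceptibilities")
    X <- X / nrm
    colnames(X) <- c(paste0("s1_", POLARIZATIONS), paste0("s2_", POLARIZATIONS))

    Ghat <- G / row_norms(G)
    Y <- cbind(Ghat,
               phi %% pi, ifelse(theta < pi / 2, theta, pi - theta), N,
               as.numeric(phi >= pi), as.numeric(theta >= pi / 2))
    colnames(Y) <- c(GROUPED_NAMES, "phi", "theta", "coverage",
                     "phi_interval", "theta_interval")
    structure(list(inputs = X, outputs = Y, seed = seed, ranges = ranges,
                   kind = kind),
              class = "vsfg_training_set")
  })
}

#' @rdname gen_training_set
#' @export
gen_test_set <- function(n, seed, ranges = training_ranges()) {
  gen_training_set(n, seed = seed, ranges = ranges, kind = "test")
}

#' Decode the 11-value solver output encoding
#'
#' Interval indicators are thresholded at 0.5 and the continuous angles are
#' folded into the indicated interval; the grouped-term block is returned
#' as stored (its scale is immaterial to the forward model after
#' normalization).
#'
#' @param Y an n x 11 matrix (or 11-vector) in the training-output encoding.
#' @return A list with `g` (n x 6), `phi`, `theta` (radians), `coverage`.
#' @export
decode_outputs <- function(Y) {
  Y <- matrix(as.numeric(Y), ncol = 11)
  phi <- Y[, 7] + ifelse(Y[, 10] > 0.5, pi, 0)
  theta <- ifelse(Y[, 11] > 0.5, pi - Y[, 8], Y[, 8])
  list(g = Y[, 1:6, drop = FALSE], phi = phi, theta = theta,
       coverage = Y[, 9])
}

#' Reconstruct normalized inputs from encoded outputs
#'
#' Pushes decoded outputs through the two-sheet forward model and
#' normalizes; used for the generator round-trip invariant and by the
#' solver's candidate scoring.
#'
#' @param Y encoded outputs (n x 11).
#' @param delta_phi_deg in-plane offset between the sheets, degrees.
#' @return An n x 16 matrix of unit-normalized susceptibilities.
#' @export
forward_from_outputs <- function(Y, delta_phi_deg = 60) {
  d <- decode_outputs(Y)
  dphi <- delta_phi_deg * pi / 180
  X <- cbind(chi_from_grouped(d$g, d$phi, d$theta),
             chi_from_grouped(d$g, d$phi + dphi, d$theta) * d$coverage)
  nrm <- row_norms(X)
  nrm[nrm == 0] <- 1
  X / nrm
}

#' Default CH-stretch peak table
#'
#' The four bands of the CH2 stretching window used throughout: symmetric
#' stretch at 2860, the asymmetric stretch at 2910 (the analysis band), and
#' Fermi resonances at 2930 and 2960 cm^-1. `rel_amplitude` scales each
#' band relative to the 2910 band; widths are Gaussian sigma and Lorentzian
#' HWHM in cm^-1.
#'
#' @return A data.frame with columns `center`, `gaussian_width`,
#'   `lorentzian_width`, `rel_amplitude`.
#' @export
ch_stretch_peaks <- function() {
  data.frame(center = c(2860, 2910, 2930, 2960),
             gaussian_width = c(8, 7, 8, 9),
             lorentzian_width = c(5, 4, 5, 5),
             rel_amplitude = c(0.35, 1, 0.45, 0.3))
}

#' Describe a synthetic scene of rhombic sheets
#'
#' @param dim image dimensions `c(ny, nx)` in pixels.
#' @param wavenumber spectral axis in cm^-1 (strictly increasing, covering
#'   2800-3000).
#' @param sheets list of sheet descriptions, each a list with `center`
#'   (pixel `c(x, y)`), `side` (pixels), `phi_deg` (in-plane rotation, also
#'   the rhombus orientation), `theta_deg` (tilt), `beta` (7 components),
#'   `scale` (thickness/coverage intensity factor).
#' @param baseline background counts.
#' @param snr target per-pixel signal-to-noise ratio at the 2910 cm^-1 peak.
#' @param peaks peak table, see [ch_stretch_peaks()].
#' @param rhombus_angle_deg acute angle of the rhombic sheets.
#' @return A list of class `sheet_scene`.
#' @export
sheet_scene <- function(dim = c(48, 64),
                        wavenumber = seq(2800, 3000, by = 2),
                        sheets = list(), baseline = 10, snr = 56,
                        peaks = ch_stretch_peaks(),
                        rhombus_angle_deg = 60) {
  stopifnot(length(dim) == 2, all(dim >= 1),
            all(diff(wavenumber) > 0),
            min(wavenumber) <= 2800, max(wavenumber) >= 3000)
  structure(list(dim = as.integer(dim), wavenumber = wavenumber,
                 sheets = sheets, baseline = baseline, snr = snr,
                 peaks = peaks, rhombus_angle_deg = rhombus_angle_deg),
            class = "sheet_scene")
}

rhombus_vertices <- function(center, side, phi_deg, acute_deg = 60) {
  a <- acute_deg * pi / 180
  u <- c(1, 0); v <- c(cos(a), sin(a))
  pts <- rbind(c(0, 0), side * u, side * (u + v), side * v)
  pts <- sweep(pts, 2, colMeans(pts))
  r <- phi_deg * pi / 180
  R <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2)
  sweep(pts %*% t(R), 2, center, "+")
}

# even-odd point-in-polygon over the full pixel grid
polygon_mask <- function(ny, nx, vertices) {
  px <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  py <- matrix(rep(seq_len(ny), nx), ny, nx)
  n <- nrow(vertices)
  inside <- matrix(FALSE, ny, nx)
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

unit_lineshape <- function(wavenumber, peaks) {
  s <- numeric(length(wavenumber))
  for (q in seq_len(nrow(peaks))) {
    pk <- voigt_peak(peaks$center[q], peaks$gaussian_width[q],
                     peaks$lorentzian_width[q], peaks$rel_amplitude[q])
    s <- s + voigt_profile(wavenumber, pk)
  }
  s
}

#' Generate a polarization-resolved hyperspectral cube
#'
#' Renders each sheet as a rhombic polygon whose per-pixel spectrum is the
#' CH-stretch multipeak lineshape scaled by the homodyne intensity
#' `|chi|^2` of the sheet's orientation for each polarization combination,
#' on a constant baseline, with additive Gaussian noise. Overlapping sheets
#' add in intensity. The noise standard deviation is set so that the mean
#' per-pixel 2910 cm^-1 peak signal over all sheet pixels meets the scene's
#' target SNR.
#'
#' @param scene a [sheet_scene()].
#' @param seed integer seed for the noise stream.
#' @return A list of class `hyperspectral_cube` with `intensity` (array
#'   `[polarization, y, x, wavenumber]`), `wavenumber`, `polarizations`,
#'   `seed`, `truth` (per-sheet masks and parameters), `scene`.
#' @export
gen_cube <- function(scene, seed) {
  stopifnot(inherits(scene, "sheet_scene"))
  ny <- scene$dim[1]; nx <- scene$dim[2]
  nw <- length(scene$wavenumber)
  shape <- unit_lineshape(scene$wavenumber, scene$peaks)
  i2910 <- which.min(abs(scene$wavenumber - 2910))

  cube <- array(scene$baseline, c(8, ny, nx, nw),
                dimnames = list(POLARIZATIONS, NULL, NULL, NULL))
  masks <- list()
  for (s in seq_along(scene$sheets)) {
    sh <- scene$sheets[[s]]
    verts <- rhombus_vertices(sh$center, sh$side, sh$phi_deg,
                              scene$rhombus_angle_deg)
    if (any(verts[, 1] < 0.5) || any(verts[, 1] > nx + 0.5) ||
        any(verts[, 2] < 0.5) || any(verts[, 2] > ny + 0.5)) {
      stop("sheet ", s, " extends outside the image bounds")
    }
    mask <- polygon_mask(ny, nx, verts)
    masks[[s]] <- mask
    chi <- lab_susceptibilities(sh$beta, sh$phi_deg * pi / 180,
                                sh$theta_deg * pi / 180)
    scale <- if (is.null(sh$scale)) 1 else sh$scale
    for (p in 1:8) {
      amp <- (abs(chi[p]) * scale)^2
      if (amp == 0) next
      add <- outer(mask * amp, shape)           # (ny*nx) x nw on the fly
      cube[p, , , ] <- cube[p, , , ] + array(add, c(ny, nx, nw))
    }
  }

  any_mask <- Reduce(`|`, masks, matrix(FALSE, ny, nx))
  sig2910 <- apply(cube[, , , i2910, drop = FALSE], c(2, 3), max) -
    scene$baseline
  mean_peak <- if (any(any_mask)) mean(sig2910[any_mask]) else scene$baseline
  sigma <- mean_peak / scene$snr
  if (!is.finite(sigma) || sigma <= 0) sigma <- scene$baseline / scene$snr

  with_seed(seed, {
    cube <- cube + array(rnorm(length(cube), sd = sigma), dim(cube))
  })
  structure(list(intensity = cube, wavenumber = scene$wavenumber,
                 polarizations = POLARIZATIONS, seed = seed,
                 noise_sd = sigma,
                 truth = list(masks = masks, sheets = scene$sheets,
                              baseline = scene$baseline),
                 scene = scene),
            class = "hyperspectral_cube")
}

#' Cube serialization
#'
#' Cubes are stored as an RDS file with a fixed list layout (`intensity`,
#' `wavenumber`, `polarizations`, `seed`, `noise_sd`, `truth`, `scene`)
#' plus a human-readable JSON sidecar (`<path>.json`) carrying the axis
#' metadata and generation seed.
#'
#' @param cube a `hyperspectral_cube`.
#' @param path file path for the RDS container.
#' @return `path` invisibly (writer); the cube (reader).
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  saveRDS(unclass(cube), path)
  meta <- list(dim = dim(cube$intensity), wavenumber_range = range(cube$wavenumber),
               polarizations = cube$polarizations, seed = cube$seed,
               noise_sd = cube$noise_sd)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  obj <- readRDS(path)
  stopifnot(is.list(obj), all(c("intensity", "wavenumber", "polarizations")
                              %in% names(obj)))
  structure(obj, class = "hyperspectral_cube")
}
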