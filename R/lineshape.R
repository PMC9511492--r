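# Voigt lineshapes and multipeak fitting of homodyne VSFG spectra.

# Weideman (1994) rational approximation of the Faddeeva function
# w(z) = exp(-z^2) erfc(-iz), accurate to ~1e-13 for Im(z) >= 0.
# Coefficients are computed once per session and cached.
faddeeva_coefs <- local({
  cache <- NULL
  function(N = 64) {
    if (!is.null(cache)) return(cache)
    M <- 2L * N
    M2 <- 2L * M
    k <- seq(-M + 1L, M - 1L)
    L <- sqrt(N / sqrt(2))
    theta <- k * pi / M
    t <- L * tan(theta / 2)
    f <- exp(-t^2) * (L^2 + t^2)
    f <- c(0, f)
    # fftshift then real FFT, as in the original formulation
    a <- Re(stats::fft(f[c((M + 1L):M2, 1:M)])) / M2
    cache <<- list(a = rev(a[2:(N + 1L)]), L = L)
    cache
  }
})

#' Faddeeva function
#'
#' Scaled complex complementary error function
#' `w(z) = exp(-z^2) * erfc(-i z)`, evaluated with a 64-term rational
#' approximation valid on the closed upper half plane.
#'
#' @param z complex (or numeric) vector with `Im(z) >= 0`.
#' @return Complex vector of `w(z)`.
#' @export
faddeeva_w <- function(z) {
  z <- as.complex(z)
  if (any(Im(z) < -1e-12)) stop("faddeeva_w requires Im(z) >= 0")
  cf <- faddeeva_coefs()
  L <- cf$L
  Z <- (L + 1i * z) / (L - 1i * z)
  p <- rep(0 + 0i, length(z))
  for (ak in cf$a) p <- p * Z + ak   # Horner; coefficients high -> low
  2 * p / (L - 1i * z)^2 + (1 / sqrt(pi)) / (L - 1i * z)
}

#' Voigt peak description
#'
#' @param center peak position, cm^-1.
#' @param gaussian_width Gaussian standard deviation sigma, cm^-1 (> 0
#'   unless the Lorentzian width is positive).
#' @param lorentzian_width Lorentzian half width at half maximum gamma,
#'   cm^-1.
#' @param amplitude peak height at the center, intensity units (>= 0).
#' @return A list of class `voigt_peak`.
#' @export
voigt_peak <- function(center, gaussian_width, lorentzian_width, amplitude) {
  stopifnot(is.finite(center), is.finite(amplitude), amplitude >= 0)
  if (gaussian_width < 0 || lorentzian_width < 0 ||
      (gaussian_width <= 0 && lorentzian_width <= 0)) {
    stop("Voigt widths must be positive (at least one of sigma, gamma > 0)")
  }
  structure(list(center = center, gaussian_width = gaussian_width,
                 lorentzian_width = lorentzian_width, amplitude = amplitude),
            class = "voigt_peak")
}

# normalized Voigt density V(x; sigma, gamma) (unit area)
voigt_density <- function(x, sigma, gamma) {
  if (sigma <= 0) {
    return((gamma / pi) / (x^2 + gamma^2))
  }
  if (gamma <= 0) {
    return(exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi)))
  }
  z <- (x + 1i * gamma) / (sigma * sqrt(2))
  Re(faddeeva_w(z)) / (sigma * sqrt(2 * pi))
}

#' Voigt profile of a peak
#'
#' Evaluates the Gaussian-Lorentzian convolution lineshape scaled so that
#' `amplitude` is the height at the peak center (the quantity the homodyne
#' intensity calibration acts on). The pure-Gaussian and pure-Lorentzian
#' limits are handled exactly.
#'
#' @param x wavenumber grid, cm^-1.
#' @param peak a [voigt_peak()].
#' @return Numeric vector of intensity contributions.
#' @export
voigt_profile <- function(x, peak) {
  stopifnot(inherits(peak, "voigt_peak"))
  v <- voigt_density(x - peak$center, peak$gaussian_width,
                     peak$lorentzian_width)
  v0 <- voigt_density(0, peak$gaussian_width, peak$lorentzian_width)
  peak$amplitude * v / v0
}

#' Spectrum container
#'
#' @param wavenumber strictly increasing axis, cm^-1.
#' @param intensity counts, same length as `wavenumber`.
#' @param polarization one of [POLARIZATIONS] (or `NA`).
#' @param provenance free-form origin tag (pixel/ROI id); the ROI pixel
#'   count is recorded here by [sum_roi()].
#' @return A list of class `vsfg_spectrum`.
#' @export
spectrum <- function(wavenumber, intensity, polarization = NA_character_,
                     provenance = list()) {
  stopifnot(length(wavenumber) == length(intensity),
            all(diff(wavenumber) > 0))
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity),
                 polarization = polarization, provenance = provenance),
            class = "vsfg_spectrum")
}

#' Two-column spectrum I/O
#'
#' Plain CSV with columns `wavenumber`, `intensity`.
#'
#' @param spec a [spectrum()].
#' @param path file path.
#' @param polarization label attached on read.
#' @return `path` invisibly (writer); a `vsfg_spectrum` (reader).
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "vsfg_spectrum"))
  write.csv(data.frame(wavenumber = spec$wavenumber,
                       intensity = spec$intensity), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, polarization = NA_character_) {
  df <- read.csv(path)
  spectrum(df$wavenumber, df$intensity, polarization,
           provenance = list(file = path))
}

#' Fit a spectrum with a sum of Voigt peaks
#'
#' Least-squares fit of `baseline + sum_q Voigt_q(omega)` by
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]). Peaks add in intensity;
#' interference cross terms between resonances are deliberately not
#' modeled. Width and amplitude positivity is enforced through box
#' constraints.
#'
#' @param spec a [spectrum()].
#' @param initial_peaks list of [voigt_peak()] starting values (centers
#'   must lie inside the axis range).
#' @param baseline starting constant baseline (fitted).
#' @param fit_centers fit peak centers (`TRUE`) or hold them fixed.
#' @return A list of class `multipeak_fit`: `peaks` (data.frame with fitted
#'   `center`, `gaussian_width`, `lorentzian_width`, `amplitude` and
#'   standard errors where available), `baseline`, `residual_norm`,
#'   `status` (`"converged"` or `"not_converged"`), `message`, `spectrum`.
#' @export
fit_multipeak <- function(spec, initial_peaks, baseline = NULL,
                          fit_centers = TRUE) {
  stopifnot(inherits(spec, "vsfg_spectrum"), length(initial_peaks) >= 1)
  w <- spec$wavenumber
  y <- spec$intensity
  if (sd(y) == 0) stop("degenerate (flat) spectrum: nothing to fit")
  for (pk in initial_peaks) {
    stopifnot(inherits(pk, "voigt_peak"))
    if (pk$center < min(w) || pk$center > max(w)) {
      stop("initial peak center ", pk$center, " outside the spectral axis")
    }
  }
  if (is.null(baseline)) baseline <- quantile(y, 0.05, names = FALSE)
  np <- length(initial_peaks)

  par0 <- c(baseline, unlist(lapply(initial_peaks, function(p) {
    c(p$center, p$gaussian_width, p$lorentzian_width, max(p$amplitude, 1e-8))
  })))
  span <- diff(range(w))
  lower <- c(-Inf, rep(c(min(w), 1e-3, 0, 0), np))
  upper <- c(Inf, rep(c(max(w), span, span, Inf), np))
  if (!fit_centers) {
    centers0 <- par0[seq(2, by = 4, length.out = np)]
    lower[seq(2, by = 4, length.out = np)] <- centers0
    upper[seq(2, by = 4, length.out = np)] <- centers0
  }

  model <- function(par) {
    out <- rep(par[1], length(w))
    for (q in seq_len(np)) {
      p <- par[2 + 4 * (q - 1) + 0:3]
      out <- out + voigt_profile(w, voigt_peak(p[1], p[2], p[3], max(p[4], 0)))
    }
    out
  }
  res <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = function(par) model(par) - y,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, maxfev = 5000))
  converged <- res$info %in% 1:4
  if (!converged) {
    warning("multipeak fit did not converge: ", res$message)
  }
  par <- res$par
  se <- rep(NA_real_, length(par))
  cov <- tryCatch({
    cv <- stats::vcov(res)
    se <- sqrt(pmax(diag(cv), 0))
    cv
  }, error = function(e) NULL)

  idx <- function(k) seq(2 + k - 1, by = 4, length.out = np)
  peaks <- data.frame(center = par[idx(1)],
                      gaussian_width = par[idx(2)],
                      lorentzian_width = par[idx(3)],
                      amplitude = pmax(par[idx(4)], 0),
                      center_se = se[idx(1)],
                      amplitude_se = se[idx(4)])
  structure(list(peaks = peaks, baseline = par[1], baseline_se = se[1],
                 residual_norm = sqrt(sum(res$fvec^2)),
                 covariance = cov,
                 status = if (converged) "converged" else "not_converged",
                 message = res$message, spectrum = spec,
                 fitted = model(par)),
            class = "multipeak_fit")
}

#' Extract |chi| at the analysis band from a fit
#'
#' Homodyne detection measures `|chi|^2`, so the susceptibility magnitude
#' at the target band is the square root of the fitted peak height; the
#' sign is undetermined by construction (see [enumerate_signs()]).
#'
#' @param fit a [fit_multipeak()] result.
#' @param target_center analysis band position, cm^-1 (default the CH2
#'   asymmetric stretch at 2910).
#' @param window half-width of the acceptance window around
#'   `target_center`, cm^-1.
#' @return Nonnegative scalar `|chi|` in arbitrary units.
#' @export
extract_chi_magnitude <- function(fit, target_center = 2910, window = 10) {
  stopifnot(inherits(fit, "multipeak_fit"))
  d <- abs(fit$peaks$center - target_center)
  if (!any(d <= window)) {
    stop("no fitted peak within ", window, " cm^-1 of ", target_center)
  }
  sqrt(fit$peaks$amplitude[which.min(d)])
}

#' JSON fit report
#'
#' @param fit a [fit_multipeak()] result.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "multipeak_fit"))
  jsonlite::write_json(list(
    status = fit$status, baseline = fit$baseline,
    residual_norm = fit$residual_norm,
    polarization = fit$spectrum$polarization,
    provenance = fit$spectrum$provenance,
    peaks = fit$peaks), path, auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(path)
}
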