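# Voigt lineshape evaluation and multipeak fitting.

test_that("voigt profile matches its limiting cases and a convolution oracle", {
  x <- seq(2880, 2940, length.out = 50)

  # Lorentzian width -> 0 limit approaches the pure Gaussian
  g <- voigt_profile(x, voigt_peak(2910, 6, 1e-8, 2))
  gauss <- 2 * exp(-(x - 2910)^2 / (2 * 6^2))
  expect_lt(max(abs(g - gauss) / max(gauss)), 1e-6)

  # Gaussian width -> 0 limit approaches the pure Lorentzian
  l <- voigt_profile(x, voigt_peak(2910, 1e-8, 4, 2))
  lor <- 2 * 4^2 / ((x - 2910)^2 + 4^2)
  expect_lt(max(abs(l - lor) / max(lor)), 1e-6)

  # generic case against direct numerical convolution
  sig <- 5.3; gam <- 3.1
  v <- voigt_profile(x, voigt_peak(2910, sig, gam, 1))
  convolve_at <- function(xx) {
    stats::integrate(function(t) {
      exp(-t^2 / (2 * sig^2)) / (sig * sqrt(2 * pi)) *
        (gam / pi) / ((xx - 2910 - t)^2 + gam^2)
    }, -Inf, Inf, rel.tol = 1e-12)$value
  }
  conv <- vapply(x, convolve_at, numeric(1)) / convolve_at(2910)
  expect_lt(max(abs(v - conv)), 1e-6)

  # symmetric about the center
  expect_equal(voigt_profile(2910 + 7.3, voigt_peak(2910, 5, 3, 1)),
               voigt_profile(2910 - 7.3, voigt_peak(2910, 5, 3, 1)))
  expect_error(voigt_peak(2910, -1, 2, 1), "width")
  expect_error(voigt_peak(2910, 0, 0, 1), "width")
})

test_that("noiseless single-Voigt parameters are recovered exactly", {
  w <- seq(2850, 2970, by = 0.5)
  truth <- voigt_peak(2911.3, 6.2, 3.4, 50)
  spec <- spectrum(w, 5 + voigt_profile(w, truth))
  fit <- fit_multipeak(spec, list(voigt_peak(2908, 5, 5, 30)), baseline = 4)
  expect_equal(fit$status, "converged")
  expect_lt(abs(fit$peaks$center - truth$center) / truth$center, 1e-6)
  expect_lt(abs(fit$peaks$amplitude - truth$amplitude) / truth$amplitude, 1e-6)
  expect_lt(abs(fit$peaks$gaussian_width - truth$gaussian_width) /
              truth$gaussian_width, 1e-4)
  expect_lt(abs(fit$baseline - 5), 1e-5)
})

test_that("four CH-stretch centers are recovered within 1 cm^-1 at SNR 100", {
  w <- seq(2800, 3000, by = 1)
  peaks <- ch_stretch_peaks()
  truth <- lapply(seq_len(nrow(peaks)), function(q) {
    voigt_peak(peaks$center[q], peaks$gaussian_width[q],
               peaks$lorentzian_width[q], 100 * peaks$rel_amplitude[q])
  })
  clean <- 10 + Reduce(`+`, lapply(truth, function(p) voigt_profile(w, p)))
  set.seed(77)
  noisy <- clean + rnorm(length(w), sd = 100 / 100)   # peak SNR 100
  init <- lapply(seq_len(nrow(peaks)), function(q) {
    voigt_peak(peaks$center[q] + 2, 6, 6, 60 * peaks$rel_amplitude[q])
  })
  fit <- fit_multipeak(spectrum(w, noisy), init)
  expect_equal(fit$status, "converged")
  expect_true(all(abs(sort(fit$peaks$center) -
                        c(2860, 2910, 2930, 2960)) < 1))
})

test_that("degenerate spectra and missing peaks raise errors", {
  w <- seq(2800, 3000, by = 2)
  expect_error(fit_multipeak(spectrum(w, rep(3, length(w))),
                             list(voigt_peak(2910, 5, 3, 1))), "flat")
  expect_error(fit_multipeak(spectrum(w, rnorm(length(w))),
                             list(voigt_peak(2700, 5, 3, 1))), "outside")

  truth <- voigt_peak(2860, 6, 3, 20)
  spec <- spectrum(w, 1 + voigt_profile(w, truth))
  fit <- fit_multipeak(spec, list(voigt_peak(2862, 5, 3, 10)))
  expect_error(extract_chi_magnitude(fit, 2910, window = 10), "2910")
})

test_that("homodyne extraction follows the square-root scaling law", {
  w <- seq(2800, 3000, by = 1)
  chi <- 3.7
  make_fit <- function(chi_val) {
    spec <- spectrum(w, 2 + voigt_profile(w, voigt_peak(2910, 6, 3,
                                                        chi_val^2)))
    fit_multipeak(spec, list(voigt_peak(2909, 5, 4, 0.5 * chi_val^2)))
  }
  f1 <- make_fit(chi)
  expect_equal(extract_chi_magnitude(f1), chi, tolerance = 1e-6)
  # doubling |chi| quadruples the peak amplitude and doubles the extraction
  f2 <- make_fit(2 * chi)
  expect_equal(f2$peaks$amplitude / f1$peaks$amplitude, 4, tolerance = 1e-5)
  expect_equal(extract_chi_magnitude(f2), 2 * chi, tolerance = 1e-6)
  # zero-amplitude peak gives |chi| = 0
  fit0 <- f1
  fit0$peaks$amplitude[1] <- 0
  expect_equal(extract_chi_magnitude(fit0), 0)
})

test_that("adding a peak at the largest residual never hurts the fit", {
  w <- seq(2800, 3000, by = 1)
  truth <- list(voigt_peak(2910, 7, 4, 100), voigt_peak(2930, 8, 5, 45))
  set.seed(5)
  y <- 10 + Reduce(`+`, lapply(truth, function(p) voigt_profile(w, p))) +
    rnorm(length(w), sd = 0.7)
  spec <- spectrum(w, y)
  fit1 <- fit_multipeak(spec, list(voigt_peak(2910, 7, 4, 80)))
  worst <- w[which.max(abs(y - fit1$fitted))]
  fit2 <- fit_multipeak(spec, list(voigt_peak(2910, 7, 4, 80),
                                   voigt_peak(worst, 7, 4, 10)))
  expect_lte(fit2$residual_norm, fit1$residual_norm + 1e-8)
})

test_that("spectra round-trip through two-column CSV", {
  w <- seq(2800, 3000, by = 2)
  sp <- spectrum(w, runif(length(w)), polarization = "SSP")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(sp, path)
  back <- read_spectrum(path, polarization = "SSP")
  expect_equal(back$wavenumber, sp$wavenumber)
  expect_equal(back$intensity, sp$intensity)
})
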