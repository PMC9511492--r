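# The symmetry-reduced hyperpolarizability tensor and the twist-averaged
# forward map to the 8 lab-frame susceptibilities.

test_that("C7 expansion produces the 13-element degeneracy pattern", {
  # zero and single-element cases
  expect_equal(expand_c7(rep(0, 7)), expand_c7(rep(0, 7)) * 0)
  tz <- expand_c7(c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(sum(tz != 0), 1L)
  expect_equal(tz["z", "z", "z"], 1)

  # generic distinct components: 13 nonzero entries in 7 classes
  b <- hyperpolarizability_c7(1.1, 0.7, 0.5, 0.3, 0.21, 0.13, 0.07)
  tens <- expand_c7(b)
  expect_equal(sum(abs(tens) > 1e-12), 13L)
  expect_equal(c7_degeneracy_classes(tens), 7L)
  expect_equal(length(unique(abs(tens[abs(tens) > 1e-12]))), 7L)

  # degeneracy/antisymmetry pattern
  expect_equal(tens["x", "x", "z"], tens["y", "y", "z"])
  expect_equal(tens["x", "z", "x"], tens["y", "z", "y"])
  expect_equal(tens["z", "x", "x"], tens["z", "y", "y"])
  expect_equal(tens["x", "z", "y"], -tens["y", "z", "x"])
  expect_equal(tens["z", "x", "y"], -tens["z", "y", "x"])
  expect_equal(tens["x", "y", "z"], -tens["y", "x", "z"])

  expect_error(hyperpolarizability_c7(NaN, 0, 0, 0), "beta_zzz")
})

test_that("Euler matrix is a proper z-y'-z'' rotation", {
  expect_equal(euler_matrix(0, 0, 0), diag(3))
  expect_equal(euler_matrix(pi / 2, 0, 0),
               matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3),
               tolerance = 1e-12)
  R <- euler_matrix(0.6, 0.4, 1.1)
  expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
  # intrinsic composition order: Rz(phi) Ry(theta) Rz(psi)
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
  expect_equal(R, rz(0.6) %*% ry(0.4) %*% rz(1.1), tolerance = 1e-14)
})

test_that("zero tilt annihilates all 8 susceptibilities", {
  set.seed(101)
  worst <- 0
  for (i in 1:1000) {
    chi <- lab_susceptibilities(random_beta(), runif(1, 0, 2 * pi), 0)
    worst <- max(worst, max(abs(chi)))
  }
  expect_identical(worst, 0)   # exact, not just small
})

test_that("closed forms agree with brute-force twist quadrature", {
  set.seed(202)
  for (i in 1:100) {
    b <- random_beta()
    phi <- runif(1, 0, 2 * pi)
    theta <- runif(1, 0.05, pi - 0.05)
    cf <- lab_susceptibilities(b, phi, theta)
    or <- chi_quadrature_oracle(b, phi, theta, n_psi = 720)
    expect_lt(max(abs(cf - or)) / max(abs(or)), 1e-8)
  }
})

test_that("forward map is linear in beta and equivariant in phi", {
  set.seed(303)
  b <- random_beta()
  phi <- 0.7; theta <- 0.4
  chi <- lab_susceptibilities(b, phi, theta)
  for (c0 in c(-1, 0.5, 3)) {
    expect_equal(as.numeric(lab_susceptibilities(c0 * unclass(b), phi, theta)),
                 as.numeric(c0 * chi), tolerance = 1e-12)
  }

  # chi(phi + delta) equals the in-plane rank-3 rotation of chi(phi)
  for (i in 1:5) {
    delta <- runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(delta), sin(delta), -sin(delta), cos(delta)), 2)
    lab <- c(S = 1L, P = 2L)
    chi_arr <- array(0, c(2, 2, 2))
    for (p in POLARIZATIONS) {
      ijk <- lab[strsplit(p, "")[[1]]]
      chi_arr[ijk[1], ijk[2], ijk[3]] <- chi[p]
    }
    rotated <- array(0, c(2, 2, 2))
    for (I in 1:2) for (J in 1:2) for (K in 1:2) {
      s <- 0
      for (i2 in 1:2) for (j2 in 1:2) for (k2 in 1:2) {
        s <- s + rot[I, i2] * rot[J, j2] * rot[K, k2] * chi_arr[i2, j2, k2]
      }
      rotated[I, J, K] <- s
    }
    shifted <- lab_susceptibilities(b, phi + delta, theta)
    for (p in POLARIZATIONS) {
      ijk <- lab[strsplit(p, "")[[1]]]
      expect_equal(shifted[[p]], rotated[ijk[1], ijk[2], ijk[3]],
                   tolerance = 1e-10)
    }
  }
})

test_that("beta-dependence of the forward map has rank exactly 6", {
  set.seed(404)
  rows <- NULL
  for (i in 1:50) {
    phi <- runif(1, 0, 2 * pi); theta <- runif(1, 0.05, pi - 0.05)
    M <- sapply(1:7, function(j) {
      b <- numeric(7); b[j] <- 1
      as.numeric(chi_from_grouped(matrix(grouped_beta(b), 1), phi, theta))
    })
    rows <- rbind(rows, M)
  }
  sv <- svd(rows)$d
  expect_equal(sum(sv > 1e-8 * sv[1]), 6L)

  # at theta = 0 the dependence rank collapses to 0
  rows0 <- sapply(1:7, function(j) {
    b <- numeric(7); b[j] <- 1
    as.numeric(lab_susceptibilities(b, 1.1, 0))
  })
  expect_identical(max(abs(rows0)), 0)
})

test_that("two-sheet column space is independent of tilt (principal angles)", {
  # the theta-dependence of the stacked two-sheet forward map factors into
  # per-column scalars, so its column space is one fixed 6-dim subspace of
  # R^16 for every tilt: tilt is identified only through the amplitude
  # prior, never through span membership
  phi <- 0.9; N <- 1.7
  basis_at <- function(theta) {
    M1 <- sapply(1:6, function(j) {
      g <- numeric(6); g[j] <- 1
      as.numeric(chi_from_grouped(matrix(g, 1), phi, theta))
    })
    M2 <- sapply(1:6, function(j) {
      g <- numeric(6); g[j] <- 1
      as.numeric(chi_from_grouped(matrix(g, 1), phi + pi / 3, theta))
    })
    qr.Q(qr(rbind(M1, N * M2)))[, 1:6]
  }
  Q1 <- basis_at(0.3); Q2 <- basis_at(1.2)
  cosines <- svd(t(Q1) %*% Q2)$d
  expect_equal(cosines, rep(1, 6), tolerance = 1e-10)
})

test_that("grouping captures the full beta dependence (null-space probe)", {
  # beta vectors differing along (-1, 1, 1) on (xzy, zxy, xyz) are
  # indistinguishable at every orientation
  set.seed(505)
  b1 <- as.numeric(random_beta())
  t0 <- 0.83
  b2 <- b1 + t0 * c(0, 0, 0, 0, -1, 1, 1)
  expect_equal(as.numeric(grouped_beta(b1)), as.numeric(grouped_beta(b2)),
               tolerance = 1e-12)
  for (i in 1:20) {
    phi <- runif(1, 0, 2 * pi); theta <- runif(1, 0, pi)
    d <- lab_susceptibilities(b1, phi, theta) -
      lab_susceptibilities(b2, phi, theta)
    expect_lt(max(abs(d)), 1e-10)
  }
  # representative reconstruction hits the same susceptibilities
  g <- grouped_beta(b1)
  br <- beta_from_grouped(g)
  chi1 <- lab_susceptibilities(b1, 0.7, 0.9)
  chi2 <- lab_susceptibilities(br, 0.7, 0.9)
  expect_equal(as.numeric(chi1), as.numeric(chi2), tolerance = 1e-12)
})

test_that("susceptibility serialization round-trips via CSV and JSON", {
  chi <- lab_susceptibilities(random_beta(), 0.5, 0.4, sheet_id = "a")
  chi2 <- lab_susceptibilities(random_beta(), 1.5, 0.7, sheet_id = "b")
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_susceptibilities(list(a = chi, b = chi2), path)
    back <- read_susceptibilities(path)
    expect_equal(names(back), c("a", "b"))
    expect_equal(back$a, setNames(as.numeric(chi), POLARIZATIONS))
    expect_equal(back$b, setNames(as.numeric(chi2), POLARIZATIONS))
  }
})
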