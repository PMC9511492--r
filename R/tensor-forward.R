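#' @useDynLib vsfgorient, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd kmeans quantile median coef
#' @importFrom utils head read.csv write.csv modifyList
NULL

#' Polarization combination labels
#'
#' The eight measurable polarization combinations of a homodyne VSFG
#' microscope once the axial (Z) field component is neglected, in the fixed
#' package order. Label positions are (signal, upconversion, IR); `S` maps to
#' lab `X` and `P` to lab `Y`, so for example `SSP` addresses the lab-frame
#' susceptibility component XXY.
#'
#' @format Character vector of length 8.
#' @export
POLARIZATIONS <- c("SSS", "SSP", "SPS", "PSS", "SPP", "PSP", "PPS", "PPP")

BETA_NAMES <- c("beta_zzz", "beta_xxz", "beta_xzx", "beta_zxx",
                "beta_xzy", "beta_zxy", "beta_xyz")

GROUPED_NAMES <- c("g_zzz", "g_xxz", "g_xzx", "g_zxx",
                   "g_xzy_plus_zxy", "g_xyz_minus_zxy")

#' C7-symmetric molecular hyperpolarizability
#'
#' Constructs the set of 7 nondegenerate molecular-frame hyperpolarizability
#' components of a C7-symmetric unit. Any axis of 7-fold (indeed any >3-fold)
#' rotational symmetry forces the rank-3 tensor into the axially isotropic
#' form with 13 nonzero entries: `beta_zzz` alone, three doubly degenerate
#' achiral pairs (`beta_xxz = beta_yyz`, `beta_xzx = beta_yzy`,
#' `beta_zxx = beta_zyy`) and three antisymmetric chiral pairs
#' (`beta_xzy = -beta_yzx`, `beta_zxy = -beta_zyx`, `beta_xyz = -beta_yxz`).
#' Amplitudes are dimensionless; only ratios matter after normalization.
#'
#' @param beta_zzz,beta_xxz,beta_xzx,beta_zxx achiral components.
#' @param beta_xzy,beta_zxy,beta_xyz chiral components (default 0).
#' @return A named numeric vector of class `c7_beta`.
#' @examples
#' hyperpolarizability_c7(1, 0.5, 0.2, 0.1)
#' @export
hyperpolarizability_c7 <- function(beta_zzz, beta_xxz, beta_xzx, beta_zxx,
                                   beta_xzy = 0, beta_zxy = 0, beta_xyz = 0) {
  b <- c(beta_zzz, beta_xxz, beta_xzx, beta_zxx, beta_xzy, beta_zxy, beta_xyz)
  names(b) <- BETA_NAMES
  bad <- !is.finite(b)
  if (any(bad)) {
    stop("non-finite hyperpolarizability component: ",
         paste(BETA_NAMES[bad], collapse = ", "))
  }
  structure(b, class = "c7_beta")
}

as_c7_beta <- function(x) {
  if (inherits(x, "c7_beta")) return(x)
  x <- as.numeric(x)
  if (length(x) != 7) stop("a C7 hyperpolarizability needs 7 components")
  do.call(hyperpolarizability_c7, as.list(x))
}

#' Expand a C7 hyperpolarizability to the full rank-3 tensor
#'
#' Applies the C7 degeneracy and antisymmetry pattern to produce the full
#' 3 x 3 x 3 molecular-frame tensor. With generic nonzero components the
#' result has exactly 13 nonzero entries in 7 symmetry-distinct classes.
#'
#' @param beta a [hyperpolarizability_c7()] object (or 7-vector).
#' @return A 3 x 3 x 3 numeric array with dimnames `x`, `y`, `z`.
#' @export
expand_c7 <- function(beta) {
  beta <- as_c7_beta(beta)
  ax <- c("x", "y", "z")
  tens <- array(0, c(3, 3, 3), dimnames = list(ax, ax, ax))
  tens["z", "z", "z"] <- beta[["beta_zzz"]]
  tens["x", "x", "z"] <- beta[["beta_xxz"]]
  tens["y", "y", "z"] <- beta[["beta_xxz"]]
  tens["x", "z", "x"] <- beta[["beta_xzx"]]
  tens["y", "z", "y"] <- beta[["beta_xzx"]]
  tens["z", "x", "x"] <- beta[["beta_zxx"]]
  tens["z", "y", "y"] <- beta[["beta_zxx"]]
  tens["x", "z", "y"] <- beta[["beta_xzy"]]
  tens["y", "z", "x"] <- -beta[["beta_xzy"]]
  tens["z", "x", "y"] <- beta[["beta_zxy"]]
  tens["z", "y", "x"] <- -beta[["beta_zxy"]]
  tens["x", "y", "z"] <- beta[["beta_xyz"]]
  tens["y", "x", "z"] <- -beta[["beta_xyz"]]
  tens
}

#' Count degeneracy classes of an expanded C7 tensor
#'
#' Groups the nonzero entries of an expanded tensor into classes that are
#' equal up to sign, i.e. the equality/antisymmetry degeneracies of the C7
#' pattern. For generic distinct components this returns 7.
#'
#' @param tensor a 3 x 3 x 3 array as returned by [expand_c7()].
#' @param tol magnitudes below `tol` count as zero.
#' @return Integer: number of symmetry-distinct nonzero classes.
#' @export
c7_degeneracy_classes <- function(tensor, tol = 1e-12) {
  vals <- abs(as.numeric(tensor))
  vals <- vals[vals > tol]
  if (!length(vals)) return(0L)
  vals <- sort(vals)
  classes <- 1L
  for (i in seq_along(vals)[-1]) {
    if (vals[i] - vals[i - 1] > tol * max(1, vals[i])) classes <- classes + 1L
  }
  classes
}

#' Euler rotation matrix (z-y'-z'' intrinsic convention)
#'
#' Rotation taking molecular-frame coordinates into the lab frame with
#' in-plane rotation `phi` about z, tilt `theta` about the new y', and twist
#' `psi` about the final z''. As a matrix product on column vectors this is
#' `Rz(phi) %*% Ry(theta) %*% Rz(psi)`.
#'
#' @param phi,theta,psi angles in radians.
#' @return A proper 3 x 3 rotation matrix.
#' @export
euler_matrix <- function(phi, theta, psi = 0) {
  stopifnot(is.finite(phi), is.finite(theta), is.finite(psi))
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
  rz(phi) %*% ry(theta) %*% rz(psi)
}

#' Grouped hyperpolarizability terms
#'
#' The twist-averaged lab-frame susceptibilities depend on the 7
#' nondegenerate components only through 6 independent linear combinations:
#' the four achiral components individually, plus the chiral sums
#' `beta_xzy + beta_zxy` and `beta_xyz - beta_zxy`. The direction
#' `(-1, 1, 1)` on `(beta_xzy, beta_zxy, beta_xyz)` is annihilated by the
#' forward map.
#'
#' @param beta a [hyperpolarizability_c7()] object (or 7-vector).
#' @return A named numeric vector of length 6, class `grouped_beta`.
#' @export
grouped_beta <- function(beta) {
  beta <- as_c7_beta(beta)
  g <- c(beta[["beta_zzz"]], beta[["beta_xxz"]], beta[["beta_xzx"]],
         beta[["beta_zxx"]],
         beta[["beta_xzy"]] + beta[["beta_zxy"]],
         beta[["beta_xyz"]] - beta[["beta_zxy"]])
  names(g) <- GROUPED_NAMES
  structure(g, class = "grouped_beta")
}

#' Representative hyperpolarizability for grouped terms
#'
#' Right inverse of [grouped_beta()]: picks the representative with
#' `beta_zxy = 0`. Any other member of the fibre produces identical
#' lab-frame susceptibilities at every orientation.
#'
#' @param g a `grouped_beta` vector (or 6-vector).
#' @return A `c7_beta` object.
#' @export
beta_from_grouped <- function(g) {
  g <- as.numeric(g)
  if (length(g) != 6) stop("grouped hyperpolarizability has 6 components")
  hyperpolarizability_c7(g[1], g[2], g[3], g[4],
                         beta_xzy = g[5], beta_zxy = 0, beta_xyz = g[6])
}

#' Vectorized forward map from grouped terms
#'
#' Closed-form twist-averaged susceptibilities as a function of the 6
#' grouped hyperpolarizability terms, vectorized over orientations. The
#' closed forms are frozen from a one-off computer-algebra derivation
#' (uniform psi-average of the z-y'-z''-rotated C7 tensor restricted to
#' X/Y lab indices; for a C7 tensor the average equals the unaveraged
#' tensor because only the m = 0 azimuthal harmonic survives at rank 3).
#'
#' @param G n x 6 matrix of grouped terms (rows), see [grouped_beta()].
#' @param phi,theta orientation angles in radians, recycled to n.
#' @return An n x 8 matrix of susceptibilities, columns in
#'   [POLARIZATIONS] order.
#' @export
chi_from_grouped <- function(G, phi, theta) {
  G <- matrix(as.numeric(G), ncol = 6)
  n <- nrow(G)
  phi <- rep_len(phi, n)
  theta <- rep_len(theta, n)
  sp <- sin(phi); cp <- cos(phi)
  st <- sin(theta); ct <- cos(theta)
  st3 <- st^3
  acp <- st * (1 - st^2 * cp^2)   # achiral "own-index" factor, cos-phi flavour
  asp <- st * (1 - st^2 * sp^2)   # sin-phi flavour
  ch <- st * ct                   # chiral factor
  g1 <- G[, 1]; g2 <- G[, 2]; g3 <- G[, 3]; g4 <- G[, 4]
  g5 <- G[, 5]; g6 <- G[, 6]

  chi <- matrix(0, n, 8, dimnames = list(NULL, POLARIZATIONS))
  chi[, "SSS"] <- st3 * cp^3 * g1 + acp * cp * (g2 + g3 + g4)
  chi[, "SSP"] <- st3 * sp * cp^2 * (g1 - g3 - g4) + acp * sp * g2 +
    ch * cp * g5
  chi[, "SPS"] <- st3 * sp * cp^2 * (g1 - g2 - g4) + acp * sp * g3 +
    ch * cp * g6
  chi[, "PSS"] <- st3 * sp * cp^2 * (g1 - g2 - g3) + acp * sp * g4 -
    ch * cp * (g5 + g6)
  chi[, "SPP"] <- st3 * sp^2 * cp * (g1 - g2 - g3) + asp * cp * g4 +
    ch * sp * (g5 + g6)
  chi[, "PSP"] <- st3 * sp^2 * cp * (g1 - g2 - g4) + asp * cp * g3 -
    ch * sp * g6
  chi[, "PPS"] <- st3 * sp^2 * cp * (g1 - g3 - g4) + asp * cp * g2 -
    ch * sp * g5
  chi[, "PPP"] <- st3 * sp^3 * g1 + asp * sp * (g2 + g3 + g4)
  chi
}

#' Twist-averaged lab-frame susceptibilities
#'
#' Computes the 8 measurable second-order susceptibilities
#' `chi_IJK = < sum R_Ii R_Jj R_Kk beta_ijk >_psi` with lab indices
#' `I, J, K` restricted to X/Y (axial component neglected) and the twist
#' angle `psi` averaged uniformly over `[0, 2*pi)`. Closed forms are frozen
#' from a symbolic derivation; they agree with brute-force psi-quadrature of
#' the rotated full tensor (see [chi_quadrature_oracle()]).
#'
#' All 8 values vanish identically at `theta = 0`: every nonzero C7 tensor
#' entry carries at least one molecular z index, which at zero tilt has no
#' projection onto the lab X/Y plane.
#'
#' @param beta a [hyperpolarizability_c7()] object (or 7-vector).
#' @param phi in-plane rotation, radians.
#' @param theta tilt from the lab Z (surface normal), radians.
#' @param sheet_id optional identifier carried in the result.
#' @return A named numeric vector of length 8 (class `susceptibility_set`)
#'   ordered as [POLARIZATIONS], with attributes `frame = "lab"` and
#'   `sheet_id`.
#' @examples
#' b <- hyperpolarizability_c7(1, 0.4, 0.3, 0.2)
#' lab_susceptibilities(b, phi = 0.7, theta = 0.4)
#' @export
lab_susceptibilities <- function(beta, phi, theta, sheet_id = NA_character_) {
  beta <- as_c7_beta(beta)
  stopifnot(is.finite(phi), is.finite(theta))
  chi <- chi_from_grouped(matrix(grouped_beta(beta), 1), phi, theta)[1, ]
  structure(chi, class = "susceptibility_set", frame = "lab",
            sheet_id = sheet_id)
}

#' Brute-force twist-quadrature oracle for the forward map
#'
#' Independent check of the closed forms: rotates the full 27-element tensor
#' by the complete Euler matrix at `n_psi` equally spaced twist angles,
#' averages, and reads off the X/Y-restricted components.
#'
#' @inheritParams lab_susceptibilities
#' @param n_psi number of quadrature nodes over `[0, 2*pi)`.
#' @return Named numeric vector of length 8.
#' @export
chi_quadrature_oracle <- function(beta, phi, theta, n_psi = 720) {
  tens <- expand_c7(beta)
  acc <- array(0, c(3, 3, 3))
  psis <- seq(0, 2 * pi, length.out = n_psi + 1)[-(n_psi + 1)]
  for (psi in psis) {
    R <- euler_matrix(phi, theta, psi)
    rot <- array(0, c(3, 3, 3))
    for (I in 1:3) for (J in 1:3) for (K in 1:3) {
      s <- 0
      for (i in 1:3) for (j in 1:3) for (k in 1:3) {
        s <- s + R[I, i] * R[J, j] * R[K, k] * tens[i, j, k]
      }
      rot[I, J, K] <- s
    }
    acc <- acc + rot
  }
  acc <- acc / n_psi
  lab <- c(S = 1L, P = 2L)  # S -> X, P -> Y
  chi <- vapply(POLARIZATIONS, function(p) {
    ijk <- lab[strsplit(p, "")[[1]]]
    acc[ijk[1], ijk[2], ijk[3]]
  }, numeric(1))
  names(chi) <- POLARIZATIONS
  chi
}

#' Write / read susceptibility sets
#'
#' Long-format CSV (`sheet_id`, `polarization`, `value`) or an equivalent
#' JSON mirror keyed by sheet then polarization.
#'
#' @param x a named list of `susceptibility_set` (or plain named 8-vectors),
#'   one per sheet.
#' @param path output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly (for the writer); a named list of 8-vectors
#'   (for the reader).
#' @export
write_susceptibilities <- function(x, path) {
  if (inherits(x, "susceptibility_set") || (is.numeric(x) && length(x) == 8)) {
    x <- list(sheet1 = x)
  }
  if (is.null(names(x))) names(x) <- paste0("sheet", seq_along(x))
  rows <- do.call(rbind, lapply(names(x), function(id) {
    v <- as.numeric(x[[id]])
    stopifnot(length(v) == 8)
    data.frame(sheet_id = id, polarization = POLARIZATIONS, value = v)
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- lapply(x, function(v) as.list(stats::setNames(as.numeric(v), POLARIZATIONS)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_susceptibilities
#' @export
read_susceptibilities <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(lapply(obj, function(v) {
      v <- unlist(v)[POLARIZATIONS]
      stats::setNames(as.numeric(v), POLARIZATIONS)
    }))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sheet_id", "polarization", "value") %in% names(df)))
  out <- lapply(split(df, df$sheet_id), function(d) {
    stats::setNames(as.numeric(d$value[match(POLARIZATIONS, d$polarization)]),
                    POLARIZATIONS)
  })
  out[unique(df$sheet_id)]
}
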