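# Independent geometric consistency checks on a recovered tilt angle.

#' Tilt angle from stacking heights
#'
#' If a stack of height `h_upright` when standing straight is observed at
#' height `h_observed`, the implied uniform tilt is
#' `acos(h_observed / h_upright)`. For the supramolecular unit cell the
#' observed 2.9 nm against an upright 3.1 nm gives roughly 20 degrees.
#'
#' @param h_observed observed stacking height, nm.
#' @param h_upright upright (untilted) stacking height, nm.
#' @return Tilt angle in degrees.
#' @examples
#' tilt_from_heights(2.9, 3.1)   # ~20.7 deg
#' @export
tilt_from_heights <- function(h_observed, h_upright) {
  stopifnot(is.finite(h_observed), is.finite(h_upright),
            h_observed > 0, h_upright > 0)
  if (h_observed > h_upright) {
    stop("observed height exceeds the upright height: no real tilt")
  }
  acos(h_observed / h_upright) * 180 / pi
}

#' Rigid-cylinder packing model
#'
#' A deliberately simple steric model: supramolecular subunits are rigid
#' cylinders on a lattice of spacing `lattice_spacing`, all tilted by the
#' same angle along the same azimuth. Defaults describe a cyclodextrin-like
#' subunit on the 1.52 nm intersupramolecular lattice with an effective
#' packing diameter of 1.25 nm, calibrated once so that a 30 degree tilt is
#' sterically tight and tilts of 45-60 degrees collide.
#'
#' @param tilt_deg common tilt of the cylinders, degrees, in `[0, 90]`.
#' @param lattice_spacing nearest-neighbour lattice distance, nm.
#' @param diameter effective cylinder diameter, nm.
#' @param height cylinder height, nm.
#' @return A list of class `packing_model`.
#' @export
packing_model <- function(tilt_deg, lattice_spacing = 1.52,
                          diameter = 1.25, height = 1.5) {
  stopifnot(lattice_spacing > 0, diameter > 0, height > 0,
            tilt_deg >= 0, tilt_deg <= 90)
  structure(list(tilt_deg = tilt_deg, lattice_spacing = lattice_spacing,
                 diameter = diameter, height = height),
            class = "packing_model")
}

#' Steric feasibility of a tilted packing
#'
#' For parallel cylinders tilted along the lattice direction the
#' perpendicular distance between neighbouring axes is
#' `lattice_spacing * cos(tilt)`, so the inter-cylinder gap is
#' `lattice_spacing * cos(tilt) - diameter`: exactly
#' `lattice_spacing - diameter` upright, and monotonically shrinking with
#' tilt. Classification thresholds: `collision` if the gap is negative,
#' `tight` if below `tight_frac` of the diameter, else `clear`.
#'
#' @param model a [packing_model()].
#' @param tight_frac fraction of the diameter below which the packing is
#'   called tight.
#' @return A list with `class` (one of `"clear"`, `"tight"`,
#'   `"collision"`), `gap_nm`, and the inputs.
#' @export
steric_class <- function(model, tight_frac = 0.1) {
  stopifnot(inherits(model, "packing_model"))
  gap <- model$lattice_spacing * cos(model$tilt_deg * pi / 180) -
    model$diameter
  cls <- if (gap < 0) "collision" else if (gap < tight_frac * model$diameter) {
    "tight"
  } else "clear"
  list(class = cls, gap_nm = gap, tilt_deg = model$tilt_deg,
       lattice_spacing = model$lattice_spacing, diameter = model$diameter)
}
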