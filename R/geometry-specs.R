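#' Bifurcation design rules
#'
#' Parameters controlling how a parent branch divides into two daughters:
#' the diameter-law exponent, the carinal curvature ratio and the axial
#' position where the transition zone begins.
#'
#' The diameter law states \eqn{d_P^{x_n} = d_A^{x_n} + d_B^{x_n}} for parent
#' P and daughters A, B. The default exponent 3 is Murray's law; when a
#' measured morphometry table is supplied the law is used as a validation
#' diagnostic, not a constraint.
#'
#' @param x_n Dimensionless diameter-law exponent (> 0). Default 3.
#' @param c_c Carinal curvature ratio in (0, 1). Default 0.1.
#' @param transition_fraction Fraction of the parent axial length where the
#'   bifurcation transition zone starts, in (0, 1). Default 0.8.
#' @return An object of class `bifurcation_spec`.
#' @export
#' @examples
#' bifurcation_spec()
bifurcation_spec <- function(x_n = 3, c_c = 0.1, transition_fraction = 0.8) {
  stopifnot(is.numeric(x_n), length(x_n) == 1L, is.finite(x_n))
  if (x_n <= 0) stop("x_n must be > 0")
  if (!(c_c > 0 && c_c < 1)) stop("c_c must lie in (0, 1)")
  if (!(transition_fraction > 0 && transition_fraction < 1)) {
    stop("transition_fraction must lie in (0, 1)")
  }
  structure(list(x_n = x_n, c_c = c_c,
                 transition_fraction = transition_fraction),
            class = "bifurcation_spec")
}

#' Tracheal cross-section specification
#'
#' The trachea is modelled as a circular tube cut by a posterior plane,
#' reproducing the C-shape left by the pars membranacea. The effective
#' cross-sectional area of the cut disk is computed by [c_shape_area()].
#'
#' @param diameter Tracheal diameter in cm. Default 1.56.
#' @param posterior_cut_offset Distance of the posterior cutting plane from
#'   the centre, in cm; must lie in (0, diameter/2]. Default 0.65.
#' @param length Tracheal length in cm.
#' @return An object of class `trachea_spec` with the effective C-shape area
#'   in `csa_effective` (cm^2).
#' @export
#' @examples
#' trachea_spec()$csa_effective # about 1.835 cm^2
trachea_spec <- function(diameter = 1.56, posterior_cut_offset = 0.65,
                         length = 10) {
  stopifnot(diameter > 0, length > 0)
  if (posterior_cut_offset <= 0 || posterior_cut_offset > diameter / 2) {
    stop("posterior_cut_offset must lie in (0, diameter/2]")
  }
  spec <- structure(list(diameter = diameter,
                         posterior_cut_offset = posterior_cut_offset,
                         length = length),
                    class = "trachea_spec")
  spec$csa_effective <- c_shape_area(spec)
  spec
}

#' Cartilaginous ring specification
#'
#' Regularly spaced rings on the tracheal and main-bronchi walls. Dimensions
#' default to characteristic adult values (sub-millimetric depth, a few mm
#' step); all are overridable. Rings are geometric annotations: by default
#' they do not enter the flow or deposition computations.
#'
#' @param step_p Ring step (centre-to-centre spacing), mm.
#' @param width_L Ring width, mm; must be smaller than the step.
#' @param depth_d Ring depth (radial protrusion), mm, >= 0.
#' @param fillet_r Fillet radius, mm.
#' @param enabled Logical; when `FALSE`, [add_rings()] is a no-op.
#' @return An object of class `ring_spec`.
#' @export
ring_spec <- function(step_p = 5.4, width_L = 3.5, depth_d = 0.45,
                      fillet_r = 0.3, enabled = TRUE) {
  stopifnot(step_p > 0, width_L > 0, depth_d >= 0, fillet_r >= 0)
  if (width_L >= step_p) stop("ring width_L must be smaller than step_p")
  structure(list(step_p = step_p, width_L = width_L, depth_d = depth_d,
                 fillet_r = fillet_r, enabled = isTRUE(enabled)),
            class = "ring_spec")
}

#' Carinal radius of curvature
#'
#' The characteristic carinal radius at a bifurcation,
#' \eqn{r_c = (R_A + R_B)\,c_c}, where \eqn{R_A} and \eqn{R_B} are the
#' daughter radii and \eqn{c_c} the carinal curvature ratio.
#'
#' @param R_A,R_B Daughter branch radii, cm (>= 0).
#' @param c_c Carinal curvature ratio; defaults to 0.1.
#' @return Carinal radius in cm.
#' @export
#' @examples
#' carinal_radius(0.4, 0.4)      # 0.08
carinal_radius <- function(R_A, R_B, c_c = 0.1) {
  if (any(R_A < 0) || any(R_B < 0)) stop("daughter radii must be >= 0")
  (R_A + R_B) * c_c
}

#' Axial start of the bifurcation transition zone
#'
#' The transition zone of a parent branch starts at a fixed fraction of its
#' axial length (default 80%), measured from the branch start.
#'
#' @param parent A branch row (with a `length_cm` or `length` entry) or a
#'   single positive length in cm.
#' @param bif_spec A [bifurcation_spec()].
#' @return Axial position in cm from the branch start.
#' @export
#' @examples
#' transition_zone(1.0) # 0.8
transition_zone <- function(parent, bif_spec = bifurcation_spec()) {
  len <- if (is.numeric(parent)) parent
  else if (!is.null(parent$length_cm)) parent$length_cm
  else parent$length
  stopifnot(is.numeric(len), length(len) == 1L)
  if (len <= 0) stop("parent length must be > 0")
  bif_spec$transition_fraction * len
}

#' Effective area of the C-shaped tracheal cross-section
#'
#' Area of a disk of diameter `d` minus the circular segment beyond the
#' posterior chord at distance `offset` from the centre:
#' \eqn{A = \pi r^2 - (r^2 \arccos(h/r) - h\sqrt{r^2 - h^2})}.
#'
#' @param spec A [trachea_spec()], or a diameter in cm when `offset` is given.
#' @param offset Chord offset from centre in cm (ignored when `spec` is a
#'   `trachea_spec`).
#' @return Area in cm^2. When the offset reaches the radius the cut is
#'   degenerate (full circle) and a warning is emitted.
#' @export
#' @examples
#' c_shape_area(trachea_spec()) # ~1.835
c_shape_area <- function(spec, offset = NULL) {
  if (inherits(spec, "trachea_spec")) {
    d <- spec$diameter
    h <- spec$posterior_cut_offset
  } else {
    d <- spec
    h <- offset
  }
  stopifnot(d > 0, h >= 0)
  r <- d / 2
  if (h >= r) {
    if (h > r) stop("cut offset beyond the radius")
    warning("cut offset equals the radius: degenerate cut, full circle")
    return(pi * r^2)
  }
  segment <- r^2 * acos(h / r) - h * sqrt(r^2 - h^2)
  pi * r^2 - segment
}

#' Perimeter of the C-shaped tracheal cross-section
#'
#' Arc length of the retained portion of the circle plus the chord, used for
#' the hydraulic diameter of the cut section.
#'
#' @inheritParams c_shape_area
#' @return Perimeter in cm.
#' @export
c_shape_perimeter <- function(spec, offset = NULL) {
  if (inherits(spec, "trachea_spec")) {
    d <- spec$diameter
    h <- spec$posterior_cut_offset
  } else {
    d <- spec
    h <- offset
  }
  r <- d / 2
  if (h >= r) return(2 * pi * r)
  half_angle <- acos(h / r)        # half-angle of the removed arc
  arc <- (2 * pi - 2 * half_angle) * r
  chord <- 2 * sqrt(r^2 - h^2)
  arc + chord
}
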