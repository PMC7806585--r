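#' Ellipse geometry helpers
#'
#' Cross-sectional area, Ramanujan perimeter approximation and hydraulic
#' diameter (4 area / perimeter) of an elliptical tube section.
#'
#' @param a,b Semi-axes, cm.
#' @return Area in cm^2, perimeter in cm, hydraulic diameter in cm.
#' @export
ellipse_csa <- function(a, b) pi * a * b

#' @rdname ellipse_csa
#' @export
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' @rdname ellipse_csa
#' @export
ellipse_hydraulic_diameter <- function(a, b) {
  4 * ellipse_csa(a, b) / ellipse_perimeter(a, b)
}

upper_airway_section <- function(name, semi_axis_a, semi_axis_b, length) {
  stopifnot(semi_axis_a > 0, semi_axis_b > 0, length > 0)
  structure(list(name = name,
                 semi_axis_a = semi_axis_a,
                 semi_axis_b = semi_axis_b,
                 length = length,
                 csa = ellipse_csa(semi_axis_a, semi_axis_b),
                 hydraulic_diameter =
                   ellipse_hydraulic_diameter(semi_axis_a, semi_axis_b)),
            class = "upper_airway_section")
}

#' Characteristic upper-airway section table
#'
#' Elliptical-tube dimensions for the oral cavity, pharynx and larynx of a
#' characteristic adult cast, anchored at cross-sectional areas of 2.98,
#' 0.95 and 0.64 cm^2 (the glottal minimum). The attribute
#' `trachea_ref_diameter_cm` (1.9 cm) is the cast's upper-tracheal diameter
#' used by [build_upper_airway()] to scale the sections onto a target
#' trachea.
#'
#' @return Data frame with columns `name, semi_axis_a_cm, semi_axis_b_cm,
#'   length_cm` and attribute `trachea_ref_diameter_cm`.
#' @export
#' @examples
#' tab <- cheng_section_table()
#' pi * tab$semi_axis_a_cm * tab$semi_axis_b_cm  # 2.98 0.95 0.64
cheng_section_table <- function() {
  tab <- data.frame(
    name = c("oral_cavity", "pharynx", "larynx"),
    semi_axis_a_cm = c(1.4000, 0.7800, 0.55270),
    semi_axis_b_cm = c(2.98 / (pi * 1.4000),
                       0.95 / (pi * 0.7800),
                       0.64 / (pi * 0.55270)),
    length_cm = c(7.0, 6.0, 4.4),
    stringsAsFactors = FALSE
  )
  attr(tab, "trachea_ref_diameter_cm") <- 1.9
  tab
}

#' Build the scaled upper airway
#'
#' Rescales the section table by a single geometric factor so that the
#' tracheal end of the upper airway matches the target tracheal diameter
#' (`scale_mode = "match_trachea"`: factor = trachea diameter / the table's
#' `trachea_ref_diameter_cm`), or leaves it unchanged
#' (`scale_mode = "identity"`). Semi-axes and lengths scale linearly, so
#' every cross-sectional area scales with the square of the factor; the
#' larynx must remain the minimum-CSA section.
#'
#' @param section_table Table as from [cheng_section_table()]; rows must be
#'   ordered mouth to glottis with non-increasing CSA.
#' @param trachea A [trachea_spec()] giving the target diameter.
#' @param scale_mode `"match_trachea"` (default) or `"identity"`.
#' @return List of `upper_airway_section` objects (oral cavity, pharynx,
#'   larynx) with the applied factor in attribute `scale_factor`.
#' @export
#' @examples
#' ua <- build_upper_airway(cheng_section_table(), trachea_spec())
#' attr(ua, "scale_factor") # 1.56 / 1.9
build_upper_airway <- function(section_table, trachea = trachea_spec(),
                               scale_mode = c("match_trachea", "identity")) {
  scale_mode <- match.arg(scale_mode)
  tab <- as.data.frame(section_table)
  need <- c("name", "semi_axis_a_cm", "semi_axis_b_cm", "length_cm")
  if (!all(need %in% names(tab))) stop("section table lacks required columns")
  csa <- pi * tab$semi_axis_a_cm * tab$semi_axis_b_cm
  if (is.unsorted(rev(csa), strictly = FALSE)) {
    stop("non-monotone section ordering: CSA must not increase mouth to glottis")
  }
  if (tab$name[nrow(tab)] != "larynx") {
    stop("last (glottal) section must be the larynx")
  }
  s <- switch(scale_mode,
              identity = 1,
              match_trachea = {
                ref <- attr(section_table, "trachea_ref_diameter_cm")
                if (is.null(ref)) stop("section table lacks trachea_ref_diameter_cm")
                trachea$diameter / ref
              })
  if (s <= 0) stop("scale factor must be positive")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    upper_airway_section(tab$name[i],
                         tab$semi_axis_a_cm[i] * s,
                         tab$semi_axis_b_cm[i] * s,
                         tab$length_cm[i] * s)
  })
  names(out) <- tab$name
  csa_out <- vapply(out, `[[`, 0, "csa")
  if (which.min(csa_out) != length(out)) {
    stop("larynx is not the minimum-CSA section after scaling")
  }
  attr(out, "scale_factor") <- s
  class(out) <- "upper_airway"
  out
}

#' @export
print.upper_airway <- function(x, ...) {
  cat("upper airway (scale factor ", format(attr(x, "scale_factor")),
      "):\n", sep = "")
  for (s in x) {
    cat(sprintf("  %-12s a=%.3f b=%.3f cm, L=%.2f cm, CSA=%.3f cm2, Dh=%.3f cm\n",
                s$name, s$semi_axis_a, s$semi_axis_b, s$length, s$csa,
                s$hydraulic_diameter))
  }
  invisible(x)
}
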