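#' Basal radius of a stem or branch
#'
#' A stem or branch of length `length` has basal radius `b * length`,
#' except that the radius never drops below the tip radius `r_tip`: short
#' segments are cylinders of radius `r_tip` rather than cones thinner than
#' their own tip.
#'
#' @param length Segment length in cm (non-negative, vectorised).
#' @param b Basal-radius-to-length ratio (dimensionless, > 0).
#' @param r_tip Tip radius in cm (> 0), the floor for the returned radius.
#'
#' @return Basal radius in cm, always `>= r_tip`.
#' @examples
#' basal_radius(20, 0.0075, 0.1)  # 0.15
#' basal_radius(10, 0.0075, 0.1)  # clamped to 0.1
#' @export
basal_radius <- function(length, b, r_tip) {
  stopifnot(b > 0, r_tip > 0)
  if (any(length < 0)) stop("'length' must be non-negative")
  pmax(b * length, r_tip)
}

#' Volume of a truncated-cone (frustum) segment
#'
#' Closed form \eqn{V = \pi L (r_1^2 + r_1 r_2 + r_2^2) / 3}; reduces to the
#' cylinder volume \eqn{\pi r^2 L} when the two radii are equal.
#'
#' @param length Segment length in cm (non-negative, vectorised).
#' @param r_base Basal radius in cm.
#' @param r_tip_seg Tip radius in cm; must satisfy `r_base >= r_tip_seg > 0`.
#'
#' @return Volume in cm^3.
#' @examples
#' frustum_volume(10, 0.1, 0.1)        # cylinder: pi * 0.01 * 10
#' frustum_volume(20, 0.15, 0.1)
#' @export
frustum_volume <- function(length, r_base, r_tip_seg) {
  check_segment(length, r_base, r_tip_seg)
  pi * length * (r_base^2 + r_base * r_tip_seg + r_tip_seg^2) / 3
}

#' Lateral (bark) surface area of a truncated-cone segment
#'
#' Slant-height form \eqn{A = \pi (r_1 + r_2) \sqrt{L^2 + (r_1 - r_2)^2}}.
#' End caps are excluded: "surface area" means the sides of stems and
#' branches, the bark/epidermis. For the slenderness ratios used here
#' (b around 0.0075) the slant correction relative to
#' \eqn{\pi (r_1 + r_2) L} is below 1e-5.
#'
#' @inheritParams frustum_volume
#' @return Lateral area in cm^2.
#' @examples
#' frustum_lateral_area(10, 0.1, 0.1)  # cylinder: 2 * pi * 0.1 * 10
#' @export
frustum_lateral_area <- function(length, r_base, r_tip_seg) {
  check_segment(length, r_base, r_tip_seg)
  pi * (r_base + r_tip_seg) * sqrt(length^2 + (r_base - r_tip_seg)^2)
}

# Segment invariants: non-negative length, r_base >= r_tip_seg > 0.
check_segment <- function(length, r_base, r_tip_seg) {
  if (any(length < 0)) stop("segment 'length' must be non-negative")
  if (any(r_tip_seg <= 0)) stop("segment 'r_tip_seg' must be positive")
  if (any(r_base < r_tip_seg)) stop("segment must have r_base >= r_tip_seg")
  invisible(TRUE)
}
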