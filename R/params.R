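#' Architectural parameter set for a plant
#'
#' Bundles the parameters of the recursive branching model. The defaults are
#' the reference values used throughout: `a = 2` child branches per parent per
#' branching step, child/parent length ratio `p = 0.5`, branching threshold
#' `l_min = 20` cm, tip radius `r_tip = 0.1` cm, and basal-radius-to-length
#' ratio `b = 0.0075`. A tree is `n = 1`; a shrub is the same architecture
#' with `n > 1` independent stems.
#'
#' @param n Number of stems (integer >= 1).
#' @param a Number of child branches added to each parent per branching step
#'   (integer >= 0). The parent's own tip is not counted as a child.
#' @param p Child/parent length ratio, `0 < p < 1` (guarantees the branching
#'   recursion terminates).
#' @param l_min Length (cm) at which a stem or branch carries its full
#'   complement of children; children begin to grow at `(2/3) * l_min`.
#' @param r_tip Tip radius (cm) of every stem and branch.
#' @param b Basal-radius-to-length ratio (used in `radius_mode =
#'   "proportional"`; also the taper of each segment in either mode's
#'   volume/area formulas via the basal-radius rule).
#' @param radius_mode `"proportional"` for `r_base = max(b * length, r_tip)`,
#'   or `"niklas_spatz"` to derive the basal radius by inverting the
#'   height-diameter relation `L = k5 * D^(2/3) - k6` (same `r_tip` floor).
#' @param ns A [niklas_spatz_params()] object; required when
#'   `radius_mode = "niklas_spatz"`.
#'
#' @return An object of class `plant_params`.
#' @examples
#' tree  <- plant_params(n = 1)
#' shrub <- plant_params(n = 5)
#' @seealso [plant_volume()], [height_from_volume()], [compare_trait()]
#' @export
plant_params <- function(n = 1L, a = 2L, p = 0.5, l_min = 20, r_tip = 0.1,
                         b = 0.0075,
                         radius_mode = c("proportional", "niklas_spatz"),
                         ns = NULL) {
  radius_mode <- match.arg(radius_mode)
  stopifnot(
    length(n) == 1, n >= 1, n == as.integer(n),
    length(a) == 1, a >= 0, a == as.integer(a),
    length(p) == 1, p > 0, p < 1,
    length(l_min) == 1, l_min > 0,
    length(r_tip) == 1, r_tip > 0,
    length(b) == 1, b > 0
  )
  if (radius_mode == "niklas_spatz") {
    if (!inherits(ns, "niklas_spatz_params"))
      stop("radius_mode = 'niklas_spatz' requires 'ns = niklas_spatz_params(...)'")
  } else {
    ns <- NULL
  }
  structure(
    list(n = as.integer(n), a = as.integer(a), p = p, l_min = l_min,
         r_tip = r_tip, b = b, radius_mode = radius_mode, ns = ns),
    class = "plant_params"
  )
}

#' @export
print.plant_params <- function(x, ...) {
  form <- if (x$n == 1L) "tree (single stem)" else sprintf("shrub (%d stems)", x$n)
  cat("Plant architecture:", form, "\n")
  cat(sprintf("  a = %d children/parent, p = %g, l_min = %g cm\n",
              x$a, x$p, x$l_min))
  cat(sprintf("  r_tip = %g cm, b = %g, radius mode: %s\n",
              x$r_tip, x$b, x$radius_mode))
  if (!is.null(x$ns))
    cat(sprintf("  Niklas-Spatz: k5 = %g, k6 = %g\n", x$ns$k5, x$ns$k6))
  invisible(x)
}

#' Height-diameter relation constants (Niklas-Spatz form)
#'
#' Constants of the empirical relation `L = k5 * D^(2/3) - k6` between stem
#' length L (cm) and basal diameter D (cm). The source relation's constants
#' are species/data dependent and must be supplied by the user; no defaults
#' are provided.
#'
#' @param k5 Coefficient (> 0), units cm^(1/3).
#' @param k6 Offset (cm, >= 0).
#' @return An object of class `niklas_spatz_params`.
#' @examples
#' ns <- niklas_spatz_params(k5 = 90, k6 = 10)
#' stem_length_from_diameter_ns(8, niklas_spatz_params(1, 0))  # 4
#' @export
niklas_spatz_params <- function(k5, k6 = 0) {
  stopifnot(length(k5) == 1, k5 > 0, length(k6) == 1, k6 >= 0)
  structure(list(k5 = k5, k6 = k6), class = "niklas_spatz_params")
}

#' @export
print.niklas_spatz_params <- function(x, ...) {
  cat(sprintf("Height-diameter relation: L = %g * D^(2/3) - %g\n", x$k5, x$k6))
  invisible(x)
}

#' Stem length from basal diameter (and the inverse)
#'
#' `stem_length_from_diameter_ns()` evaluates `L = k5 * D^(2/3) - k6`,
#' clamped at zero; `diameter_from_stem_length_ns()` inverts it,
#' `D = ((L + k6) / k5)^(3/2)`.
#'
#' @param D Basal diameter in cm (> 0, vectorised).
#' @param L Stem length in cm (>= 0, vectorised).
#' @param ns A [niklas_spatz_params()] object.
#' @return Length (cm), respectively diameter (cm).
#' @export
stem_length_from_diameter_ns <- function(D, ns) {
  stopifnot(inherits(ns, "niklas_spatz_params"))
  if (any(D <= 0)) stop("'D' must be positive")
  pmax(ns$k5 * D^(2 / 3) - ns$k6, 0)
}

#' @rdname stem_length_from_diameter_ns
#' @export
diameter_from_stem_length_ns <- function(L, ns) {
  stopifnot(inherits(ns, "niklas_spatz_params"))
  if (any(L < 0)) stop("'L' must be non-negative")
  ((L + ns$k6) / ns$k5)^(3 / 2)
}
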