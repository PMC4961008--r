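#' Spatial path of a leaning or uprising stem
#'
#' Two path shapes, parameterised by arc length `s` from the base. A
#' `"straight"` stem leans at a fixed angle from the vertical, so its
#' horizontal offset is `x(s) = s * sin(angle)`. An `"uprising"` stem (the
#' shape of many multi-stemmed trees) leans at `lean_angle` until its
#' horizontal offset reaches `horizontal_cutoff`, then turns and grows
#' straight upward, so `x(s)` is capped at the cutoff; the bend is a sharp
#' corner.
#'
#' @param kind `"straight"` or `"uprising"`.
#' @param lean_angle Angle from the vertical in degrees, `0 <= angle < 90`.
#' @param total_length Arc length of the stem in m (> 0).
#' @param horizontal_cutoff Horizontal offset (m) at which an uprising stem
#'   turns vertical; required for `kind = "uprising"`.
#' @return An object of class `stem_path`.
#' @examples
#' stem_path("straight", 45, total_length = 10)
#' stem_path("uprising", 20, total_length = 10, horizontal_cutoff = 1)
#' @export
stem_path <- function(kind = c("straight", "uprising"), lean_angle,
                      total_length, horizontal_cutoff = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(lean_angle) == 1, lean_angle >= 0, lean_angle < 90,
            length(total_length) == 1, total_length > 0)
  if (kind == "uprising") {
    if (is.null(horizontal_cutoff) || horizontal_cutoff <= 0)
      stop("'horizontal_cutoff' must be a positive distance (m) for uprising paths")
  } else {
    horizontal_cutoff <- NULL
  }
  structure(list(kind = kind, lean_angle = lean_angle,
                 total_length = total_length,
                 horizontal_cutoff = horizontal_cutoff),
            class = "stem_path")
}

#' @export
print.stem_path <- function(x, ...) {
  cat(sprintf("%s stem path: %g m at %g deg from vertical", x$kind,
              x$total_length, x$lean_angle))
  if (!is.null(x$horizontal_cutoff))
    cat(sprintf(", vertical beyond %g m horizontal offset", x$horizontal_cutoff))
  cat("\n")
  invisible(x)
}

#' Horizontal offset along a stem path
#'
#' @param s Arc length from the base in m (vectorised), `0 <= s <=
#'   total_length`.
#' @param path A [stem_path()] object.
#' @return Horizontal offset x(s) in m.
#' @export
horizontal_offset <- function(s, path) {
  stopifnot(inherits(path, "stem_path"))
  if (any(s < 0 | s > path$total_length))
    stop("'s' must lie within [0, total_length]")
  x <- s * sin(path$lean_angle * pi / 180)
  if (path$kind == "uprising") x <- pmin(x, path$horizontal_cutoff)
  x
}

#' Conical taper specification (SI units)
#'
#' Linear radius profile from `max(b * total_length, r_tip)` at the base to
#' `r_tip` at the tip, the metre-scale version of the proportional
#' basal-radius rule.
#'
#' @param b Basal-radius-to-length ratio (dimensionless).
#' @param r_tip Tip radius in m (default 0.001 m = 0.1 cm).
#' @return An object of class `taper_spec`.
#' @export
taper_conical <- function(b = 0.0075, r_tip = 0.001) {
  stopifnot(b > 0, r_tip > 0)
  structure(list(kind = "conical", b = b, r_tip = r_tip), class = "taper_spec")
}

#' Niklas-Spatz taper specification (SI units)
#'
#' Radius profile derived from the height-diameter relation: at arc position
#' `s` the remaining length above is `L - s`, and the local diameter solves
#' `L - s = k5 * D^(2/3) - k6`, i.e. `D(s) = ((L - s + k6) / k5)^(3/2)`.
#' Constants must be supplied in metre-consistent units.
#'
#' @param k5 Coefficient (> 0), units m^(1/3).
#' @param k6 Offset in m (>= 0).
#' @return An object of class `taper_spec`.
#' @export
taper_niklas_spatz <- function(k5, k6 = 0) {
  stopifnot(k5 > 0, k6 >= 0)
  structure(list(kind = "niklas_spatz", k5 = k5, k6 = k6), class = "taper_spec")
}

#' A tapered stem ready for bending-moment integration
#'
#' @param path A [stem_path()] object.
#' @param taper A `taper_spec` from [taper_conical()] or
#'   [taper_niklas_spatz()].
#' @param wood_density Green wood density in kg m^-3 (default 600).
#' @param gravity Gravitational acceleration in m s^-2 (default 9.81).
#' @return An object of class `tapered_stem`.
#' @examples
#' ts <- tapered_stem(stem_path("straight", 30, total_length = 5))
#' bending_moment(ts)
#' @export
tapered_stem <- function(path, taper = taper_conical(),
                         wood_density = 600, gravity = 9.81) {
  stopifnot(inherits(path, "stem_path"), inherits(taper, "taper_spec"),
            wood_density > 0, gravity > 0)
  structure(list(path = path, taper = taper,
                 wood_density = wood_density, gravity = gravity),
            class = "tapered_stem")
}

#' @export
print.tapered_stem <- function(x, ...) {
  print(x$path)
  cat(sprintf("  taper: %s, density %g kg/m^3, g = %g m/s^2\n",
              x$taper$kind, x$wood_density, x$gravity))
  invisible(x)
}

#' Radius profile along a tapered stem
#'
#' @param s Arc length from the base in m (vectorised), within
#'   `[0, total_length]`.
#' @param stem A [tapered_stem()] object.
#' @return Radius in m.
#' @export
radius_profile <- function(s, stem) {
  stopifnot(inherits(stem, "tapered_stem"))
  L <- stem$path$total_length
  if (any(s < 0 | s > L)) stop("'s' must lie within [0, total_length]")
  tp <- stem$taper
  if (tp$kind == "conical") {
    r0 <- max(tp$b * L, tp$r_tip)
    r0 + (tp$r_tip - r0) * s / L
  } else {
    ((L - s + tp$k6) / tp$k5)^(3 / 2) / 2
  }
}

#' Gravity-loaded bending moment about the stem base
#'
#' The magnitude of the bending moment exerted by the stem's own distributed
#' mass about its base, \deqn{M = \int_0^L \rho\, g\, \pi\, r(s)^2\, x(s)\,
#' ds,} where `x(s)` is the horizontal offset of arc position `s`. Branches
#' and foliage are excluded, so the values are lower bounds for a real
#' crowned stem. Evaluated by adaptive quadrature ([stats::integrate()]),
#' with the domain split at the uprising corner so the integrand stays smooth
#' on each piece.
#'
#' @param stem A [tapered_stem()] object.
#' @param rel_tol Relative quadrature tolerance (default 1e-10).
#' @return Bending moment in N m (0 exactly for a vertical stem).
#' @export
bending_moment <- function(stem, rel_tol = 1e-10) {
  stopifnot(inherits(stem, "tapered_stem"))
  path <- stem$path
  if (path$lean_angle == 0 && path$kind == "straight") return(0)
  integrand <- function(s)
    stem$wood_density * stem$gravity * pi * radius_profile(s, stem)^2 *
      horizontal_offset(s, path)
  L <- path$total_length
  cuts <- L
  if (path$kind == "uprising") {
    sin_a <- sin(path$lean_angle * pi / 180)
    if (sin_a > 0) {
      corner <- path$horizontal_cutoff / sin_a
      if (corner < L) cuts <- c(corner, L)
    }
  }
  lo <- 0
  total <- 0
  for (hi in cuts) {
    total <- total + stats::integrate(integrand, lo, hi, rel.tol = rel_tol,
                                      abs.tol = 0)$value
    lo <- hi
  }
  total
}

#' Bending-moment curves over stem length
#'
#' Evaluates [bending_moment()] for each scenario across a grid of stem
#' lengths, in long form — the numeric content of the moment-versus-length
#' comparison of straight leaning stems with the uprising stem shape.
#'
#' @param lengths Vector of stem lengths in m (> 0).
#' @param scenarios Named list of functions taking a total length (m) and
#'   returning a [stem_path()]. Default: straight stems at 15, 30 and 45
#'   degrees plus an uprising stem at 20 degrees with a 1 m cutoff.
#' @param taper,wood_density,gravity Passed to [tapered_stem()].
#' @return A data.frame with columns `length_m`, `path_label`, `moment_Nm`.
#' @export
bending_moment_curve <- function(lengths,
                                 scenarios = default_bending_scenarios(),
                                 taper = taper_conical(),
                                 wood_density = 600, gravity = 9.81) {
  stopifnot(all(lengths > 0))
  rows <- lapply(names(scenarios), function(lab) {
    data.frame(
      length_m = lengths,
      path_label = lab,
      moment_Nm = vapply(lengths, function(L) {
        bending_moment(tapered_stem(scenarios[[lab]](L), taper,
                                    wood_density, gravity))
      }, numeric(1))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname bending_moment_curve
#' @export
default_bending_scenarios <- function() {
  list(
    straight_15 = function(L) stem_path("straight", 15, L),
    straight_30 = function(L) stem_path("straight", 30, L),
    straight_45 = function(L) stem_path("straight", 45, L),
    uprising_20 = function(L) stem_path("uprising", 20, L, horizontal_cutoff = 1)
  )
}
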