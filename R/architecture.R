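#' Length of a child branch given its parent's length
#'
#' Children appear continuously: a parent below `(2/3) * l_min` carries no
#' children; between `(2/3) * l_min` and `l_min` the child length ramps
#' linearly from 0 up to `p * l_min`; from `l_min` onward children keep the
#' fixed proportion `p` of their parent. The ramp makes total plant volume a
#' continuous function of stem length (otherwise branches of length
#' `p * l_min` would appear out of nowhere).
#'
#' @param parent_length Parent stem/branch length in cm (>= 0, vectorised).
#' @param p Child/parent length ratio.
#' @param l_min Branching threshold length in cm.
#' @return Child length in cm (0 when the parent is too short).
#' @examples
#' child_length(10, 0.5, 20)  # 0, below the ramp
#' child_length(20, 0.5, 20)  # 10 = p * l_min
#' child_length(40, 0.5, 20)  # 20 = p * parent
#' @export
child_length <- function(parent_length, p, l_min) {
  if (any(parent_length < 0)) stop("'parent_length' must be non-negative")
  lo <- (2 / 3) * l_min
  ramp <- p * l_min * (parent_length - lo) / (l_min - lo)
  ifelse(parent_length < lo, 0,
         ifelse(parent_length < l_min, ramp, p * parent_length))
}

# Basal radius of a segment under the active radius mode.
segment_radius <- function(length, params) {
  if (params$radius_mode == "proportional") {
    basal_radius(length, params$b, params$r_tip)
  } else {
    pmax(diameter_from_stem_length_ns(length, params$ns) / 2, params$r_tip)
  }
}

#' Enumerate the branching generations of one stem
#'
#' Depth 0 is the stem itself; each subsequent generation applies
#' [child_length()] to the previous one and multiplies the per-stem segment
#' count by `a`. The recursion stops when the child length reaches 0, which
#' the ramp guarantees in finitely many steps.
#'
#' @param stem_length Stem length in cm (>= 0, scalar).
#' @param params A [plant_params()] object.
#' @return A data.frame with one row per generation and columns `depth`,
#'   `count_per_stem` (= `a^depth`), `length` (cm) and `r_base` (cm).
#' @examples
#' enumerate_generations(80, plant_params())  # lengths 80,40,20,10; counts 1,2,4,8
#' @export
enumerate_generations <- function(stem_length, params) {
  stopifnot(inherits(params, "plant_params"), length(stem_length) == 1,
            stem_length >= 0)
  lengths <- numeric(0)
  L <- stem_length
  while (L > 0) {
    lengths <- c(lengths, L)
    L <- child_length(L, params$p, params$l_min)
  }
  if (length(lengths) == 0) lengths <- stem_length  # zero-length stem
  depth <- seq_along(lengths) - 1L
  data.frame(
    depth = depth,
    count_per_stem = params$a^depth,
    length = lengths,
    r_base = segment_radius(lengths, params)
  )
}

# Sum count * f(length, r_base) over generations, times n stems.
sum_over_plant <- function(stem_length, params, f) {
  vapply(stem_length, function(h) {
    if (h <= 0) return(0)
    g <- enumerate_generations(h, params)
    params$n * sum(g$count_per_stem * f(g$length, g$r_base))
  }, numeric(1))
}

#' Total above-ground woody volume of a plant
#'
#' Sum of frustum volumes over all stems and branches: `n` identical stems,
#' each carrying the generations from [enumerate_generations()]. Strictly
#' increasing and continuous in `stem_length` (including across the ramp
#' joints at `(2/3) * l_min` and `l_min`).
#'
#' @param stem_length Stem length in cm (>= 0, vectorised).
#' @param params A [plant_params()] object.
#' @return Volume in cm^3.
#' @export
plant_volume <- function(stem_length, params) {
  sum_over_plant(stem_length, params, function(L, r)
    frustum_volume(L, r, pmin(params$r_tip, r)))
}

#' Total bark (epidermis) surface area of a plant
#'
#' Sum of truncated-cone lateral areas over all stems and branches. The same
#' quantity proxies the vascular-cambium area and the stem-photosynthetic
#' area, which differ only by interpretation.
#'
#' @inheritParams plant_volume
#' @return Lateral surface area in cm^2.
#' @export
plant_surface_area <- function(stem_length, params) {
  sum_over_plant(stem_length, params, function(L, r)
    frustum_lateral_area(L, r, pmin(params$r_tip, r)))
}

#' Total cross-sectional area at the stem base(s)
#'
#' `n * pi * r_base(stem_length)^2`, the model's proxy for total sapwood
#' area at ground level.
#'
#' @inheritParams plant_volume
#' @return Area in cm^2.
#' @export
basal_cross_section_total <- function(stem_length, params) {
  if (any(stem_length < 0)) stop("'stem_length' must be non-negative")
  params$n * pi * segment_radius(stem_length, params)^2
}

#' Sprouting area on the lower part of the stems
#'
#' Lateral area of the basal fraction (default the lower 25%) of each stem
#' only — the zone where basal resprouting buds sit. Branches are excluded.
#'
#' @inheritParams plant_volume
#' @param stem_fraction Fraction of each stem's length counted, in `(0, 1]`.
#' @return Area in cm^2.
#' @export
sprout_area <- function(stem_length, params, stem_fraction = 0.25) {
  if (length(stem_fraction) != 1 || stem_fraction <= 0 || stem_fraction > 1)
    stop("'stem_fraction' must be in (0, 1]")
  vapply(stem_length, function(h) {
    if (h <= 0) return(0)
    r1 <- segment_radius(h, params)
    r_top <- pmin(params$r_tip, r1)
    # radius at the cut, linear taper along the stem
    r2 <- r1 + (r_top - r1) * stem_fraction
    params$n * frustum_lateral_area(stem_fraction * h, r1, r2)
  }, numeric(1))
}

#' Number of twigs (outermost branching generation)
#'
#' `n` times the per-stem count of the deepest generation with positive
#' length; equals `n` when the stems carry no branches yet. Non-decreasing in
#' stem length, jumping by factors of `a` as new generations appear.
#'
#' @inheritParams plant_volume
#' @return Integer twig count.
#' @examples
#' twig_count(80, plant_params())       # 8 = a^3
#' twig_count(10, plant_params(n = 3))  # 3, the bare stems
#' @export
twig_count <- function(stem_length, params) {
  vapply(stem_length, function(h) {
    if (h <= 0) return(params$n * 1)
    g <- enumerate_generations(h, params)
    params$n * g$count_per_stem[nrow(g)]
  }, numeric(1))
}
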