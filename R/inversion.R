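#' Solve stem length (height) from above-ground woody volume
#'
#' Inverts the monotone map [plant_volume()] by bracketing root finding:
#' the bracket is grown by geometric expansion until it contains the target
#' volume, Brent's method ([stats::uniroot()]) locates the root, and a short
#' bisection polish enforces the volume-residual tolerance. The volume
#' function is continuous and strictly increasing (piecewise smooth with
#' kinks at the ramp joints), so the solution is unique and derivative-free
#' bracketing is robust.
#'
#' @param v Target volume in cm^3 (> 0, vectorised).
#' @param params A [plant_params()] object.
#' @param rel_tol Relative tolerance on the volume residual,
#'   `|V(h) - v| / v` (default 1e-12).
#' @return Stem length(s) h in cm with `plant_volume(h, params)` within
#'   `rel_tol` of `v`.
#' @examples
#' tree <- plant_params()
#' h <- height_from_volume(500, tree)
#' plant_volume(h, tree)  # 500
#' @export
height_from_volume <- function(v, params, rel_tol = 1e-12) {
  if (any(v <= 0)) stop("'v' must be positive")
  vapply(v, function(vi) {
    f <- function(h) plant_volume(h, params) - vi
    lo <- 0
    hi <- 1
    while (f(hi) < 0) {
      lo <- hi
      hi <- hi * 2
      if (hi > 1e12) stop("failed to bracket the volume ", vi)
    }
    h <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps / 4,
                        maxiter = 2000)$root
    if (abs(f(h)) > rel_tol * vi) {
      # rare fallback: plain bisection on the expansion bracket
      for (i in 1:200) {
        h <- (lo + hi) / 2
        res <- f(h)
        if (abs(res) <= rel_tol * vi || (hi - lo) <= .Machine$double.eps * hi)
          break
        if (res > 0) hi <- h else lo <- h
      }
    }
    h
  }, numeric(1))
}

# Evaluate one comparison trait at stem length h.
trait_value <- function(trait, h, params) {
  switch(trait,
    height        = h,
    cross_section = basal_cross_section_total(h, params),
    surface_area  = plant_surface_area(h, params),
    sprout_area   = sprout_area(h, params),
    twig_count    = twig_count(h, params),
    stop("unknown trait '", trait, "'")
  )
}

#' Traits available to [compare_trait()] and [curve_sample()]
#' @return Character vector of trait names.
#' @export
comparison_traits <- function() {
  c("height", "cross_section", "surface_area", "sprout_area", "twig_count")
}

#' Compare a trait between a shrub and a tree at equal woody volume
#'
#' Solves the heights at which both plants hold the same above-ground woody
#' volume `v` (the shrub at `g_s * v`, where `g_s` is the shrub/tree
#' growth-rate ratio, 1 by default), evaluates the trait for each, and
#' reports the percent by which the shrub exceeds the tree,
#' `100 * (shrub - tree) / tree`.
#'
#' @param trait One of [comparison_traits()].
#' @param v Common above-ground woody volume in cm^3 (> 0).
#' @param shrub,tree [plant_params()] for the two growth forms.
#' @param g_s Shrub/tree growth-rate ratio; the shrub is evaluated at volume
#'   `g_s * v`.
#' @return An object of class `trait_comparison`: a one-row data.frame with
#'   columns `volume_cm3`, `trait`, `n`, `g_s`, `tree_value`, `shrub_value`,
#'   `percent_greater`.
#' @examples
#' compare_trait("cross_section", 500, plant_params(n = 3), plant_params())
#' @export
compare_trait <- function(trait, v, shrub, tree = plant_params(), g_s = 1) {
  trait <- match.arg(trait, comparison_traits())
  stopifnot(length(v) == 1, v > 0, g_s > 0,
            inherits(shrub, "plant_params"), inherits(tree, "plant_params"))
  h_tree <- height_from_volume(v, tree)
  h_shrub <- height_from_volume(g_s * v, shrub)
  tv <- trait_value(trait, h_tree, tree)
  sv <- trait_value(trait, h_shrub, shrub)
  out <- data.frame(
    volume_cm3 = v, trait = trait, n = shrub$n, g_s = g_s,
    tree_value = tv, shrub_value = sv,
    percent_greater = 100 * (sv - tv) / tv
  )
  class(out) <- c("trait_comparison", "data.frame")
  out
}

#' @export
print.trait_comparison <- function(x, ...) {
  cat(sprintf(
    "%s at %g cm^3 woody volume (n = %d stems, g_s = %g):\n",
    x$trait, x$volume_cm3, x$n, x$g_s))
  cat(sprintf("  tree %.6g, shrub %.6g  ->  shrub %+.2f%%\n",
              x$tree_value, x$shrub_value, x$percent_greater))
  invisible(x)
}

#' Sample trait curves over a volume grid
#'
#' Evaluates one or more traits for a tree and a set of shrubs over a grid of
#' common volumes, yielding the curves of the height/area/twig comparisons in
#' long (tidy) form.
#'
#' @param trait Character vector of trait names from [comparison_traits()].
#' @param v_grid Increasing vector of positive volumes (cm^3). Default: 200
#'   log-spaced points between 1 and 1000 cm^3.
#' @param tree A [plant_params()] object for the reference tree.
#' @param shrubs A list of [plant_params()] objects (e.g. varying `n`).
#' @param g_s Growth-rate ratio applied to the shrubs' volumes.
#' @return A data.frame with columns `volume_cm3`, `plant_label`, `n`,
#'   `trait`, `value`.
#' @export
curve_sample <- function(trait, v_grid = default_v_grid(),
                         tree = plant_params(),
                         shrubs = lapply(c(3, 5, 7), function(n) plant_params(n = n)),
                         g_s = 1) {
  trait <- vapply(trait, match.arg, "", choices = comparison_traits())
  stopifnot(all(v_grid > 0), !is.unsorted(v_grid))
  if (inherits(shrubs, "plant_params")) shrubs <- list(shrubs)
  plants <- c(list(tree), shrubs)
  labels <- c("tree",
              vapply(shrubs, function(p) sprintf("shrub_n%d", p$n), ""))
  vols <- c(list(v_grid), lapply(shrubs, function(p) g_s * v_grid))
  rows <- lapply(seq_along(plants), function(i) {
    h <- height_from_volume(vols[[i]], plants[[i]])
    do.call(rbind, lapply(trait, function(tr) {
      data.frame(volume_cm3 = v_grid, plant_label = labels[i],
                 n = plants[[i]]$n, trait = tr,
                 value = vapply(h, trait_value, numeric(1), trait = tr,
                                params = plants[[i]]))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default volume grid for curve sampling
#' @param from,to Grid limits in cm^3.
#' @param length.out Number of log-spaced points.
#' @return Numeric vector of volumes.
#' @export
default_v_grid <- function(from = 1, to = 1000, length.out = 200) {
  exp(seq(log(from), log(to), length.out = length.out))
}
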