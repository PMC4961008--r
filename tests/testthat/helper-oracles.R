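# Independent oracles, written from the closed forms only; they never call the
# package's assembly code, so they can catch errors in it.

# Explicit segment table for a default-parameter plant, built by hand:
# generation k has a^k segments per stem of length p^k * h (with the linear
# ramp for newborn children), basal radius max(b * L, r_tip), tip radius r_tip.
oracle_segments <- function(h, p = 0.5, l_min = 20, a = 2,
                            b = 0.0075, r_tip = 0.1) {
  segs <- list()
  L <- h
  count <- 1
  while (L > 0) {
    segs[[length(segs) + 1]] <- c(count = count, length = L,
                                  r_base = max(b * L, r_tip))
    lo <- (2 / 3) * l_min
    L <- if (L < lo) 0
         else if (L < l_min) p * l_min * (L - lo) / (l_min - lo)
         else p * L
    count <- count * a
  }
  do.call(rbind, segs)
}

oracle_volume <- function(h, n = 1, ...) {
  s <- oracle_segments(h, ...)
  r_tip <- 0.1
  n * sum(s[, "count"] *
            pi * s[, "length"] / 3 *
            (s[, "r_base"]^2 + s[, "r_base"] * r_tip + r_tip^2))
}

oracle_surface <- function(h, n = 1, ...) {
  s <- oracle_segments(h, ...)
  r_tip <- 0.1
  n * sum(s[, "count"] *
            pi * (s[, "r_base"] + r_tip) *
            sqrt(s[, "length"]^2 + (s[, "r_base"] - r_tip)^2))
}

# Midpoint Riemann sum for the bending-moment integral, with the geometry
# (linear conical taper, capped horizontal offset) restated from scratch.
oracle_moment_riemann <- function(total_length, lean_angle_deg,
                                  cutoff = Inf, b = 0.0075, r_tip = 0.001,
                                  rho = 600, g = 9.81, panels = 1e6) {
  L <- total_length
  ds <- L / panels
  s <- (seq_len(panels) - 0.5) * ds
  r0 <- max(b * L, r_tip)
  r <- r0 + (r_tip - r0) * s / L
  x <- pmin(s * sin(lean_angle_deg * pi / 180), cutoff)
  sum(rho * g * pi * r^2 * x) * ds
}

default_tree <- function() plant_params(n = 1)
default_shrub <- function(n) plant_params(n = n)
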