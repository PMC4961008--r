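test_that("child length is zero, ramped, then proportional — and continuous", {
  expect_equal(child_length(10, 0.5, 20), 0)
  expect_equal(child_length(20, 0.5, 20), 10)        # p * l_min at the joint
  expect_equal(child_length(40, 0.5, 20), 20)        # p * parent above l_min
  expect_equal(child_length(50 / 3, 0.5, 20), 5)     # midpoint of the ramp
  # continuity at both joints
  eps <- 1e-9
  for (j in c(2 / 3 * 20, 20))
    expect_equal(child_length(j - eps, 0.5, 20), child_length(j + eps, 0.5, 20),
                 tolerance = 1e-7)
  expect_error(child_length(-1, 0.5, 20), "non-negative")
})

test_that("generation enumeration terminates and follows the branching rule", {
  tree <- default_tree()

  g <- enumerate_generations(10, tree)       # below the ramp: stem only
  expect_equal(nrow(g), 1)
  expect_equal(g$count_per_stem, 1)

  g <- enumerate_generations(20, tree)       # one child generation, no more
  expect_equal(g$length, c(20, 10))
  expect_equal(g$count_per_stem, c(1, 2))

  g <- enumerate_generations(80, tree)       # proportional chain
  expect_equal(g$length, c(80, 40, 20, 10))
  expect_equal(g$count_per_stem, c(1, 2, 4, 8))
  expect_equal(g$r_base, c(0.6, 0.3, 0.15, 0.1))
  expect_equal(g$depth, 0:3)
})

test_that("plant volume assembles the generations (hand-built oracle)", {
  tree <- default_tree()
  expect_equal(plant_volume(0, tree), 0)
  expect_equal(plant_volume(20, tree),
               (20 * pi / 3) * (0.0225 + 0.015 + 0.01) + 2 * pi * 0.01 * 10,
               tolerance = 1e-14)
  for (h in c(5, 14, 17, 20, 35, 80, 123.4)) {
    expect_equal(plant_volume(h, tree), oracle_volume(h), tolerance = 1e-12)
    expect_equal(plant_surface_area(h, tree), oracle_surface(h),
                 tolerance = 1e-12)
  }
})

test_that("a shrub is n independent copies of the tree stem: V(h, n) = n V(h, 1)", {
  set.seed(42)
  tree <- default_tree()
  h <- runif(100, 0.5, 400)
  for (n in c(2, 3, 5, 7)) {
    shrub <- default_shrub(n)
    expect_equal(plant_volume(h, shrub), n * plant_volume(h, tree),
                 tolerance = 1e-15)
    expect_equal(plant_surface_area(h, shrub), n * plant_surface_area(h, tree),
                 tolerance = 1e-15)
  }
})

test_that("volume and surface area are continuous across the ramp joints", {
  tree <- default_tree()
  eps <- 1e-9
  for (j in c(2 / 3 * 20, 20, 40)) {  # joints of the stem and of its children
    for (f in list(plant_volume, plant_surface_area)) {
      lo <- f(j - eps, tree)
      hi <- f(j + eps, tree)
      expect_lt(abs(hi - lo) / lo, 1e-9)
    }
  }
})

test_that("volume and surface area are strictly increasing in stem length", {
  tree <- default_tree()
  h <- seq(0.5, 150, by = 0.5)
  expect_true(all(diff(plant_volume(h, tree)) > 0))
  expect_true(all(diff(plant_surface_area(h, tree)) > 0))
})

test_that("basal cross-section, sprout area and twig count follow their definitions", {
  tree <- default_tree()
  expect_equal(basal_cross_section_total(20, tree), pi * 0.15^2)
  expect_equal(basal_cross_section_total(20, default_shrub(3)), 3 * pi * 0.15^2)

  # sprout area: lateral area of the lower quarter of each stem
  h <- 80
  r1 <- 0.6
  r2 <- r1 + (0.1 - r1) * 0.25
  expect_equal(sprout_area(h, tree, 0.25),
               pi * (r1 + r2) * sqrt(20^2 + (r1 - r2)^2))
  expect_error(sprout_area(h, tree, 0), "must be in")
  expect_error(sprout_area(h, tree, 1.5), "must be in")

  expect_equal(twig_count(10, default_shrub(3)), 3)   # bare stems
  expect_equal(twig_count(80, tree), 8)               # a^3 deepest twigs
  # non-decreasing, jumping by factors of a
  tc <- twig_count(seq(1, 200, by = 0.25), tree)
  expect_true(all(diff(tc) >= 0))
  jumps <- unique(tc)
  expect_equal(jumps, 2^(0:(length(jumps) - 1)))
})

test_that("height-diameter relation mode: forward, inverse, and assembly", {
  ns <- niklas_spatz_params(k5 = 1, k6 = 0)
  expect_equal(stem_length_from_diameter_ns(8, ns), 4)  # 8^(2/3)
  ns <- niklas_spatz_params(k5 = 90, k6 = 10)
  D <- c(0.5, 2, 5, 10)
  expect_equal(diameter_from_stem_length_ns(stem_length_from_diameter_ns(D, ns), ns),
               D, tolerance = 1e-12)
  expect_error(stem_length_from_diameter_ns(-1, ns), "positive")

  p_ns <- plant_params(n = 1, radius_mode = "niklas_spatz", ns = ns)
  g <- enumerate_generations(80, p_ns)
  expect_equal(g$r_base[1], ((80 + 10) / 90)^1.5 / 2)
  expect_true(all(g$r_base >= p_ns$r_tip))
  expect_error(plant_params(radius_mode = "niklas_spatz"), "requires")
})
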