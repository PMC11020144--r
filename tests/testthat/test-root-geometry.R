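test_that("root_length sums segment lengths over visible nodes", {
  expect_equal(root_length(rbind(c(0, 0), c(0, 10))), 10)
  expect_equal(root_length(rbind(c(0, 0), c(3, 4), c(3, 4))), 5)
  occluded <- rbind(c(NaN, NaN), c(0, 0), c(0, 5), c(0, 9), c(0, 12),
                    c(0, 14))
  expect_equal(root_length(occluded), 14)
  expect_true(is.nan(root_length(rbind(c(1, 2), c(NaN, NaN)))))
})

test_that("base_tip_distance is the chord between first and last visible", {
  expect_equal(base_tip_distance(rbind(c(0, 0), c(0, 7), c(0, 14))), 14)
  bent <- rbind(c(0, 0), c(0, 10), c(10, 10))
  expect_equal(base_tip_distance(bent), sqrt(200))
  expect_true(is.nan(base_tip_distance(rbind(c(1, 1), c(NaN, NaN)))))
})

test_that("curve_index follows its definition and degenerates to NaN", {
  expect_equal(curve_index(20, 20), 0)
  expect_equal(curve_index(20, sqrt(200)), (20 - sqrt(200)) / 20)
  expect_true(is.nan(curve_index(0, 0)))
  expect_true(is.nan(curve_index(NaN, 5)))
  # triangle inequality keeps the index in [0, 1) for real polylines
  set.seed(11)
  for (i in 1:50) {
    m <- cbind(cumsum(runif(6, -5, 5)), cumsum(runif(6, 1, 10)))
    ci <- curve_index(root_length(m), base_tip_distance(m))
    expect_true(ci >= 0 && ci < 1)
  }
})

test_that("gravity_angle measures degrees from straight down, unsigned", {
  down <- straight_instance(c(0, 0), c(0, 50), 6)
  expect_equal(gravity_angle(down, "proximal"), 0)
  expect_equal(gravity_angle(down, "distal"), 0)
  diag45 <- straight_instance(c(0, 0), c(50, 50), 6)
  expect_equal(gravity_angle(diag45, "proximal"), 45)
  horiz <- straight_instance(c(0, 0), c(-70, 0), 6)
  expect_equal(gravity_angle(horiz, "distal"), 90)
  up <- straight_instance(c(0, 0), c(0, -50), 6)
  expect_equal(gravity_angle(up, "proximal"), 180)
})

test_that("gravity_angle is translation-invariant and mirror-symmetric", {
  set.seed(7)
  for (i in 1:25) {
    nodes <- cbind(cumsum(runif(6, -8, 8)), cumsum(runif(6, 0.5, 10)))
    shift <- runif(2, -500, 500)
    shifted <- sweep(nodes, 2, shift, "+")
    mirrored <- cbind(-nodes[, 1], nodes[, 2])
    for (mode in c("proximal", "distal")) {
      expect_equal(gravity_angle(shifted, mode), gravity_angle(nodes, mode))
      expect_equal(gravity_angle(mirrored, mode), gravity_angle(nodes, mode))
    }
  }
})

test_that("proximal uses a near-base node, distal a near-tip node", {
  # base -> r3 points at 90 deg, r4 -> r6 drop straight down:
  # proximal reads the near-base direction, distal the overall-to-tip one
  nodes <- rbind(c(0, 0), c(10, 0), c(20, 0), c(20, 10), c(20, 20),
                 c(20, 30))
  expect_equal(gravity_angle(nodes, "proximal"), 90)
  expect_equal(gravity_angle(nodes, "distal"),
               atan2(20, 30) * 180 / pi)
  # occluded tip: distal falls back to the last visible node in the 2nd half
  nodes[6, ] <- NaN
  expect_equal(gravity_angle(nodes, "distal"), 45)
})

test_that("bases_and_tips extracts endpoints and flags occluded bases", {
  l1 <- lateral_at(c(10, 20))
  l2 <- root_instance(rbind(c(NaN, NaN), c(5, 30), c(6, 40), c(7, 50)),
                      "lateral")
  bt <- bases_and_tips(list(l1, l2))
  expect_equal(bt$base_xs, c(10, NaN))
  expect_equal(bt$base_ys, c(20, NaN))
  expect_false(anyNA(bt$tip_xs))
  expect_equal(bt$tip_ys[2], 50)
  empty <- bases_and_tips(list())
  expect_length(empty$base_xs, 0L)
})

test_that("base scalar traits follow their definitions", {
  tr <- base_scalar_traits(c(20, 50, 80), primary_length = 100,
                           primary_tip_y = 100)
  expect_equal(tr$base_length, 60)
  expect_equal(tr$base_length_ratio, 0.6)
  expect_equal(tr$base_median_ratio, 0.5)
  expect_equal(tr$base_ct_density, 0.03)
  expect_equal(tr$lateral_count, 3L)

  expect_equal(base_scalar_traits(40, 100, 100)$base_length, 0)

  none <- base_scalar_traits(numeric(0), 100, 100, n_instances = 0L)
  expect_true(is.nan(none$base_length))
  expect_true(is.nan(none$base_ct_density))
  expect_equal(none$lateral_count, 0L)

  # occluded bases (NaN) are excluded but the instance count is exact
  some <- base_scalar_traits(c(NaN, 30, 70), 100, 100)
  expect_equal(some$base_length, 40)
  expect_equal(some$base_ct_density, 0.02)
  expect_equal(some$lateral_count, 3L)
})

test_that("width matching pairs opposite bases and applies the tolerance", {
  prim <- straight_instance(c(0, 0), c(0, 100), 6, "primary")
  # symmetric pair at the same projection: one width of 10
  w <- match_root_widths(prim, list(lateral_at(c(-5, 50), dir = c(-1, 1)),
                                    lateral_at(c(5, 50))))
  expect_equal(w, 10)
  # projections 0.50 vs 0.53: cost 0.03 > default tolerance 0.02 -> dropped
  w2 <- match_root_widths(prim, list(lateral_at(c(-5, 50), dir = c(-1, 1)),
                                     lateral_at(c(5, 53))))
  expect_length(w2, 0L)
  # ... but kept under a looser tolerance
  w3 <- match_root_widths(prim, list(lateral_at(c(-5, 50), dir = c(-1, 1)),
                                     lateral_at(c(5, 53))),
                          width_match_config(projection_tolerance = 0.05))
  expect_equal(w3, sqrt(10^2 + 3^2))
  # all bases on one side: nothing to pair
  expect_length(match_root_widths(prim, list(lateral_at(c(5, 20)),
                                             lateral_at(c(5, 60)))), 0L)
})

test_that("width matching reproduces the exhaustive assignment optimum", {
  prim <- straight_instance(c(0, 0), c(0, 100), 6, "primary")
  lats <- list(lateral_at(c(-4, 20), dir = c(-1, 1)),
               lateral_at(c(-4, 60), dir = c(-1, 1)),
               lateral_at(c(4, 21)), lateral_at(c(4, 59)))
  w <- match_root_widths(prim, lats)
  expect_length(w, 2L)
  expect_equal(sort(w), sort(c(sqrt(8^2 + 1^2), sqrt(8^2 + 1^2))))
  # assignment equals the exhaustive minimum over both pairings:
  # |0.2 - 0.21| + |0.6 - 0.59| = 0.02 < |0.2 - 0.59| + |0.6 - 0.21|
  cost <- abs(outer(c(0.2, 0.6), c(0.21, 0.59), "-"))
  expect_equal(assignment_cost(cost), oracle_assignment_cost(cost))
  expect_equal(assignment_cost(cost), 0.02)
})

test_that("pairs whose connector misses the primary line are excluded", {
  # opposite-side pair located beyond the primary tip: projections agree
  # (both clamp to 1) but the connecting segment passes below the polyline
  prim <- straight_instance(c(0, 0), c(0, 100), 6, "primary")
  lats <- list(lateral_at(c(-5, 105), dir = c(-1, 1)),
               lateral_at(c(5, 105)))
  with_cross <- match_root_widths(prim, lats, width_match_config(1, TRUE))
  without <- match_root_widths(prim, lats, width_match_config(1, FALSE))
  expect_length(with_cross, 0L)
  expect_length(without, 1L)
})

test_that("hungarian solver matches brute force on random instances", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(1:5, 1); m <- sample(1:6, 1)
    cost <- matrix(runif(n * m), n, m)
    expect_equal(assignment_cost(cost), oracle_assignment_cost(cost),
                 tolerance = 1e-12)
  }
})

test_that("widths are translation-invariant and bounded in count", {
  set.seed(3)
  for (i in 1:20) {
    prim_nodes <- cbind(cumsum(runif(6, -6, 6)), cumsum(runif(6, 10, 30)))
    prim <- root_instance(prim_nodes, "primary")
    lats <- lapply(1:6, function(k)
      lateral_at(c(runif(1, -40, 40), runif(1, 10, 120))))
    cfg <- width_match_config(0.2)
    w <- match_root_widths(prim, lats, cfg)
    expect_true(all(w >= 0))
    expect_lte(length(w), 3L)   # <= min(#left, #right) <= floor(6/2)
    shift <- runif(2, -300, 300)
    move <- function(inst)
      root_instance(sweep(inst$nodes, 2, shift, "+"), inst$root_class)
    w_shift <- match_root_widths(move(prim), lapply(lats, move), cfg)
    expect_equal(w_shift, w, tolerance = 1e-9)
  }
})
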