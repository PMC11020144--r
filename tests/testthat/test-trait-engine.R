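test_that("pipelines define the documented trait counts", {
  dic <- build_pipeline("dicot")
  sc <- vapply(dic$definitions, `[[`, logical(1), "scalar")
  expect_length(dic$definitions, 35L)
  expect_equal(sum(sc), 25L)
  expect_equal(sum(!sc), 10L)
  expect_length(trait_column_names(dic, "frame"), 115L)
  expect_length(trait_column_names(dic, "plant"), 1035L)

  mono <- build_pipeline("younger_monocot")
  scm <- vapply(mono$definitions, `[[`, logical(1), "scalar")
  expect_length(mono$definitions, 30L)
  expect_equal(sum(scm), 21L)
  expect_equal(sum(!scm), 9L)
  expect_length(trait_column_names(mono, "frame"), 102L)
  expect_length(trait_column_names(mono, "plant"), 918L)

  expect_error(build_pipeline("fern"))
})

test_that("topological order respects dependencies deterministically", {
  for (kind in c("dicot", "younger_monocot")) {
    p <- build_pipeline(kind)
    ord <- vapply(topological_order(p), `[[`, "", "name")
    expect_setequal(ord, vapply(p$definitions, `[[`, "", "name"))
    pos <- match(c("curve_index", "primary_length", "primary_base_tip_dist",
                   "network_solidity", "chull_area",
                   "scanline_first_ind", "scanline_intersection_counts"),
                 ord)
    expect_gt(pos[1], pos[2])
    expect_gt(pos[1], pos[3])
    expect_gt(pos[4], pos[5])
    expect_gt(pos[6], pos[7])
    # deterministic: same order on rebuild
    expect_identical(ord, vapply(topological_order(build_pipeline(kind)),
                                 `[[`, "", "name"))
  }
})

test_that("a cyclic graph is rejected with the cycle named", {
  defs <- list(
    rootpose:::trait_def("a", "b", TRUE, function(v, ctx) 1),
    rootpose:::trait_def("b", "a", TRUE, function(v, ctx) 2))
  expect_error(topological_order(defs, roots = character(0)),
               "cycle involving: a, b")
})

test_that("frame traits on a constructed dicot frame are exact", {
  prim <- straight_instance(c(100, 0), c(100, 100), 6, "primary")
  lats <- lapply(c(20, 50, 80), function(y)
    lateral_at(c(100, y), dir = c(ifelse(y == 50, -1, 1), 1)))
  frame <- frame_landmarks(0L, c(list(prim), lats))
  ft <- compute_frame_traits(frame, build_pipeline("dicot"),
                             image_size = c(2048, 1088))
  expect_length(ft, 35L)
  expect_equal(ft$primary_length, 100)
  expect_equal(ft$curve_index, 0)
  expect_equal(ft$lateral_count, 3)
  expect_equal(ft$primary_tip_pt_y, 100)
  expect_equal(ft$base_length, 60)
  expect_equal(ft$base_length_ratio, 0.6)
  expect_equal(ft$base_median_ratio, 0.5)
  expect_equal(ft$base_ct_density, 0.03)
  expect_equal(sort(ft$lateral_base_pt_ys), c(20, 50, 80))
  expect_equal(ft$network_length, 100 + 3 * root_length(lats[[1]]))
})

test_that("frames with no laterals or nothing at all degrade gracefully", {
  prim <- straight_instance(c(0, 0), c(0, 100), 6, "primary")
  p <- build_pipeline("dicot")
  only_prim <- compute_frame_traits(frame_landmarks(0L, list(prim)), p)
  expect_equal(only_prim$lateral_count, 0)
  expect_true(is.nan(only_prim$base_length))
  expect_length(only_prim$root_widths, 0L)
  expect_length(only_prim$lateral_lengths, 0L)

  empty <- compute_frame_traits(frame_landmarks(0L, list()), p)
  expect_equal(empty$lateral_count, 0)
  scalars <- vapply(p$definitions, `[[`, logical(1), "scalar")
  nms <- vapply(p$definitions, `[[`, "", "name")
  for (nm in setdiff(nms[scalars],
                     c("lateral_count", "scanline_first_ind",
                       "scanline_last_ind")))
    expect_true(is.nan(empty[[nm]]), label = paste("NaN", nm))
  expect_true(all(empty$scanline_intersection_counts == 0))
  expect_true(is.nan(empty$scanline_first_ind))
})

test_that("the longest of several primary detections is used", {
  short <- straight_instance(c(0, 0), c(0, 40), 6, "primary")
  long <- straight_instance(c(10, 0), c(10, 90), 6, "primary")
  ft <- compute_frame_traits(frame_landmarks(0L, list(short, long)),
                             build_pipeline("dicot"))
  expect_equal(ft$primary_length, 90)
  expect_equal(ft$network_length, 90)   # the surplus detection is discarded
})

test_that("summary statistics follow the documented conventions", {
  s <- summarize_values(c(1, 2, 3))
  expect_named(s, SUMMARY_STATS)
  expect_equal(unname(s),
               c(3, 1, 2, 2, sqrt(2 / 3), 1.1, 1.5, 2.5, 2.9))
  one <- summarize_values(5)
  expect_true(all(one[c("max", "min", "mean", "median",
                        "p5", "p25", "p75", "p95")] == 5))
  expect_equal(unname(one["std"]), 0)
  expect_true(all(is.nan(summarize_values(c(NaN, NA)))))
  # missing values are ignored, not propagated
  expect_equal(unname(summarize_values(c(NaN, 1, 3))["mean"]), 2)
})

test_that("plant summaries have the exact column structure", {
  g <- generate_plant(plant_model(kind = "dicot", n_children = 3,
                                  n_frames = 4, seed = 2))
  p <- build_pipeline("dicot")
  tr <- compute_plant_traits(g$series, p)
  expect_length(tr, 1035L)
  expect_identical(names(tr), trait_column_names(p))
  expect_true("lateral_tip_pt_ys_max_median" %in% names(tr))
  expect_true("primary_length_median" %in% names(tr))

  gm <- generate_plant(plant_model(kind = "younger_monocot", n_children = 4,
                                   n_frames = 4, seed = 2))
  pm <- build_pipeline("younger_monocot")
  trm <- compute_plant_traits(gm$series, pm)
  expect_length(trm, 918L)
  expect_true("main_tip_pt_ys_max_median" %in% names(trm))

  # ordering invariant: min <= p5 <= p25 <= median <= p75 <= p95 <= max
  for (tr_vec in list(tr, trm)) {
    m <- matrix(tr_vec, ncol = 9, byrow = TRUE)
    colnames(m) <- SUMMARY_STATS
    fin <- apply(m, 1, function(r) all(is.finite(r)))
    m <- m[fin, , drop = FALSE]
    expect_true(all(m[, "min"] <= m[, "p5"] + 1e-12))
    expect_true(all(m[, "p5"] <= m[, "p25"] + 1e-12))
    expect_true(all(m[, "p25"] <= m[, "median"] + 1e-12))
    expect_true(all(m[, "median"] <= m[, "p75"] + 1e-12))
    expect_true(all(m[, "p75"] <= m[, "p95"] + 1e-12))
    expect_true(all(m[, "p95"] <= m[, "max"] + 1e-12))
    expect_true(all(m[, "min"] <= m[, "mean"] & m[, "mean"] <= m[, "max"]))
  }
})

test_that("a one-frame series collapses plant stats onto the frame value", {
  prim <- straight_instance(c(0, 0), c(0, 100), 6, "primary")
  s <- one_frame_series(list(prim, lateral_at(c(0, 30)),
                             lateral_at(c(0, 60))))
  tr <- compute_plant_traits(s, build_pipeline("dicot"))
  expect_equal(unname(tr["primary_length_min"]),
               unname(tr["primary_length_max"]))
  expect_equal(unname(tr["primary_length_median"]), 100)
  expect_equal(unname(tr["primary_length_std"]), 0)
})

test_that("plant traits are invariant under frame reordering", {
  g <- generate_plant(plant_model(kind = "dicot", n_children = 4,
                                  n_frames = 8, seed = 9))
  p <- build_pipeline("dicot")
  tr1 <- compute_plant_traits(g$series, p)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  shuffled <- g$series$frames[perm]
  for (k in seq_along(shuffled)) shuffled[[k]]$frame_index <- k - 1L
  s2 <- plant_series(g$series$plant_id, shuffled,
                     image_size = g$series$image_size)
  tr2 <- compute_plant_traits(s2, p)
  expect_equal(unclass(tr2), unclass(tr1), ignore_attr = TRUE)
  expect_identical(names(tr2), names(tr1))
})

test_that("run_batch writes deterministic CSV with the documented header", {
  co <- generate_cohort(2, "dicot", seed = 4, n_frames = 3)
  p <- build_pipeline("dicot")
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  df <- run_batch(co$plants, p, path = f1)
  expect_equal(dim(df), c(2L, 1036L))
  expect_identical(names(df)[1], "plant_id")
  run_batch(co$plants, p, path = f2)
  expect_identical(readLines(f1), readLines(f2))
  header <- strsplit(readLines(f1, n = 1), ",")[[1]]
  expect_identical(header, c("plant_id", trait_column_names(p)))
  back <- read_trait_table(f1)
  expect_equal(back$primary_length_median, df$primary_length_median,
               tolerance = 1e-9)

  # empty collection: header-only CSV
  f3 <- withr::local_tempfile(fileext = ".csv")
  df0 <- run_batch(list(), p, path = f3)
  expect_equal(nrow(df0), 0L)
  expect_length(readLines(f3), 1L)
})
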