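#' @title Trait dependency graph and pipelines
#' @name trait_engine
#' @description
#' Traits are declared as nodes of a directed acyclic graph whose edges are
#' input dependencies; per frame, traits are evaluated in topological order so
#' every trait is computed only after its inputs. Two pipelines are provided:
#' the dicot pipeline (primary + lateral roots; 35 per-frame traits, 25 scalar
#' and 10 non-scalar) and the younger-monocot pipeline (primary + crown/"main"
#' roots; 30 per-frame traits, 21 scalar and 9 non-scalar). Non-scalar traits
#' are summarized per frame by nine statistics, and every per-frame trait is
#' summarized again across frames, yielding 1,035 (dicot) or 918 (monocot)
#' summarized traits per plant.
NULL

#' Names of the nine summary statistics, in fixed column order
#' @export
SUMMARY_STATS <- c("max", "min", "mean", "median", "std",
                   "p5", "p25", "p75", "p95")

#' Nine summary statistics of a numeric vector
#'
#' Missing (`NaN`/`NA`/infinite) values are ignored; an all-missing or empty
#' input yields nine `NaN`s. The standard deviation uses divisor n (population
#' form) and percentiles use linear interpolation, for bit-exact parity with
#' the conventions of array libraries.
#'
#' @param x Numeric vector.
#' @return Named numeric vector of length 9, in [SUMMARY_STATS] order:
#'   maximum, minimum, mean, median, SD, and the 5th/25th/75th/95th
#'   percentiles.
#' @export
summarize_values <- function(x) {
  v <- x[is.finite(x)]
  if (!length(v))
    return(stats::setNames(rep(NaN, 9L), SUMMARY_STATS))
  q <- stats::quantile(v, c(0.05, 0.25, 0.75, 0.95), names = FALSE, type = 7)
  stats::setNames(
    c(max(v), min(v), mean(v), stats::median(v),
      sqrt(mean((v - mean(v))^2)), q),
    SUMMARY_STATS)
}

#' Trait computation configuration
#'
#' @param scanline_n Number of horizontal scanlines (default 50).
#' @param width_tolerance Projection tolerance for root-width base matching,
#'   as a fraction of primary root length (default 0.02).
#' @param require_crossing Require matched base pairs to cross the primary
#'   root line (default `TRUE`).
#' @param lower_fraction Fraction of the bounding-box depth defining the lower
#'   network region (default 2/3).
#' @return Object of class `trait_config`.
#' @export
trait_config <- function(scanline_n = 50, width_tolerance = 0.02,
                         require_crossing = TRUE, lower_fraction = 2 / 3) {
  stopifnot(scanline_n >= 2, width_tolerance >= 0,
            lower_fraction > 0, lower_fraction <= 1)
  structure(list(scanline_n = as.integer(scanline_n),
                 width_tolerance = width_tolerance,
                 require_crossing = require_crossing,
                 lower_fraction = lower_fraction),
            class = "trait_config")
}

trait_def <- function(name, inputs, scalar, fun) {
  list(name = name, inputs = inputs, scalar = scalar, fun = fun)
}

or_nan <- function(x) if (is.null(x) || length(x) == 0L) NaN else x

memoize <- function(ctx, name, fun) {
  if (is.null(ctx$memo[[name]])) ctx$memo[[name]] <- fun()
  ctx$memo[[name]]
}

ctx_chull <- function(ctx)
  memoize(ctx, "chull", function() convex_hull_traits(ctx$cloud))
ctx_ellipse <- function(ctx)
  memoize(ctx, "ellipse", function() fit_ellipse_traits(ctx$cloud))
ctx_scan <- function(ctx)
  memoize(ctx, "scan", function()
    scanline_profile(ctx$net_instances,
                     scanline_config(ctx$config$scanline_n, ctx$height)))
ctx_net <- function(ctx)
  memoize(ctx, "net", function()
    network_traits(ctx$net_instances, ctx$cloud,
                   ctx_chull(ctx)$chull_area, ctx$config$lower_fraction))
ctx_bt <- function(ctx)
  memoize(ctx, "bt", function() bases_and_tips(ctx$secondary))

# trait definitions shared by both pipelines; `sec` is the landmark root name
# of the secondary class ("lateral_pts" or "main_pts")
primary_defs <- function() list(
  trait_def("primary_length", "primary_pts", TRUE, function(v, ctx)
    if (is.null(ctx$primary)) NaN else root_length(ctx$primary)),
  trait_def("primary_base_tip_dist", "primary_pts", TRUE, function(v, ctx)
    if (is.null(ctx$primary)) NaN else base_tip_distance(ctx$primary)),
  trait_def("curve_index", c("primary_length", "primary_base_tip_dist"),
            TRUE, function(v, ctx)
    curve_index(v$primary_length, v$primary_base_tip_dist)),
  trait_def("primary_angle_proximal", "primary_pts", TRUE, function(v, ctx)
    if (is.null(ctx$primary)) NaN else gravity_angle(ctx$primary, "proximal")),
  trait_def("primary_angle_distal", "primary_pts", TRUE, function(v, ctx)
    if (is.null(ctx$primary)) NaN else gravity_angle(ctx$primary, "distal")),
  trait_def("primary_tip_pt_y", "primary_pts", TRUE, function(v, ctx)
    if (is.null(ctx$primary)) NaN else
      or_nan(bases_and_tips(list(ctx$primary))$tip_ys))
)

system_defs <- function(sec) list(
  trait_def("chull_perimeter", c("primary_pts", sec), TRUE,
            function(v, ctx) ctx_chull(ctx)$chull_perimeter),
  trait_def("chull_area", c("primary_pts", sec), TRUE,
            function(v, ctx) ctx_chull(ctx)$chull_area),
  trait_def("chull_max_width", c("primary_pts", sec), TRUE,
            function(v, ctx) ctx_chull(ctx)$chull_max_width),
  trait_def("chull_max_height", c("primary_pts", sec), TRUE,
            function(v, ctx) ctx_chull(ctx)$chull_max_height),
  trait_def("chull_line_lengths", c("primary_pts", sec), FALSE,
            function(v, ctx) ctx_chull(ctx)$chull_line_lengths),
  trait_def("ellipse_a", c("primary_pts", sec), TRUE,
            function(v, ctx) ctx_ellipse(ctx)$ellipse_a),
  trait_def("ellipse_b", c("primary_pts", sec), TRUE,
            function(v, ctx) ctx_ellipse(ctx)$ellipse_b),
  trait_def("ellipse_ratio", c("ellipse_a", "ellipse_b"), TRUE,
            function(v, ctx) ctx_ellipse(ctx)$ellipse_ratio),
  trait_def("scanline_intersection_counts", c("primary_pts", sec), FALSE,
            function(v, ctx) ctx_scan(ctx)$scanline_intersection_counts),
  trait_def("scanline_first_ind", "scanline_intersection_counts", TRUE,
            function(v, ctx) ctx_scan(ctx)$scanline_first_ind),
  trait_def("scanline_last_ind", "scanline_intersection_counts", TRUE,
            function(v, ctx) ctx_scan(ctx)$scanline_last_ind),
  trait_def("network_length", c("primary_pts", sec), TRUE,
            function(v, ctx) ctx_net(ctx)$network_length),
  trait_def("network_width_depth_ratio", c("primary_pts", sec), TRUE,
            function(v, ctx) ctx_net(ctx)$network_width_depth_ratio),
  trait_def("network_solidity", c("network_length", "chull_area"), TRUE,
            function(v, ctx) ctx_net(ctx)$network_solidity),
  trait_def("network_length_lower", c("primary_pts", sec), TRUE,
            function(v, ctx) ctx_net(ctx)$network_length_lower),
  trait_def("network_length_distribution",
            c("network_length_lower", "network_length"), TRUE,
            function(v, ctx) ctx_net(ctx)$network_length_distribution)
)

dicot_defs <- function() c(
  primary_defs(),
  list(
    trait_def("lateral_lengths", "lateral_pts", FALSE, function(v, ctx)
      vapply(ctx$secondary, root_length, numeric(1L))),
    trait_def("lateral_angles_proximal", "lateral_pts", FALSE,
              function(v, ctx)
      vapply(ctx$secondary, gravity_angle, numeric(1L), mode = "proximal")),
    trait_def("lateral_angles_distal", "lateral_pts", FALSE, function(v, ctx)
      vapply(ctx$secondary, gravity_angle, numeric(1L), mode = "distal")),
    trait_def("lateral_base_pt_xs", "lateral_pts", FALSE,
              function(v, ctx) ctx_bt(ctx)$base_xs),
    trait_def("lateral_base_pt_ys", "lateral_pts", FALSE,
              function(v, ctx) ctx_bt(ctx)$base_ys),
    trait_def("lateral_tip_pt_xs", "lateral_pts", FALSE,
              function(v, ctx) ctx_bt(ctx)$tip_xs),
    trait_def("lateral_tip_pt_ys", "lateral_pts", FALSE,
              function(v, ctx) ctx_bt(ctx)$tip_ys),
    trait_def("root_widths", c("primary_pts", "lateral_pts"), FALSE,
              function(v, ctx)
      match_root_widths(ctx$primary, ctx$secondary,
                        width_match_config(ctx$config$width_tolerance,
                                           ctx$config$require_crossing))),
    trait_def("lateral_count", "lateral_pts", TRUE, function(v, ctx)
      length(ctx$secondary)),
    trait_def("base_length", "lateral_base_pt_ys", TRUE, function(v, ctx)
      ctx_base(ctx, v)$base_length),
    trait_def("base_length_ratio", c("base_length", "primary_length"), TRUE,
              function(v, ctx) ctx_base(ctx, v)$base_length_ratio),
    trait_def("base_median_ratio",
              c("lateral_base_pt_ys", "primary_tip_pt_y"), TRUE,
              function(v, ctx) ctx_base(ctx, v)$base_median_ratio),
    trait_def("base_ct_density", c("lateral_base_pt_ys", "primary_length"),
              TRUE, function(v, ctx) ctx_base(ctx, v)$base_ct_density)
  ),
  system_defs("lateral_pts")
)

ctx_base <- function(ctx, v)
  memoize(ctx, "base", function()
    base_scalar_traits(ctx_bt(ctx)$base_ys, v$primary_length,
                       v$primary_tip_pt_y, length(ctx$secondary)))

monocot_defs <- function() c(
  primary_defs(),
  list(
    trait_def("main_lengths", "main_pts", FALSE, function(v, ctx)
      vapply(ctx$secondary, root_length, numeric(1L))),
    trait_def("main_base_tip_dists", "main_pts", FALSE, function(v, ctx)
      vapply(ctx$secondary, base_tip_distance, numeric(1L))),
    trait_def("main_curve_indices", c("main_lengths", "main_base_tip_dists"),
              FALSE, function(v, ctx)
      curve_index(v$main_lengths, v$main_base_tip_dists)),
    trait_def("main_angles_proximal", "main_pts", FALSE, function(v, ctx)
      vapply(ctx$secondary, gravity_angle, numeric(1L), mode = "proximal")),
    trait_def("main_angles_distal", "main_pts", FALSE, function(v, ctx)
      vapply(ctx$secondary, gravity_angle, numeric(1L), mode = "distal")),
    trait_def("main_tip_pt_xs", "main_pts", FALSE,
              function(v, ctx) ctx_bt(ctx)$tip_xs),
    trait_def("main_tip_pt_ys", "main_pts", FALSE,
              function(v, ctx) ctx_bt(ctx)$tip_ys),
    trait_def("main_count", "main_pts", TRUE, function(v, ctx)
      length(ctx$secondary))
  ),
  system_defs("main_pts")
)

#' Build a trait extraction pipeline
#'
#' @param kind `"dicot"` (primary + lateral roots) or `"younger_monocot"`
#'   (primary + crown roots, collectively the "main" class).
#' @param config A [trait_config].
#'
#' @details The dicot pipeline defines 35 per-frame traits (25 scalar, 10
#'   non-scalar), expanding to 115 per-frame and 1,035 per-plant summarized
#'   traits. The younger-monocot pipeline defines 30 per-frame traits (21
#'   scalar, 9 non-scalar), expanding to 102 per-frame and 918 per-plant
#'   traits. System-level traits (convex hull, ellipse, scanlines, network) in
#'   the monocot pipeline are computed over the "main" class only, which by
#'   the labeling convention already contains the primary root.
#'
#' @return Object of class `trait_pipeline` with elements `kind`,
#'   `definitions` (list of trait definitions with `name`, `inputs`, `scalar`,
#'   `fun`), `roots` (landmark input names), and `config`.
#' @export
build_pipeline <- function(kind = c("dicot", "younger_monocot"),
                           config = trait_config()) {
  kind <- match.arg(kind)
  defs <- switch(kind, dicot = dicot_defs(), younger_monocot = monocot_defs())
  roots <- switch(kind, dicot = c("primary_pts", "lateral_pts"),
                  younger_monocot = c("primary_pts", "main_pts"))
  nm <- vapply(defs, `[[`, "", "name")
  stopifnot(!anyDuplicated(nm))
  structure(list(kind = kind, definitions = defs, roots = roots,
                 config = config),
            class = "trait_pipeline")
}

#' @export
print.trait_pipeline <- function(x, ...) {
  sc <- vapply(x$definitions, `[[`, logical(1L), "scalar")
  cat(sprintf(
    "<trait_pipeline '%s': %d per-frame traits (%d scalar, %d non-scalar)>\n",
    x$kind, length(sc), sum(sc), sum(!sc)))
  invisible(x)
}

#' Topological evaluation order of a trait pipeline
#'
#' Kahn's algorithm with deterministic tie-breaking: among ready traits, the
#' one declared first in the pipeline comes first. Landmark roots (e.g.
#' `primary_pts`) are treated as already satisfied.
#'
#' @param pipeline A `trait_pipeline` (from [build_pipeline]), or a bare list
#'   of trait definitions plus a `roots` character vector.
#' @param roots Landmark input names (taken from the pipeline if missing).
#'
#' @return The trait definitions reordered so that every trait appears after
#'   all of its inputs.
#' @export
topological_order <- function(pipeline, roots = NULL) {
  defs <- if (inherits(pipeline, "trait_pipeline")) pipeline$definitions
          else pipeline
  roots <- roots %||% pipeline$roots
  nm <- vapply(defs, `[[`, "", "name")
  pending <- lapply(defs, function(d) setdiff(d$inputs, roots))
  done <- character(0L)
  order_idx <- integer(0L)
  remaining <- seq_along(defs)
  while (length(remaining)) {
    ready <- remaining[vapply(pending[remaining], function(ins)
      all(ins %in% done), logical(1L))]
    if (!length(ready)) {
      stop("trait graph has a cycle involving: ",
           paste(nm[remaining], collapse = ", "))
    }
    nxt <- ready[1L]
    order_idx <- c(order_idx, nxt)
    done <- c(done, nm[nxt])
    remaining <- setdiff(remaining, nxt)
  }
  defs[order_idx]
}

make_frame_ctx <- function(frame, pipeline, image_size) {
  contributing <- function(insts)
    Filter(function(i) n_visible(i) >= 2L, insts)
  primary <- select_longest_instance(contributing(frame$instances$primary))
  ctx <- new.env(parent = emptyenv())
  ctx$primary <- primary
  ctx$config <- pipeline$config
  ctx$height <- image_size[2L]
  ctx$memo <- list()
  if (pipeline$kind == "dicot") {
    ctx$secondary <- contributing(frame$instances$lateral)
    ctx$net_instances <- c(if (!is.null(primary)) list(primary),
                           ctx$secondary)
  } else {
    ctx$secondary <- contributing(frame$instances$main)
    ctx$net_instances <- ctx$secondary
  }
  ctx$cloud <- frame_point_cloud(ctx$net_instances)
  ctx
}

#' Compute per-frame traits
#'
#' Evaluates all trait definitions of a pipeline for one frame, in topological
#' order. Missing prerequisites (no primary root, empty frame, degenerate
#' geometry) propagate as `NaN`; counts are exact regardless.
#'
#' @param frame A [frame_landmarks] object.
#' @param pipeline A `trait_pipeline`.
#' @param image_size `c(width, height)` in px, used for scanline placement.
#'
#' @return Named list of trait values: scalars are length-1 numerics,
#'   non-scalar traits are numeric vectors (one value per root, hull vertex
#'   pair, or scanline).
#' @export
compute_frame_traits <- function(frame, pipeline,
                                 image_size = c(2048, 1088)) {
  ctx <- make_frame_ctx(frame, pipeline, image_size)
  values <- list()
  for (def in topological_order(pipeline)) {
    val <- def$fun(values, ctx)
    if (def$scalar && length(val) != 1L) val <- or_nan(val)[1L]
    values[[def$name]] <- as.numeric(val)
  }
  values[vapply(pipeline$definitions, `[[`, "", "name")]
}

frame_trait_vector <- function(values, pipeline) {
  out <- numeric(0L)
  for (def in pipeline$definitions) {
    v <- values[[def$name]]
    if (def$scalar) {
      out <- c(out, stats::setNames(or_nan(v)[1L], def$name))
    } else {
      s <- summarize_values(v)
      names(s) <- paste(def$name, SUMMARY_STATS, sep = "_")
      out <- c(out, s)
    }
  }
  out
}

#' Trait table column names of a pipeline
#'
#' @param pipeline A `trait_pipeline`.
#' @param level `"plant"` (default) for the fully summarized per-plant columns
#'   (`{trait}_{plantstat}` for scalars, `{trait}_{framestat}_{plantstat}` for
#'   non-scalar traits) or `"frame"` for the expanded per-frame columns.
#' @return Character vector of column names in deterministic order (pipeline
#'   definition order crossed with the fixed statistic order).
#' @export
trait_column_names <- function(pipeline, level = c("plant", "frame")) {
  level <- match.arg(level)
  frame_cols <- unlist(lapply(pipeline$definitions, function(def)
    if (def$scalar) def$name else
      paste(def$name, SUMMARY_STATS, sep = "_")))
  if (level == "frame") return(frame_cols)
  unlist(lapply(frame_cols, function(cn)
    paste(cn, SUMMARY_STATS, sep = "_")))
}

#' Compute summarized per-plant traits
#'
#' Per frame, scalar traits are kept as-is and non-scalar traits are reduced
#' by the nine summary statistics (dicot: 25 + 10 x 9 = 115 per-frame traits;
#' younger monocot: 21 + 9 x 9 = 102). Each per-frame trait is then summarized
#' by the nine statistics across frames (dicot: 115 x 9 = 1,035 per-plant
#' traits; monocot: 102 x 9 = 918). Statistics ignore missing values, so a
#' frame in which a trait is undefined contributes nothing to the plant-level
#' statistic.
#'
#' @param series A [plant_series].
#' @param pipeline A `trait_pipeline`.
#'
#' @return Named numeric vector of summarized traits (1,035 for dicot, 918 for
#'   younger monocot), with the per-frame trait matrix attached as attribute
#'   `"frame_traits"`.
#' @export
compute_plant_traits <- function(series, pipeline) {
  stopifnot(inherits(series, "plant_series"), length(series$frames) >= 1L)
  rows <- lapply(series$frames, function(f)
    frame_trait_vector(compute_frame_traits(f, pipeline, series$image_size),
                       pipeline))
  mat <- do.call(rbind, rows)
  out <- unlist(lapply(colnames(mat), function(cn) {
    s <- summarize_values(mat[, cn])
    names(s) <- paste(cn, SUMMARY_STATS, sep = "_")
    s
  }))
  attr(out, "frame_traits") <- mat
  out
}

#' Compute a trait table for a collection of plants
#'
#' @param series_list Named list of [plant_series] (e.g. from
#'   [read_landmarks] + [merge_series], or [generate_cohort]).
#' @param pipeline A `trait_pipeline`.
#' @param path Optional output CSV path; if given, the table is written with
#'   header `plant_id` followed by the trait columns.
#' @param verbose Log per-plant timing and missing-value fraction.
#'
#' @return A `data.frame` with one row per plant: `plant_id` plus 1,035
#'   (dicot) or 918 (younger monocot) trait columns, in deterministic order.
#' @export
run_batch <- function(series_list, pipeline, path = NULL, verbose = FALSE) {
  cols <- trait_column_names(pipeline)
  rows <- matrix(numeric(0L), nrow = 0L, ncol = length(cols),
                 dimnames = list(NULL, cols))
  ids <- character(0L)
  for (s in series_list) {
    t0 <- proc.time()[["elapsed"]]
    tr <- compute_plant_traits(s, pipeline)
    stopifnot(identical(names(tr), cols))
    rows <- rbind(rows, tr)
    ids <- c(ids, s$plant_id)
    if (verbose)
      message(sprintf("plant %s: %.2fs, %.1f%% missing", s$plant_id,
                      proc.time()[["elapsed"]] - t0,
                      100 * mean(!is.finite(tr))))
  }
  df <- data.frame(plant_id = ids, rows, row.names = NULL,
                   check.names = FALSE)
  if (!is.null(path)) write_trait_table(df, path)
  df
}

#' Write a trait table to CSV
#'
#' @param df Trait table `data.frame` (first column `plant_id`).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_trait_table <- function(df, path) {
  stopifnot(names(df)[1L] == "plant_id")
  num <- vapply(df, is.numeric, logical(1L))
  out <- df
  out[num] <- lapply(df[num], function(v)
    ifelse(is.finite(v), sprintf("%.10g", v), ""))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trait table from CSV
#'
#' @param path CSV path written by [write_trait_table] (or any CSV whose first
#'   column is `plant_id` and remaining columns are numeric traits).
#' @return A `data.frame`.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(plant_id = "character"))
  for (j in setdiff(names(df), "plant_id")) df[[j]] <- as.numeric(df[[j]])
  df
}
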