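#' @title Synthetic root-system generator
#' @name synthetic_roots
#' @description
#' Parametric generator of multi-view landmark series with known ground truth,
#' emulating rotating-stage acquisitions of dicot (primary + lateral) and
#' younger-monocot (primary + crown) root systems. The primary root is a
#' smooth bowed curve resampled to exactly 6 nodes at equal arc length;
#' laterals/crowns are straight polylines anchored on the primary at given
#' arc-length fractions with given angles from gravity. Frame-to-frame
#' rotation is emulated as a rigid sinusoidal horizontal sway of the whole
#' root system, which preserves per-frame geometry (lengths, angles, widths)
#' while exercising multi-view summaries of coordinate traits.
NULL

#' Specify a synthetic plant model
#'
#' @param kind `"dicot"` or `"younger_monocot"`.
#' @param primary_length True arc length of the primary root (px).
#' @param primary_curvature Unitless bow parameter (0 = straight); the primary
#'   follows the shape `x = curvature * sin(pi * t)` before scaling.
#' @param n_children Number of child roots: lateral roots (dicot) or crown
#'   roots (monocot).
#' @param branch_positions Fractions of primary arc length (in (0, 1)) where
#'   child roots attach; recycled/defaulted to evenly spaced positions.
#' @param branch_angles Child root angles from gravity (degrees, one per
#'   child; recycled).
#' @param child_lengths Child root lengths (px; recycled).
#' @param lateral_nodes Nodes per lateral root (3 or 4; crowns always use 6).
#' @param visibility_dropout Probability that a child root's base or tip node
#'   is occluded (applied independently per frame and per terminal node; never
#'   leaves fewer than 2 visible nodes, and never creates interior gaps).
#' @param n_frames Number of frames (default 72).
#' @param rotation_amplitude Amplitude (px) of the sinusoidal per-frame
#'   horizontal sway.
#' @param base_x,base_y Image position of the primary root base (px).
#' @param scale Pixel scale (px/mm).
#' @param image_size `c(width, height)` px.
#' @param seed Integer seed making the generated series reproducible.
#'
#' @return Object of class `plant_model`.
#' @export
plant_model <- function(kind = c("dicot", "younger_monocot"),
                        primary_length = 900,
                        primary_curvature = 0.05,
                        n_children = 4,
                        branch_positions = NULL,
                        branch_angles = 55,
                        child_lengths = 150,
                        lateral_nodes = 4,
                        visibility_dropout = 0,
                        n_frames = 72,
                        rotation_amplitude = 40,
                        base_x = 1024, base_y = 120,
                        scale = 10.6,
                        image_size = c(2048, 1088),
                        seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(primary_length > 0, n_children >= 0,
            visibility_dropout >= 0, visibility_dropout <= 1,
            n_frames >= 1, lateral_nodes %in% c(3L, 4L),
            all(child_lengths > 0))
  if (is.null(branch_positions)) {
    branch_positions <- if (kind == "dicot")
      seq(0.15, 0.6, length.out = max(n_children, 1L))
    else seq(0.02, 0.08, length.out = max(n_children, 1L))
  }
  if (n_children > 0) {
    stopifnot(all(branch_positions > 0), all(branch_positions < 1))
    branch_positions <- rep_len(branch_positions, n_children)
    branch_angles <- rep_len(branch_angles, n_children)
    child_lengths <- rep_len(child_lengths, n_children)
  }
  structure(list(kind = kind, primary_length = primary_length,
                 primary_curvature = primary_curvature,
                 n_children = as.integer(n_children),
                 branch_positions = branch_positions,
                 branch_angles = branch_angles,
                 child_lengths = child_lengths,
                 lateral_nodes = as.integer(lateral_nodes),
                 visibility_dropout = visibility_dropout,
                 n_frames = as.integer(n_frames),
                 rotation_amplitude = rotation_amplitude,
                 base_x = base_x, base_y = base_y, scale = scale,
                 image_size = image_size, seed = as.integer(seed)),
            class = "plant_model")
}

# dense bowed primary curve with true arc length = len; returns the dense
# polyline and a function mapping arc-length fraction to a point on it
primary_curve <- function(len, curvature, base_x, base_y, n_dense = 2001L) {
  t <- seq(0, 1, length.out = n_dense)
  shape <- cbind(curvature * sin(pi * t), t)
  seg <- sqrt(rowSums(diff(shape)^2))
  arc <- c(0, cumsum(seg))
  sc <- len / arc[n_dense]
  pts <- cbind(base_x + shape[, 1L] * sc, base_y + shape[, 2L] * sc)
  arc <- arc * sc
  point_at <- function(frac) {
    s <- frac * len
    i <- findInterval(s, arc, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n_dense - 1L)
    w <- (s - arc[i]) / (arc[i + 1L] - arc[i])
    pts[i, ] + w * (pts[i + 1L, ] - pts[i, ])
  }
  list(point_at = point_at, arc = arc, pts = pts)
}

resample_nodes <- function(curve, n_nodes, len) {
  t(vapply(seq(0, 1, length.out = n_nodes), curve$point_at, numeric(2L)))
}

child_nodes <- function(anchor, angle_deg, len, n_nodes, side) {
  a <- angle_deg * pi / 180
  dir <- c(sin(a) * side, cos(a))
  s <- seq(0, len, length.out = n_nodes)
  cbind(anchor[1L] + s * dir[1L], anchor[2L] + s * dir[2L])
}

apply_dropout <- function(nodes, p) {
  if (p <= 0) return(nodes)
  vis <- rep(TRUE, nrow(nodes))
  if (stats::runif(1L) < p) vis[1L] <- FALSE
  if (stats::runif(1L) < p) vis[length(vis)] <- FALSE
  if (sum(vis) < 2L) return(nodes)   # keep the instance contributing
  nodes[!vis, ] <- NaN
  nodes
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic plant series with ground truth
#'
#' @param model A [plant_model].
#' @param plant_id Plant identifier for the generated series.
#'
#' @return List with elements `series` (a [plant_series]) and `truth`, a
#'   ground-truth record with: `primary_length` (true curve arc length),
#'   `primary_polyline_length` (length of the 6-node resampled polyline, the
#'   value a landmark-based pipeline measures), `primary_curve_index` (of the
#'   6-node polyline), `n_children`, `branch_angles`, `child_lengths`,
#'   `branch_positions`, `deepest_tip_y` (maximal tip y over all roots; sway
#'   does not affect y), and `base_ys` (child base depths).
#' @export
generate_plant <- function(model, plant_id = sprintf("synth-%03d",
                                                     model$seed %% 1000L)) {
  with_seed(model$seed, {
    curve <- primary_curve(model$primary_length, model$primary_curvature,
                           model$base_x, model$base_y)
    prim <- resample_nodes(curve, 6L, model$primary_length)
    n <- model$n_children
    anchors <- if (n > 0)
      t(vapply(model$branch_positions, curve$point_at, numeric(2L)))
    else matrix(numeric(0L), ncol = 2L)
    sides <- if (n > 0) rep_len(c(-1, 1), n) else numeric(0L)
    child_n_nodes <- if (model$kind == "dicot") model$lateral_nodes else 6L
    children <- lapply(seq_len(n), function(k)
      child_nodes(anchors[k, ], model$branch_angles[k],
                  model$child_lengths[k], child_n_nodes, sides[k]))
    frames <- lapply(seq_len(model$n_frames) - 1L, function(fi) {
      dx <- model$rotation_amplitude *
        sin(2 * pi * fi / model$n_frames)
      shift <- function(m) { m[, 1L] <- m[, 1L] + dx; m }
      insts <- list(root_instance(shift(prim), "primary"))
      cls <- if (model$kind == "dicot") "lateral" else "main"
      if (model$kind == "younger_monocot") {
        # the "main" class contains the primary root plus the crown roots
        insts <- c(insts, list(root_instance(shift(prim), "main")))
      }
      for (ch in children) {
        nodes <- apply_dropout(shift(ch), model$visibility_dropout)
        insts <- c(insts, list(root_instance(nodes, cls)))
      }
      frame_landmarks(fi, insts)
    })
    series <- plant_series(plant_id, frames, scale = model$scale,
                           image_size = model$image_size)
    poly_len <- root_length(prim)
    tips_y <- c(prim[6L, 2L],
                if (n > 0) anchors[, 2L] +
                  model$child_lengths * cos(model$branch_angles * pi / 180))
    truth <- list(
      primary_length = model$primary_length,
      primary_polyline_length = poly_len,
      primary_curve_index = curve_index(poly_len, base_tip_distance(prim)),
      n_children = n,
      branch_angles = model$branch_angles,
      child_lengths = model$child_lengths,
      branch_positions = model$branch_positions,
      deepest_tip_y = max(tips_y),
      base_ys = if (n > 0) anchors[, 2L] else numeric(0L)
    )
    list(series = series, truth = truth)
  })
}

#' Generate a cohort of synthetic plants
#'
#' Plant parameters are drawn independently from realistic ranges for young
#' gel-cylinder-grown plants: primary length U(500, 850) px (~47-80 mm at
#' 10.6 px/mm, inside a 110 mm cylinder and the default image frame), bow
#' U(0, 0.1), child count uniform on `children_range`, branch angles
#' U(30, 80) degrees, child lengths U(80, 250) px, branch positions uniform
#' in the class-appropriate zone of the primary.
#'
#' @param n_plants Number of plants (>= 0).
#' @param kind `"dicot"` or `"younger_monocot"`.
#' @param seed Integer seed; the cohort is reproducible given the seed.
#' @param children_range Integer range for the child-root count
#'   (default 2..6).
#' @param visibility_dropout Terminal-node dropout probability (default 0).
#' @param n_frames Frames per plant (default 72).
#'
#' @return List with `plants` (named list of [plant_series]) and `truths`
#'   (named list of ground-truth records).
#' @export
generate_cohort <- function(n_plants, kind = c("dicot", "younger_monocot"),
                            seed = 1L, children_range = c(2L, 6L),
                            visibility_dropout = 0, n_frames = 72L) {
  kind <- match.arg(kind)
  stopifnot(n_plants >= 0)
  plants <- list()
  truths <- list()
  if (n_plants == 0)
    return(list(plants = plants, truths = truths))
  params <- with_seed(seed, {
    lapply(seq_len(n_plants), function(i) {
      n_ch <- sample(seq(children_range[1L], children_range[2L]), 1L)
      pos_zone <- if (kind == "dicot") c(0.1, 0.7) else c(0.02, 0.1)
      list(
        primary_length = stats::runif(1L, 500, 850),
        primary_curvature = stats::runif(1L, 0, 0.1),
        n_children = n_ch,
        branch_positions = sort(stats::runif(n_ch, pos_zone[1L],
                                             pos_zone[2L])),
        branch_angles = stats::runif(n_ch, 30, 80),
        child_lengths = stats::runif(n_ch, 80, 250),
        lateral_nodes = if (kind == "dicot") sample(3:4, 1L) else 4L,
        seed = sample.int(.Machine$integer.max - 1L, 1L)
      )
    })
  })
  for (i in seq_len(n_plants)) {
    p <- params[[i]]
    model <- plant_model(
      kind = kind, primary_length = p$primary_length,
      primary_curvature = p$primary_curvature, n_children = p$n_children,
      branch_positions = p$branch_positions, branch_angles = p$branch_angles,
      child_lengths = p$child_lengths, lateral_nodes = p$lateral_nodes,
      visibility_dropout = visibility_dropout, n_frames = n_frames,
      seed = p$seed)
    pid <- sprintf("plant-%03d", i)
    g <- generate_plant(model, plant_id = pid)
    plants[[pid]] <- g$series
    truths[[pid]] <- g$truth
  }
  list(plants = plants, truths = truths)
}
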