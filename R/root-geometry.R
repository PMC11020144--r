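#' @title Per-root geometry operators
#' @name root_geometry
#' @description
#' Trait operators acting on a single root polyline (or a list of them):
#' lengths, base/tip extraction, gravity angles, curve index, scalar traits
#' derived from lateral bases, and root-width estimation by linear-assignment
#' matching of left/right lateral bases along the primary root. All units are
#' pixels; angles are degrees from the gravity vector (0, +1).
NULL

#' Root length
#'
#' Polyline length: the sum of Euclidean distances between consecutive visible
#' nodes. Because visibility gaps are only permitted at the base or tip,
#' visible nodes are always consecutive along the root.
#'
#' @param instance A [root_instance] or an N x 2 node matrix.
#' @return Length in px; `NaN` if fewer than 2 nodes are visible.
#' @export
root_length <- function(instance) {
  m <- instance_nodes(instance)
  m <- m[visible_mask(instance), , drop = FALSE]
  if (nrow(m) < 2L) return(NaN)
  sum(sqrt(rowSums(diff(m)^2)))
}

#' Base-to-tip distance
#'
#' Straight-line (chord) distance between the first and last visible nodes.
#'
#' @inheritParams root_length
#' @return Distance in px; `NaN` if fewer than 2 nodes are visible.
#' @export
base_tip_distance <- function(instance) {
  m <- instance_nodes(instance)
  m <- m[visible_mask(instance), , drop = FALSE]
  if (nrow(m) < 2L) return(NaN)
  sqrt(sum((m[nrow(m), ] - m[1L, ])^2))
}

#' Curve index
#'
#' `(length - base_tip) / length`: 0 for a straight root, approaching 1 as the
#' root curls back on itself. Lies in \[0, 1) for any valid polyline by the
#' triangle inequality.
#'
#' @param length Root polyline length (px).
#' @param base_tip Base-to-tip chord distance (px).
#' @return Unitless index; `NaN` if inputs are not finite or `length <= 0`.
#' @export
curve_index <- function(length, base_tip) {
  ifelse(is.finite(length) & is.finite(base_tip) & length > 0,
         (length - base_tip) / length, NaN)
}

# unsigned angle (degrees, [0, 180]) between vector (dx, dy) and the gravity
# vector (0, +1); 0 = straight down, 90 = horizontal
angle_from_gravity <- function(dx, dy)
  unname(atan2(abs(dx), dy) * 180 / pi)

#' Gravity angle of a root
#'
#' Angle between the vector from the root's base node to a reference node and
#' the gravity vector (0, +1), in degrees: 0 is straight down, 90 horizontal,
#' values above 90 point upward. The angle is unsigned (left/right symmetric),
#' since on a rotating-stage imaging system signed angles are view-dependent.
#'
#' The reference node depends on `mode`:
#' * `"proximal"`: the last visible node within the first half of the node
#'   list, excluding the base -- a near-base direction estimate;
#' * `"distal"`: the last visible node within the second half of the node
#'   list -- a near-tip direction estimate.
#'
#' @inheritParams root_length
#' @param mode `"proximal"` or `"distal"`.
#' @return Angle in degrees in \[0, 180\]; `NaN` if the base or the reference
#'   node cannot be resolved.
#' @export
gravity_angle <- function(instance, mode = c("proximal", "distal")) {
  mode <- match.arg(mode)
  m <- instance_nodes(instance)
  vis <- visible_mask(instance)
  if (!any(vis)) return(NaN)
  n <- nrow(m)
  base_idx <- which(vis)[1L]
  half <- ceiling(n / 2)
  cand <- if (mode == "proximal") {
    which(vis & seq_len(n) > base_idx & seq_len(n) <= half)
  } else {
    which(vis & seq_len(n) > max(half, base_idx))
  }
  if (!length(cand)) return(NaN)
  ref_idx <- cand[length(cand)]
  angle_from_gravity(m[ref_idx, 1L] - m[base_idx, 1L],
                     m[ref_idx, 2L] - m[base_idx, 2L])
}

#' Base and tip points of root instances
#'
#' The base is node r1 when visible; an instance with an occluded base
#' contributes a `NaN` base (and is excluded from base-derived traits). The
#' tip is the last visible node -- by the labeling convention, the tip
#' landmark is placed at the last discernible point of the root.
#'
#' @param instances List of [root_instance] objects (or node matrices).
#' @return List with numeric vectors `base_xs`, `base_ys`, `tip_xs`, `tip_ys`,
#'   one entry per instance (empty vectors for an empty list).
#' @export
bases_and_tips <- function(instances) {
  n <- length(instances)
  out <- list(base_xs = rep(NaN, n), base_ys = rep(NaN, n),
              tip_xs = rep(NaN, n), tip_ys = rep(NaN, n))
  for (k in seq_len(n)) {
    m <- instance_nodes(instances[[k]])
    vis <- visible_mask(instances[[k]])
    if (vis[1L]) {
      out$base_xs[k] <- m[1L, 1L]
      out$base_ys[k] <- m[1L, 2L]
    }
    if (any(vis)) {
      tip <- which(vis)[sum(vis)]
      out$tip_xs[k] <- m[tip, 1L]
      out$tip_ys[k] <- m[tip, 2L]
    }
  }
  out
}

#' Scalar traits derived from lateral root bases
#'
#' @param base_ys Y coordinates of lateral root bases (px), `NaN` for occluded
#'   bases.
#' @param primary_length Primary root length (px).
#' @param primary_tip_y Y coordinate of the primary root tip (px).
#' @param n_instances Number of lateral root instances (defaults to
#'   `length(base_ys)`).
#'
#' @return Named list: `base_length` (y-extent between first and last visible
#'   base), `base_length_ratio` (`base_length / primary_length`),
#'   `base_median_ratio` (median base y over primary tip y), `base_ct_density`
#'   (visible base count over primary length), and `lateral_count`. Base
#'   traits are `NaN` when no visible base exists; the count is always exact.
#' @export
base_scalar_traits <- function(base_ys, primary_length, primary_tip_y,
                               n_instances = length(base_ys)) {
  ys <- base_ys[is.finite(base_ys)]
  ok_len <- is.finite(primary_length) && primary_length > 0
  if (!length(ys)) {
    return(list(base_length = NaN, base_length_ratio = NaN,
                base_median_ratio = NaN, base_ct_density = NaN,
                lateral_count = n_instances))
  }
  base_length <- max(ys) - min(ys)
  list(
    base_length = base_length,
    base_length_ratio = if (ok_len) base_length / primary_length else NaN,
    base_median_ratio = if (is.finite(primary_tip_y) && primary_tip_y != 0)
      stats::median(ys) / primary_tip_y else NaN,
    base_ct_density = if (ok_len) length(ys) / primary_length else NaN,
    lateral_count = n_instances
  )
}

#' Root-width matching configuration
#'
#' @param projection_tolerance Maximum allowed difference between the
#'   normalized arc-length projections of a matched left/right base pair,
#'   as a fraction of the primary root length (default 0.02).
#' @param require_crossing If `TRUE` (default), a matched pair is kept only if
#'   the segment connecting the two bases intersects the primary root
#'   polyline.
#'
#' @return An object of class `width_match_config`.
#' @export
width_match_config <- function(projection_tolerance = 0.02,
                               require_crossing = TRUE) {
  stopifnot(projection_tolerance >= 0)
  structure(list(projection_tolerance = projection_tolerance,
                 require_crossing = require_crossing),
            class = "width_match_config")
}

# nearest point of each query point on a piecewise-linear polyline;
# returns per point: normalized arc-length position in [0,1], side of the
# locally nearest segment (sign of the 2D cross product of the segment
# direction with the vector to the point; 0 = on the line), and squared
# distance. Ties between segments resolve to the first (lowest-index) one.
polyline_projection <- function(poly, pts) {
  seg_d <- diff(poly)
  seg_len <- sqrt(rowSums(seg_d^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  n_pts <- nrow(pts)
  proj <- side <- dist2 <- numeric(n_pts)
  for (k in seq_len(n_pts)) {
    p <- pts[k, ]
    best <- Inf; best_arc <- 0; best_side <- 0
    for (i in seq_len(nrow(seg_d))) {
      if (seg_len[i] == 0) next
      v <- p - poly[i, ]
      t <- max(0, min(1, sum(v * seg_d[i, ]) / seg_len[i]^2))
      q <- poly[i, ] + t * seg_d[i, ]
      d2 <- sum((p - q)^2)
      if (d2 < best) {
        best <- d2
        best_arc <- cum[i] + t * seg_len[i]
        w <- p - q
        best_side <- sign(seg_d[i, 1L] * w[2L] - seg_d[i, 2L] * w[1L])
      }
    }
    proj[k] <- if (total > 0) max(0, min(1, best_arc / total)) else NaN
    side[k] <- best_side
    dist2[k] <- best
  }
  list(projection = proj, side = side, dist2 = dist2)
}

# do segments (p1,p2) and (q1,q2) intersect (touching counts)?
segments_intersect <- function(p1, p2, q1, q2) {
  o <- function(a, b, c)
    sign((b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L]))
  d1 <- o(q1, q2, p1); d2 <- o(q1, q2, p2)
  d3 <- o(p1, p2, q1); d4 <- o(p1, p2, q2)
  if (d1 != d2 && d3 != d4) return(TRUE)
  on_seg <- function(a, b, c)
    o(a, b, c) == 0 &&
      min(a[1L], b[1L]) <= c[1L] && c[1L] <= max(a[1L], b[1L]) &&
      min(a[2L], b[2L]) <= c[2L] && c[2L] <= max(a[2L], b[2L])
  on_seg(q1, q2, p1) || on_seg(q1, q2, p2) ||
    on_seg(p1, p2, q1) || on_seg(p1, p2, q2)
}

segment_crosses_polyline <- function(p1, p2, poly) {
  for (i in seq_len(nrow(poly) - 1L))
    if (segments_intersect(p1, p2, poly[i, ], poly[i + 1L, ])) return(TRUE)
  FALSE
}

# Minimum-cost rectangular linear assignment (Hungarian algorithm with
# potentials). Returns, for each row, the assigned column (0 = unassigned);
# all rows are assigned when nrow <= ncol, otherwise all columns are.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(integer(n))
  if (n > m) {
    col_of_row <- integer(n)
    row_of_col <- solve_assignment(t(cost))
    col_of_row[row_of_col] <- seq_len(m)
    return(col_of_row)
  }
  u <- numeric(n); v <- numeric(m + 1L)   # v[m+1] is the virtual column
  p <- integer(m + 1L)                    # p[j] = row matched to column j
  way <- integer(m)
  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- logical(m); used0 <- FALSE
    repeat {
      if (j0 == 0L) used0 <- TRUE else used[j0] <- TRUE
      i0 <- if (j0 == 0L) p[m + 1L] else p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      if (used0) { u[p[m + 1L]] <- u[p[m + 1L]] + delta
                   v[m + 1L] <- v[m + 1L] - delta }
      sel <- which(used)
      if (length(sel)) {
        u[p[sel]] <- u[p[sel]] + delta
        v[sel] <- v[sel] - delta
      }
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      if (j1 == 0L) { p[j0] <- p[m + 1L]; break }
      p[j0] <- p[j1]
      j0 <- j1
    }
  }
  match <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) match[p[j]] <- j
  match
}

#' Estimate primary root widths from paired lateral root bases
#'
#' Visible lateral root bases are split into those lying to the left and to
#' the right of the primary root polyline (by the sign of the cross product of
#' the locally nearest primary segment direction with the vector from the
#' nearest point on the primary to the base; bases exactly on the line are
#' excluded). Each base is assigned its normalized arc-length projection onto
#' the primary polyline, and left and right bases are paired by solving the
#' rectangular linear assignment problem on the cost matrix of absolute
#' projection differences (Hungarian algorithm). Pairs whose projection
#' difference exceeds `projection_tolerance`, or (when `require_crossing`)
#' whose connecting segment does not intersect the primary polyline, are
#' dropped. The widths are the Euclidean distances between the surviving base
#' pairs.
#'
#' @param primary The primary [root_instance] (at least 2 visible nodes).
#' @param laterals List of lateral [root_instance] objects.
#' @param config A [width_match_config].
#'
#' @return Numeric vector of widths (px), possibly empty.
#' @export
match_root_widths <- function(primary, laterals,
                              config = width_match_config()) {
  if (is.null(primary) || n_visible(primary) < 2L) return(numeric(0L))
  poly <- instance_nodes(primary)
  poly <- poly[visible_mask(primary), , drop = FALSE]
  bt <- bases_and_tips(laterals)
  ok <- is.finite(bt$base_xs) & is.finite(bt$base_ys)
  if (!any(ok)) return(numeric(0L))
  bases <- cbind(bt$base_xs[ok], bt$base_ys[ok])
  pr <- polyline_projection(poly, bases)
  left <- which(pr$side > 0)
  right <- which(pr$side < 0)
  if (!length(left) || !length(right)) return(numeric(0L))
  cost <- abs(outer(pr$projection[left], pr$projection[right], "-"))
  match <- solve_assignment(cost)
  widths <- numeric(0L)
  for (i in seq_along(left)) {
    j <- match[i]
    if (j == 0L) next
    if (cost[i, j] > config$projection_tolerance) next
    b1 <- bases[left[i], ]; b2 <- bases[right[j], ]
    if (config$require_crossing && !segment_crosses_polyline(b1, b2, poly))
      next
    widths <- c(widths, sqrt(sum((b1 - b2)^2)))
  }
  widths
}
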