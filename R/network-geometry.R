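#' @title Frame-level root-network morphometrics
#' @name network_geometry
#' @description
#' Whole-root-system traits computed per frame from the point cloud of all
#' visible landmark nodes and from the set of root polylines: convex hull
#' descriptors, least-squares ellipse fit, horizontal scanline intersection
#' profile, bounding box, and network length/solidity/depth distribution.
NULL

# matrix of all visible nodes of a list of instances (0-row matrix if none)
frame_point_cloud <- function(instances) {
  pts <- do.call(rbind, lapply(instances, function(i)
    instance_nodes(i)[visible_mask(i), , drop = FALSE]))
  if (is.null(pts)) pts <- matrix(numeric(0L), ncol = 2L)
  colnames(pts) <- c("x", "y")
  pts
}

hull_degenerate <- list(chull_perimeter = NaN, chull_area = NaN,
                        chull_max_width = NaN, chull_max_height = NaN,
                        chull_line_lengths = NaN)

#' Convex hull traits of a point cloud
#'
#' @param cloud Numeric matrix of (x, y) points (all visible landmark nodes in
#'   a frame). Non-finite rows are dropped.
#'
#' @return Named list: `chull_perimeter`, `chull_area` (shoelace formula),
#'   `chull_max_width` / `chull_max_height` (maximum x / y difference between
#'   hull vertices), and `chull_line_lengths` (Euclidean distances between all
#'   unordered pairs of hull vertices). All `NaN` when the hull is undefined
#'   (fewer than 3 non-collinear points).
#' @export
convex_hull_traits <- function(cloud) {
  pts <- cloud[is.finite(cloud[, 1L]) & is.finite(cloud[, 2L]), ,
               drop = FALSE]
  pts <- unique(pts)
  if (nrow(pts) < 3L) return(hull_degenerate)
  h <- grDevices::chull(pts)
  verts <- pts[h, , drop = FALSE]
  if (nrow(verts) < 3L) return(hull_degenerate)
  xs <- verts[, 1L]; ys <- verts[, 2L]
  area <- abs(sum(xs * ys[c(2:length(ys), 1L)] -
                  xs[c(2:length(xs), 1L)] * ys)) / 2
  if (area == 0) return(hull_degenerate)
  closed <- rbind(verts, verts[1L, ])
  list(chull_perimeter = sum(sqrt(rowSums(diff(closed)^2))),
       chull_area = area,
       chull_max_width = max(xs) - min(xs),
       chull_max_height = max(ys) - min(ys),
       chull_line_lengths = as.numeric(stats::dist(verts)))
}

#' Least-squares ellipse fit of a point cloud
#'
#' Direct algebraic conic fit with the ellipse-specific constraint
#' (stabilized Fitzgibbon method): minimizes algebraic distance subject to
#' `4AC - B^2 = 1`, guaranteeing an ellipse solution when one exists.
#'
#' @inheritParams convex_hull_traits
#'
#' @return Named list: `ellipse_a` (semi-major axis, px), `ellipse_b`
#'   (semi-minor axis, px), `ellipse_ratio` (`a/b`, >= 1). All `NaN` for
#'   degenerate input (fewer than 5 points, collinear points) or a
#'   non-convergent/non-elliptical fit.
#' @export
fit_ellipse_traits <- function(cloud) {
  bad <- list(ellipse_a = NaN, ellipse_b = NaN, ellipse_ratio = NaN)
  pts <- cloud[is.finite(cloud[, 1L]) & is.finite(cloud[, 2L]), ,
               drop = FALSE]
  pts <- unique(pts)
  if (nrow(pts) < 5L) return(bad)
  # center and scale for numerical conditioning
  mx <- mean(pts[, 1L]); my <- mean(pts[, 2L])
  sc <- max(stats::sd(pts[, 1L]), stats::sd(pts[, 2L]))
  if (!is.finite(sc) || sc == 0) return(bad)
  x <- (pts[, 1L] - mx) / sc
  y <- (pts[, 2L] - my) / sc
  fit <- tryCatch({
    D1 <- cbind(x^2, x * y, y^2)
    D2 <- cbind(x, y, 1)
    S1 <- crossprod(D1)
    S2 <- crossprod(D1, D2)
    S3 <- crossprod(D2)
    Tm <- -solve(S3, t(S2))
    M <- S1 + S2 %*% Tm
    M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
    ev <- eigen(M)
    V <- Re(ev$vectors)
    cond <- 4 * V[1L, ] * V[3L, ] - V[2L, ]^2
    k <- which(cond > 0)
    if (!length(k)) return(bad)
    a1 <- V[, k[1L]]
    c(a1, as.numeric(Tm %*% a1))
  }, error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(fit))) return(bad)
  A <- fit[1L]; B <- fit[2L]; C <- fit[3L]
  D <- fit[4L]; E <- fit[5L]; F <- fit[6L]
  den <- B^2 - 4 * A * C
  if (!(den < 0)) return(bad)
  # semi-axes of the general conic
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  s <- sqrt((A - C)^2 + B^2)
  ax2 <- num * (A + C + c(s, -s)) / den^2
  if (any(ax2 <= 0) || any(!is.finite(ax2))) return(bad)
  axes <- sort(sqrt(ax2), decreasing = TRUE) * sc
  list(ellipse_a = axes[1L], ellipse_b = axes[2L],
       ellipse_ratio = axes[1L] / axes[2L])
}

#' Scanline configuration
#'
#' @param n_lines Number of evenly spaced horizontal scanlines (>= 2,
#'   default 50), placed from y = 0 to y = `height` inclusive.
#' @param height Image height in px (default 1088).
#' @return Object of class `scanline_config`.
#' @export
scanline_config <- function(n_lines = 50, height = 1088) {
  stopifnot(n_lines >= 2, height > 0)
  structure(list(n_lines = as.integer(n_lines), height = height),
            class = "scanline_config")
}

#' Scanline intersection profile
#'
#' Horizontal scanlines are placed at `y_i = i * height / (n_lines - 1)` for
#' `i = 0 ... n_lines - 1` (top to bottom). Each polyline segment of each
#' instance whose half-open y-interval `[min(y), max(y))` contains `y_i`
#' counts one intersection with line i; exactly horizontal segments are
#' ignored. The half-open convention makes counts deterministic when segments
#' share endpoint y values; so that a root is still counted on a line exactly
#' touching its deepest point (e.g. a tip ending exactly on the bottom line),
#' a line equal to the instance's maximal y counts one extra intersection.
#'
#' @param instances List of [root_instance] objects.
#' @param config A [scanline_config].
#'
#' @return Named list: `scanline_intersection_counts` (integer vector of
#'   length `n_lines`), `scanline_first_ind` and `scanline_last_ind` (0-based
#'   indices of the first/last line with a nonzero count, `NaN` when no line
#'   intersects any root).
#' @export
scanline_profile <- function(instances, config = scanline_config()) {
  ys <- seq(0, config$height, length.out = config$n_lines)
  counts <- integer(config$n_lines)
  for (inst in instances) {
    m <- instance_nodes(inst)
    m <- m[visible_mask(inst), , drop = FALSE]
    if (nrow(m) < 2L) next
    for (i in seq_len(nrow(m) - 1L)) {
      lo <- min(m[i, 2L], m[i + 1L, 2L])
      hi <- max(m[i, 2L], m[i + 1L, 2L])
      if (lo == hi) next
      hit <- ys >= lo & ys < hi
      counts[hit] <- counts[hit] + 1L
    }
    deepest <- ys == max(m[, 2L])
    counts[deepest] <- counts[deepest] + 1L
  }
  nz <- which(counts > 0L)
  list(scanline_intersection_counts = counts,
       scanline_first_ind = if (length(nz)) nz[1L] - 1L else NaN,
       scanline_last_ind = if (length(nz)) nz[length(nz)] - 1L else NaN)
}

# total polyline length of the parts of all instances lying at or below the
# horizontal line y = y_min + (1 - fraction) * depth of the cloud's bounding
# box; segments are split exactly at the boundary (linear interpolation)
network_length_below <- function(instances, threshold) {
  total <- 0
  for (inst in instances) {
    m <- instance_nodes(inst)
    m <- m[visible_mask(inst), , drop = FALSE]
    if (nrow(m) < 2L) next
    for (i in seq_len(nrow(m) - 1L)) {
      p <- m[i, ]; q <- m[i + 1L, ]
      len <- sqrt(sum((q - p)^2))
      if (len == 0) next
      y1 <- p[2L]; y2 <- q[2L]
      if (y1 >= threshold && y2 >= threshold) {
        total <- total + len
      } else if (y1 < threshold && y2 < threshold) {
        # nothing
      } else {
        frac_below <- (max(y1, y2) - threshold) / abs(y2 - y1)
        total <- total + len * frac_below
      }
    }
  }
  unname(total)
}

#' Network-level traits
#'
#' @param instances List of [root_instance] objects in the frame.
#' @param cloud Point cloud of all visible nodes (see [frame_point_cloud]
#'   is internal; any (x, y) matrix works).
#' @param chull_area Convex hull area of the cloud (px^2), e.g. from
#'   [convex_hull_traits].
#' @param lower_fraction Fraction of the bounding-box depth defining the
#'   "lower" region (default 2/3): the region with
#'   `y >= y_min + (1 - lower_fraction) * depth`.
#'
#' @return Named list: `network_length` (sum of root lengths, px),
#'   `network_width_depth_ratio` (bounding-box x-extent over y-extent),
#'   `network_solidity` (`network_length / chull_area`, 1/px),
#'   `network_length_lower` (root length inside the lower region, px, with
#'   segments split exactly at the boundary), and
#'   `network_length_distribution` (`lower / total`). Degenerate inputs give
#'   `NaN` for the affected traits.
#' @export
network_traits <- function(instances, cloud, chull_area,
                           lower_fraction = 2 / 3) {
  lens <- vapply(instances, root_length, numeric(1L))
  lens <- lens[is.finite(lens)]
  network_length <- if (length(lens)) sum(lens) else NaN
  pts <- cloud[is.finite(cloud[, 1L]) & is.finite(cloud[, 2L]), ,
               drop = FALSE]
  if (!nrow(pts)) {
    return(list(network_length = network_length,
                network_width_depth_ratio = NaN, network_solidity = NaN,
                network_length_lower = NaN,
                network_length_distribution = NaN))
  }
  width <- max(pts[, 1L]) - min(pts[, 1L])
  depth <- max(pts[, 2L]) - min(pts[, 2L])
  threshold <- min(pts[, 2L]) + (1 - lower_fraction) * depth
  lower <- network_length_below(instances, threshold)
  list(
    network_length = network_length,
    network_width_depth_ratio = if (depth > 0) width / depth else NaN,
    network_solidity = if (is.finite(chull_area) && is.finite(network_length)
                           && chull_area > 0)
      network_length / chull_area else NaN,
    network_length_lower = if (is.finite(network_length)) lower else NaN,
    network_length_distribution =
      if (is.finite(network_length) && network_length > 0)
        lower / network_length else NaN
  )
}
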