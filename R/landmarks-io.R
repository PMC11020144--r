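#' @title Landmark data model and exchange format
#' @name landmarks_io
#' @description
#' Roots are represented as ordered polylines of landmark nodes in image
#' coordinates (origin top-left, y increasing downward so that deeper roots
#' have larger y). A root instance has a fixed number of nodes per root class
#' (six for primary/crown roots, three to four for lateral roots); occluded
#' nodes are encoded as `NaN` coordinates and may only occur as a contiguous
#' run at the base or at the tip of the polyline.
NULL

RLCSV_HEADER <- c("plant_id", "frame_idx", "root_class", "instance_idx",
                  "node_idx", "x", "y")
ROOT_CLASSES <- c("primary", "lateral", "main")

#' Create a root instance
#'
#' @param nodes Numeric matrix with one row per landmark node and two columns
#'   (x, y), ordered from base (r1) to tip (rN). Occluded nodes are encoded as
#'   `NaN`/`NA` in both columns.
#' @param root_class One of `"primary"`, `"lateral"`, `"main"`.
#' @param id Optional character label used in validation messages.
#'
#' @details Interior visibility gaps (an occluded node between two visible
#'   ones) are invalid: occlusions are only permitted as a contiguous run at
#'   the start (occluded base) or end (occluded tip) of the node list.
#'
#' @return An object of class `root_instance`: a list with elements `nodes`
#'   (N x 2 numeric matrix) and `root_class`.
#' @export
root_instance <- function(nodes, root_class, id = NULL) {
  nodes <- as.matrix(nodes)
  if (ncol(nodes) != 2L)
    stop("'nodes' must be a matrix with two columns (x, y)")
  storage.mode(nodes) <- "double"
  colnames(nodes) <- c("x", "y")
  root_class <- match.arg(root_class, ROOT_CLASSES)
  vx <- is.finite(nodes[, 1L])
  vy <- is.finite(nodes[, 2L])
  if (any(vx != vy))
    stop("invalid node encoding: x and y must be both finite or both missing",
         if (!is.null(id)) paste0(" (", id, ")"))
  check_no_interior_gap(vx, id)
  structure(list(nodes = nodes, root_class = root_class),
            class = "root_instance")
}

check_no_interior_gap <- function(visible, id = NULL) {
  if (!any(visible)) return(invisible(TRUE))
  span <- range(which(visible))
  if (!all(visible[span[1L]:span[2L]]))
    stop("interior visibility gap in root instance",
         if (!is.null(id)) paste0(" ", id),
         ": occluded nodes may only occur at the base or the tip")
  invisible(TRUE)
}

# N x 2 matrix of nodes regardless of whether a root_instance or a bare
# matrix was supplied; geometry operators accept both.
instance_nodes <- function(x) {
  if (inherits(x, "root_instance")) x$nodes else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

visible_mask <- function(x) {
  m <- instance_nodes(x)
  is.finite(m[, 1L]) & is.finite(m[, 2L])
}

n_visible <- function(x) sum(visible_mask(x))

#' Create a frame of root landmarks
#'
#' @param frame_index Integer frame index (0-based; a full multi-view series
#'   typically has indices 0 to 71).
#' @param instances List of [root_instance] objects observed in this frame.
#'
#' @return An object of class `frame_landmarks` with elements `frame_index`
#'   and `instances` (a list named by root class, each a list of instances).
#' @export
frame_landmarks <- function(frame_index, instances = list()) {
  stopifnot(length(frame_index) == 1L, is.finite(frame_index))
  grouped <- list(primary = list(), lateral = list(), main = list())
  for (inst in instances) {
    if (!inherits(inst, "root_instance"))
      stop("all instances must be root_instance objects")
    grouped[[inst$root_class]] <- c(grouped[[inst$root_class]], list(inst))
  }
  structure(list(frame_index = as.integer(frame_index), instances = grouped),
            class = "frame_landmarks")
}

#' Create a plant series
#'
#' A plant series is the ordered sequence of landmark frames captured for one
#' plant on the rotating-stage imaging system (5 degree steps, typically 72
#' frames), plus acquisition metadata.
#'
#' @param plant_id Character plant identifier (e.g. cylinder barcode).
#' @param frames List of [frame_landmarks], sorted by frame index.
#' @param scale Pixel scale in px/mm (default 10.6).
#' @param image_size Integer vector `c(width, height)` in px
#'   (default `c(2048, 1088)`).
#'
#' @return An object of class `plant_series`.
#' @export
plant_series <- function(plant_id, frames, scale = 10.6,
                         image_size = c(2048, 1088)) {
  stopifnot(is.character(plant_id), length(plant_id) == 1L,
            length(image_size) == 2L, scale > 0)
  idx <- vapply(frames, function(f) f$frame_index, integer(1L))
  if (anyDuplicated(idx))
    stop("duplicate frame_index in series '", plant_id, "'")
  frames <- frames[order(idx)]
  structure(list(plant_id = plant_id, frames = frames, scale = scale,
                 image_size = as.numeric(image_size)),
            class = "plant_series")
}

#' @export
print.plant_series <- function(x, ...) {
  n_inst <- vapply(x$frames, function(f)
    sum(lengths(f$instances)), integer(1L))
  cat(sprintf("<plant_series '%s': %d frames, %s instances/frame, %g px/mm>\n",
              x$plant_id, length(x$frames),
              if (length(n_inst)) paste0(min(n_inst), "-", max(n_inst)) else "0",
              x$scale))
  invisible(x)
}

#' Read a root landmark CSV (RLCSV) file
#'
#' The RLCSV exchange dialect is a plain UTF-8 CSV with header exactly
#' `plant_id,frame_idx,root_class,instance_idx,node_idx,x,y`. `node_idx` is
#' 0-based from base to tip; an occluded node is a row with empty `x` and `y`
#' fields; rows need not be sorted.
#'
#' @param path Path to the CSV file.
#' @param root_class Optional class filter (`"primary"`, `"lateral"`,
#'   `"main"`); if given, only rows of that class are read.
#' @param scale,image_size Acquisition metadata attached to each series (see
#'   [plant_series]).
#'
#' @return A named list of [plant_series], keyed and sorted by `plant_id`.
#' @export
read_landmarks <- function(path, root_class = NULL, scale = 10.6,
                           image_size = c(2048, 1088)) {
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), paste(RLCSV_HEADER, collapse = ",")))
    stop("malformed RLCSV header in '", path, "': expected '",
         paste(RLCSV_HEADER, collapse = ","), "'")
  df <- utils::read.csv(path, colClasses = c(
    plant_id = "character", frame_idx = "integer", root_class = "character",
    instance_idx = "integer", node_idx = "integer", x = "numeric",
    y = "numeric"), na.strings = "")
  if (!is.null(root_class)) {
    root_class <- match.arg(root_class, ROOT_CLASSES)
    df <- df[df$root_class == root_class, , drop = FALSE]
  }
  bad <- setdiff(unique(df$root_class), ROOT_CLASSES)
  if (length(bad))
    stop("unknown root_class value(s): ", paste(bad, collapse = ", "))
  key <- paste(df$plant_id, df$frame_idx, df$root_class, df$instance_idx,
               df$node_idx)
  if (anyDuplicated(key))
    stop("duplicate (plant, frame, class, instance, node) record(s), e.g.: ",
         key[duplicated(key)][1L])
  out <- list()
  for (pid in sort(unique(df$plant_id))) {
    dp <- df[df$plant_id == pid, , drop = FALSE]
    frames <- list()
    for (fi in sort(unique(dp$frame_idx))) {
      dfr <- dp[dp$frame_idx == fi, , drop = FALSE]
      insts <- list()
      ord_key <- order(match(dfr$root_class, ROOT_CLASSES), dfr$instance_idx)
      dfr <- dfr[ord_key, , drop = FALSE]
      for (grp in split(dfr, paste(match(dfr$root_class, ROOT_CLASSES),
                                   dfr$instance_idx), drop = TRUE)) {
        grp <- grp[order(grp$node_idx), , drop = FALSE]
        if (!identical(grp$node_idx, seq_len(nrow(grp)) - 1L))
          stop("non-contiguous node_idx for plant '", pid, "' frame ", fi,
               " ", grp$root_class[1L], " instance ", grp$instance_idx[1L])
        nodes <- cbind(x = grp$x, y = grp$y)
        nodes[is.na(nodes)] <- NaN
        insts <- c(insts, list(root_instance(
          nodes, grp$root_class[1L],
          id = sprintf("plant '%s' frame %d %s instance %d", pid, fi,
                       grp$root_class[1L], grp$instance_idx[1L]))))
      }
      frames <- c(frames, list(frame_landmarks(fi, insts)))
    }
    series <- plant_series(pid, frames, scale = scale,
                           image_size = image_size)
    validate_series(series)
    out[[pid]] <- series
  }
  # instances are re-indexed 0..k-1 within class on read; original indices are
  # only used for grouping and ordering
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

validate_series <- function(series) {
  w <- series$image_size[1L]; h <- series$image_size[2L]
  for (cls in ROOT_CLASSES) {
    ns <- unlist(lapply(series$frames, function(f)
      vapply(f$instances[[cls]], function(i) nrow(i$nodes), integer(1L))))
    if (!length(ns)) next
    if (length(unique(ns)) > 1L)
      warning("node count not uniform within class '", cls, "' in series '",
              series$plant_id, "': ", paste(unique(ns), collapse = ", "))
    expected <- if (cls == "lateral") c(3L, 4L) else 6L
    if (!all(unique(ns) %in% expected))
      warning("unexpected node count for class '", cls, "' in series '",
              series$plant_id, "' (expected ",
              paste(expected, collapse = " or "), ")")
  }
  xy <- do.call(rbind, lapply(series$frames, function(f)
    do.call(rbind, lapply(unlist(f$instances, recursive = FALSE),
                          instance_nodes))))
  if (!is.null(xy)) {
    vis <- is.finite(xy[, 1L])
    if (any(vis & (xy[, 1L] < 0 | xy[, 1L] > w | xy[, 2L] < 0 | xy[, 2L] > h)))
      warning("series '", series$plant_id,
              "' has visible nodes outside the image bounds")
  }
  invisible(series)
}

fmt_coord <- function(v) ifelse(is.finite(v), sprintf("%.10g", v), "")

#' Write plant series to a root landmark CSV (RLCSV) file
#'
#' Rows are written sorted by plant, frame, root class, instance, and node, so
#' that a read/write cycle is idempotent (the second write is byte-identical).
#'
#' @param series A [plant_series] or a (named) list of them.
#' @param path Output file path.
#' @param root_class Optional class filter; if given, only instances of that
#'   class are written.
#'
#' @return Invisibly, the path.
#' @export
write_landmarks <- function(series, path, root_class = NULL) {
  if (inherits(series, "plant_series")) series <- list(series)
  rows <- character(0L)
  for (s in series[order(vapply(series, `[[`, "", "plant_id"))]) {
    for (f in s$frames) {
      for (cls in if (is.null(root_class)) ROOT_CLASSES else root_class) {
        insts <- f$instances[[cls]]
        for (k in seq_along(insts)) {
          m <- insts[[k]]$nodes
          rows <- c(rows, sprintf("%s,%d,%s,%d,%d,%s,%s",
                                  s$plant_id, f$frame_index, cls, k - 1L,
                                  seq_len(nrow(m)) - 1L,
                                  fmt_coord(m[, 1L]), fmt_coord(m[, 2L])))
        }
      }
    }
  }
  writeLines(c(paste(RLCSV_HEADER, collapse = ","), rows), path)
  invisible(path)
}

#' Merge two plant-series collections by root class
#'
#' Combines, per plant and frame, the instances of two collections (typically
#' one holding primary-root predictions and one holding lateral- or crown-root
#' predictions). Plants present in only one input are kept, with a warning,
#' and carry no instances of the missing class.
#'
#' @param primary Named list of [plant_series] (usually the primary class).
#' @param secondary Named list of [plant_series] of the complementary class
#'   (`lateral` or `main`).
#'
#' @return Named list of merged [plant_series].
#' @export
merge_series <- function(primary, secondary) {
  ids <- sort(union(names(primary), names(secondary)))
  out <- list()
  for (pid in ids) {
    a <- primary[[pid]]; b <- secondary[[pid]]
    if (is.null(a) || is.null(b)) {
      warning("plant '", pid, "' present in only one input; the other root ",
              "class is empty")
      out[[pid]] <- a %||% b
      next
    }
    if (length(a$frames) != length(b$frames))
      stop("conflicting frame counts for plant '", pid, "': ",
           length(a$frames), " vs ", length(b$frames))
    ia <- vapply(a$frames, `[[`, integer(1L), "frame_index")
    ib <- vapply(b$frames, `[[`, integer(1L), "frame_index")
    if (!identical(ia, ib))
      stop("frame indices disagree for plant '", pid, "'")
    frames <- mapply(function(fa, fb) {
      merged <- fa
      for (cls in ROOT_CLASSES)
        merged$instances[[cls]] <- c(fa$instances[[cls]], fb$instances[[cls]])
      merged
    }, a$frames, b$frames, SIMPLIFY = FALSE)
    out[[pid]] <- plant_series(pid, frames, scale = a$scale,
                               image_size = a$image_size)
  }
  out
}

#' Select the longest root instance
#'
#' Resolves multiple detections of a root that should be unique in a frame
#' (e.g. the primary root) to a single instance: the one with the largest
#' polyline length, ties broken by the lowest instance index.
#'
#' @param instances List of [root_instance] objects.
#'
#' @return The selected [root_instance], or `NULL` for an empty list.
#' @export
select_longest_instance <- function(instances) {
  if (!length(instances)) return(NULL)
  lens <- vapply(instances, root_length, numeric(1L))
  lens[!is.finite(lens)] <- -Inf
  instances[[which.max(lens)]]
}
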