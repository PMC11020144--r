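# Independent oracles and small constructors used across tests. The oracles
# deliberately avoid the code paths they check: convex hull by gift wrapping,
# assignment by exhaustive permutation search.

# straight root instance from `from` towards unit direction of `to`, with
# n nodes evenly spaced (inclusive of both endpoints)
straight_instance <- function(from, to, n = 6L, root_class = "primary") {
  s <- seq(0, 1, length.out = n)
  root_instance(cbind(from[1] + s * (to[1] - from[1]),
                      from[2] + s * (to[2] - from[2])), root_class)
}

# lateral with a prescribed base point (only the base matters for width
# matching); runs diagonally down-outward from the base
lateral_at <- function(base, n = 4L, dir = c(1, 1)) {
  s <- seq(0, 20, length.out = n)
  root_instance(cbind(base[1] + s * dir[1], base[2] + s * dir[2]), "lateral")
}

cross2 <- function(o, a, b)
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])

# convex hull area and perimeter by gift wrapping (Jarvis march)
oracle_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3L) return(list(area = NaN, perimeter = NaN))
  start <- order(pts[, 1], pts[, 2])[1]
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    nxt <- if (cur == 1L) 2L else 1L
    for (j in seq_len(n)) {
      if (j == cur) next
      cr <- cross2(pts[cur, ], pts[nxt, ], pts[j, ])
      further <- sum((pts[j, ] - pts[cur, ])^2) >
        sum((pts[nxt, ] - pts[cur, ])^2)
      if (cr < 0 || (cr == 0 && further)) nxt <- j
    }
    cur <- nxt
    if (cur == start) break
    if (length(hull) > n) stop("gift wrapping failed to close")
  }
  if (length(hull) < 3L) return(list(area = NaN, perimeter = NaN))
  v <- pts[hull, , drop = FALSE]
  xs <- v[, 1]; ys <- v[, 2]
  area <- abs(sum(xs * ys[c(2:length(ys), 1)] -
                  xs[c(2:length(xs), 1)] * ys)) / 2
  if (area == 0) return(list(area = NaN, perimeter = NaN))
  closed <- rbind(v, v[1, ])
  list(area = area, perimeter = sum(sqrt(rowSums(diff(closed)^2))))
}

# minimum total assignment cost over all injective row -> column maps,
# by exhaustive permutation (requires nrow <= ncol after orientation)
oracle_assignment_cost <- function(cost) {
  if (nrow(cost) > ncol(cost)) cost <- t(cost)
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) { best <<- acc; return() }
    for (j in seq_len(m)) if (!used[j]) {
      used[j] <- TRUE
      rec(i + 1L, used, acc + cost[i, j])
      used[j] <- FALSE
    }
  }
  rec(1L, logical(m), 0)
  best
}

assignment_cost <- function(cost) {
  match <- rootpose:::solve_assignment(cost)
  sum(cost[cbind(which(match > 0), match[match > 0])])
}

# one-frame plant series wrapper
one_frame_series <- function(instances, plant_id = "t",
                             image_size = c(2048, 1088)) {
  plant_series(plant_id, list(frame_landmarks(0L, instances)),
               image_size = image_size)
}
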