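#' @useDynLib prothallus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames t.test ks.test quantile prcomp
#' @importFrom stats aggregate
#' @importFrom utils head read.csv tail write.csv combn
#' @importFrom grDevices chull colorRamp
NULL

# ---- planar polygon primitives -------------------------------------------
# Polygons are n x 2 matrices of (x, y) vertices in micrometres, implicitly
# closed, oriented either way. All functions are pure.

#' Signed and absolute polygon area (shoelace formula)
#' @param poly n x 2 vertex matrix (um)
#' @return area in um^2
#' @keywords internal
poly_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Polygon centroid (area-weighted)
#' @keywords internal
poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Clip a polygon against the half-plane dot(p - pt, nrm) <= 0
#'
#' Sutherland-Hodgman against a single half-plane; exact for convex input and
#' well-behaved for the near-convex cells the simulator produces.
#' @keywords internal
clip_halfplane <- function(poly, pt, nrm) {
  n <- nrow(poly)
  d <- as.vector((poly[, 1] - pt[1]) * nrm[1] + (poly[, 2] - pt[2]) * nrm[2])
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) out <- rbind(out, poly[i, , drop = FALSE])
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  dedup_vertices(out)
}

#' Drop consecutive duplicate vertices
#' @keywords internal
dedup_vertices <- function(poly, tol = 1e-9) {
  if (nrow(poly) < 2) return(poly)
  keep <- rep(TRUE, nrow(poly))
  for (i in seq_len(nrow(poly))) {
    j <- if (i == nrow(poly)) 1L else i + 1L
    if (sqrt(sum((poly[i, ] - poly[j, ])^2)) < tol) keep[j] <- FALSE
  }
  poly[keep, , drop = FALSE]
}

#' Split a polygon by the line through `pt` with direction `dir`
#'
#' Returns the two pieces (each side of the line). The split is exact:
#' daughter areas sum to the parent area up to floating point.
#' @param poly n x 2 vertex matrix
#' @param pt point on the splitting line (um)
#' @param dir unit direction of the line
#' @return list of two polygons; the first lies on the +normal side
#' @keywords internal
split_polygon <- function(poly, pt, dir) {
  nrm <- c(-dir[2], dir[1])
  a <- clip_halfplane(poly, pt, -nrm) # dot(p-pt, nrm) >= 0 side
  b <- clip_halfplane(poly, pt, nrm)
  if (nrow(a) < 3 || nrow(b) < 3)
    stop("degenerate polygon split: line through ", paste(round(pt, 3),
         collapse = ","), " misses the cell interior")
  list(a, b)
}

#' The chord segment where the splitting line crosses the polygon
#' @return 2 x 2 matrix (two endpoints)
#' @keywords internal
split_chord <- function(poly, pt, dir) {
  nrm <- c(-dir[2], dir[1])
  n <- nrow(poly)
  d <- as.vector((poly[, 1] - pt[1]) * nrm[1] + (poly[, 2] - pt[2]) * nrm[2])
  pts <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if ((d[i] < 0 && d[j] > 0) || (d[i] > 0 && d[j] < 0)) {
      t <- d[i] / (d[i] - d[j])
      pts <- rbind(pts, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    } else if (d[i] == 0) {
      pts <- rbind(pts, poly[i, , drop = FALSE])
    }
  }
  pts <- unique(round(pts, 9))
  if (nrow(pts) < 2) stop("splitting line does not cross the polygon")
  # keep the two extreme points along dir
  s <- pts %*% dir
  pts[c(which.min(s), which.max(s)), , drop = FALSE]
}

#' Length of the overlap of two collinear segments (0 if not collinear)
#' @keywords internal
collinear_overlap <- function(p1, p2, q1, q2, tol = 1e-6) {
  v <- p2 - p1
  len <- sqrt(sum(v^2))
  if (len < tol) return(0)
  u <- v / len
  # both q endpoints must lie on the line through p1-p2
  d1 <- abs((q1[1] - p1[1]) * u[2] - (q1[2] - p1[2]) * u[1])
  d2 <- abs((q2[1] - p1[1]) * u[2] - (q2[2] - p1[2]) * u[1])
  if (d1 > tol || d2 > tol) return(0)
  t1 <- sum((q1 - p1) * u); t2 <- sum((q2 - p1) * u)
  lo <- max(0, min(t1, t2)); hi <- min(len, max(t1, t2))
  max(0, hi - lo)
}

#' Shared boundary length between two polygons
#' @keywords internal
shared_boundary_length <- function(pa, pb, tol = 1e-6) {
  total <- 0
  na <- nrow(pa); nb <- nrow(pb)
  for (i in seq_len(na)) {
    i2 <- if (i == na) 1L else i + 1L
    for (j in seq_len(nb)) {
      j2 <- if (j == nb) 1L else j + 1L
      total <- total + collinear_overlap(pa[i, ], pa[i2, ], pb[j, ], pb[j2, ],
                                         tol)
    }
  }
  total
}

#' Insert vertices of neighbouring cells that lie on this polygon's edges
#'
#' Keeps the planar subdivision conforming after chord insertions create
#' T-junctions. `pts` is a matrix of candidate vertices.
#' @keywords internal
insert_edge_points <- function(poly, pts, tol = 1e-6) {
  out <- list()
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- poly[i, ]; b <- poly[j, ]
    out[[length(out) + 1L]] <- a
    v <- b - a
    len <- sqrt(sum(v^2))
    if (len < tol) next
    u <- v / len
    ts <- numeric(0)
    for (k in seq_len(nrow(pts))) {
      p <- pts[k, ]
      d <- abs((p[1] - a[1]) * u[2] - (p[2] - a[2]) * u[1])
      if (d > tol) next
      t <- sum((p - a) * u)
      if (t > tol && t < len - tol) ts <- c(ts, t)
    }
    for (t in sort(unique(round(ts, 9))))
      out[[length(out) + 1L]] <- a + t * u
  }
  dedup_vertices(do.call(rbind, out))
}

#' Boundary loops of a set of polygons forming a planar subdivision
#'
#' Edges (between consecutive conforming vertices) that belong to exactly one
#' cell form the tissue outline. Returns the vertices of the longest loop in
#' order.
#' @param polys list of n x 2 matrices with conforming shared edges
#' @return m x 2 matrix of ordered boundary vertices (closed implicitly)
#' @keywords internal
union_boundary <- function(polys, digits = 6) {
  key <- function(p) paste(round(p[1], digits), round(p[2], digits))
  ecount <- new.env(parent = emptyenv())
  estore <- new.env(parent = emptyenv())
  for (poly in polys) {
    n <- nrow(poly)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      k1 <- key(poly[i, ]); k2 <- key(poly[j, ])
      ek <- paste(sort(c(k1, k2)), collapse = "|")
      cur <- if (is.null(ecount[[ek]])) 0L else ecount[[ek]]
      ecount[[ek]] <- cur + 1L
      estore[[ek]] <- rbind(poly[i, ], poly[j, ])
    }
  }
  eks <- ls(ecount)
  bnd <- eks[vapply(eks, function(k) ecount[[k]] == 1L, logical(1))]
  if (length(bnd) == 0) stop("no boundary edges found")
  # chain the boundary edges into loops
  adj <- new.env(parent = emptyenv())
  vpos <- new.env(parent = emptyenv())
  for (ek in bnd) {
    seg <- estore[[ek]]
    k1 <- key(seg[1, ]); k2 <- key(seg[2, ])
    vpos[[k1]] <- seg[1, ]; vpos[[k2]] <- seg[2, ]
    adj[[k1]] <- c(if (is.null(adj[[k1]])) character(0) else adj[[k1]], k2)
    adj[[k2]] <- c(if (is.null(adj[[k2]])) character(0) else adj[[k2]], k1)
  }
  visited <- new.env(parent = emptyenv())
  loops <- list()
  for (start in sort(ls(adj))) {
    if (!is.null(visited[[start]])) next
    loop <- character(0)
    cur <- start; prev <- ""
    repeat {
      visited[[cur]] <- TRUE
      loop <- c(loop, cur)
      nxts <- setdiff(adj[[cur]], prev)
      nxts <- nxts[is.na(match(nxts, loop)) | nxts == start]
      if (length(nxts) == 0) break
      prev <- cur
      cur <- nxts[1]
      if (cur == start) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  best <- loops[[which.max(vapply(loops, length, integer(1)))]]
  do.call(rbind, lapply(best, function(k) vpos[[k]]))
}

#' Resample a closed polyline at uniform arc-length spacing
#'
#' Margin tangents are estimated on a uniformly resampled boundary so the
#' smoothing span is a physical distance, independent of vertex density or
#' pixel size.
#' @param pts m x 2 ordered vertices of a closed loop
#' @param spacing arc-length step (um)
#' @keywords internal
resample_polyline <- function(pts, spacing = 2) {
  m <- nrow(pts)
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] -
                         closed[-(m + 1), , drop = FALSE])^2))
  total <- sum(seg)
  if (total < spacing * 3) return(pts)
  n_out <- max(8L, floor(total / spacing))
  targets <- seq(0, total, length.out = n_out + 1L)[-(n_out + 1L)]
  cum <- c(0, cumsum(seg))
  out <- matrix(0, n_out, 2)
  j <- 1L
  for (i in seq_len(n_out)) {
    t <- targets[i]
    while (j < m && cum[j + 1] < t) j <- j + 1L
    denom <- max(cum[j + 1] - cum[j], 1e-12)
    f <- (t - cum[j]) / denom
    out[i, ] <- closed[j, ] + f * (closed[j + 1, ] - closed[j, ])
  }
  out
}

#' Tangents along a closed polyline, smoothed over a moving window
#' @param pts m x 2 ordered vertices of a closed loop
#' @param window odd window size for smoothing (default 5)
#' @return m x 2 matrix of unit tangents
#' @keywords internal
polyline_tangents <- function(pts, window = 5) {
  m <- nrow(pts)
  h <- window %/% 2
  tg <- matrix(0, m, 2)
  for (i in seq_len(m)) {
    i0 <- ((i - 1 - h) %% m) + 1L
    i1 <- ((i - 1 + h) %% m) + 1L
    v <- pts[i1, ] - pts[i0, ]
    len <- sqrt(sum(v^2))
    if (len < 1e-12) v <- c(1, 0) else v <- v / len
    tg[i, ] <- v
  }
  tg
}

#' Nearest vertex index of a polyline to a point
#' @keywords internal
nearest_vertex <- function(pts, p) {
  which.min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)
}

#' Acute angle (degrees, in [0, 90]) between two directions
#' @keywords internal
acute_angle <- function(u, v) {
  cu <- u / sqrt(sum(u^2)); cv <- v / sqrt(sum(v^2))
  d <- abs(sum(cu * cv))
  d <- min(1, max(-1, d))
  acos(d) * 180 / pi
}

#' Rotate a 2D direction by `deg` degrees counter-clockwise
#' @keywords internal
rotate_dir <- function(v, deg) {
  th <- deg * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
}
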