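# ---- layers, division orientation, packets, trichomes ----------------------

#' Extract the tissue margin polyline from a label map
#'
#' The margin is the outer boundary of the union of non-trichome cells,
#' traced at pixel resolution and smoothed over a 5-point window for tangent
#' estimation. With disconnected tissue the largest component is used and a
#' warning is raised.
#'
#' @param lm a `label_map`
#' @param trichome_ids label ids flagged as trichomes (excluded)
#' @return a `margin_polyline`: `points` (m x 2 um, closed) and unit
#'   `tangents`
#' @export
extract_margin <- function(lm, trichome_ids = integer(0)) {
  lab <- lm$labels
  mask <- lab > 0 & !(lab %in% trichome_ids)
  if (!any(mask)) stop("no non-trichome tissue to trace")
  mask <- cpp_fill_holes(mask)
  comp <- cpp_conncomp(mask)
  if (max(comp) > 1) {
    warning("disconnected tissue: margin of the largest component only")
    sizes <- tabulate(comp[comp > 0])
    mask <- comp == which.max(sizes)
  }
  b <- cpp_trace_boundary(mask)
  ps <- lm$pixel_size
  pts <- cbind(lm$origin[1] + (b[, 2] + 0.5) * ps,
               lm$origin[2] + (b[, 1] + 0.5) * ps)
  pts <- resample_polyline(pts, 2)
  structure(list(points = pts, tangents = polyline_tangents(pts, 11),
                 mask = mask),
            class = "margin_polyline")
}

#' Assign marginal / submarginal / inner layers
#'
#' Marginal cells touch the tissue margin (at least one edge pixel on the
#' boundary of the non-trichome union); submarginal cells are the one layer
#' in direct contact with marginal cells; everything else is inner. Trichomes
#' are labelled "trichome". `updates` (from [layer_update_rules()]) applies
#' the time-lapse bookkeeping: a cell added inward by a marginal cell's
#' periclinal division is the new submarginal cell for the next window,
#' whereas one added inward by a submarginal cell's periclinal division is
#' not counted as submarginal in the following window.
#'
#' @param lm a `label_map`
#' @param margin optional precomputed [extract_margin()] result
#' @param trichome_ids label ids flagged as trichomes
#' @param updates optional data frame (cell_id, layer) of overrides
#' @return named character vector of layers by cell id
#' @export
assign_layers <- function(lm, margin = NULL, trichome_ids = integer(0),
                          updates = NULL) {
  lab <- lm$labels
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  layers <- setNames(rep("inner", length(ids)), ids)
  layers[as.character(intersect(ids, trichome_ids))] <- "trichome"
  mask <- lab > 0 & !(lab %in% trichome_ids)
  mask <- cpp_fill_holes(mask)
  mi <- mask + 0L
  storage.mode(mi) <- "integer"
  bnd <- cpp_boundary_mask(mi) & (lab > 0)
  marginal <- setdiff(unique(lab[bnd]), c(0L, trichome_ids))
  layers[as.character(marginal)] <- "marginal"
  adj <- cpp_adjacency_counts(lab)
  adj <- adj[adj$a > 0 & adj$b > 0, , drop = FALSE]
  touch_marg <- unique(c(adj$b[adj$a %in% marginal],
                         adj$a[adj$b %in% marginal]))
  sub <- setdiff(touch_marg, c(marginal, trichome_ids))
  layers[as.character(sub)] <- "submarginal"
  if (!is.null(updates) && nrow(updates) > 0) {
    sel <- as.character(updates$cell_id)
    sel_ok <- sel %in% names(layers)
    layers[sel[sel_ok]] <- updates$layer[sel_ok]
  }
  layers
}

#' Layer bookkeeping across consecutive windows
#'
#' Derives the layer overrides for window k+1 from window k's periclinal
#' divisions: the inward daughter of a marginal periclinal division becomes
#' submarginal; the inward daughter of a submarginal periclinal division is
#' excluded from the submarginal layer (set to inner).
#'
#' @param events data frame with columns parent_layer, orientation, and
#'   inward_daughter (cell id in the next window's label map)
#' @return data frame (cell_id, layer) for [assign_layers()] `updates`
#' @export
layer_update_rules <- function(events) {
  ev <- events[events$orientation == "periclinal" &
                 events$parent_layer %in% c("marginal", "submarginal"), ,
               drop = FALSE]
  if (nrow(ev) == 0)
    return(data.frame(cell_id = integer(0), layer = character(0)))
  data.frame(cell_id = ev$inward_daughter,
             layer = ifelse(ev$parent_layer == "marginal",
                            "submarginal", "inner"),
             stringsAsFactors = FALSE)
}

#' Estimate the new wall between two daughter cells
#'
#' The new wall is the shared pixel boundary between the two daughter labels,
#' returned as world-um points (midpoints of adjacent pixel pairs).
#'
#' @param lm a `label_map` (t1)
#' @param a,b the two daughter label ids
#' @return k x 2 matrix of um points; fewer than 2 points means degenerate
#' @export
estimate_new_wall <- function(lm, a, b) {
  lab <- lm$labels
  nr <- nrow(lab); nc <- ncol(lab)
  pts <- matrix(numeric(0), ncol = 2)
  wa <- which(lab == a, arr.ind = TRUE)
  for (i in seq_len(nrow(wa))) {
    r <- wa[i, 1]; c <- wa[i, 2]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (lab[rr, cc] == b)
        pts <- rbind(pts, c((c + cc) / 2, (r + rr) / 2))
    }
  }
  if (nrow(pts) == 0) return(pts)
  pts <- unique(pts)
  ps <- lm$pixel_size
  cbind(lm$origin[1] + (pts[, 1] - 0.5) * ps,
        lm$origin[2] + (pts[, 2] - 0.5) * ps)
}

#' Classify a division's orientation against the margin
#'
#' The wall-margin angle is the acute angle between the new wall's principal
#' direction and the margin tangent at the margin point nearest the parent
#' centroid. Angles above `anticlinal_min` are anticlinal, below
#' `periclinal_max` periclinal, otherwise oblique. The default 30/60-degree
#' bands are symmetric about 45 degrees and configurable.
#'
#' @param wall k x 2 matrix of um points (the new wall)
#' @param margin a [extract_margin()] result (or any list with `points` and
#'   `tangents`)
#' @param parent_centroid (x, y) um of the parent cell
#' @param anticlinal_min,periclinal_max angular thresholds in degrees
#' @return list: orientation ("anticlinal"/"periclinal"/"oblique" or NA for
#'   a degenerate wall, with `qc` explaining why), angle (degrees)
#' @export
classify_orientation <- function(wall, margin, parent_centroid,
                                 anticlinal_min = 60, periclinal_max = 30) {
  if (is.null(wall) || nrow(wall) < 2)
    return(list(orientation = NA_character_, angle = NA_real_,
                qc = "degenerate wall (< 2 px)"))
  if (nrow(wall) == 2) {
    dirw <- wall[2, ] - wall[1, ]
  } else {
    pc <- prcomp(wall, center = TRUE)
    dirw <- pc$rotation[, 1]
  }
  i <- nearest_vertex(margin$points, parent_centroid)
  tg <- margin$tangents[i, ]
  ang <- acute_angle(dirw, tg)
  list(orientation = orientation_from_angle(ang, anticlinal_min,
                                            periclinal_max),
       angle = ang, qc = NULL)
}

# --- rectangularity ---------------------------------------------------------

# Solidity and minimum-area-bounding-rectangle fill from a cell's pixel
# coordinates (rows of `w`, arr.ind convention).
rectangularity <- function(w) {
  n <- nrow(w)
  if (n < 4) return(list(solidity = 0, fill = 0))
  pts <- cbind(w[, 2], w[, 1]) # (x, y) in px
  h <- chull(pts)
  hull <- pts[h, , drop = FALSE]
  if (nrow(hull) < 3) return(list(solidity = 1, fill = 1))
  ha <- poly_area(hull)
  # pixel-footprint correction: hull of centres underestimates by ~ the
  # half-pixel rim
  per <- sum(sqrt(rowSums((hull - hull[c(2:nrow(hull), 1), ])^2)))
  ha_corr <- ha + per / 2 + 1
  solidity <- min(1, n / ha_corr)
  fill <- 0
  for (i in seq_len(nrow(hull))) {
    j <- if (i == nrow(hull)) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-9) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- pts %*% u
    pv <- pts %*% v
    area <- (diff(range(pu)) + 1) * (diff(range(pv)) + 1)
    f <- n / area
    fill <- max(fill, min(1, f))
  }
  list(solidity = solidity, fill = fill)
}

#' Detect three-celled packets
#'
#' A packet is two adjacent rectangular marginal ("upper") cells plus one
#' rectangular submarginal ("lower") cell adjacent to both. Rectangularity
#' requires solidity >= `min_solidity` and minimum-area bounding-rectangle
#' fill >= `min_fill`. Overlapping candidates are resolved greedily by
#' descending mean rectangularity; no cell belongs to two packets.
#'
#' @param lm a `label_map`
#' @param layers named layer vector from [assign_layers()]
#' @param min_solidity,min_fill rectangularity thresholds
#' @return data frame: upper_a, upper_b, lower, score (may be empty)
#' @export
detect_packets <- function(lm, layers, min_solidity = 0.9, min_fill = 0.8) {
  lab <- lm$labels
  ids <- as.integer(names(layers))
  rect <- lapply(setNames(ids, ids), function(id) {
    rectangularity(which(lab == id, arr.ind = TRUE))
  })
  is_rect <- vapply(rect, function(r)
    r$solidity >= min_solidity && r$fill >= min_fill, logical(1))
  score <- vapply(rect, function(r) (r$solidity + r$fill) / 2, numeric(1))
  marg <- ids[layers[as.character(ids)] == "marginal" &
                is_rect[as.character(ids)]]
  sub <- ids[layers[as.character(ids)] == "submarginal" &
               is_rect[as.character(ids)]]
  adj <- cpp_adjacency_counts(lab)
  adj <- adj[adj$a > 0 & adj$b > 0, , drop = FALSE]
  adj_pairs <- paste(pmin(adj$a, adj$b), pmax(adj$a, adj$b))
  adjacent <- function(x, y) paste(min(x, y), max(x, y)) %in% adj_pairs
  cand <- list()
  for (i in seq_along(marg)) for (j in seq_along(marg)) {
    if (i >= j) next
    ua <- marg[i]; ub <- marg[j]
    if (!adjacent(ua, ub)) next
    for (lo in sub) {
      if (adjacent(ua, lo) && adjacent(ub, lo)) {
        s <- mean(score[as.character(c(ua, ub, lo))])
        cand[[length(cand) + 1L]] <- data.frame(upper_a = ua, upper_b = ub,
                                                lower = lo, score = s)
      }
    }
  }
  if (length(cand) == 0)
    return(data.frame(upper_a = integer(0), upper_b = integer(0),
                      lower = integer(0), score = numeric(0)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$upper_a, cand$upper_b, cand$lower), ,
               drop = FALSE]
  used <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    trio <- c(cand$upper_a[i], cand$upper_b[i], cand$lower[i])
    if (!any(trio %in% used)) {
      keep[i] <- TRUE
      used <- c(used, trio)
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the division types of a packet over one window
#'
#' Type I is an anticlinal division of an upper cell, Type II periclinal of
#' an upper cell, Type III anticlinal of the lower cell, Type IV periclinal
#' of the lower cell. Any packet cell dividing more than once in the window
#' makes the whole packet "complex" (excluded from the percentage
#' calculations); no division is "none". Multiple single divisions across
#' different packet cells coexist as a set of types.
#'
#' @param packet one row of [detect_packets()] output
#' @param events data frame of the window's events with columns parent_id and
#'   orientation
#' @param meta a [window_meta()]
#' @return list: packet, types (character vector, possibly length 0),
#'   complex (logical)
#' @export
classify_packet_division <- function(packet, events, meta = NULL) {
  members <- c(packet$upper_a, packet$upper_b, packet$lower)
  ev <- events[events$parent_id %in% members, , drop = FALSE]
  if (nrow(ev) == 0)
    return(list(packet = packet, types = character(0), complex = FALSE))
  per_parent <- table(ev$parent_id)
  if (any(per_parent >= 2))
    return(list(packet = packet, types = character(0), complex = TRUE))
  types <- character(0)
  for (i in seq_len(nrow(ev))) {
    upper <- ev$parent_id[i] %in% c(packet$upper_a, packet$upper_b)
    ori <- ev$orientation[i]
    ty <- if (upper && ori == "anticlinal") "I"
      else if (upper && ori == "periclinal") "II"
      else if (!upper && ori == "anticlinal") "III"
      else if (!upper && ori == "periclinal") "IV"
      else NA_character_ # oblique divisions carry no packet type
    if (!is.na(ty)) types <- c(types, ty)
  }
  list(packet = packet, types = sort(types), complex = FALSE)
}

#' Flag trichome cells
#'
#' In synthetic (truth) mode the simulator's flags are passed through. In
#' rule mode a cell is a trichome when at least `outside_fraction` of its
#' area lies outside the convex hull of the remaining tissue, or when its
#' aspect ratio is >= `aspect_min` with the long axis within 30 degrees of
#' the outward margin normal. Flagged cells are excluded from margin
#' extraction, layer statistics and size quantification.
#'
#' @param lm a `label_map`
#' @param truth_flags optional integer vector of truth trichome label ids
#' @param outside_fraction,aspect_min rule-mode thresholds
#' @return named logical vector by cell id
#' @export
flag_trichomes <- function(lm, truth_flags = NULL, outside_fraction = 0.6,
                           aspect_min = 3) {
  lab <- lm$labels
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (!is.null(truth_flags))
    return(setNames(ids %in% truth_flags, ids))
  flags <- setNames(rep(FALSE, length(ids)), ids)
  all_px <- which(lab > 0, arr.ind = TRUE)
  lab_px <- lab[cbind(all_px[, 1], all_px[, 2])]
  ctr_all <- colMeans(all_px)
  for (id in ids) {
    sel <- lab_px == id
    mine <- all_px[sel, , drop = FALSE]
    others <- all_px[!sel, , drop = FALSE]
    if (nrow(others) < 3 || nrow(mine) == 0) next
    h <- chull(others[, 2], others[, 1])
    hull <- cbind(others[h, 2], others[h, 1])
    outside <- !points_in_convex(cbind(mine[, 2], mine[, 1]), hull)
    frac_out <- mean(outside)
    # aspect ratio along the outward direction; requires some genuine
    # protrusion, since freshly divided anticlinal daughters are also thin
    # and normal-aligned but stay inside the tissue outline
    aspect_hit <- FALSE
    if (nrow(mine) >= 4 && frac_out > 0.1) {
      pc <- prcomp(cbind(mine[, 2], mine[, 1]))
      sds <- pc$sdev
      if (sds[2] > 0 && sds[1] / sds[2] >= aspect_min) {
        ctr <- colMeans(cbind(mine[, 2], mine[, 1]))
        outdir <- ctr - c(ctr_all[2], ctr_all[1])
        if (sqrt(sum(outdir^2)) > 0 &&
            acute_angle(pc$rotation[, 1], outdir) <= 30)
          aspect_hit <- TRUE
      }
    }
    flags[as.character(id)] <- frac_out >= outside_fraction || aspect_hit
  }
  flags
}

# Points-in-convex-polygon test (hull vertices in order).
points_in_convex <- function(pts, hull) {
  n <- nrow(hull)
  inside <- rep(TRUE, nrow(pts))
  # ensure counter-clockwise orientation
  x <- hull[, 1]; y <- hull[, 2]
  a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (a2 < 0) { hull <- hull[n:1, , drop = FALSE] }
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    d <- (pts[, 1] - hull[i, 1]) * e[2] - (pts[, 2] - hull[i, 2]) * e[1]
    inside <- inside & (d <= 1e-9)
  }
  inside
}
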