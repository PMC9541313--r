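# ---- gametophyte growth simulator ------------------------------------------
# Cells are convex-ish polygons in a shared, conforming planar subdivision.
# A division inserts a chord through the (grown) parent: anticlinal chords run
# along the local margin normal through the centroid, periclinal chords along
# the tangent, oblique chords at 45 degrees. Trichome initiation cuts a corner
# triangle off a margin-facing vertex (asymmetric division); the triangle
# apex is later extruded outward so the trichome protrudes.

new_sim_cell <- function(id, poly, role, birth_window, trichome = FALSE,
                         out_of_plane = FALSE) {
  list(id = id, poly = poly, role = role, birth_window = birth_window,
       trichome = trichome, out_of_plane = out_of_plane)
}

init_tissue <- function(params) {
  cells <- list()
  if (params$init_rows == 1L && params$init_cols == 1L) {
    s <- params$spore_size
    poly <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
    cells[[1]] <- new_sim_cell(1L, poly, "spore", 0L)
  } else {
    id <- 0L
    w <- params$cell_w; h <- params$cell_h
    for (r in seq_len(params$init_rows)) {
      for (cc in seq_len(params$init_cols)) {
        id <- id + 1L
        x0 <- (cc - 1) * w; y0 <- -(r - 1) * h - h
        # row 1 is the top (margin-facing) row; y decreases inward
        poly <- rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h),
                      c(x0, y0 + h))
        cells[[id]] <- new_sim_cell(id, poly, "ordinary", 0L)
      }
    }
  }
  cells
}

# Insert T-junction vertices so shared boundaries are decomposed identically
# in both incident cells.
conform_mesh <- function(cells, tol = 1e-6) {
  if (length(cells) < 2) return(cells)
  all_pts <- do.call(rbind, lapply(cells, function(cl) cl$poly))
  all_pts <- unique(round(all_pts, 9))
  for (i in seq_along(cells)) {
    poly <- cells[[i]]$poly
    bb <- c(range(poly[, 1]), range(poly[, 2]))
    sel <- all_pts[, 1] >= bb[1] - tol & all_pts[, 1] <= bb[2] + tol &
           all_pts[, 2] >= bb[3] - tol & all_pts[, 2] <= bb[4] + tol
    pts <- all_pts[sel, , drop = FALSE]
    if (nrow(pts) > 0)
      cells[[i]]$poly <- insert_edge_points(poly, pts, tol)
  }
  cells
}

# Edge-key bookkeeping over a set of cells: which edges are on the outline
# (owned once) and which cells are adjacent (share an edge).
edge_census <- function(cells, digits = 6) {
  vkey <- function(p) paste(round(p[1], digits), round(p[2], digits))
  owners <- new.env(parent = emptyenv())
  for (cl in cells) {
    poly <- cl$poly
    n <- nrow(poly)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      ek <- paste(sort(c(vkey(poly[i, ]), vkey(poly[j, ]))), collapse = "|")
      owners[[ek]] <- c(if (is.null(owners[[ek]])) integer(0)
                        else owners[[ek]], cl$id)
    }
  }
  owners
}

# Geometric truth layers: marginal cells own an edge on the main outline of
# the non-trichome tissue; submarginal cells are adjacent to a marginal cell;
# the rest are inner. Trichomes are reported as "trichome".
truth_layers <- function(cells, digits = 6) {
  ids <- vapply(cells, `[[`, integer(1), "id")
  tri <- vapply(cells, `[[`, logical(1), "trichome")
  body <- cells[!tri]
  layers <- setNames(rep("inner", length(cells)), as.character(ids))
  layers[as.character(ids[tri])] <- "trichome"
  if (length(body) == 0) return(layers)
  owners <- edge_census(body, digits)
  # outline loop of the non-trichome union
  margin <- union_boundary(lapply(body, `[[`, "poly"), digits)
  vkey <- function(p) paste(round(p[1], digits), round(p[2], digits))
  m <- nrow(margin)
  loop_edges <- character(m)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    loop_edges[i] <- paste(sort(c(vkey(margin[i, ]), vkey(margin[j, ]))),
                           collapse = "|")
  }
  marginal_ids <- integer(0)
  adj_pairs <- list()
  for (ek in ls(owners)) {
    own <- owners[[ek]]
    if (length(own) == 1L && ek %in% loop_edges)
      marginal_ids <- c(marginal_ids, own)
    if (length(own) == 2L) adj_pairs[[length(adj_pairs) + 1L]] <- own
  }
  marginal_ids <- unique(marginal_ids)
  layers[as.character(marginal_ids)] <- "marginal"
  sub_ids <- integer(0)
  for (pr in adj_pairs) {
    if (pr[1] %in% marginal_ids && !(pr[2] %in% marginal_ids))
      sub_ids <- c(sub_ids, pr[2])
    if (pr[2] %in% marginal_ids && !(pr[1] %in% marginal_ids))
      sub_ids <- c(sub_ids, pr[1])
  }
  sub_ids <- setdiff(unique(sub_ids), ids[tri])
  layers[as.character(sub_ids)] <- "submarginal"
  attr(layers, "adjacency") <- if (length(adj_pairs) == 0)
    matrix(integer(0), ncol = 2) else do.call(rbind, adj_pairs)
  layers
}

# Which margin points lie in the apical meristem sector: the given fraction
# of the margin arc centred on the apex (+y-most margin point). Points are
# uniformly resampled, so index distance is arc distance.
meristem_sector <- function(margin, fraction) {
  n <- nrow(margin$points)
  if (fraction >= 1) return(rep(TRUE, n))
  # apex: the top-centre of the margin — among the highest points (within a
  # 2-um band, since a flat top ties), the one nearest the tissue's median x.
  # A deterministic, stable apex keeps the meristem sector in place across
  # windows instead of wandering along the margin.
  ymax <- max(margin$points[, 2])
  cand <- which(margin$points[, 2] >= ymax - 2)
  cx <- mean(range(margin$points[, 1]))
  apex <- cand[which.min(abs(margin$points[cand, 1] - cx))]
  half <- max(1L, floor(fraction * n / 2))
  d <- abs(seq_len(n) - apex)
  d <- pmin(d, n - d)
  d <= half
}

# Margin polyline + tangents of the non-trichome tissue, resampled to
# uniform 2-um spacing so tangents match the raster pipeline's estimates.
sim_margin <- function(cells, digits = 6) {
  tri <- vapply(cells, `[[`, logical(1), "trichome")
  body <- cells[!tri]
  pts <- union_boundary(lapply(body, `[[`, "poly"), digits)
  pts <- resample_polyline(pts, 2)
  list(points = pts, tangents = polyline_tangents(pts, 11))
}

local_frame <- function(margin, p) {
  i <- nearest_vertex(margin$points, p)
  tg <- margin$tangents[i, ]
  out <- p - margin$points[i, ]
  # outward direction: away from the margin point toward the cell is inward
  nr <- c(-tg[2], tg[1])
  if (sum(nr * out) > 0) nr <- -nr # normal pointing outward of tissue
  list(tangent = tg, normal = nr, margin_point = margin$points[i, ])
}

dist_to_margin <- function(margin, p) {
  min(sqrt((margin$points[, 1] - p[1])^2 + (margin$points[, 2] - p[2])^2))
}

#' Simulate gametophyte development under the apical division grammar
#'
#' Runs the cell-based growth model for `params$n_windows` 48-h windows and
#' returns the full ground truth: per-window snapshots of every cell polygon,
#' the lineage forest, and a log of every division event with its orientation,
#' packet type and parent layer. Deterministic for a fixed `rng_seed`.
#'
#' @param params a [sim_params()] object
#' @return a `truth_series` with elements `snapshots` (list of
#'   `list(time_h, cells)`), `lineage` (data frame: parent_id, daughter_id,
#'   window), `events` (data frame, one row per division, with list columns
#'   `wall` (2 x 2 chord endpoints), `parent_poly` and `daughter_polys`), and
#'   `params`.
#' @export
simulate_gametophyte <- function(params = sim_params()) {
  validate_sim_params(params)
  set.seed(params$rng_seed)
  cells <- init_tissue(params)
  phase <- if (length(cells) == 1L) "initial" else "meristem"
  apical_id <- if (phase == "initial") 1L else NA_integer_
  next_id <- length(cells) + 1L
  events <- list()
  lineage <- list()
  snapshots <- list()

  snap <- function(time_h) {
    layers <- truth_layers(cells)
    list(time_h = time_h,
         cells = lapply(cells, function(cl) {
           cl$layer <- unname(layers[as.character(cl$id)])
           cl
         }))
  }
  snapshots[[1]] <- snap(0)

  for (w in seq_len(params$n_windows)) {
    cells <- conform_mesh(cells)
    layers <- truth_layers(cells)
    ids <- vapply(cells, `[[`, integer(1), "id")
    ord <- order(ids)
    cells <- cells[ord]
    ids <- ids[ord]

    # assign roles for this window; in the meristem phase only the apical
    # sector of the margin proliferates
    if (phase == "meristem") {
      margin_pre <- sim_margin(cells)
      sector <- meristem_sector(margin_pre, params$meristem_fraction)
      adj <- attr(layers, "adjacency")
      mer_marginal <- integer(0)
      for (i in seq_along(cells)) {
        cl <- cells[[i]]
        if (cl$trichome) next
        if (layers[as.character(cl$id)] == "marginal") {
          k <- nearest_vertex(margin_pre$points, poly_centroid(cl$poly))
          if (sector[k]) mer_marginal <- c(mer_marginal, cl$id)
        }
      }
      mer_sub <- integer(0)
      for (r in seq_len(nrow(adj))) {
        pr <- adj[r, ]
        if (pr[1] %in% mer_marginal &&
            layers[as.character(pr[2])] == "submarginal")
          mer_sub <- c(mer_sub, pr[2])
        if (pr[2] %in% mer_marginal &&
            layers[as.character(pr[1])] == "submarginal")
          mer_sub <- c(mer_sub, pr[1])
      }
    }
    for (i in seq_along(cells)) {
      cl <- cells[[i]]
      if (cl$trichome) { cells[[i]]$role <- "trichome"; next }
      if (phase == "initial") {
        cells[[i]]$role <- if (identical(cl$id, apical_id)) {
          if (cl$role == "spore") "spore" else "apical_initial"
        } else "derivative"
      } else {
        cells[[i]]$role <- if (cl$id %in% mer_marginal) "packet_upper"
          else if (cl$id %in% mer_sub) "packet_lower"
          else "ordinary"
      }
    }

    # decide divisions (id order; at most one division per cell per window)
    plan <- list()
    for (i in seq_along(cells)) {
      cl <- cells[[i]]
      if (cl$trichome) next
      area <- poly_area(cl$poly)
      gated <- area < params$size_gate
      u <- runif(1)
      kind <- "none"
      role <- cl$role
      if (role %in% c("spore", "apical_initial")) {
        if (u < params$p_oblique) kind <- "oblique"
        else if (u < params$p_oblique + params$p_terminate) kind <- "terminate"
      } else if (role == "derivative") {
        if (u < params$p_derivative) kind <- "anticlinal_derivative"
      } else if (role == "packet_upper") {
        if (u < params$q1) kind <- "type_I"
        else if (u < params$q1 + params$q2) kind <- "type_II"
      } else if (role == "packet_lower") {
        if (u < params$q3) kind <- "type_III"
        else if (u < params$q3 + params$q4) kind <- "type_IV"
      }
      if (kind != "none" && gated) kind <- "none"
      if (kind == "none") {
        ly <- layers[as.character(cl$id)]
        eligible <- !cl$trichome && ly %in% c("marginal", "inner")
        if (eligible && runif(1) < params$p_trichome && !gated)
          kind <- "trichome"
      }
      if (kind != "none")
        plan[[length(plan) + 1L]] <- list(idx = i, id = cl$id, kind = kind,
                                          layer = unname(
                                            layers[as.character(cl$id)]))
    }
    dividing <- vapply(plan, `[[`, integer(1), "id")

    # growth: per-vertex averaging of per-cell affine expansion proposals.
    # Every cell (dividers included) expands by the same linear factor, so
    # cells that never divide compound growth across windows while dividing
    # lineages are reset by halving; this is what links small size to high
    # division activity in the tissue.
    cells <- grow_cells(cells, params$growth_factor)

    # chord placement uses the post-growth margin
    margin <- sim_margin(cells)

    for (pl in plan) {
      i <- match(pl$id, vapply(cells, `[[`, integer(1), "id"))
      cl <- cells[[i]]
      res <- divide_cell(cl, pl$kind, margin, params, w, next_id, pl$layer)
      next_id <- res$next_id
      # replace parent with daughters
      cells[[i]] <- res$daughters[[1]]
      cells[[length(cells) + 1L]] <- res$daughters[[2]]
      ev <- res$event
      ev$layer <- pl$layer
      events[[length(events) + 1L]] <- ev
      for (d in res$daughters)
        lineage[[length(lineage) + 1L]] <-
          list(parent_id = cl$id, daughter_id = d$id, window = w)
      if (length(cells) > params$max_cells)
        stop("non-viable parameter set: cell count exceeded max_cells = ",
             params$max_cells)
      if (!is.na(res$new_apical)) apical_id <- res$new_apical
      if (identical(res$phase_change, TRUE)) {
        phase <- "meristem"
        apical_id <- NA_integer_
      }
    }

    cells <- conform_mesh(cells)
    cells <- elongate_trichomes(cells, params)
    snapshots[[w + 1L]] <- snap(w * 48)
  }

  ev_df <- events_to_df(events)
  lg_df <- if (length(lineage) == 0)
    data.frame(parent_id = integer(0), daughter_id = integer(0),
               window = integer(0))
  else data.frame(parent_id = vapply(lineage, `[[`, integer(1), "parent_id"),
                  daughter_id = vapply(lineage, `[[`, integer(1),
                                       "daughter_id"),
                  window = vapply(lineage, `[[`, integer(1), "window"))
  structure(list(snapshots = snapshots, lineage = lg_df, events = ev_df,
                 params = params),
            class = "truth_series")
}

events_to_df <- function(events) {
  if (length(events) == 0) {
    df <- data.frame(parent_id = integer(0), daughter_ids = character(0),
                     orientation = character(0), packet_type = character(0),
                     layer = character(0), window = integer(0),
                     wall_angle = numeric(0), trichome_init = logical(0),
                     stringsAsFactors = FALSE)
    df$wall <- list()
    df$parent_poly <- list()
    df$daughter_polys <- list()
    return(df)
  }
  df <- data.frame(
    parent_id = vapply(events, `[[`, integer(1), "parent_id"),
    daughter_ids = vapply(events, function(e)
      paste(e$daughter_ids, collapse = ";"), character(1)),
    orientation = vapply(events, `[[`, character(1), "orientation"),
    packet_type = vapply(events, `[[`, character(1), "packet_type"),
    layer = vapply(events, `[[`, character(1), "layer"),
    window = vapply(events, `[[`, integer(1), "window"),
    wall_angle = vapply(events, `[[`, numeric(1), "wall_angle"),
    trichome_init = vapply(events, `[[`, logical(1), "trichome_init"),
    stringsAsFactors = FALSE)
  df$wall <- lapply(events, `[[`, "wall")
  df$parent_poly <- lapply(events, `[[`, "parent_poly")
  df$daughter_polys <- lapply(events, `[[`, "daughter_polys")
  df
}

# Uniform dilation about the tissue centroid: the same affine map is applied
# to every cell, so shared vertices stay shared (the mesh remains conforming)
# and every cell's linear dimensions scale by exactly growth_factor. Local
# per-cell expansion proposals averaged at shared vertices do not integrate
# into tissue-level growth (the displacement is bounded by one cell radius),
# so the dilation is applied globally.
grow_cells <- function(cells, growth_factor, digits = 6) {
  if (growth_factor == 1) return(cells)
  areas <- vapply(cells, function(cl) poly_area(cl$poly), numeric(1))
  ctrs <- t(vapply(cells, function(cl) poly_centroid(cl$poly), numeric(2)))
  tissue_ctr <- colSums(ctrs * areas) / sum(areas)
  for (ci in seq_along(cells)) {
    poly <- cells[[ci]]$poly
    poly[, 1] <- tissue_ctr[1] + growth_factor * (poly[, 1] - tissue_ctr[1])
    poly[, 2] <- tissue_ctr[2] + growth_factor * (poly[, 2] - tissue_ctr[2])
    cells[[ci]]$poly <- poly
  }
  cells
}

# Execute one division; returns daughters, the logged event, bookkeeping.
divide_cell <- function(cl, kind, margin, params, window, next_id,
                        parent_layer = NA_character_) {
  ctr <- poly_centroid(cl$poly)
  fr <- local_frame(margin, ctr)
  phase_change <- FALSE
  new_apical <- NA_integer_
  trichome_init <- FALSE

  if (kind == "trichome") {
    res <- trichome_cut(cl$poly, margin)
    pieces <- res$pieces
    wall <- res$wall
    ang <- acute_angle(wall[2, ] - wall[1, ], fr$tangent)
    orientation <- orientation_from_angle(ang)
    trichome_init <- TRUE
    packet <- "none"
  } else {
    dir <- switch(kind,
      oblique = rotate_dir(fr$tangent, 45),
      terminate = fr$tangent,
      anticlinal_derivative = fr$normal,
      type_I = fr$normal,
      type_II = fr$tangent,
      type_III = fr$normal,
      type_IV = fr$tangent)
    pieces <- split_polygon(cl$poly, ctr, dir)
    wall <- split_chord(cl$poly, ctr, dir)
    ang <- acute_angle(dir, fr$tangent)
    orientation <- switch(kind, oblique = "oblique", terminate = "periclinal",
                          anticlinal_derivative = "anticlinal",
                          type_I = "anticlinal", type_II = "periclinal",
                          type_III = "anticlinal", type_IV = "periclinal")
    packet <- switch(kind, type_I = "I", type_II = "II", type_III = "III",
                     type_IV = "IV", "none")
  }

  d1 <- next_id; d2 <- next_id + 1L
  # daughter ordering: the piece closer to the margin (outer) gets the first id
  dm <- vapply(pieces, function(p) dist_to_margin(margin, poly_centroid(p)),
               numeric(1))
  if (kind == "trichome") {
    # piece 1 from trichome_cut is always the corner triangle (outer)
    ordp <- 1:2
  } else ordp <- order(dm)
  outer_poly <- pieces[[ordp[1]]]; inner_poly <- pieces[[ordp[2]]]

  roles <- switch(kind,
    oblique = c("apical_initial", "derivative"),
    terminate = c("derivative", "derivative"),
    anticlinal_derivative = c("derivative", "derivative"),
    type_I = c("packet_upper", "packet_upper"),
    type_II = c("packet_upper", "packet_lower"),
    type_III = c("packet_lower", "packet_lower"),
    type_IV = c("packet_lower", "ordinary"),
    trichome = c("trichome", cl$role))
  if (kind == "oblique") {
    # the wedge daughter keeps the apex: it is the piece nearer the margin
    new_apical <- d1
  }
  if (kind == "terminate") phase_change <- TRUE

  daughters <- list(
    new_sim_cell(d1, outer_poly, roles[1], window,
                 trichome = kind == "trichome",
                 out_of_plane = kind == "trichome" &&
                   identical(parent_layer, "inner")),
    new_sim_cell(d2, inner_poly, roles[2], window))
  event <- list(parent_id = cl$id, daughter_ids = c(d1, d2),
                orientation = orientation, packet_type = packet,
                layer = NA_character_, window = as.integer(window),
                wall_angle = ang, trichome_init = trichome_init,
                wall = wall, parent_poly = cl$poly,
                daughter_polys = list(outer_poly, inner_poly))
  list(daughters = daughters, event = event, next_id = next_id + 2L,
       phase_change = phase_change, new_apical = new_apical)
}

# Cut a corner triangle off the polygon vertex nearest the margin.
trichome_cut <- function(poly, margin) {
  dm <- apply(poly, 1, function(v) dist_to_margin(margin, v))
  k <- which.min(dm)
  n <- nrow(poly)
  prev <- if (k == 1L) n else k - 1L
  nxt <- if (k == n) 1L else k + 1L
  m1 <- (poly[k, ] + poly[prev, ]) / 2
  m2 <- (poly[k, ] + poly[nxt, ]) / 2
  triangle <- rbind(m1, poly[k, ], m2)
  # the remainder replaces vertex k by (m1, m2)
  idx <- seq_len(n)
  rest <- rbind(poly[idx < k, , drop = FALSE], m1, m2,
                poly[idx > k, , drop = FALSE])
  list(pieces = list(triangle, dedup_vertices(rest)),
       wall = rbind(m1, m2))
}

# Extrude in-plane trichomes outward so they protrude as spikes. The first
# elongation inserts a fresh apex vertex at the midpoint of the trichome's
# own margin edge (a vertex no other cell shares, so the mesh stays
# conforming); later windows push the same apex further out.
elongate_trichomes <- function(cells, params, digits = 6) {
  tri_idx <- which(vapply(cells, function(cl)
    cl$trichome && !cl$out_of_plane, logical(1)))
  if (length(tri_idx) == 0) return(cells)
  vkey <- function(p) paste(round(p[1], digits), round(p[2], digits))
  usage <- new.env(parent = emptyenv())
  for (cl in cells)
    for (i in seq_len(nrow(cl$poly))) {
      k <- vkey(cl$poly[i, ])
      usage[[k]] <- if (is.null(usage[[k]])) 1L else usage[[k]] + 1L
    }
  owners <- edge_census(cells, digits)
  all_ctr <- colMeans(do.call(rbind, lapply(cells, function(cl)
    poly_centroid(cl$poly))))
  for (i in tri_idx) {
    poly <- cells[[i]]$poly
    n <- nrow(poly)
    free <- vapply(seq_len(n), function(j)
      usage[[vkey(poly[j, ])]] == 1L, logical(1))
    if (any(free)) {
      # push the existing apex further out
      d <- sqrt((poly[, 1] - all_ctr[1])^2 + (poly[, 2] - all_ctr[2])^2)
      d[!free] <- -Inf
      j <- which.max(d)
      outdir <- poly[j, ] - all_ctr
      outdir <- outdir / sqrt(sum(outdir^2))
      poly[j, ] <- poly[j, ] + params$trichome_elong * outdir
      cells[[i]]$poly <- poly
      next
    }
    # first elongation: split the longest solely-owned (margin) edge and
    # displace the new midpoint vertex outward
    best_len <- -1; best_j <- NA_integer_
    for (j in seq_len(n)) {
      j2 <- if (j == n) 1L else j + 1L
      ek <- paste(sort(c(vkey(poly[j, ]), vkey(poly[j2, ]))), collapse = "|")
      own <- owners[[ek]]
      if (!is.null(own) && length(own) == 1L) {
        len <- sqrt(sum((poly[j2, ] - poly[j, ])^2))
        if (len > best_len) { best_len <- len; best_j <- j }
      }
    }
    if (is.na(best_j)) next # fully enclosed; cannot protrude
    j2 <- if (best_j == n) 1L else best_j + 1L
    mid <- (poly[best_j, ] + poly[j2, ]) / 2
    outdir <- mid - all_ctr
    outdir <- outdir / sqrt(sum(outdir^2))
    apex <- mid + params$trichome_elong * outdir
    poly <- rbind(poly[seq_len(best_j), , drop = FALSE], apex,
                  poly[seq(best_j + 1, length.out = n - best_j), ,
                       drop = FALSE])
    cells[[i]]$poly <- poly
  }
  cells
}

orientation_from_angle <- function(angle, anticlinal_min = 60,
                                   periclinal_max = 30) {
  if (is.na(angle)) return(NA_character_)
  if (angle > anticlinal_min) "anticlinal"
  else if (angle < periclinal_max) "periclinal"
  else "oblique"
}

#' Per-cell table for one snapshot of a truth series
#'
#' @param series a `truth_series`
#' @param i snapshot index (1 = time 0)
#' @return data frame with id, role, layer, trichome flag, area (um^2) and
#'   centroid coordinates
#' @export
snapshot_table <- function(series, i) {
  sn <- series$snapshots[[i]]
  cells <- sn$cells
  data.frame(
    id = vapply(cells, `[[`, integer(1), "id"),
    role = vapply(cells, `[[`, character(1), "role"),
    layer = vapply(cells, `[[`, character(1), "layer"),
    trichome = vapply(cells, `[[`, logical(1), "trichome"),
    area = vapply(cells, function(cl) poly_area(cl$poly), numeric(1)),
    x = vapply(cells, function(cl) poly_centroid(cl$poly)[1], numeric(1)),
    y = vapply(cells, function(cl) poly_centroid(cl$poly)[2], numeric(1)),
    time_h = sn$time_h,
    stringsAsFactors = FALSE)
}
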