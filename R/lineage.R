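# ---- time-lapse registration and lineage tracking --------------------------

#' Imaging window metadata
#'
#' @param t0_h,t1_h start and end times in hours; the paper-conformant
#'   timeframes are 24 and 48 h
#' @return a `window_meta` list with `timeframe_h = t1_h - t0_h`
#' @export
window_meta <- function(t0_h, t1_h) {
  tf <- t1_h - t0_h
  if (!is.finite(tf) || tf <= 0) stop("timeframe must be positive")
  structure(list(t0_h = t0_h, t1_h = t1_h, timeframe_h = tf),
            class = "window_meta")
}

#' Similarity registration of two label maps
#'
#' Samples were moved between imaging sessions, so consecutive label maps are
#' related by an unknown rotation and translation; the tissue also expands
#' measurably over a 24-48 h window, so an isotropic scale is estimated too
#' (a similarity transform). The transform is found by aligning tissue-mask
#' centroids, then alternately grid-searching rotation in \[-30, 30\] degrees
#' (1-degree steps, refined to 0.1) and scale in \[0.9, 1.3\] (0.01 steps),
#' and finally polishing the translation over +/-2 px, maximizing tissue-mask
#' overlap. Residual non-uniform growth is absorbed by the overlap-fraction
#' matching criteria.
#'
#' @param lm0,lm1 `label_map`s at the start and end of the window
#' @param scale_range search interval for the expansion factor; fix to
#'   `c(1, 1)` for a strictly rigid registration
#' @return a `rigid_transform`: rotation (degrees), scale, translation (um,
#'   x/y), plus the pixel-space parameters needed to apply it
#' @export
register_maps <- function(lm0, lm1, scale_range = c(0.9, 1.3)) {
  m0 <- lm0$labels > 0
  m1 <- lm1$labels > 0
  if (!any(m0) || !any(m1)) stop("empty label map: cannot register")
  w0 <- which(m0, arr.ind = TRUE)
  w1 <- which(m1, arr.ind = TRUE)
  c0 <- colMeans(w0) # (row, col) centroid in lm0
  c1 <- colMeans(w1)
  base_dr <- c1[1] - c0[1]
  base_dc <- c1[2] - c0[2]
  mi0 <- m0 + 0L
  storage.mode(mi0) <- "integer"
  n1 <- sum(m1)
  # intersection-over-union of the masks: unlike raw overlap it penalizes a
  # transform that spills beyond the t1 tissue, so the scale/rotation search
  # cannot drift along the "still inside the grown mask" plateau
  score_mask <- function(rot, scl, dr, dc) {
    t0 <- cpp_transform_labels(mi0, rot, scl, dr, dc, c0[1], c0[2],
                               nrow(m1), ncol(m1))
    inter <- sum(t0 == 1L & m1)
    inter / (sum(t0 == 1L) + n1 - inter)
  }
  # the outer mask is nearly rotation-invariant for a blob-shaped tissue, so
  # fine stages score the internal wall pattern instead (dilated by 1 px to
  # tolerate residual growth)
  dil <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    m | rbind(m[-1, , drop = FALSE], FALSE) |
      rbind(FALSE, m[-nr, , drop = FALSE]) |
      cbind(m[, -1, drop = FALSE], FALSE) |
      cbind(FALSE, m[, -nc, drop = FALSE])
  }
  wl0 <- dil(cpp_boundary_mask(lm0$labels))
  wl1 <- dil(cpp_boundary_mask(lm1$labels))
  wi0 <- wl0 + 0L
  storage.mode(wi0) <- "integer"
  nw1 <- sum(wl1)
  score <- function(rot, scl, dr, dc) {
    t0 <- cpp_transform_labels(wi0, rot, scl, dr, dc, c0[1], c0[2],
                               nrow(m1), ncol(m1))
    inter <- sum(t0 == 1L & wl1)
    inter / (sum(t0 == 1L) + nw1 - inter)
  }
  # NN resampling quantizes the score, so grids tie over small parameter
  # ranges; ties are broken toward the incumbent value (0 rotation, unit
  # scale, centroid shift) for determinism and unbiasedness
  argbest <- function(grid, vals, center) {
    idx <- which(vals == max(vals))
    grid[idx[which.min(abs(grid[idx] - center))]]
  }
  scl <- 1
  coarse <- seq(-30, 30, by = 1)
  sc <- vapply(coarse, function(r) score_mask(r, scl, base_dr, base_dc),
               numeric(1))
  rot <- argbest(coarse, sc, 0)
  scales <- seq(scale_range[1], scale_range[2], by = 0.01)
  if (length(scales) > 1) {
    ss <- vapply(scales, function(s) score(rot, s, base_dr, base_dc),
                 numeric(1))
    scl <- argbest(scales, ss, 1)
  }
  fine <- seq(rot - 3, rot + 3, by = 0.1)
  scf <- vapply(fine, function(r) score(r, scl, base_dr, base_dc),
                numeric(1))
  rot <- argbest(fine, scf, rot)
  if (length(scales) > 1) {
    sfine <- seq(scl - 0.01, scl + 0.01, by = 0.0025)
    ssf <- vapply(sfine, function(s) score(rot, s, base_dr, base_dc),
                  numeric(1))
    scl <- argbest(sfine, ssf, scl)
  }
  # translation polish at half-pixel resolution
  best_s <- -1; best_dr <- base_dr; best_dc <- base_dc
  for (dr in base_dr + seq(-2, 2, by = 0.5))
    for (dc in base_dc + seq(-2, 2, by = 0.5)) {
      s <- score(rot, scl, dr, dc)
      if (s > best_s) { best_s <- s; best_dr <- dr; best_dc <- dc }
    }
  t0b <- cpp_transform_labels(mi0, rot, scl, best_dr, best_dc, c0[1], c0[2],
                              nrow(m1), ncol(m1))
  overlap_px <- sum(t0b == 1L & m1)
  if (overlap_px < 0.5 * min(sum(m0), sum(m1)))
    stop("registration failure: best overlap below 50% of the smaller mask")
  ps <- lm1$pixel_size
  structure(list(rotation = rot, scale = scl,
                 translation = c(best_dc * ps, best_dr * ps),
                 ctr_px = c0, shift_px = c(best_dr, best_dc),
                 dim_out = dim(m1), overlap_px = overlap_px,
                 mask_iou = best_s),
            class = "rigid_transform")
}

#' Identity transform for maps already in the same frame
#' @param lm1 the target `label_map` (fixes the output frame)
#' @export
identity_transform <- function(lm1) {
  structure(list(rotation = 0, scale = 1, translation = c(0, 0),
                 ctr_px = c(0, 0), shift_px = c(0, 0),
                 dim_out = dim(lm1$labels), overlap_px = NA_real_),
            class = "rigid_transform")
}

#' Apply a registration transform to a label map (nearest-neighbour)
#' @param lm a `label_map`
#' @param tf a `rigid_transform` from [register_maps()]
#' @return the transformed integer label matrix in the t1 pixel frame
#' @export
apply_transform <- function(lm, tf) {
  cpp_transform_labels(lm$labels, tf$rotation, tf$scale %||% 1,
                       tf$shift_px[1], tf$shift_px[2],
                       tf$ctr_px[1], tf$ctr_px[2], tf$dim_out[1],
                       tf$dim_out[2])
}

#' Match cells across a time window and detect divisions
#'
#' Every t1 cell is assigned to the t0 cell containing the largest fraction
#' of its (transformed) area; ties go to the smaller t0 label. A t0 cell with
#' at least two children whose overlap fractions are >= `strong_fraction`
#' constitutes a division. Children whose best overlap fraction is below
#' `min_fraction` are flagged unmatched (parent NA) rather than silently
#' attached.
#'
#' @param lm0,lm1 `label_map`s
#' @param tf `rigid_transform` mapping t0 into the t1 frame
#' @param meta a [window_meta()]
#' @param strong_fraction overlap fraction required of each child for its
#'   parent to count as divided (default 0.5)
#' @param min_fraction minimum fraction for any assignment (default 0.25)
#' @return data frame of links: parent_id (NA = unmatched), child_id,
#'   overlap_fraction; attributes `divided_parents` (integer vector), `meta`,
#'   and `qc` (shrinkage warnings for non-dividing links)
#' @export
match_lineage <- function(lm0, lm1, tf, meta, strong_fraction = 0.5,
                          min_fraction = 0.25) {
  l0t <- apply_transform(lm0, tf)
  l1 <- lm1$labels
  tab <- cpp_overlap_table(l0t, l1)
  child_px <- tabulate(l1[l1 > 0])
  parent_px <- tabulate(lm0$labels[lm0$labels > 0])
  tab <- tab[tab$b > 0, , drop = FALSE]
  tab$frac <- tab$n / child_px[tab$b]
  # best parent per child: highest fraction, ties to smaller parent id;
  # background rows (a == 0) are never assignable
  cand <- tab[tab$a > 0, , drop = FALSE]
  cand <- cand[order(cand$b, -cand$frac, cand$a), , drop = FALSE]
  best <- cand[!duplicated(cand$b), , drop = FALSE]
  children <- sort(unique(tab$b))
  links <- data.frame(parent_id = NA_integer_, child_id = children,
                      overlap_fraction = NA_real_)
  idx <- match(children, best$b)
  has <- !is.na(idx)
  links$parent_id[has] <- best$a[idx[has]]
  links$overlap_fraction[has] <- best$frac[idx[has]]
  weak <- !is.na(links$overlap_fraction) &
    links$overlap_fraction < min_fraction
  links$parent_id[weak] <- NA_integer_
  # local polish: residual non-uniform growth leaves each parent's footprint
  # a few pixels off its daughters; for parents with several children,
  # re-evaluate the overlap fractions under the best small integer shift of
  # the parent footprint (what a human tracker does by eye)
  multi <- names(which(table(links$parent_id[!is.na(links$parent_id)]) >= 2))
  nr1 <- nrow(l1); nc1 <- ncol(l1)
  for (p in as.integer(multi)) {
    kids <- links$child_id[!is.na(links$parent_id) & links$parent_id == p]
    pw <- which(l0t == p, arr.ind = TRUE)
    if (nrow(pw) == 0) next
    best_total <- -1; best_counts <- NULL
    for (dr in -2:2) for (dc in -2:2) {
      rr <- pw[, 1] + dr; cc <- pw[, 2] + dc
      okp <- rr >= 1 & rr <= nr1 & cc >= 1 & cc <= nc1
      vals <- l1[cbind(rr[okp], cc[okp])]
      counts <- vapply(kids, function(k) sum(vals == k), numeric(1))
      # score per-child fractions, not raw counts, so a small daughter
      # weighs as much as its big sibling; slight preference for no shift
      total <- sum(counts / child_px[kids]) - (abs(dr) + abs(dc)) * 1e-6
      if (total > best_total) { best_total <- total; best_counts <- counts }
    }
    for (j in seq_along(kids)) {
      i <- which(links$child_id == kids[j])
      links$overlap_fraction[i] <- best_counts[j] / child_px[kids[j]]
    }
  }
  # divisions
  strong <- links[!is.na(links$parent_id) &
                    links$overlap_fraction >= strong_fraction, , drop = FALSE]
  nk <- table(strong$parent_id)
  divided <- as.integer(names(nk)[nk >= 2])
  # QC: non-dividing children should not shrink below 80% of the parent
  qc <- character(0)
  ps0 <- lm0$pixel_size; ps1 <- lm1$pixel_size
  single <- links[!is.na(links$parent_id) &
                    !(links$parent_id %in% divided), , drop = FALSE]
  for (i in seq_len(nrow(single))) {
    pa <- parent_px[single$parent_id[i]] * ps0^2
    ca <- child_px[single$child_id[i]] * ps1^2
    if (ca < 0.8 * pa)
      qc <- c(qc, sprintf("cell %d -> %d shrank: %.1f -> %.1f um^2",
                          single$parent_id[i], single$child_id[i], pa, ca))
  }
  attr(links, "divided_parents") <- divided
  attr(links, "meta") <- meta
  attr(links, "qc") <- qc
  links
}

#' Divided / non-divided map of a tracked window
#'
#' @param links output of [match_lineage()]
#' @param lm0 the t0 `label_map` to paint
#' @return list: `divided` (named logical by t0 cell id), `overlay` (RGB
#'   array; divided cells red, others green), `n_divided`, `n_nondivided`
#' @export
divided_map <- function(links, lm0) {
  ids <- sort(setdiff(unique(as.vector(lm0$labels)), 0L))
  divided <- setNames(ids %in% attr(links, "divided_parents"), ids)
  lab <- lm0$labels
  overlay <- array(0, c(nrow(lab), ncol(lab), 3))
  red <- ids[divided]
  fg <- which(lab > 0)
  r_plane <- overlay[, , 1]; g_plane <- overlay[, , 2]
  r_plane[fg] <- as.numeric(lab[fg] %in% red)
  g_plane[fg] <- as.numeric(!(lab[fg] %in% red))
  overlay[, , 1] <- r_plane
  overlay[, , 2] <- g_plane
  list(divided = divided, overlay = overlay,
       n_divided = sum(divided), n_nondivided = sum(!divided))
}

#' Compose per-window lineage links into full descendant sets
#'
#' A multi-round series (0 -> 48 -> 96 h) is always analyzed as consecutive
#' windows; this composes the per-window links so each starting cell maps to
#' its final descendants.
#'
#' @param links_list list of link data frames, consecutive windows in order
#' @return named list: for each t0 cell id, the integer vector of descendant
#'   ids at the final time point
#' @export
compose_links <- function(links_list) {
  stopifnot(length(links_list) >= 1)
  first <- links_list[[1]]
  desc <- split(first$child_id[!is.na(first$parent_id)],
                first$parent_id[!is.na(first$parent_id)])
  for (k in seq_along(links_list)[-1]) {
    lk <- links_list[[k]]
    step <- split(lk$child_id[!is.na(lk$parent_id)],
                  lk$parent_id[!is.na(lk$parent_id)])
    desc <- lapply(desc, function(ids) {
      out <- unlist(step[as.character(ids)], use.names = FALSE)
      sort(unique(out))
    })
  }
  desc
}
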