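# ---- watershed segmentation of wall-stain images ---------------------------

#' Segmentation configuration
#'
#' Knobs of the marker-controlled watershed. The method: Gaussian smoothing,
#' percentile background subtraction and normalization to a \[0, 1\]
#' wall-probability image; a tissue mask by thresholding and hole filling;
#' seeds from the regional minima of the h-minima transform of the wall
#' probability; watershed flooding from the seeds; and merging of regions
#' below `min_cell_area` into the neighbour sharing the longest boundary.
#'
#' @param blur_sigma Gaussian smoothing sigma in px
#' @param background_percentile percentile (0-100) subtracted as background
#' @param h_minima_depth seed suppression depth on the normalized \[0, 1\]
#'   wall-probability scale: shallower minima than this are not seeds
#' @param min_cell_area minimum cell area in um^2; smaller watershed regions
#'   are merged away
#' @param border_policy "keep" or "drop" cells touching the image border
#' @param mask_threshold normalized intensity above which a pixel counts as
#'   stained tissue when building the mask
#' @param mask_erode pixels of morphological erosion applied to the filled
#'   mask, trimming the blur halo that otherwise inflates edge cells
#' @return a `seg_config` list
#' @export
seg_config <- function(blur_sigma = 1, background_percentile = 25,
                       h_minima_depth = 0.1, min_cell_area = 20,
                       border_policy = c("keep", "drop"),
                       mask_threshold = 0.15, mask_erode = 1) {
  border_policy <- match.arg(border_policy)
  if (min_cell_area <= 0) stop("min_cell_area must be > 0")
  structure(list(blur_sigma = blur_sigma,
                 background_percentile = background_percentile,
                 h_minima_depth = h_minima_depth,
                 min_cell_area = min_cell_area,
                 border_policy = border_policy,
                 mask_threshold = mask_threshold,
                 mask_erode = mask_erode),
            class = "seg_config")
}

erode_mask <- function(mask, n = 1) {
  for (k in seq_len(n)) {
    nr <- nrow(mask); nc <- ncol(mask)
    up <- rbind(mask[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, mask[-nr, , drop = FALSE])
    lf <- cbind(mask[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, mask[, -nc, drop = FALSE])
    mask <- mask & up & dn & lf & rt
  }
  mask
}

#' Maximum-intensity projection of a Z-stack
#'
#' @param stack list of `pixel_image` slices with identical shape and pixel
#'   size
#' @return a `pixel_image`: the per-pixel maximum across slices
#' @export
max_project <- function(stack) {
  if (length(stack) == 0) stop("empty stack")
  dims <- vapply(stack, function(s) dim(s$intensities), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mismatched slice shapes")
  ps <- vapply(stack, `[[`, numeric(1), "pixel_size")
  if (any(ps != ps[1])) stop("mismatched pixel sizes")
  out <- stack[[1]]
  out$intensities <- Reduce(pmax, lapply(stack, `[[`, "intensities"))
  out
}

#' Preprocess a stain image into a wall-probability image
#'
#' Gaussian smoothing, percentile background subtraction, and normalization
#' to \[0, 1\]. A constant input returns an all-zero image with attribute
#' `constant_input = TRUE` instead of failing.
#'
#' @param img a `pixel_image`
#' @param cfg a [seg_config()]
#' @return a `pixel_image` of wall probabilities in \[0, 1\]
#' @export
preprocess_image <- function(img, cfg = seg_config()) {
  x <- img$intensities
  if (cfg$blur_sigma > 0) {
    r <- ceiling(3 * cfg$blur_sigma)
    k <- exp(-((-r:r)^2) / (2 * cfg$blur_sigma^2))
    x <- cpp_convolve_sep(x, k / sum(k))
  }
  bg <- quantile(x, cfg$background_percentile / 100, names = FALSE)
  x <- x - bg
  x[x < 0] <- 0
  m <- max(x)
  if (m == 0) {
    out <- img
    out$intensities <- x
    attr(out, "constant_input") <- TRUE
    return(out)
  }
  out <- img
  out$intensities <- x / m
  out
}

#' Marker-controlled watershed segmentation
#'
#' @param wallprob a preprocessed `pixel_image` (see [preprocess_image()])
#' @param cfg a [seg_config()]
#' @param mask optional logical matrix overriding the derived tissue mask
#' @return a `label_map`; labels are 1..K in raster order of first occurrence
#' @export
segment_cells <- function(wallprob, cfg = seg_config(), mask = NULL) {
  wp <- wallprob$intensities
  if (is.null(mask)) {
    mask <- cpp_fill_holes(wp > cfg$mask_threshold)
    if (cfg$mask_erode > 0) mask <- erode_mask(mask, cfg$mask_erode)
  }
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("no tissue mask found: empty segmentation")
  # h-minima transform via reconstruction by dilation on the negated image
  h <- cfg$h_minima_depth
  hmin <- -cpp_reconstruct_dilate(-wp - h, -wp)
  markers <- cpp_regional_minima(hmin, mask)
  if (max(markers) == 0) markers <- cpp_regional_minima(wp, mask)
  lab <- cpp_watershed(wp, markers, mask)
  lab <- merge_small_regions(lab, cfg$min_cell_area, wallprob$pixel_size)
  if (cfg$border_policy == "drop") {
    edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    lab[lab %in% setdiff(edge, 0L)] <- 0L
  }
  lab <- relabel_raster_order(lab)
  label_map(lab, wallprob$pixel_size, wallprob$origin)
}

# Merge regions smaller than min_area (um^2) into the adjacent region sharing
# the longest boundary; smallest regions first, deterministic.
merge_small_regions <- function(lab, min_area, pixel_size) {
  min_px <- min_area / pixel_size^2
  repeat {
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes > 0 & sizes < min_px)
    if (length(small) == 0) break
    target <- small[order(sizes[small], small)][1]
    adj <- cpp_adjacency_counts(lab)
    nb <- adj[(adj$a == target | adj$b == target), , drop = FALSE]
    nb$other <- ifelse(nb$a == target, nb$b, nb$a)
    nb <- nb[nb$other != 0, , drop = FALSE]
    if (nrow(nb) == 0) {
      lab[lab == target] <- 0L # isolated speck
    } else {
      best <- nb$other[order(-nb$n, nb$other)][1]
      lab[lab == target] <- best
    }
  }
  lab
}

relabel_raster_order <- function(lab) {
  ids <- unique(as.vector(lab))
  ids <- ids[ids != 0]
  # raster order of first occurrence (column-major like the matrix itself is
  # fine as long as it is fixed)
  first <- vapply(ids, function(i) which(lab == i)[1], numeric(1))
  remap <- integer(max(ids))
  remap[ids[order(first)]] <- seq_along(ids)
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Per-cell measurements from a label map
#'
#' One record per label: area in um^2 (pixel count x pixel_size^2), centroid
#' in world um coordinates, and the traced boundary polygon. Layer, trichome
#' and divided status start unassigned.
#'
#' @param lm a `label_map`
#' @param pixel_size um/px; defaults to the map's own
#' @return data frame with columns cell_id, area, x, y, n_px, layer,
#'   is_trichome, divided, and a list column `boundary` of m x 2 um polygons
#' @export
quantify_areas <- function(lm, pixel_size = lm$pixel_size) {
  lab <- lm$labels
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids != 0]
  if (length(ids) == 0) {
    out <- data.frame(cell_id = integer(0), area = numeric(0), x = numeric(0),
                      y = numeric(0), n_px = integer(0), layer = character(0),
                      is_trichome = logical(0), divided = logical(0),
                      stringsAsFactors = FALSE)
    out$boundary <- list()
    return(out)
  }
  ox <- lm$origin[1]; oy <- lm$origin[2]
  rows <- lapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    n <- nrow(w)
    cx <- ox + (mean(w[, 2]) - 0.5) * pixel_size
    cy <- oy + (mean(w[, 1]) - 0.5) * pixel_size
    list(id = id, n = n, cx = cx, cy = cy, w = w)
  })
  out <- data.frame(
    cell_id = ids,
    area = vapply(rows, function(r) r$n * pixel_size^2, numeric(1)),
    x = vapply(rows, `[[`, numeric(1), "cx"),
    y = vapply(rows, `[[`, numeric(1), "cy"),
    n_px = vapply(rows, `[[`, integer(1), "n"),
    layer = "unassigned", is_trichome = FALSE, divided = NA,
    stringsAsFactors = FALSE)
  out$boundary <- lapply(rows, function(r) {
    # trace in a cropped window for speed
    r0 <- min(r$w[, 1]); r1 <- max(r$w[, 1])
    c0 <- min(r$w[, 2]); c1 <- max(r$w[, 2])
    sub <- lab[r0:r1, c0:c1, drop = FALSE] == r$id
    b <- cpp_trace_boundary(sub)
    if (nrow(b) == 0) b <- cbind(r$w[1, 1] - r0, r$w[1, 2] - c0)
    cbind(ox + (b[, 2] + c0 - 1 - 0.5) * pixel_size,
          oy + (b[, 1] + r0 - 1 - 0.5) * pixel_size)
  })
  out
}

#' Blue-to-red colour scale used for area maps
#'
#' Exact blue at 0 and exact red at 1, passing through cyan, green and
#' yellow (a standard heat-map ramp).
#' @param t values in \[0, 1\]
#' @return matrix with columns r, g, b in \[0, 1\]
#' @export
area_colormap <- function(t) {
  ramp <- colorRamp(c("blue", "cyan", "green", "yellow", "red"))
  ramp(pmin(pmax(t, 0), 1)) / 255
}

#' Cell-area colour overlay
#'
#' Fills each cell with a colour from the blue-to-red scale at position
#' `min(area, cap) / cap`, emulating the published area maps (caps of 2000 or
#' 3000 um^2 depending on the stage shown). The cap and colormap name are
#' recorded as attributes.
#'
#' @param cells data frame from [quantify_areas()]
#' @param lm the `label_map` the records came from
#' @param cap saturation area in um^2
#' @return H x W x 3 RGB array in \[0, 1\] with attributes `cap` and
#'   `colormap`
#' @export
colorize_areas <- function(cells, lm, cap = 2000) {
  if (cap <= 0) stop("cap must be > 0")
  lab <- lm$labels
  out <- array(0, c(nrow(lab), ncol(lab), 3))
  if (nrow(cells) > 0) {
    t <- pmin(cells$area, cap) / cap
    cols <- area_colormap(t)
    lut <- matrix(0, max(cells$cell_id), 3)
    lut[cells$cell_id, ] <- cols
    idx <- which(lab > 0)
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[idx] <- lut[lab[idx], ch]
      out[, , ch] <- plane
    }
  }
  attr(out, "cap") <- cap
  attr(out, "colormap") <- "blue-cyan-green-yellow-red"
  out
}
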