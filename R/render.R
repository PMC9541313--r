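# ---- synthetic membrane-stain rendering ------------------------------------

#' Construct a pixel image object
#'
#' A 2D intensity grid plus the metadata the pipeline needs: pixel size
#' (um/px), the world coordinate of the image origin (the outer corner of
#' pixel \[1,1\]), acquisition time and sample id. Pixel (r, c) is centred at
#' `origin + (c - 0.5, r - 0.5) * pixel_size` in (x, y) um.
#'
#' @param intensities numeric matrix (rows = y, cols = x)
#' @param pixel_size um per pixel
#' @param origin length-2 numeric, world (x, y) of the image corner
#' @param time_h acquisition time in hours
#' @param sample_id sample identifier
#' @export
pixel_image <- function(intensities, pixel_size, origin = c(0, 0),
                        time_h = NA_real_, sample_id = NA_character_) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (nrow(intensities) < 16 || ncol(intensities) < 16)
    stop("image must be at least 16 x 16 px")
  structure(list(intensities = intensities, pixel_size = pixel_size,
                 origin = as.numeric(origin), time_h = time_h,
                 sample_id = sample_id),
            class = "pixel_image")
}

#' Construct a label map object
#'
#' Integer partition of the image plane into cells; 0 is background. Shares
#' the pixel geometry conventions of [pixel_image()].
#' @param labels integer matrix
#' @param pixel_size um per pixel
#' @param origin length-2 numeric, world (x, y) of the image corner
#' @export
label_map <- function(labels, pixel_size, origin = c(0, 0)) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "label_map")
}

#' Render a snapshot of simulated cells as a wall-stain image
#'
#' Rasterizes the cell polygons to a ground-truth label map, paints cell
#' boundary pixels at `wall_intensity`, interiors at `interior_intensity` and
#' background at `background_intensity`, then applies Gaussian blur and
#' additive seeded noise. Out-of-plane trichomes (initiated from inner cells)
#' are drawn as a bright disk overlying the mother cell, as they appear in a
#' maximum-intensity projection.
#'
#' @param cells list of simulated cells (a snapshot's `cells` element)
#' @param rp a [render_params()] object
#' @param time_h,sample_id metadata stamped on the returned image
#' @param pad_um background margin around the tissue (um)
#' @return list with `image` (a `pixel_image`) and `labels` (the ground-truth
#'   `label_map`)
#' @export
render_snapshot <- function(cells, rp = render_params(), time_h = NA_real_,
                            sample_id = NA_character_, pad_um = 6) {
  ids <- vapply(cells, `[[`, integer(1), "id")
  ord <- order(ids)
  cells <- cells[ord]; ids <- ids[ord]
  polys <- lapply(cells, `[[`, "poly")
  ps <- rp$pixel_size
  allv <- do.call(rbind, polys)
  ox <- min(allv[, 1]) - pad_um
  oy <- min(allv[, 2]) - pad_um
  ncol_ <- as.integer(ceiling((max(allv[, 1]) + pad_um - ox) / ps))
  nrow_ <- as.integer(ceiling((max(allv[, 2]) + pad_um - oy) / ps))
  nrow_ <- max(nrow_, 16L); ncol_ <- max(ncol_, 16L)
  lab <- cpp_rasterize_polygons(polys, ids, nrow_, ncol_, ps, ox, oy)

  px_counts <- tabulate(lab[lab > 0], nbins = max(ids))
  tiny <- which(px_counts < 4 & seq_len(max(ids)) %in% ids)
  if (length(tiny) >= 2)
    stop("pixel_size too coarse: cells ", paste(tiny, collapse = ", "),
         " rasterize to fewer than 4 px each")

  wall <- cpp_boundary_mask(lab)
  img <- matrix(rp$background_intensity, nrow_, ncol_)
  img[lab > 0] <- rp$interior_intensity
  img[wall] <- rp$wall_intensity

  # out-of-plane trichomes: bright disk over the mother cell footprint
  for (cl in cells) {
    if (!isTRUE(cl$out_of_plane)) next
    ctr <- poly_centroid(cl$poly)
    rad <- 0.5 * sqrt(poly_area(cl$poly) / pi)
    rr <- outer(seq_len(nrow_), seq_len(ncol_), function(r, c) {
      x <- ox + (c - 0.5) * ps; y <- oy + (r - 0.5) * ps
      (x - ctr[1])^2 + (y - ctr[2])^2
    })
    img[rr <= rad^2] <- rp$wall_intensity
  }

  if (rp$blur_sigma > 0) {
    r <- ceiling(3 * rp$blur_sigma)
    k <- exp(-((-r:r)^2) / (2 * rp$blur_sigma^2))
    img <- cpp_convolve_sep(img, k / sum(k))
  }
  if (rp$noise_sd > 0) {
    set.seed(rp$rng_seed)
    img <- img + matrix(rnorm(length(img), 0, rp$noise_sd), nrow_, ncol_)
    img[img < 0] <- 0
  }
  list(image = pixel_image(img, ps, c(ox, oy), time_h, sample_id),
       labels = label_map(lab, ps, c(ox, oy)))
}
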