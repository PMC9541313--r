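# ---- ground-truth export / import ------------------------------------------

#' Export a truth series to disk
#'
#' Writes, per snapshot, the rendered stain image (16-bit TIFF) and the
#' ground-truth label map (32-bit TIFF); plus one lineage table, one event
#' table (CSV) and a JSON manifest echoing pixel size, time points, seed and
#' the full parameter set. The files round-trip losslessly through
#' [import_truth()].
#'
#' @param series a `truth_series` from [simulate_gametophyte()]
#' @param directory output directory (created if needed)
#' @param rp a [render_params()] used for the image renders
#' @return invisibly, the manifest list
#' @export
export_truth <- function(series, directory, rp = render_params()) {
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok || file.access(directory, 2) != 0)
    stop("unwritable directory: ", directory)
  n <- length(series$snapshots)
  times <- numeric(0)
  for (i in seq_len(n)) {
    sn <- series$snapshots[[i]]
    times <- c(times, sn$time_h)
    rpi <- rp
    rpi$rng_seed <- rp$rng_seed + i - 1L
    r <- render_snapshot(sn$cells, rpi, time_h = sn$time_h)
    write_tiff(r$image$intensities, file.path(directory,
               sprintf("image_%03d.tif", i)), bits = 16)
    write_tiff(r$labels$labels, file.path(directory,
               sprintf("labels_%03d.tif", i)), bits = 32)
    # image geometry sidecar so label maps keep their world frame
    geo <- list(pixel_size = r$labels$pixel_size, origin = r$labels$origin,
                time_h = sn$time_h)
    jsonlite::write_json(geo, file.path(directory,
                         sprintf("geometry_%03d.json", i)),
                         auto_unbox = TRUE, digits = NA)
  }
  write.csv(series$lineage, file.path(directory, "lineage.csv"),
            row.names = FALSE)
  ev <- series$events
  ev_flat <- ev[, c("parent_id", "daughter_ids", "orientation",
                    "packet_type", "layer", "window", "wall_angle",
                    "trichome_init")]
  write.csv(ev_flat, file.path(directory, "events.csv"), row.names = FALSE)
  manifest <- list(schema_version = 1L,
                   n_snapshots = n,
                   time_points_h = times,
                   pixel_size = rp$pixel_size,
                   rng_seed = series$params$rng_seed,
                   params = unclass(series$params),
                   render_params = unclass(rp))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Import a truth series directory
#'
#' @param directory a directory written by [export_truth()]
#' @return list: manifest, images (list of `pixel_image`), labels (list of
#'   `label_map`), lineage and events data frames
#' @export
import_truth <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = TRUE)
  n <- manifest$n_snapshots
  images <- vector("list", n)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    geo <- jsonlite::read_json(file.path(directory,
                               sprintf("geometry_%03d.json", i)),
                               simplifyVector = TRUE)
    img <- read_tiff(file.path(directory, sprintf("image_%03d.tif", i)))
    lab <- read_tiff(file.path(directory, sprintf("labels_%03d.tif", i)))
    images[[i]] <- pixel_image(img, geo$pixel_size, geo$origin,
                               time_h = geo$time_h)
    labels[[i]] <- label_map(lab, geo$pixel_size, geo$origin)
  }
  lineage <- read.csv(file.path(directory, "lineage.csv"))
  events <- read.csv(file.path(directory, "events.csv"),
                     colClasses = c(daughter_ids = "character"))
  list(manifest = manifest, images = images, labels = labels,
       lineage = lineage, events = events)
}
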