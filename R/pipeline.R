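# ---- run configuration, end-to-end orchestration, result tables ------------

#' Full pipeline configuration
#'
#' Bundles every knob of the pipeline: segmentation, lineage matching
#' thresholds, orientation bands, packet rectangularity, trichome rules and
#' statistics flags, plus echoes of simulation/render parameters when the
#' run is synthetic. Round-trips losslessly through JSON
#' ([write_run_config()] / [read_run_config()]); every result table cites
#' the config hash.
#'
#' @param seg a [seg_config()]
#' @param strong_fraction,min_fraction lineage overlap thresholds
#' @param anticlinal_min,periclinal_max orientation bands (degrees)
#' @param min_solidity,min_fill packet rectangularity thresholds
#' @param outside_fraction,aspect_min trichome rule thresholds
#' @param trichome_mode "rule" or "truth"
#' @param welch use Welch's t-test in all statistics
#' @param sim optional [sim_params()] echo
#' @param render optional [render_params()] echo
#' @return a `run_config` list
#' @export
run_config <- function(seg = seg_config(), strong_fraction = 0.5,
                       min_fraction = 0.25, anticlinal_min = 60,
                       periclinal_max = 30, min_solidity = 0.9,
                       min_fill = 0.8, outside_fraction = 0.6,
                       aspect_min = 3, trichome_mode = c("rule", "truth"),
                       welch = FALSE, sim = NULL, render = NULL) {
  trichome_mode <- match.arg(trichome_mode)
  structure(list(seg = unclass(seg), strong_fraction = strong_fraction,
                 min_fraction = min_fraction,
                 anticlinal_min = anticlinal_min,
                 periclinal_max = periclinal_max,
                 min_solidity = min_solidity, min_fill = min_fill,
                 outside_fraction = outside_fraction,
                 aspect_min = aspect_min, trichome_mode = trichome_mode,
                 welch = welch,
                 sim = if (is.null(sim)) NULL else unclass(sim),
                 render = if (is.null(render)) NULL else unclass(render)),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`
#' @param path JSON file
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config()
  for (nm in names(x)) cfg[[nm]] <- x[[nm]]
  cfg$seg <- structure(cfg$seg, class = "seg_config")
  cfg
}

#' Deterministic hash of a configuration (FNV-1a over its JSON form)
#' @param cfg a `run_config` (or any serializable list)
#' @return 8-hex-digit string
#' @export
config_hash <- function(cfg) {
  strip <- function(x) {
    x <- unclass(x)
    if (is.list(x)) lapply(x, strip) else x
  }
  s <- jsonlite::toJSON(strip(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Track one imaging window and classify its divisions
#'
#' Registers the two segmented maps, matches cells, detects divisions,
#' estimates each division's new wall from the daughters' shared boundary,
#' and classifies its orientation against the t1 margin. Layers and layer
#' counts are taken at the window start (t0), as the rate equations require.
#'
#' @param lm0,lm1 segmented `label_map`s at window start/end
#' @param meta a [window_meta()]
#' @param cfg a [run_config()]
#' @param trichomes0,trichomes1 optional truth trichome label ids (used when
#'   `cfg$trichome_mode == "truth"`)
#' @return list: links, divided (named logical), events (data frame:
#'   parent_id, child_ids, orientation, angle, layer_of_parent,
#'   trichome_init, qc), layers0, layer_counts, cells0 (area records at t0),
#'   trichome_flags0/1, transform
#' @export
analyze_window <- function(lm0, lm1, meta, cfg = run_config(),
                           trichomes0 = NULL, trichomes1 = NULL) {
  tf <- register_maps(lm0, lm1)
  links <- match_lineage(lm0, lm1, tf, meta,
                         strong_fraction = cfg$strong_fraction,
                         min_fraction = cfg$min_fraction)
  divided_parents <- attr(links, "divided_parents")
  tri0 <- if (cfg$trichome_mode == "truth" && !is.null(trichomes0))
    flag_trichomes(lm0, truth_flags = trichomes0)
  else flag_trichomes(lm0, outside_fraction = cfg$outside_fraction,
                      aspect_min = cfg$aspect_min)
  tri1 <- if (cfg$trichome_mode == "truth" && !is.null(trichomes1))
    flag_trichomes(lm1, truth_flags = trichomes1)
  else flag_trichomes(lm1, outside_fraction = cfg$outside_fraction,
                      aspect_min = cfg$aspect_min)
  tri0_ids <- as.integer(names(tri0)[tri0])
  tri1_ids <- as.integer(names(tri1)[tri1])
  margin0 <- extract_margin(lm0, tri0_ids)
  layers0 <- assign_layers(lm0, margin0, tri0_ids)
  margin1 <- extract_margin(lm1, tri1_ids)
  l0t <- apply_transform(lm0, tf)
  ps1 <- lm1$pixel_size
  ev_rows <- list()
  for (p in divided_parents) {
    kids <- links$child_id[!is.na(links$parent_id) & links$parent_id == p &
                             links$overlap_fraction >= cfg$strong_fraction]
    if (length(kids) < 2) next
    # strongest k-1 daughter-pair walls (spanning tree of the child graph)
    pairs <- t(combn(sort(kids), 2))
    walls <- lapply(seq_len(nrow(pairs)), function(i)
      estimate_new_wall(lm1, pairs[i, 1], pairs[i, 2]))
    wlen <- vapply(walls, nrow, integer(1))
    ordp <- order(-wlen, pairs[, 1], pairs[, 2])
    comp <- as.list(sort(kids))
    names(comp) <- as.character(sort(kids))
    find <- function(x) { while (comp[[as.character(x)]] != x)
      x <- comp[[as.character(x)]]; x }
    chosen <- integer(0)
    for (i in ordp) {
      if (wlen[i] == 0) next
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) {
        comp[[as.character(ra)]] <- rb
        chosen <- c(chosen, i)
      }
    }
    # parent centroid in the t1 frame
    wpx <- which(l0t == p, arr.ind = TRUE)
    pc <- if (nrow(wpx) > 0)
      c(lm1$origin[1] + (mean(wpx[, 2]) - 0.5) * ps1,
        lm1$origin[2] + (mean(wpx[, 1]) - 0.5) * ps1)
    else c(NA_real_, NA_real_)
    for (i in chosen) {
      cls <- classify_orientation(walls[[i]], margin1, pc,
                                  cfg$anticlinal_min, cfg$periclinal_max)
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        parent_id = p,
        child_ids = paste(pairs[i, ], collapse = ";"),
        orientation = if (is.na(cls$orientation)) NA_character_
          else cls$orientation,
        angle = cls$angle,
        layer_of_parent = unname(layers0[as.character(p)]),
        trichome_init = any(pairs[i, ] %in% tri1_ids),
        qc = if (is.null(cls$qc)) NA_character_ else cls$qc,
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(ev_rows) == 0)
    data.frame(parent_id = integer(0), child_ids = character(0),
               orientation = character(0), angle = numeric(0),
               layer_of_parent = character(0), trichome_init = logical(0),
               qc = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, ev_rows)
  cells0 <- quantify_areas(lm0)
  cells0$layer <- unname(layers0[as.character(cells0$cell_id)])
  cells0$is_trichome <- cells0$cell_id %in% tri0_ids
  cells0$divided <- cells0$cell_id %in% divided_parents
  lc <- table(factor(layers0[!(names(layers0) %in%
                                 as.character(tri0_ids))],
                     levels = c("marginal", "submarginal", "inner")))
  list(links = links, divided = divided_parents, events = events,
       layers0 = layers0,
       layer_counts = list(n_marginal = unname(lc["marginal"]),
                           n_submarginal = unname(lc["submarginal"]),
                           n_inner = unname(lc["inner"]),
                           timeframe_h = meta$timeframe_h),
       cells0 = cells0, trichome_flags0 = tri0, trichome_flags1 = tri1,
       transform = tf)
}

#' Render, segment and track every window of a simulated series
#'
#' The end-to-end synthetic workflow: each snapshot is rendered and
#' segmented, consecutive maps are registered and tracked, and each window's
#' divisions are classified. When `truth_match = TRUE` the t0 segmentation is
#' matched to the ground-truth label map so detected parents are reported in
#' truth ids, ready for comparison with `series$events`.
#'
#' @param series a `truth_series`
#' @param rp a [render_params()]; per-snapshot noise seeds are derived from
#'   `rp$rng_seed`
#' @param cfg a [run_config()]
#' @param truth_match also match segmentations against truth label maps
#' @return list of per-window results (as [analyze_window()], plus
#'   `truth_map0` and `seg_eval` when requested) and `renders` (the
#'   per-snapshot render + segmentation)
#' @export
analyze_truth_series <- function(series, rp = render_params(),
                                 cfg = run_config(), truth_match = TRUE) {
  n <- length(series$snapshots)
  renders <- vector("list", n)
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    rpi <- rp
    rpi$rng_seed <- rp$rng_seed + i - 1L
    r <- render_snapshot(series$snapshots[[i]]$cells, rpi,
                         time_h = series$snapshots[[i]]$time_h)
    wp <- preprocess_image(r$image, structure(cfg$seg, class = "seg_config"))
    segs[[i]] <- segment_cells(wp, structure(cfg$seg, class = "seg_config"))
    renders[[i]] <- r
  }
  windows <- vector("list", max(0, n - 1))
  for (w in seq_len(max(0, n - 1))) {
    meta <- window_meta(series$snapshots[[w]]$time_h,
                        series$snapshots[[w + 1]]$time_h)
    tri_truth0 <- truth_trichome_seg_ids(series, w, renders[[w]]$labels,
                                         segs[[w]])
    tri_truth1 <- truth_trichome_seg_ids(series, w + 1,
                                         renders[[w + 1]]$labels,
                                         segs[[w + 1]])
    res <- analyze_window(segs[[w]], segs[[w + 1]], meta, cfg,
                          trichomes0 = tri_truth0, trichomes1 = tri_truth1)
    if (truth_match) {
      m0 <- match_labels(renders[[w]]$labels, segs[[w]])
      res$truth_map0 <- m0
      res$seg_eval <- evaluate_segmentation(renders[[w]]$labels, segs[[w]])
    }
    windows[[w]] <- res
  }
  list(windows = windows, renders = renders, segs = segs)
}

# Truth trichome ids of snapshot i translated into segmented label ids.
truth_trichome_seg_ids <- function(series, i, truth_lm, seg_lm) {
  cells <- series$snapshots[[i]]$cells
  tri <- vapply(cells, `[[`, logical(1), "trichome")
  if (!any(tri)) return(integer(0))
  tru_ids <- vapply(cells, `[[`, integer(1), "id")[tri]
  m <- match_labels(truth_lm, seg_lm)
  m$b[m$a %in% tru_ids]
}

#' Write a bundle of result tables, overlays and a manifest
#'
#' Tables are CSV with deterministic row order (sorted by sample, time and
#' cell_id columns when present); overlays are PPM rasters; the manifest
#' records the schema version and the config hash every table cites.
#'
#' @param bundle list with elements `tables` (named list of data frames),
#'   `overlays` (named list of RGB arrays, optional) and `config`
#' @param directory output directory
#' @return invisibly, the manifest list
#' @export
write_tables <- function(bundle, directory) {
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok) stop("unwritable directory: ", directory)
  hash <- config_hash(bundle$config)
  for (nm in names(bundle$tables)) {
    tb <- bundle$tables[[nm]]
    sort_cols <- intersect(c("sample", "time_h", "set", "window", "cell_id",
                             "parent_id"), names(tb))
    if (length(sort_cols) > 0 && nrow(tb) > 0)
      tb <- tb[do.call(order, tb[sort_cols]), , drop = FALSE]
    tb$config_hash <- rep(hash, nrow(tb))
    write.csv(tb, file.path(directory, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  for (nm in names(bundle$overlays))
    write_ppm(bundle$overlays[[nm]], file.path(directory,
              paste0(nm, ".ppm")))
  manifest <- list(schema_version = 1L, config_hash = hash,
                   tables = names(bundle$tables),
                   overlays = names(bundle$overlays),
                   config = unclass(bundle$config))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
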