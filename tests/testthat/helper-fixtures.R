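# Shared fixture builders. Everything is generated in code; no stored data.

# One square cell of the given side (um), as a snapshot cell list.
square_cell <- function(side = 20) {
  list(list(id = 1L,
            poly = rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)),
            role = "spore", birth_window = 0L, trichome = FALSE,
            out_of_plane = FALSE))
}

# A rectangular grid of cells at the established-meristem stage.
grid_series <- function(rows, cols, windows = 0, seed = 1, ...) {
  simulate_gametophyte(sim_params(n_windows = windows, init_rows = rows,
                                  init_cols = cols, rng_seed = seed, ...))
}

# Noise-free render parameters.
rp_clean <- function(pixel_size = 1) {
  render_params(pixel_size = pixel_size, blur_sigma = 0, noise_sd = 0)
}

# Render + segment a snapshot, returning truth labels and segmentation.
render_and_segment <- function(cells, rp = render_params(), cfg = seg_config()) {
  r <- render_snapshot(cells, rp)
  wp <- preprocess_image(r$image, cfg)
  list(truth = r$labels, seg = segment_cells(wp, cfg), image = r$image)
}

# Random convex polygon around the origin (radius ~ [3, 10] um).
random_convex_poly <- function(n = 8) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 3, 10)
  cbind(r * cos(th), r * sin(th))
}

# A label map built directly from an integer matrix.
lm_from_matrix <- function(m, pixel_size = 1, origin = c(0, 0)) {
  label_map(m, pixel_size, origin)
}

# Map detected (segmented t0) parent ids to truth ids for a tracked window.
to_truth_ids <- function(ids, truth_map) {
  truth_map$a[match(ids, truth_map$b)]
}

# Independent brute-force recounts of the percentage statistics, written as
# direct transcriptions of the defining equations over raw event lists.
brute_packet <- function(records) {
  keep <- !records$complex
  rec <- records[keep, , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(rec))) {
    t <- rec$types[[i]]
    out <- rbind(out, data.frame(
      set = rec$set[i],
      I = 100 * sum(t == "I") / 2, II = 100 * sum(t == "II") / 2,
      III = 100 * sum(t == "III") / 1, IV = 100 * sum(t == "IV") / 1))
  }
  sets <- sort(unique(out$set))
  per_set <- do.call(rbind, lapply(sets, function(s) {
    sub <- out[out$set == s, ]
    data.frame(set = s, I = mean(sub$I), II = mean(sub$II),
               III = mean(sub$III), IV = mean(sub$IV))
  }))
  means <- c(I = mean(per_set$I), II = mean(per_set$II),
             III = mean(per_set$III), IV = mean(per_set$IV))
  list(per_set = per_set, means = means)
}

brute_layer_rates <- function(events, layer_counts) {
  out <- NULL
  for (i in seq_len(nrow(layer_counts))) {
    s <- layer_counts$set[i]
    row <- list(set = s)
    for (ly in c("marginal", "submarginal")) {
      ncell <- layer_counts[[paste0("n_", ly)]][i]
      for (ori in c("anticlinal", "periclinal")) {
        nev <- 0
        for (j in seq_len(nrow(events)))
          if (events$set[j] == s && events$layer[j] == ly &&
              events$orientation[j] == ori)
            nev <- nev + 1
        row[[paste0(ly, "_", ori)]] <- if (ncell == 0) NA_real_
          else nev / ncell / layer_counts$timeframe_h[i] * 48 * 100
      }
    }
    out <- rbind(out, as.data.frame(row))
  }
  out
}

brute_fractions <- function(events) {
  sets <- sort(unique(events$set))
  out <- NULL
  for (s in sets) {
    row <- list(set = s)
    for (ly in c("marginal", "submarginal")) {
      tot <- 0; na <- 0; np <- 0
      for (j in seq_len(nrow(events)))
        if (events$set[j] == s && events$layer[j] == ly) {
          tot <- tot + 1
          if (events$orientation[j] == "anticlinal") na <- na + 1
          if (events$orientation[j] == "periclinal") np <- np + 1
        }
      row[[paste0(ly, "_anticlinal")]] <- if (tot == 0) NA_real_
        else 100 * na / tot
      row[[paste0(ly, "_periclinal")]] <- if (tot == 0) NA_real_
        else 100 * np / tot
    }
    out <- rbind(out, as.data.frame(row))
  }
  out
}

# Random event tables / packet records for the equation oracles.
random_packet_records <- function(n_sets, seed) {
  set.seed(seed)
  recs <- list()
  for (s in seq_len(n_sets)) {
    for (k in seq_len(sample(1:4, 1))) {
      # keep at least one analyzable packet in every draw
      complex <- length(recs) > 0 && runif(1) < 0.1
      types <- character(0)
      if (!complex) {
        if (runif(1) < 0.4) types <- c(types, sample(c("I", "II"), 1))
        if (runif(1) < 0.4) types <- c(types, sample(c("I", "II"), 1))
        if (runif(1) < 0.4) types <- c(types, sample(c("III", "IV"), 1))
      }
      recs[[length(recs) + 1]] <- data.frame(set = s, complex = complex)
      recs[[length(recs)]]$types <- list(sort(types))
    }
  }
  do.call(rbind, recs)
}

random_event_table <- function(n_sets, seed) {
  set.seed(seed)
  ev <- NULL
  lc <- NULL
  for (s in seq_len(n_sets)) {
    nm <- sample(5:40, 1); ns <- sample(0:25, 1)
    tf <- sample(c(24, 48), 1)
    lc <- rbind(lc, data.frame(set = s, n_marginal = nm, n_submarginal = ns,
                               timeframe_h = tf))
    n_ev <- sample(0:10, 1)
    if (n_ev > 0)
      ev <- rbind(ev, data.frame(
        set = s,
        layer = sample(c("marginal", "submarginal"), n_ev, replace = TRUE),
        orientation = sample(c("anticlinal", "periclinal", "oblique"),
                             n_ev, replace = TRUE, prob = c(.45, .45, .1))))
  }
  if (is.null(ev))
    ev <- data.frame(set = integer(0), layer = character(0),
                     orientation = character(0))
  list(events = ev, layer_counts = lc)
}
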