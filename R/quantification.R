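# ---- division statistics ---------------------------------------------------
# Conventions used throughout: the unit of replication is the time-lapse set
# (one sample over one analyzed window); SE = SD / sqrt(n of sets); t-tests
# are Student's two-tailed with pooled variance (Welch behind a flag).

se <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

two_tailed_t <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    return(list(t = NA_real_, p = NA_real_, df = NA_real_))
  if (sd(c(x, y)) == 0) # identical groups: no evidence of a difference
    return(list(t = 0, p = 1, df = length(x) + length(y) - 2))
  ht <- tryCatch(t.test(x, y, var.equal = !welch, alternative = "two.sided"),
                 error = function(e) NULL)
  if (is.null(ht)) # degenerate (e.g. both groups constant but different)
    return(list(t = NA_real_, p = NA_real_, df = NA_real_))
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Packet division-type percentages (Types I-IV)
#'
#' Per packet: Type I % = (number of Type I divisions) / 2 x 100 and likewise
#' for Type II (the two upper cells are the denominator); Type III % =
#' (number of Type III) / 1 x 100 and likewise Type IV (one lower cell).
#' Complex packets (any cell dividing more than once in the window) are
#' excluded. Packets aggregate to per-set means; sets aggregate to the
#' reported mean +/- SE. Because all three cells are scored per packet the
#' type percentages can sum to more than 100.
#'
#' @param records data frame with one row per packet: `set`, `types`
#'   (list column of character vectors, or ";"-separated strings), `complex`
#' @param welch use Welch's t-test instead of pooled variance
#' @return a `packet_stats` list: per_packet, per_set, summary (type, mean,
#'   se), tests (I vs II, III vs IV), n_sets, n_packets, n_excluded_complex
#' @export
packet_percentages <- function(records, welch = FALSE) {
  if (is.null(records) || nrow(records) == 0)
    stop("no packet records: missing 'set' grouping to aggregate over")
  if (!"set" %in% names(records))
    stop("packet records must carry a 'set' grouping column")
  types <- records$types
  if (!is.list(types))
    types <- strsplit(ifelse(is.na(types), "", types), ";", fixed = TRUE)
  complex <- if ("complex" %in% names(records)) records$complex
    else rep(FALSE, nrow(records))
  keep <- !complex
  n_excl <- sum(!keep)
  rec <- records[keep, , drop = FALSE]
  types <- types[keep]
  if (nrow(rec) == 0) stop("all packets excluded as complex")
  per_packet <- data.frame(
    set = rec$set,
    I = vapply(types, function(t) sum(t == "I") / 2 * 100, numeric(1)),
    II = vapply(types, function(t) sum(t == "II") / 2 * 100, numeric(1)),
    III = vapply(types, function(t) sum(t == "III") / 1 * 100, numeric(1)),
    IV = vapply(types, function(t) sum(t == "IV") / 1 * 100, numeric(1)))
  per_set <- aggregate(per_packet[c("I", "II", "III", "IV")],
                       by = list(set = per_packet$set), FUN = mean)
  summary <- data.frame(
    type = c("I", "II", "III", "IV"),
    mean = vapply(c("I", "II", "III", "IV"), function(k)
      mean(per_set[[k]]), numeric(1)),
    se = vapply(c("I", "II", "III", "IV"), function(k)
      se(per_set[[k]]), numeric(1)),
    row.names = NULL)
  tests <- list(I_vs_II = two_tailed_t(per_set$I, per_set$II, welch),
                III_vs_IV = two_tailed_t(per_set$III, per_set$IV, welch))
  structure(list(per_packet = per_packet, per_set = per_set,
                 summary = summary, tests = tests,
                 n_sets = nrow(per_set), n_packets = nrow(rec),
                 n_excluded_complex = n_excl),
            class = "packet_stats")
}

#' Per-48-h layer division rates
#'
#' For each time-lapse set and each of the four combinations
#' (marginal/submarginal x anticlinal/periclinal):
#' rate = number of divisions / number of layer cells before imaging /
#' timeframe_h x 48 x 100 (%), so 24-h windows are normalized to the 48-h
#' scale. Oblique events are excluded from these rates (and logged). Sets
#' with zero cells in a layer have that layer's rates undefined and are
#' dropped listwise for that statistic, with counts reported.
#'
#' @param events data frame: set, layer ("marginal"/"submarginal"),
#'   orientation ("anticlinal"/"periclinal"/"oblique"); one row per division
#'   event (a cell dividing twice contributes two rows)
#' @param layer_counts data frame: set, n_marginal, n_submarginal,
#'   timeframe_h — the cell counts at the start of each set's window
#' @param welch use Welch's t-test
#' @return a `layer_stats` list: per_set (set, marginal_anticlinal,
#'   marginal_periclinal, submarginal_anticlinal, submarginal_periclinal),
#'   summary, tests, n_sets, n_oblique_excluded, n_undefined
#' @export
layer_rates <- function(events, layer_counts, welch = FALSE) {
  if (!all(c("set", "n_marginal", "n_submarginal", "timeframe_h") %in%
             names(layer_counts)))
    stop("layer_counts needs set, n_marginal, n_submarginal, timeframe_h")
  n_obl <- sum(events$orientation == "oblique")
  ev <- events[events$orientation %in% c("anticlinal", "periclinal"), ,
               drop = FALSE]
  count_ev <- function(s, ly, ori)
    sum(ev$set == s & ev$layer == ly & ev$orientation == ori)
  per_set <- data.frame(set = layer_counts$set)
  for (ly in c("marginal", "submarginal")) {
    ncell <- layer_counts[[paste0("n_", ly)]]
    for (ori in c("anticlinal", "periclinal")) {
      v <- vapply(seq_len(nrow(layer_counts)), function(i) {
        if (is.na(ncell[i]) || ncell[i] == 0) return(NA_real_)
        nev <- count_ev(layer_counts$set[i], ly, ori)
        nev / ncell[i] / layer_counts$timeframe_h[i] * 48 * 100
      }, numeric(1))
      per_set[[paste0(ly, "_", ori)]] <- v
    }
  }
  cols <- c("marginal_anticlinal", "marginal_periclinal",
            "submarginal_anticlinal", "submarginal_periclinal")
  summary <- data.frame(
    rate = cols,
    mean = vapply(cols, function(k) mean(per_set[[k]], na.rm = TRUE),
                  numeric(1)),
    se = vapply(cols, function(k) se(per_set[[k]]), numeric(1)),
    n = vapply(cols, function(k) sum(!is.na(per_set[[k]])), numeric(1)),
    row.names = NULL)
  tests <- list(
    marginal_vs_submarginal_anticlinal =
      two_tailed_t(per_set$marginal_anticlinal,
                   per_set$submarginal_anticlinal, welch),
    marginal_vs_submarginal_periclinal =
      two_tailed_t(per_set$marginal_periclinal,
                   per_set$submarginal_periclinal, welch),
    marginal_anticlinal_vs_periclinal =
      two_tailed_t(per_set$marginal_anticlinal,
                   per_set$marginal_periclinal, welch),
    submarginal_anticlinal_vs_periclinal =
      two_tailed_t(per_set$submarginal_anticlinal,
                   per_set$submarginal_periclinal, welch))
  structure(list(per_set = per_set, summary = summary, tests = tests,
                 n_sets = nrow(per_set), n_oblique_excluded = n_obl,
                 n_undefined = sum(is.na(as.matrix(per_set[cols])))),
            class = "layer_stats")
}

#' Orientation fractions among cells that divided
#'
#' Per layer and set: anticlinal % = anticlinal events / all division events
#' in that layer x 100 (periclinal likewise). A cell dividing more than once
#' contributes every event. Oblique events stay in the denominator, so the
#' two percentages sum to 100 only when no oblique event occurred. Layers
#' with zero events in a set are undefined and excluded (logged).
#'
#' @param events data frame: set, layer, orientation
#' @param welch use Welch's t-test
#' @return a `dividing_fractions` list: per_set, summary, tests (a vs p
#'   within each layer), n_undefined
#' @export
dividing_cell_fractions <- function(events, welch = FALSE) {
  sets <- sort(unique(events$set))
  per_set <- data.frame(set = sets)
  for (ly in c("marginal", "submarginal")) {
    for (ori in c("anticlinal", "periclinal")) {
      v <- vapply(sets, function(s) {
        tot <- sum(events$set == s & events$layer == ly)
        if (tot == 0) return(NA_real_)
        sum(events$set == s & events$layer == ly &
              events$orientation == ori) / tot * 100
      }, numeric(1))
      per_set[[paste0(ly, "_", ori)]] <- v
    }
  }
  cols <- setdiff(names(per_set), "set")
  summary <- data.frame(
    fraction = cols,
    mean = vapply(cols, function(k) mean(per_set[[k]], na.rm = TRUE),
                  numeric(1)),
    se = vapply(cols, function(k) se(per_set[[k]]), numeric(1)),
    n = vapply(cols, function(k) sum(!is.na(per_set[[k]])), numeric(1)),
    row.names = NULL)
  tests <- list(
    marginal_anticlinal_vs_periclinal =
      two_tailed_t(per_set$marginal_anticlinal,
                   per_set$marginal_periclinal, welch),
    submarginal_anticlinal_vs_periclinal =
      two_tailed_t(per_set$submarginal_anticlinal,
                   per_set$submarginal_periclinal, welch))
  structure(list(per_set = per_set, summary = summary, tests = tests,
                 n_undefined = sum(is.na(as.matrix(per_set[cols])))),
            class = "dividing_fractions")
}

#' Compare areas of cells that divided vs cells that did not
#'
#' Cell areas are taken at the window start; trichome-flagged cells must be
#' removed upstream (or passed via `trichome`). Reports group means with
#' SE = SD/sqrt(n) and a Student's two-tailed t-test (pooled variance;
#' Welch behind the flag). With fewer than two cells in a group the means
#' are still reported but the test is undefined.
#'
#' @param areas numeric vector of cell areas (um^2) at window start
#' @param divided logical vector: did the cell divide during the window
#' @param trichome optional logical vector; flagged cells are dropped
#' @param welch use Welch's t-test
#' @return a `size_comparison` list: mean/se/n per group, t, p, df
#' @export
size_vs_division <- function(areas, divided, trichome = NULL,
                             welch = FALSE) {
  stopifnot(length(areas) == length(divided))
  if (!is.null(trichome)) {
    areas <- areas[!trichome]
    divided <- divided[!trichome]
  }
  a_div <- areas[divided]
  a_non <- areas[!divided]
  ht <- two_tailed_t(a_div, a_non, welch)
  structure(list(
    mean_divided = mean(a_div), se_divided = se(a_div),
    n_divided = length(a_div),
    mean_nondivided = mean(a_non), se_nondivided = se(a_non),
    n_nondivided = length(a_non),
    t_statistic = ht$t, p_value = ht$p, df = ht$df),
    class = "size_comparison")
}

#' Gametophyte growth rates and group comparison
#'
#' The growth rate of each gametophyte over 48 h is area(48 h) / area(0 h),
#' trichomes excluded upstream. Groups (e.g. stain vs mock) are compared
#' with a two-tailed t-test.
#'
#' @param samples data frame: sample, group, area0, area48 (um^2)
#' @param welch use Welch's t-test
#' @return a `growth_result` list: per_sample (with rate), group_means,
#'   test (t, p, df)
#' @export
growth_rate_comparison <- function(samples, welch = FALSE) {
  if (any(samples$area0 <= 0)) stop("zero or negative baseline area")
  samples$rate <- samples$area48 / samples$area0
  groups <- split(samples$rate, samples$group)
  if (length(groups) != 2)
    stop("exactly two groups required, got ", length(groups))
  gm <- data.frame(group = names(groups),
                   mean = vapply(groups, mean, numeric(1)),
                   se = vapply(groups, se, numeric(1)),
                   n = vapply(groups, length, numeric(1)),
                   row.names = NULL)
  ht <- two_tailed_t(groups[[1]], groups[[2]], welch)
  structure(list(per_sample = samples, group_means = gm, test = ht),
            class = "growth_result")
}
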