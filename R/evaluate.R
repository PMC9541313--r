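# ---- truth-vs-pipeline evaluation helpers ----------------------------------

#' One-to-one label matching between two label maps by IoU
#'
#' Computes the intersection-over-union of every co-occurring label pair and
#' greedily matches pairs by descending IoU (ties: smaller ids), each label
#' used at most once.
#'
#' @param lm_a,lm_b `label_map`s of identical shape
#' @return data frame with columns a, b, iou, sorted by a
#' @export
match_labels <- function(lm_a, lm_b) {
  la <- lm_a$labels; lb <- lm_b$labels
  if (!all(dim(la) == dim(lb))) stop("label maps must have the same shape")
  tab <- cpp_overlap_table(la, lb)
  na <- tabulate(la[la > 0])
  nb <- tabulate(lb[lb > 0])
  tab <- tab[tab$a > 0 & tab$b > 0, , drop = FALSE]
  if (nrow(tab) == 0)
    return(data.frame(a = integer(0), b = integer(0), iou = numeric(0)))
  tab$iou <- tab$n / (na[tab$a] + nb[tab$b] - tab$n)
  tab <- tab[order(-tab$iou, tab$a, tab$b), , drop = FALSE]
  used_a <- logical(max(tab$a)); used_b <- logical(max(tab$b))
  keep <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!used_a[tab$a[i]] && !used_b[tab$b[i]]) {
      keep[i] <- TRUE
      used_a[tab$a[i]] <- TRUE
      used_b[tab$b[i]] <- TRUE
    }
  }
  out <- tab[keep, c("a", "b", "iou")]
  out[order(out$a), , drop = FALSE]
}

#' Segmentation quality against a ground-truth label map
#'
#' @param lm_truth,lm_seg truth and segmented `label_map`s
#' @param iou_threshold minimum IoU for a truth cell to count as recovered
#' @return list: n_truth, n_seg, n_matched (one-to-one at threshold),
#'   match_fraction, mean_iou over matches, and pixel_agreement (fraction of
#'   foreground pixels agreeing after optimal matching)
#' @export
evaluate_segmentation <- function(lm_truth, lm_seg, iou_threshold = 0.7) {
  m <- match_labels(lm_truth, lm_seg)
  n_truth <- length(setdiff(unique(as.vector(lm_truth$labels)), 0L))
  n_seg <- length(setdiff(unique(as.vector(lm_seg$labels)), 0L))
  ok <- m[m$iou >= iou_threshold, , drop = FALSE]
  # pixel agreement under the matched relabelling
  la <- lm_truth$labels; lb <- lm_seg$labels
  fg <- la > 0 | lb > 0
  remap <- integer(max(c(1L, lb)))
  if (nrow(m) > 0) remap[m$b] <- m$a
  lb_m <- lb
  lb_m[lb > 0] <- remap[lb[lb > 0]]
  agree <- sum(la[fg] == lb_m[fg]) / sum(fg)
  list(n_truth = n_truth, n_seg = n_seg, n_matched = nrow(ok),
       match_fraction = if (n_truth > 0) nrow(ok) / n_truth else NA_real_,
       mean_iou = if (nrow(ok) > 0) mean(ok$iou) else NA_real_,
       pixel_agreement = agree)
}

#' Precision/recall of detected division events against simulator truth
#'
#' @param detected data frame with a `parent_id` column of t0 cells called
#'   divided (in truth ids, i.e. after matching the t0 segmentation to truth)
#' @param truth_parents integer vector of truth parent ids that divided
#' @return list with precision, recall, n_detected, n_truth
#' @export
evaluate_divisions <- function(detected, truth_parents) {
  det <- unique(detected$parent_id)
  tru <- unique(truth_parents)
  tp <- length(intersect(det, tru))
  list(precision = if (length(det) > 0) tp / length(det) else NA_real_,
       recall = if (length(tru) > 0) tp / length(tru) else NA_real_,
       n_detected = length(det), n_truth = length(tru))
}
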