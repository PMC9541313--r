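test_that("window metadata validates its timeframe", {
  m <- window_meta(0, 48)
  expect_equal(m$timeframe_h, 48)
  expect_error(window_meta(48, 48), "positive")
})

test_that("registering a map to itself recovers the identity", {
  s <- grid_series(4, 5, seed = 2)
  r <- render_snapshot(s$snapshots[[1]]$cells, render_params())
  tf <- register_maps(r$labels, r$labels)
  expect_equal(tf$rotation, 0, tolerance = 0.11)
  expect_equal(tf$scale, 1, tolerance = 0.011)
  expect_lt(sqrt(sum(tf$translation^2)), 0.5)
})

test_that("a known translation is recovered within half a micrometre", {
  s <- grid_series(4, 5, seed = 2)
  r <- render_snapshot(s$snapshots[[1]]$cells, render_params())
  lab <- r$labels$labels
  ps <- r$labels$pixel_size
  # shift by (5, -3) px via embedding into a larger frame
  big <- matrix(0L, nrow(lab) + 20, ncol(lab) + 20)
  big[10 + seq_len(nrow(lab)) - 3, 10 + seq_len(ncol(lab)) + 5] <- lab
  lm1 <- label_map(big, ps)
  tf <- register_maps(r$labels, lm1)
  # row shift -3 px, col shift +5 px relative to the centroid alignment
  expect_equal(tf$rotation, 0, tolerance = 0.11)
  expect_equal(tf$scale, 1, tolerance = 0.011)
  l0t <- apply_transform(r$labels, tf)
  agree <- sum(l0t == big & big > 0) / sum(big > 0)
  expect_gt(agree, 0.95)
})

test_that("a known rotation about the centroid is recovered within 0.5 deg", {
  s <- grid_series(4, 6, seed = 3)
  r <- render_snapshot(s$snapshots[[1]]$cells, render_params())
  lab <- r$labels$labels
  w <- which(lab > 0, arr.ind = TRUE)
  ctr <- colMeans(w)
  rot10 <- prothallus:::cpp_transform_labels(lab, 10, 1, 0, 0, ctr[1],
                                             ctr[2], nrow(lab), ncol(lab))
  lm1 <- label_map(rot10, r$labels$pixel_size)
  tf <- register_maps(r$labels, lm1)
  expect_equal(tf$rotation, 10, tolerance = 0.5)
})

test_that("matching a map to itself is bijective with zero divisions", {
  s <- grid_series(4, 5, seed = 2)
  r <- render_snapshot(s$snapshots[[1]]$cells, render_params())
  tf <- identity_transform(r$labels)
  links <- match_lineage(r$labels, r$labels, tf, window_meta(0, 48))
  expect_equal(nrow(links), max(r$labels$labels))
  expect_equal(links$parent_id, links$child_id)
  expect_true(all(links$overlap_fraction == 1))
  expect_length(attr(links, "divided_parents"), 0)
  dm <- divided_map(links, r$labels)
  expect_equal(dm$n_divided, 0)
  expect_equal(dm$n_nondivided, max(r$labels$labels))
  # all-green overlay
  expect_true(all(dm$overlay[, , 1] == 0))
})

test_that("a bisected cell yields exactly one division link", {
  m0 <- matrix(0L, 40, 40)
  m0[5:35, 5:35] <- 1L
  m1 <- m0
  m1[5:35, 21:35] <- 2L
  lm0 <- lm_from_matrix(m0)
  lm1 <- lm_from_matrix(m1)
  links <- match_lineage(lm0, lm1, identity_transform(lm1),
                         window_meta(0, 48))
  expect_equal(nrow(links), 2)
  expect_equal(attr(links, "divided_parents"), 1L)
  dm <- divided_map(links, lm0)
  expect_equal(dm$n_divided, 1)
  # all-red overlay on the single cell
  expect_true(all(dm$overlay[m0 > 0][1] == 1))
})

test_that("every cell bisected turns the whole map red", {
  m0 <- matrix(0L, 30, 46)
  m0[5:25, 5:25] <- 1L
  m0[5:25, 26:42] <- 2L
  m1 <- m0
  m1[15:25, 5:25] <- 3L
  m1[15:25, 26:42] <- 4L
  links <- match_lineage(lm_from_matrix(m0), lm_from_matrix(m1),
                         identity_transform(lm_from_matrix(m1)),
                         window_meta(0, 48))
  dm <- divided_map(links, lm_from_matrix(m0))
  expect_equal(dm$n_divided, 2)
  expect_equal(dm$n_nondivided, 0)
})

test_that("links are invariant to a known applied transform", {
  s <- grid_series(4, 5, windows = 1, seed = 5)
  r0 <- render_snapshot(s$snapshots[[1]]$cells, render_params(rng_seed = 1))
  r1 <- render_snapshot(s$snapshots[[2]]$cells, render_params(rng_seed = 2))
  tf <- register_maps(r0$labels, r1$labels)
  links_a <- match_lineage(r0$labels, r1$labels, tf, window_meta(0, 48))
  # rotate/translate the t1 map and re-register
  lab1 <- r1$labels$labels
  big <- matrix(0L, nrow(lab1) + 30, ncol(lab1) + 30)
  big[15 + seq_len(nrow(lab1)), 15 + seq_len(ncol(lab1))] <- lab1
  w <- which(big > 0, arr.ind = TRUE)
  ctr <- colMeans(w)
  rot <- prothallus:::cpp_transform_labels(big, 8, 1, 2, -3, ctr[1], ctr[2],
                                           nrow(big), ncol(big))
  lm1b <- label_map(rot, r1$labels$pixel_size)
  tf_b <- register_maps(r0$labels, lm1b)
  links_b <- match_lineage(r0$labels, lm1b, tf_b, window_meta(0, 48))
  key <- function(l) paste(l$parent_id, l$child_id)
  shared <- intersect(key(links_a), key(links_b))
  expect_gte(length(shared) / max(nrow(links_a), nrow(links_b)), 0.95)
  expect_setequal(attr(links_a, "divided_parents"),
                  attr(links_b, "divided_parents"))
})

test_that("substantial shrinkage is logged as a QC warning, not an error", {
  m0 <- matrix(0L, 30, 30)
  m0[5:25, 5:25] <- 1L
  m1 <- matrix(0L, 30, 30)
  m1[10:20, 10:20] <- 1L # same cell, much smaller
  links <- match_lineage(lm_from_matrix(m0), lm_from_matrix(m1),
                         identity_transform(lm_from_matrix(m1)),
                         window_meta(0, 48))
  expect_gt(length(attr(links, "qc")), 0)
  expect_match(attr(links, "qc")[1], "shrank")
})

test_that("composing per-window links yields full descendant sets", {
  s <- grid_series(4, 6, windows = 2, seed = 7, p_trichome = 0)
  # track on the truth label maps themselves: labels are truth ids
  rs <- lapply(1:3, function(i)
    render_snapshot(s$snapshots[[i]]$cells, rp_clean(0.5))$labels)
  links <- lapply(1:2, function(w)
    match_lineage(rs[[w]], rs[[w + 1]], register_maps(rs[[w]], rs[[w + 1]]),
                  window_meta((w - 1) * 48, w * 48)))
  desc <- compose_links(links)
  # truth descendant sets from the lineage table
  lg <- s$lineage
  truth_desc <- function(id) {
    cur <- id
    for (w in 1:2) {
      nxt <- unlist(lapply(cur, function(p) {
        d <- lg$daughter_id[lg$parent_id == p & lg$window == w]
        if (length(d) == 0) p else d
      }))
      cur <- sort(unique(nxt))
    }
    cur
  }
  st <- snapshot_table(s, 1)
  ok <- 0
  for (id in st$id)
    if (identical(sort(desc[[as.character(id)]]), truth_desc(id)))
      ok <- ok + 1
  expect_gte(ok / nrow(st), 0.9)
})
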