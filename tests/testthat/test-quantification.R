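test_that("packet percentages substitute into the defining equations", {
  # one packet, a single Type I division: I = 1/2 x 100 = 50%
  rec <- data.frame(set = 1, complex = FALSE)
  rec$types <- list("I")
  ps <- packet_percentages(rec)
  expect_equal(ps$summary$mean, c(50, 0, 0, 0))
  # both uppers periclinal + lower anticlinal: II = 2/2, III = 1/1
  rec2 <- data.frame(set = 1, complex = FALSE)
  rec2$types <- list(c("II", "II", "III"))
  ps2 <- packet_percentages(rec2)
  expect_equal(ps2$summary$mean, c(0, 100, 100, 0))
  # complex packets are excluded and counted
  rec3 <- rbind(rec, rec)
  rec3$types <- list("I", "IV")
  rec3$complex <- c(FALSE, TRUE)
  ps3 <- packet_percentages(rec3)
  expect_equal(ps3$n_excluded_complex, 1)
  expect_equal(ps3$n_packets, 1)
  expect_equal(ps3$summary$mean, c(50, 0, 0, 0))
  expect_error(packet_percentages(rec[0, ]), "set|packet")
})

test_that("packet percentages match a brute-force recount on random sets", {
  for (seed in 1:40) {
    rec <- random_packet_records(n_sets = sample(2:6, 1), seed = seed)
    ps <- packet_percentages(rec)
    bf <- brute_packet(rec)
    expect_equal(ps$summary$mean, unname(bf$means))
    expect_equal(ps$per_set$I, bf$per_set$I)
    expect_equal(ps$per_set$IV, bf$per_set$IV)
  }
})

test_that("layer rates substitute into the normalization equation", {
  # 5 anticlinal events among 50 marginal cells over 24 h:
  # 5 / 50 / 24 * 48 * 100 = 20%
  ev <- data.frame(set = rep(1, 5), layer = "marginal",
                   orientation = "anticlinal")
  lc <- data.frame(set = 1, n_marginal = 50, n_submarginal = 10,
                   timeframe_h = 24)
  lr <- layer_rates(ev, lc)
  expect_equal(lr$per_set$marginal_anticlinal, 20)
  expect_equal(lr$per_set$marginal_periclinal, 0)
  # no events at all: all rates zero
  lr0 <- layer_rates(ev[0, ], lc)
  expect_true(all(unlist(lr0$per_set[, -1]) == 0))
  # zero cells in a layer: undefined, logged
  lc2 <- data.frame(set = 1, n_marginal = 50, n_submarginal = 0,
                    timeframe_h = 48)
  lr2 <- layer_rates(ev, lc2)
  expect_true(is.na(lr2$per_set$submarginal_anticlinal))
  expect_equal(lr2$n_undefined, 2)
})

test_that("a 24-h window rate equals a 48-h rate with doubled events", {
  ev24 <- data.frame(set = 1, layer = rep("marginal", 3),
                     orientation = "periclinal")
  lc24 <- data.frame(set = 1, n_marginal = 30, n_submarginal = 5,
                     timeframe_h = 24)
  ev48 <- data.frame(set = 1, layer = rep("marginal", 6),
                     orientation = "periclinal")
  lc48 <- data.frame(set = 1, n_marginal = 30, n_submarginal = 5,
                     timeframe_h = 48)
  expect_equal(layer_rates(ev24, lc24)$per_set$marginal_periclinal,
               layer_rates(ev48, lc48)$per_set$marginal_periclinal)
})

test_that("layer rates and fractions match brute force on random tables", {
  for (seed in 1:40) {
    tab <- random_event_table(n_sets = sample(2:6, 1), seed = seed + 1000)
    lr <- layer_rates(tab$events, tab$layer_counts)
    bf <- brute_layer_rates(
      tab$events[tab$events$orientation != "oblique", , drop = FALSE],
      tab$layer_counts)
    for (col in c("marginal_anticlinal", "marginal_periclinal",
                  "submarginal_anticlinal", "submarginal_periclinal"))
      expect_equal(lr$per_set[[col]], bf[[col]])
    if (nrow(tab$events) > 0) {
      fr <- dividing_cell_fractions(tab$events)
      bf2 <- brute_fractions(tab$events)
      for (col in names(fr$per_set)[-1])
        expect_equal(fr$per_set[[col]], bf2[[col]])
    }
  }
})

test_that("dividing-cell fractions split anticlinal vs periclinal", {
  ev <- data.frame(set = 1, layer = rep("marginal", 4),
                   orientation = c(rep("anticlinal", 3), "periclinal"))
  fr <- dividing_cell_fractions(ev)
  expect_equal(fr$per_set$marginal_anticlinal, 75)
  expect_equal(fr$per_set$marginal_periclinal, 25)
  ev2 <- data.frame(set = 1, layer = rep("marginal", 2),
                    orientation = "anticlinal")
  fr2 <- dividing_cell_fractions(ev2)
  expect_equal(fr2$per_set$marginal_anticlinal, 100)
  expect_equal(fr2$per_set$marginal_periclinal, 0)
  expect_true(is.na(fr2$per_set$submarginal_anticlinal))
})

test_that("size comparison reproduces the closed-form pooled t-test", {
  same <- size_vs_division(c(10, 20, 30, 10, 20, 30),
                           c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  # {1,2} vs {3,4}: means 1.5/3.5, pooled var 0.5,
  # t = -2 / sqrt(0.5 * (1/2 + 1/2)) = -2.8284271, df = 2;
  # p = 2 * (1 - (1/2 + t/(2 sqrt(2) sqrt(1 + t^2/2)))) = 0.10557281
  sc <- size_vs_division(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sc$t_statistic, -2 * sqrt(2), tolerance = 1e-10)
  expect_equal(sc$df, 2)
  expect_equal(sc$p_value, 0.1055728090, tolerance = 1e-8)
  expect_equal(sc$se_divided, sd(c(1, 2)) / sqrt(2))
  # a one-cell group reports means but no test
  one <- size_vs_division(c(5, 7, 9), c(TRUE, FALSE, FALSE))
  expect_equal(one$mean_divided, 5)
  expect_true(is.na(one$t_statistic))
})

test_that("size statistics are invariant to area rescaling", {
  set.seed(21)
  areas <- rlnorm(60, 5, 0.4)
  div <- runif(60) < 0.3
  a <- size_vs_division(areas, div)
  b <- size_vs_division(areas * 7.3, div)
  expect_equal(a$t_statistic, b$t_statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("trichome-flagged cells are excluded from size statistics", {
  areas <- c(10, 20, 1000, 30)
  div <- c(TRUE, FALSE, FALSE, FALSE)
  tri <- c(FALSE, FALSE, TRUE, FALSE)
  sc <- size_vs_division(areas, div, trichome = tri)
  expect_equal(sc$n_nondivided, 2)
  expect_equal(sc$mean_nondivided, 25)
})

test_that("growth rates are ratios with a two-group comparison", {
  df <- data.frame(sample = 1:4, group = c("PI", "PI", "mock", "mock"),
                   area0 = c(100, 100, 100, 100),
                   area48 = c(100, 200, 150, 150))
  gr <- growth_rate_comparison(df)
  expect_equal(gr$per_sample$rate, c(1, 2, 1.5, 1.5))
  expect_equal(gr$group_means$mean[gr$group_means$group == "mock"], 1.5)
  df$area0[1] <- 0
  expect_error(growth_rate_comparison(df), "baseline")
})

test_that("the group test is calibrated under the null growth law", {
  # two groups drawn from one growth law: p-values should be uniform
  set.seed(77)
  pvals <- replicate(200, {
    rates <- rlnorm(12, log(1.6), 0.15)
    df <- data.frame(sample = 1:12,
                     group = rep(c("PI", "mock"), each = 6),
                     area0 = 100, area48 = 100 * rates)
    growth_rate_comparison(df)$test$p
  })
  ks <- ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_gt(min(pvals), 0)
  expect_lt(max(pvals), 1 + 1e-9)
})
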