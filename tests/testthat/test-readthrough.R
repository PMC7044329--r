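test_that("uniform coverage forces a nascent ratio of exactly 10", {
  trk <- make_track(rep(3, 8000))
  g <- one_gene(2000, 5000, "+")
  r <- proseq_readthrough_ratio(trk, g[1, ])
  expect_true(r$valid)
  expect_identical(r$ratio, 10)            # 500 * c / (50 * c)
})

test_that("signal confined to the gene body gives nascent ratio 0", {
  v <- numeric(8000); v[2001:5000] <- 5    # stops exactly at the TES
  trk <- make_track(v)
  r <- proseq_readthrough_ratio(trk, one_gene(2000, 5000, "+")[1, ])
  expect_true(r$valid)
  expect_equal(r$ratio, 0)
})

test_that("minus-strand spikes land in mirrored windows", {
  # tes at genomic 5000 for a - gene spanning [5000, 6000):
  # downstream offset d maps to genomic 5000 - 1 - d, upstream window
  # [-50, 0) maps to genomic [5000, 5050)
  minus <- numeric(8000)
  minus[4200 + 1] <- 3                     # offset 799: in [500, 1000)
  minus[5020 + 1] <- 2                     # 20 bases upstream of the TES
  trk <- make_track(numeric(8000), minus)
  r <- proseq_readthrough_ratio(trk, one_gene(5000, 6000, "-")[1, ])
  expect_equal(r$numerator, 3)
  expect_equal(r$denominator, 2)
  expect_equal(r$ratio, 1.5)
})

test_that("zero denominator and out-of-bounds windows invalidate, not error", {
  trk <- make_track(numeric(4000))
  r <- proseq_readthrough_ratio(trk, one_gene(1000, 2000, "+")[1, ])
  expect_false(r$valid)
  expect_equal(r$invalid_reason, "zero_denominator")
  r <- proseq_readthrough_ratio(trk, one_gene(2500, 3500, "+")[1, ])
  expect_false(r$valid)                    # window would end at 4500 > 4000
  expect_equal(r$invalid_reason, "window_out_of_bounds")
})

test_that("occupancy ratio follows its closed form and stays in [0,1]", {
  # uniform c over [TSS, TES + 1000), L = 1000 -> ratio 1000/(L+1000) = 0.5
  v <- numeric(8000); v[2001:4000] <- 4
  r <- polii_readthrough_ratio(make_track(v), one_gene(2000, 3000, "+")[1, ])
  expect_equal(r$ratio, 0.5)
  # all signal inside the gene body -> 0
  v2 <- numeric(8000); v2[2001:3000] <- 4
  r <- polii_readthrough_ratio(make_track(v2), one_gene(2000, 3000, "+")[1, ])
  expect_equal(r$ratio, 0)
  # all signal downstream of the TES -> 1
  v3 <- numeric(8000); v3[3001:4000] <- 4
  r <- polii_readthrough_ratio(make_track(v3), one_gene(2000, 3000, "+")[1, ])
  expect_equal(r$ratio, 1)
})

test_that("occupancy ratio sums both strands", {
  plus <- numeric(8000); plus[2001:4000] <- 1
  minus <- numeric(8000); minus[3001:4000] <- 1
  r <- polii_readthrough_ratio(make_track(plus, minus),
                               one_gene(2000, 3000, "+")[1, ])
  expect_equal(r$ratio, (1000 + 1000) / (2000 + 1000))
})

test_that("both ratios match a per-base oracle on random genes and tracks", {
  withr::local_seed(2024)
  n <- 12000
  for (rep in 1:25) {
    dense_p <- numeric(n); dense_m <- numeric(n)
    dense_p[sample.int(n, 300)] <- sample(1:5, 300, replace = TRUE)
    dense_m[sample.int(n, 300)] <- sample(1:5, 300, replace = TRUE)
    trk <- make_track(dense_p, dense_m)
    strand <- sample(c("+", "-"), 1)
    L <- sample(200:2000, 1)
    start <- sample(2000:(n - L - 2000), 1)
    g <- one_gene(start, start + L, strand)[1, ]
    tes <- if (strand == "+") start + L else start
    dense <- if (strand == "+") dense_p else dense_m
    num <- naive_window_sum(dense, tes, strand, 500, 1000)
    den <- naive_window_sum(dense, tes, strand, -50, 0)
    r <- proseq_readthrough_ratio(trk, g)
    expect_equal(r$numerator, num)
    expect_equal(r$denominator, den)
    if (den > 0) expect_identical(r$ratio, num / den)
    both <- dense_p + dense_m
    num2 <- naive_window_sum(both, tes, strand, 0, 1000)
    den2 <- naive_window_sum(both, tes, strand, -L, 1000)
    r2 <- polii_readthrough_ratio(trk, g)
    expect_equal(r2$numerator, num2)
    expect_equal(r2$denominator, den2)
    if (r2$valid) expect_true(r2$ratio >= 0 && r2$ratio <= 1)
  }
})

test_that("ratios are invariant under spike-in scaling", {
  withr::local_seed(11)
  v <- rpois(8000, 0.4)
  trk <- make_track(v)
  g <- one_gene(2000, 5000, "+")[1, ]
  r0 <- proseq_readthrough_ratio(trk, g)
  p0 <- polii_readthrough_ratio(trk, g)
  scaled <- spike_in_scale(trk, sample_spike_signal = 4e6,
                           reference_spike_signal = 1e6)
  expect_equal(interval_sum(scaled, "chrT", 0, 8000, "+"), sum(v) / 4)
  expect_equal(proseq_readthrough_ratio(scaled, g)$ratio, r0$ratio)
  expect_equal(polii_readthrough_ratio(scaled, g)$ratio, p0$ratio)
  expect_error(spike_in_scale(trk, 0, 1), "positive")
  # equal spike totals leave the track unchanged
  same <- spike_in_scale(trk, 5, 5)
  expect_equal(interval_sum(same, "chrT", 0, 8000, "+"), sum(v))
})

test_that("occupancy ratio is monotone in where signal is added", {
  v <- numeric(8000); v[2001:4000] <- 2
  g <- one_gene(2000, 3000, "+")[1, ]
  base <- polii_readthrough_ratio(make_track(v), g)$ratio
  v_down <- v; v_down[3500] <- v_down[3500] + 50   # inside [TES, TES+1000)
  expect_gt(polii_readthrough_ratio(make_track(v_down), g)$ratio, base)
  v_body <- v; v_body[2500] <- v_body[2500] + 50   # inside [TSS, TES)
  expect_lt(polii_readthrough_ratio(make_track(v_body), g)$ratio, base)
})

test_that("mirroring gene and track to the - strand leaves ratios unchanged", {
  withr::local_seed(3)
  n <- 9000
  dense <- rpois(n, 0.3)
  gp <- one_gene(3000, 4500, "+")[1, ]
  trk_p <- make_track(dense, numeric(n))
  trk_m <- make_track(numeric(n), rev(dense))
  gm <- one_gene(n - 4500, n - 3000, "-")[1, ]
  rp <- proseq_readthrough_ratio(trk_p, gp)
  rm <- proseq_readthrough_ratio(trk_m, gm)
  expect_equal(rm$numerator, rp$numerator)
  expect_equal(rm$denominator, rp$denominator)
  expect_equal(polii_readthrough_ratio(trk_m, gm)$ratio,
               polii_readthrough_ratio(trk_p, gp)$ratio)
})

test_that("group comparison reproduces the pooled-variance t test by hand", {
  cmp <- compare_groups(fake_results(1:5), fake_results(3:7), "histone")
  # textbook pooled t: n1 = n2 = 5, mean diff -2, pooled var 2.5
  sp2 <- (4 * var(1:5) + 4 * var(3:7)) / 8
  t_hand <- (mean(1:5) - mean(3:7)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  p_hand <- 2 * pt(-abs(t_hand), df = 8)
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(cmp$p_value, p_hand, tolerance = 1e-12)
  expect_equal(cmp$df, 8)
  # identical vectors -> t = 0, p = 1
  same <- compare_groups(fake_results(c(1, 2, 3)), fake_results(c(1, 2, 3)),
                         "histone")
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("whiskers stop at the most extreme point within 1.5 IQR", {
  x <- c(1, 2, 3, 4, 5, 6, 100)
  cmp <- compare_groups(fake_results(x), fake_results(x), "histone")
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  hi_fence <- q[2] + 1.5 * (q[2] - q[1])
  expect_equal(cmp$box_a$whisker_high, max(x[x <= hi_fence]))
  expect_lt(cmp$box_a$whisker_high, 100)
  expect_equal(cmp$box_a$median, median(x))
  expect_true(cmp$box_a$q1 <= cmp$box_a$median &&
                cmp$box_a$median <= cmp$box_a$q3)
})

test_that("group comparison excludes invalid genes and refuses tiny groups", {
  ra <- fake_results(c(1, 2, 3, NA), valid = c(TRUE, TRUE, TRUE, FALSE))
  rb <- fake_results(c(2, 3, 4, 5))
  cmp <- compare_groups(ra, rb, "histone")
  expect_equal(unname(cmp$n), c(3, 4))
  expect_equal(unname(cmp$n_excluded), c(1, 0))
  expect_error(compare_groups(fake_results(1), fake_results(1:5), "histone"),
               "fewer than 2")
})

test_that("readthrough window parameters are validated", {
  expect_error(readthrough_params(pro_down_start = 800, pro_down_end = 500),
               "pro_down_start")
  expect_error(readthrough_params(pro_up_len = 0), "positive")
})
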