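# PPS systematic sampling, allocation arithmetic and the two design stages.

test_that("equal sizes give equal inclusion probabilities", {
  set.seed(1)
  s <- pps_systematic_sample(data.frame(unit_id = 1:4,
                                        size = c(36, 36, 36, 36)), 2)
  expect_equal(nrow(s), 2L)
  expect_equal(s$pi, c(0.5, 0.5))
})

test_that("certainty units are peeled off and the remainder rescaled", {
  set.seed(2)
  s <- pps_systematic_sample(data.frame(unit_id = 1:4,
                                        size = c(4, 16, 36, 64)), 2)
  expect_true(4 %in% s$unit_id)
  expect_equal(s$pi[s$unit_id == 4], 1)
  others <- s[s$unit_id != 4, ]
  expect_equal(others$pi, others$size * 1 / 56)
})

test_that("drawing the whole frame returns certainty for everyone", {
  s <- pps_systematic_sample(data.frame(unit_id = letters[1:3],
                                        size = c(1, 5, 9)), 3)
  expect_equal(sort(s$unit_id), c("a", "b", "c"))
  expect_equal(s$pi, rep(1, 3))
})

test_that("invalid frames and draw counts are rejected", {
  fr <- data.frame(unit_id = 1:3, size = c(1, 2, 3))
  expect_error(pps_systematic_sample(fr, 4), "exceeds")
  expect_error(pps_systematic_sample(data.frame(unit_id = 1, size = 0), 1),
               "positive")
})

test_that("inclusion probabilities sum to the draw count on random frames", {
  set.seed(77)
  for (r in 1:25) {
    m <- sample(3:12, 1)
    n <- sample.int(m, 1)
    fr <- data.frame(unit_id = seq_len(m),
                     size = stats::rlnorm(m, sdlog = 1.5))
    s <- pps_systematic_sample(fr, n)
    expect_equal(nrow(s), n)
    expect_equal(length(unique(s$unit_id)), n)
    # frame-level sum of pi: selected carry theirs; recompute for the rest
    noncert <- s$unit_id[s$pi < 1]
    cert <- s$unit_id[s$pi == 1]
    rest <- fr[!fr$unit_id %in% cert, ]
    n_rest <- n - length(cert)
    if (n_rest > 0) {
      pi_all <- n_rest * rest$size / sum(rest$size)
      expect_equal(sum(pi_all) + length(cert), n, tolerance = 1e-12)
      expect_equal(sort(s$pi[s$pi < 1]),
                   sort(pi_all[match(noncert, rest$unit_id)]),
                   tolerance = 1e-12)
    }
  }
})

test_that("Horvitz-Thompson estimate of the frame size total is unbiased", {
  fr <- data.frame(unit_id = 1:5, size = c(2, 3, 7, 11, 20))
  true_total <- sum(fr$size)
  set.seed(99)
  n_rep <- 2000
  est <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    s <- pps_systematic_sample(fr, 2)
    est[r] <- sum(s$size / s$pi)
  }
  mc_se <- stats::sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - true_total), 3 * mc_se + 1e-9)
})

test_that("allocation arithmetic reproduces the planned design totals", {
  alloc <- dui_allocation()
  al <- allocate_totals(alloc, c(high_concentration = 23,
                                 low_concentration = 25))
  expect_equal(al$total_cos, 334)
  expect_equal(al$total_drivers, 806)
  bg <- al$by_geo
  expect_equal(bg$n_cos[bg$geo_stratum == "high_concentration"], 184)
  expect_equal(bg$n_cos[bg$geo_stratum == "low_concentration"], 150)
  expect_equal(bg$n_drivers[bg$geo_stratum == "high_concentration"], 506)
  expect_equal(bg$n_drivers[bg$geo_stratum == "low_concentration"], 300)

  one <- allocate_totals(alloc, c(high_concentration = 1,
                                  low_concentration = 1))
  expect_equal(one$total_cos, 14)
  expect_equal(one$total_drivers, 34)

  zero <- allocate_totals(alloc, c(high_concentration = 0,
                                   low_concentration = 0))
  expect_equal(zero$total_cos, 0)
  expect_equal(zero$total_drivers, 0)
  expect_error(allocate_totals(alloc, c(nowhere = 3)), "stratum")
})

test_that("sample-size planning arithmetic", {
  expect_equal(srs_margin(600), 0.04, tolerance = 0.001)
  expect_equal(inflate_for_loss(600, 0.25), 800)
})

test_that("CEA selection excludes empty areas and honours strata", {
  ceas <- data.frame(cea_id = sprintf("c%02d", 1:25),
                     geo_stratum = "low_concentration", n_outlets = 1L)
  set.seed(3)
  s <- select_ceas(ceas, c(low_concentration = 5))
  expect_equal(nrow(s), 5L)
  expect_equal(s$pi1, rep(0.2, 5))

  # one CEA holds all outlets: it is certain, others never selected
  ceas2 <- data.frame(cea_id = c("big", "z1", "z2"),
                      geo_stratum = "high_concentration",
                      n_outlets = c(9L, 0L, 0L))
  s2 <- select_ceas(ceas2, c(high_concentration = 1))
  expect_equal(s2$cea_id, "big")
  expect_equal(s2$pi1, 1)
  expect_error(select_ceas(ceas2, c(high_concentration = 2)), "cannot draw")
})

test_that("COS selection uses squared-duration PPS within CEA cells", {
  sel_cea <- data.frame(cea_id = "cea1", geo_stratum = "low_concentration",
                        n_outlets = 2, pi1 = 0.5)
  cosf <- data.frame(cos_id = c("a", "b"), outlet_id = "o1", cea_id = "cea1",
                     weekday = 6, start_h = c(15, 18), end_h = c(18, 27),
                     duration_h = c(6, 3), generic_shift = 15,
                     arc_prevalence = 3.17, arc_stratum = "intermediate",
                     size_measure = c(36, 9))
  alloc <- data.frame(geo_stratum = "low_concentration",
                      arc_stratum = "intermediate",
                      n_cos_per_cea = 1, n_drivers_per_cos = 2)
  set.seed(8)
  pis <- replicate(300, {
    s <- select_cos(cosf, sel_cea, alloc)
    c(s$pi2, s$cos_id == "a")
  })
  expect_true(all(pis[1, ] %in% c(0.8, 0.2)))
  # the 6h shift should win far more often than the 3h one (0.8 vs 0.2)
  expect_gt(mean(pis[2, ]), 0.7)

  # cell with exactly the allocated count: certainty
  alloc2 <- alloc
  alloc2$n_cos_per_cea <- 2
  s2 <- select_cos(cosf, sel_cea, alloc2)
  expect_equal(s2$pi2, c(1, 1))
  expect_equal(s2$driver_quota, c(2, 2))

  # empty cell: shortfall logged, no draws
  alloc3 <- data.frame(geo_stratum = "low_concentration",
                       arc_stratum = "high",
                       n_cos_per_cea = 2, n_drivers_per_cos = 2)
  s3 <- select_cos(cosf, sel_cea, alloc3)
  expect_equal(nrow(s3), 0L)
  expect_equal(attr(s3, "shortfall")$available, 0L)
})
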