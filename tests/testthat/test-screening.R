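# Inverse-sampling screening: session randomisers, outcome taxonomy, the
# one-in-four rule and stop conditions.

test_that("session randomisers have the declared support", {
  set.seed(5)
  for (i in 1:50) {
    r <- draw_session_randomizers()
    expect_true(r$start_offset_min %in% c(0, 30, 60))
    expect_true(r$nondui_random_start %in% 1:4)
  }
})

test_that("rounding a uniform start to the half hour gives 1/4,1/2,1/4", {
  set.seed(6)
  n <- 20000
  off <- replicate(n, draw_session_randomizers()$start_offset_min)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(mean(off == 30) - 0.5), 3 * se)
  se2 <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(off == 0) - 0.25), 3 * se2)
  expect_lt(abs(mean(off == 60) - 0.25), 3 * se2)
  starts <- replicate(n, draw_session_randomizers()$nondui_random_start)
  expect_lt(max(abs(tabulate(starts, 4) / n - 0.25)), 3 * se2)
})

test_that("screening outcomes follow the eligibility taxonomy", {
  expect_equal(classify_exit(TRUE, FALSE, TRUE, TRUE, TRUE),
               "noneligible_other")
  expect_equal(classify_exit(FALSE, TRUE, TRUE, TRUE, TRUE),
               "noneligible_other")
  expect_equal(classify_exit(TRUE, TRUE, FALSE, TRUE, TRUE),
               "noneligible_other")
  expect_equal(classify_exit(TRUE, TRUE, TRUE, TRUE, FALSE),
               "noneligible_nodrink_nodrive")
  expect_equal(classify_exit(TRUE, TRUE, TRUE, FALSE, FALSE),
               "noneligible_nodrink_nodrive")
  expect_equal(classify_exit(TRUE, TRUE, TRUE, TRUE, TRUE),
               "eligible_drank_driver")
  expect_error(classify_exit(NA, TRUE, TRUE, TRUE, TRUE), "complete")
})

test_that("one-in-four selection hits the arithmetic progression", {
  st <- toy_stream(10, intent = FALSE)
  out <- run_screening(st, duration_h = 6, quota = Inf,
                       start_offset_min = 0, random_start = 2)
  hit <- which(out$records$outcome == "interviewed")
  expect_equal(hit, c(2L, 6L, 10L))
  expect_equal(out$session$stop_reason, "shift_ended_with_interviews")
  expect_equal(out$session$window_fraction, 1)
})

test_that("quota stop and empty-stream stop reasons", {
  st <- toy_stream(5, intent = TRUE)
  out <- run_screening(st, duration_h = 6, quota = 4,
                       start_offset_min = 0, random_start = 1)
  expect_equal(sum(out$records$outcome == "interviewed"), 4L)
  expect_equal(out$session$stop_reason, "quota_reached")
  # stopping exit excluded from weighted screening counts
  expect_equal(sum(!out$records$counts_for_screening), 1L)
  expect_false(out$records$counts_for_screening[nrow(out$records)])

  empty <- toy_stream(0, intent = logical(0))
  out2 <- run_screening(empty, duration_h = 6, quota = 4,
                        start_offset_min = 30, random_start = 1)
  expect_equal(out2$session$stop_reason, "shift_ended_no_interviews")
  expect_equal(out2$session$window_fraction, 5.5 / 6)

  out3 <- run_screening(empty, duration_h = 0.5, quota = 4,
                        start_offset_min = 60, random_start = 1)
  expect_equal(out3$session$stop_reason, "impossible")
})

test_that("exits before the screening start are not approached", {
  st <- toy_stream(4, intent = TRUE, exit_time_h = c(0.1, 0.4, 2, 5))
  out <- run_screening(st, duration_h = 6, quota = Inf,
                       start_offset_min = 30, random_start = 1)
  expect_equal(nrow(out$records), 2L)
  expect_equal(out$session$window_fraction, 5.5 / 6)
})

test_that("marginal inclusion of non-DUI drivers is exactly 1/4", {
  # enumerate the 4 equiprobable random starts on fixed streams
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(6:14, 1)
    st <- toy_stream(n, intent = stats::runif(n) < 0.4)
    nondui <- which(!st$intent)
    counts <- integer(n)
    for (r in 1:4) {
      out <- run_screening(st, duration_h = 6, quota = Inf,
                           start_offset_min = 0, random_start = r)
      counts <- counts + (out$records$outcome == "interviewed")
    }
    expect_equal(counts[nondui], rep(1L, length(nondui)))  # 1 of 4 starts
    expect_equal(counts[-nondui], rep(4L, n - length(nondui)))
  }
})

test_that("screening tallies partition the approached stream", {
  set.seed(13)
  n <- 60
  st <- toy_stream(n, intent = NA,
                   age_ok = stats::runif(n) < 0.95,
                   resident = stats::runif(n) < 0.8,
                   not_prior = stats::runif(n) < 0.99,
                   driver = stats::runif(n) < 0.7,
                   drank = stats::runif(n) < 0.5,
                   refuses = stats::runif(n) < 0.1)
  eligible <- st$age_ok & st$resident & st$not_prior & st$driver & st$drank
  st$intent <- ifelse(eligible, stats::runif(n) < 0.5, NA)
  out <- run_screening(st, duration_h = 6, quota = Inf,
                       start_offset_min = 0, random_start = 3)
  tl <- screening_tally(out$records)
  total <- tl[tl$outcome == "total", ]
  rows <- tl[tl$outcome != "total", ]
  expect_equal(sum(rows$approached), total$approached)
  expect_equal(total$approached, nrow(out$records))
  # drank-driver identity: interviewed + skipped + refused = drank drivers
  dd <- rows[rows$outcome %in% c("interviewed", "non_dui_skipped",
                                 "refused_driver"), ]
  expect_equal(sum(dd$approached), sum(eligible))
})
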