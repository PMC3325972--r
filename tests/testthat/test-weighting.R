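# Base weights, post-stratum targets and post-stratification calibration.

test_that("base weights invert the stage probabilities and the 1-in-4 rate", {
  expect_equal(base_weight(0.5, 0.5, 1, dui = TRUE), 4)
  expect_equal(base_weight(0.5, 0.5, 1, dui = FALSE), 16)
  expect_equal(base_weight(0.5, 0.5, 0.5, dui = TRUE), 8)
  expect_equal(screening_weight(0.5, 0.5, 0.5), 8)
  # non-DUI weight is always 4x the matching DUI weight
  set.seed(20)
  p1 <- stats::runif(20, 0.05, 1)
  p2 <- stats::runif(20, 0.05, 1)
  f <- stats::runif(20, 0.1, 1)
  expect_equal(base_weight(p1, p2, f, FALSE), 4 * base_weight(p1, p2, f, TRUE))
  expect_error(base_weight(0, 0.5, 1, TRUE), "probabilities")
  expect_error(base_weight(0.5, 0.5, 0, TRUE), "positive")
  expect_error(base_weight(0.5, 1.2, 1, TRUE), "probabilities")
})

test_that("post-stratum targets scale proportions to the total", {
  cells <- expand.grid(geo_stratum = c("high_concentration",
                                       "low_concentration"),
                       sex = c("men", "women"),
                       age_group = c("18-29", "30-44", "45+"),
                       intent = c("going", "not_going"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$proportion <- 1 / 24
  t <- poststratum_targets(cells, 24000)
  expect_equal(t$target_total, rep(1000, 24))
  expect_equal(sum(t$target_total), 24000)
  cells$proportion[1] <- 0
  expect_error(poststratum_targets(cells, 100), "sum to 1")
})

test_that("packaged post-stratum table sums to its packaged total", {
  ps <- dui_poststrata()
  expect_equal(nrow(ps), 24L)
  expect_equal(sum(ps$target_total), 151573)
  zero <- ps[ps$sex == "women" & ps$age_group == "45+" &
               ps$geo_stratum == "low_concentration" &
               ps$intent == "going", ]
  expect_equal(zero$target_total, 0)
})

test_that("calibration rescales cells to their targets exactly", {
  d <- cell_drivers(c(3, 7))
  t <- data.frame(geo_stratum = "high_concentration", sex = "men",
                  age_group = "18-29", intent = "going", target_total = 20)
  out <- poststratify(d, t)
  expect_equal(out$g_factor, c(2, 2))
  expect_equal(out$calibrated_weight, c(6, 14))
})

test_that("calibration is idempotent and exact across many cells", {
  set.seed(21)
  ps <- dui_poststrata()
  nonzero <- ps[ps$target_total > 0, ]
  d <- nonzero[rep(seq_len(nrow(nonzero)), each = 3), ]
  d$target_total <- NULL
  d$base_weight <- stats::rlnorm(nrow(d), 3, 1)
  out <- poststratify(d, ps)
  sums <- tapply(out$calibrated_weight,
                 paste(out$geo_stratum, out$sex, out$age_group, out$intent),
                 sum)
  tgt <- stats::setNames(nonzero$target_total,
                         paste(nonzero$geo_stratum, nonzero$sex,
                               nonzero$age_group, nonzero$intent))
  expect_equal(as.numeric(sums[names(tgt)]), as.numeric(tgt),
               tolerance = 1e-12)
  expect_equal(sum(out$calibrated_weight), 151573, tolerance = 1e-9)

  # idempotence: recalibrating the calibrated weights changes nothing
  d2 <- out
  d2$base_weight <- d2$calibrated_weight
  out2 <- poststratify(d2, ps)
  expect_equal(out2$calibrated_weight, out$calibrated_weight,
               tolerance = 1e-12)
  # identity case: targets equal to current sums give g = 1
  t_id <- stats::aggregate(base_weight ~ geo_stratum + sex + age_group +
                             intent, data = d, FUN = sum)
  names(t_id)[names(t_id) == "base_weight"] <- "target_total"
  zero_cell <- ps[ps$target_total == 0, ]
  t_id <- rbind(t_id, zero_cell)
  out3 <- poststratify(d, t_id)
  expect_equal(out3$g_factor, rep(1, nrow(d)), tolerance = 1e-12)
})

test_that("zero-target cells with respondents get zero weight", {
  d <- cell_drivers(c(2, 5))
  t <- data.frame(geo_stratum = "high_concentration", sex = "men",
                  age_group = "18-29", intent = "going", target_total = 0)
  out <- poststratify(d, t)
  expect_equal(out$calibrated_weight, c(0, 0))
})

test_that("positive-target empty cells collapse into adjacent age cells", {
  d <- cell_drivers(c(10, 10), age_group = "30-44")
  t <- rbind(
    data.frame(geo_stratum = "high_concentration", sex = "men",
               age_group = "18-29", intent = "going", target_total = 30),
    data.frame(geo_stratum = "high_concentration", sex = "men",
               age_group = "30-44", intent = "going", target_total = 50))
  out <- poststratify(d, t)
  # merged target 80 over weight 20: g = 4 for both drivers
  expect_equal(out$g_factor, c(4, 4))
  expect_equal(sum(out$calibrated_weight), 80)
  expect_equal(nrow(attr(out, "collapsed")), 1L)

  # no age-adjacent cell with respondents (same sex/intent/stratum): error
  d2 <- cell_drivers(5, sex = "women", age_group = "18-29")
  t2 <- rbind(t[1, ],
              data.frame(geo_stratum = "high_concentration", sex = "women",
                         age_group = "18-29", intent = "going",
                         target_total = 10))
  expect_error(poststratify(d2, t2), "no age-adjacent cell")
})

test_that("age groups are closed-open at 30 and 45", {
  expect_equal(as.character(age_group_of(c(18, 29.99, 30, 44.5, 45, 80))),
               c("18-29", "18-29", "30-44", "30-44", "45+", "45+"))
  expect_error(age_group_of(17), "18")
})
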