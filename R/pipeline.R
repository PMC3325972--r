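# End-to-end survey pipeline on a synthetic city, and the Monte Carlo
# driver used to validate design-unbiasedness, calibration repair and
# confidence-interval coverage.

#' Run the full venue-based DUI survey pipeline on a synthetic city
#'
#' Executes every stage on generated data: builds the outlet-shift frame and
#' stratifies it by crash prevalence; selects CEAs (PPS by outlet count) and
#' COS (PPS by squared duration) per the allocation table; screens the exit
#' stream of every selected COS with the inverse-sampling protocol; forms
#' Horvitz-Thompson screening and driver weights; derives the 24
#' post-stratum targets from the screening estimates; calibrates the driver
#' weights by post-stratification; and produces domain estimates with
#' ultimate-cluster standard errors.  Ground truth for the generated
#' population is returned alongside.
#'
#' @param config a [sim_config()] list.
#' @param seed integer seed for the run (city generation excluded when
#'   \code{city} is supplied).
#' @param city optional pre-generated city from [generate_city()]; when
#'   NULL a city is generated from \code{config} first.
#' @param arc_table weekday-by-shift crash prevalence grid (default: the
#'   packaged table).
#' @param alloc per-stratum allocation table (default: the packaged table).
#' @param exits optional pre-generated exit streams (mainly for tests).
#' @return list with \code{estimates} (domain table, see
#'   [estimate_dui_table()]), \code{drivers} (calibrated respondents),
#'   \code{screening} (all approached records with weights),
#'   \code{sessions}, \code{targets}, \code{total_hat} (screening-based
#'   population total), \code{uncalibrated_prevalence_pct}, \code{truth}
#'   (see [truth_summary()]), \code{selected_ceas}, \code{selected_cos}.
#' @export
run_dui_survey <- function(config = sim_config(), seed = NULL, city = NULL,
                           arc_table = dui_arc_table(),
                           alloc = dui_allocation(), exits = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(city)) city <- generate_city(config)
  cutoffs <- compute_quartile_cutoffs(arc_table$prevalence_pct)
  cos_frame <- build_cos_frame(city$outlets, city$schedules, arc_table,
                               cutoffs)
  cos_frame$geo_stratum <-
    city$ceas$geo_stratum[match(cos_frame$cea_id, city$ceas$cea_id)]
  if (is.null(exits)) exits <- generate_exit_streams(cos_frame, config)
  truth <- truth_summary(exits)

  sel_ceas <- select_ceas(city$ceas, config$n_cea_sample)
  sel_cos <- select_cos(cos_frame, sel_ceas, alloc)
  if (nrow(sel_cos) == 0L) stop("no COS selected; frame too sparse")
  sel_cos <- sel_cos[order(sel_cos$weekday, sel_cos$start_h,
                           sel_cos$cos_id), ]

  n_sel <- nrow(sel_cos)
  screening <- vector("list", n_sel)
  exit_rows <- split(seq_len(nrow(exits)), exits$cos_id)
  ses_offset <- ses_start <- ses_quota <- ses_napp <- ses_nint <-
    integer(n_sel)
  ses_stop <- character(n_sel)
  ses_wf <- numeric(n_sel)
  for (i in seq_len(n_sel)) {
    rnd <- draw_session_randomizers()
    stream <- exits[exit_rows[[sel_cos$cos_id[i]]], , drop = FALSE]
    quota <- if (!is.null(config$quota_override)) config$quota_override
    else sel_cos$driver_quota[i]
    scr <- run_screening(stream, sel_cos$duration_h[i], quota,
                         rnd$start_offset_min, rnd$nondui_random_start)
    ses <- scr$session
    ses_offset[i] <- ses$start_offset_min
    ses_start[i] <- ses$random_start
    ses_quota[i] <- quota
    ses_stop[i] <- ses$stop_reason
    ses_wf[i] <- ses$window_fraction
    ses_napp[i] <- ses$n_approached
    ses_nint[i] <- ses$n_interviewed
    if (nrow(scr$records)) {
      rec <- scr$records
      rec$cea_id <- sel_cos$cea_id[i]
      rec$pi1 <- sel_cos$pi1[i]
      rec$pi2 <- sel_cos$pi2[i]
      rec$window_fraction <- ses$window_fraction
      screening[[i]] <- rec
    }
  }
  sessions <- data.frame(
    cos_id = sel_cos$cos_id, cea_id = sel_cos$cea_id,
    geo_stratum = sel_cos$geo_stratum, arc_stratum = sel_cos$arc_stratum,
    duration_h = sel_cos$duration_h, pi1 = sel_cos$pi1, pi2 = sel_cos$pi2,
    start_offset_min = ses_offset, random_start = ses_start,
    quota = ses_quota, stop_reason = ses_stop, window_fraction = ses_wf,
    n_approached = ses_napp, n_interviewed = ses_nint)
  screening <- screening[!vapply(screening, is.null, logical(1L))]
  if (length(screening) == 0L) stop("no clients approached in any session")
  screening <- do.call(rbind, screening)
  rownames(screening) <- NULL
  screening$screen_weight <-
    screening_weight(screening$pi1, screening$pi2,
                     screening$window_fraction) *
    screening$counts_for_screening

  # screening-based population total and 24-cell proportions
  drank_driver <- screening$outcome %in%
    c("interviewed", "non_dui_skipped", "refused_driver")
  sd_ <- screening[drank_driver, , drop = FALSE]
  sd_$intent_lbl <- ifelse(sd_$intent, "going", "not_going")
  total_hat <- sum(sd_$screen_weight)
  if (total_hat <= 0) stop("screening yielded no weighted drinking drivers")
  cells <- expand.grid(geo_stratum = GEO_STRATA,
                       sex = c("men", "women"), age_group = AGE_GROUPS,
                       intent = c("going", "not_going"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ckey <- poststratum_key(cells)
  skey <- paste(sd_$geo_stratum, sd_$sex, sd_$age_group, sd_$intent_lbl,
                sep = "|")
  wsum <- tapply(sd_$screen_weight, skey, sum)
  cells$proportion <- unname(ifelse(is.na(wsum[ckey]), 0,
                                    wsum[ckey])) / total_hat
  targets <- poststratum_targets(cells, total_hat)

  # interviewed drivers: base weights then post-stratification
  drivers <- screening[screening$outcome == "interviewed", , drop = FALSE]
  if (nrow(drivers) == 0L) stop("no completed interviews in this run")
  drivers$intent <- ifelse(drivers$intent, "going", "not_going")
  drivers$base_weight <- base_weight(drivers$pi1, drivers$pi2,
                                     drivers$window_fraction,
                                     drivers$intent == "going")
  uncal_prev <- estimate_prevalence(drivers$base_weight,
                                    drivers$intent == "going")
  drivers <- poststratify(drivers, targets)
  estimates <- estimate_dui_table(drivers, screening = sd_)

  list(estimates = estimates, drivers = drivers, screening = screening,
       sessions = sessions, targets = targets, total_hat = total_hat,
       uncalibrated_prevalence_pct = uncal_prev, truth = truth,
       selected_ceas = sel_ceas, selected_cos = sel_cos)
}

#' Monte Carlo study of the full pipeline
#'
#' Repeats [run_dui_survey()] on a fixed synthetic city with freshly
#' generated exit streams and fresh sample draws, recording for each
#' replicate the estimated and true population total and DUI prevalence,
#' their standard errors, the uncalibrated prevalence, and whether the
#' nominal 95\% normal confidence intervals cover the replicate's truth.
#'
#' Confidence intervals use the t reference distribution with the survey
#' degrees of freedom (number of sampled PSUs minus number of first-stage
#' strata), the standard practice for design-based intervals when the
#' number of PSUs is modest.
#'
#' @param config a [sim_config()] list.
#' @param n_rep number of replicates.
#' @param seed master seed; per-replicate seeds are drawn from it.
#' @return data.frame with one row per successful replicate (columns
#'   \code{est_total}, \code{se_total}, \code{true_total},
#'   \code{covered_total}, \code{est_prev}, \code{se_prev},
#'   \code{true_prev}, \code{covered_prev}, \code{uncal_prev});
#'   attribute \code{"n_failed"} counts replicates that errored (e.g. an
#'   uncollapsible empty post-stratum).
#' @export
mc_study <- function(config = sim_config(), n_rep = 500, seed = 1) {
  set.seed(seed)
  city <- generate_city(config)
  arc <- dui_arc_table()
  alloc <- dui_allocation()
  rep_seeds <- sample.int(2147483646L, n_rep)
  degf <- sum(config$n_cea_sample) - length(config$n_cea_sample)
  z <- stats::qt(0.975, df = degf)
  rows <- vector("list", n_rep)
  n_failed <- 0L
  for (r in seq_len(n_rep)) {
    res <- tryCatch(
      suppressWarnings(run_dui_survey(config, seed = rep_seeds[r],
                                      city = city, arc_table = arc,
                                      alloc = alloc)),
      error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    all_row <- res$estimates[res$estimates$domain == "All", ]
    est_total <- all_row$total_thousands * 1000
    se_total <- all_row$total_se_thousands * 1000
    true_total <- res$truth$total
    est_prev <- all_row$prevalence_pct
    se_prev <- all_row$prevalence_se
    true_prev <- res$truth$prevalence_pct
    rows[[r]] <- data.frame(
      est_total = est_total, se_total = se_total, true_total = true_total,
      covered_total = abs(est_total - true_total) <= z * se_total,
      est_prev = est_prev, se_prev = se_prev, true_prev = true_prev,
      covered_prev = abs(est_prev - true_prev) <= z * se_prev,
      uncal_prev = res$uncalibrated_prevalence_pct)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- n_failed
  out
}

#' Summarise a Monte Carlo study
#'
#' @param mc data.frame from [mc_study()].
#' @return list with the relative bias of the estimated total and its Monte
#'   Carlo standard error, the bias of the estimated prevalence (percentage
#'   points) and its MC standard error, the same for the uncalibrated
#'   prevalence, and the empirical coverage of the nominal 95\% intervals.
#' @export
mc_summary <- function(mc) {
  n <- nrow(mc)
  rb_total <- mean(mc$est_total - mc$true_total) / mean(mc$true_total)
  rb_total_se <- stats::sd(mc$est_total - mc$true_total) / sqrt(n) /
    mean(mc$true_total)
  bias_prev <- mean(mc$est_prev - mc$true_prev)
  bias_prev_se <- stats::sd(mc$est_prev - mc$true_prev) / sqrt(n)
  bias_uncal <- mean(mc$uncal_prev - mc$true_prev)
  bias_uncal_se <- stats::sd(mc$uncal_prev - mc$true_prev) / sqrt(n)
  list(n_rep = n,
       rel_bias_total = rb_total, rel_bias_total_mcse = rb_total_se,
       bias_prev_pp = bias_prev, bias_prev_mcse = bias_prev_se,
       bias_uncal_prev_pp = bias_uncal, bias_uncal_prev_mcse = bias_uncal_se,
       coverage_prev = mean(mc$covered_prev),
       coverage_total = mean(mc$covered_total))
}
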