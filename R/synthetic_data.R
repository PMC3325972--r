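# Synthetic-city generator: census areas in two outlet-density strata,
# outlets with weekly opening schedules whose derived shifts reproduce the
# field duration mix (2-8 h, mean ~4.8 h, mode 6 h, ~11% two-hour shifts),
# and time-ordered exit streams with latent ground truth for every client,
# so the whole pipeline can be validated by Monte Carlo.

#' Configuration for the synthetic-city generator
#'
#' Returns a validated configuration list with defaults chosen to emulate
#' the field study's frame and screening margins: opening-schedule templates
#' whose derived shifts have durations between 2 and 6.5 hours with mean
#' near 4.8 h, mode 6 h and roughly 11\% two-hour shifts; screening
#' attribute rates near the field margins (about 18\% of approached clients
#' out of scope, about half of eligible clients neither drinking nor
#' driving); and cell-level intention probabilities whose population mix
#' yields an overall DUI prevalence near 56\%.
#'
#' @param n_cea named vector: number of census areas per geographic stratum.
#' @param n_cea_sample named vector: CEAs to select per stratum.
#' @param outlet_lambda named vector: Poisson mean of extra outlets per CEA
#'   (on top of \code{outlet_min}).
#' @param outlet_min named vector: minimum outlets per CEA.
#' @param templates data.frame of opening-interval templates with columns
#'   \code{name}, \code{open_h}, \code{close_h}, \code{weight}.
#' @param p_open_day probability an outlet opens on any given weekday (at
#'   least one day is guaranteed).
#' @param exit_rate_per_h named vector: exits per hour by ARTC stratum.
#' @param p_age_ok,p_resident,p_driver,p_drank,p_men attribute
#'   probabilities per exiting client.
#' @param p_claims_prior probability a client reports prior participation.
#' @param age_group_probs probabilities of the three age groups.
#' @param intent_prob either a single probability used everywhere, or a
#'   data.frame with columns \code{sex}, \code{age_group},
#'   \code{geo_stratum}, \code{prob} covering all 12 cells.
#' @param refusal_prob named vector \code{c(going = , not_going = )}:
#'   refusal probability of a selected driver by intention (a constant
#'   refusal within post-strata, the condition under which calibration is
#'   unbiased).
#' @param p_refusal_noneligible,p_unable nuisance outcome probabilities.
#' @param quota_override optional single interview quota applied to every
#'   COS instead of the allocation table's per-stratum quotas.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_cea = c(high_concentration = 18,
                                 low_concentration = 28),
                       n_cea_sample = c(high_concentration = 12,
                                        low_concentration = 14),
                       outlet_lambda = c(high_concentration = 2,
                                         low_concentration = 0.7),
                       outlet_min = c(high_concentration = 2,
                                      low_concentration = 1),
                       templates = default_schedule_templates(),
                       p_open_day = 0.8,
                       exit_rate_per_h = c(low = 2, intermediate = 4,
                                           high = 7),
                       p_age_ok = 0.97, p_resident = 0.85,
                       p_claims_prior = 0.01,
                       p_driver = 0.79, p_drank = 0.53,
                       p_men = 0.76,
                       age_group_probs = c(0.32, 0.38, 0.30),
                       intent_prob = default_intent_probs(),
                       refusal_prob = c(going = 0.057, not_going = 0.057),
                       p_refusal_noneligible = 0.02, p_unable = 0.001,
                       quota_override = NULL) {
  probs <- c(p_open_day, p_age_ok, p_resident, p_claims_prior, p_driver,
             p_drank, p_men, p_refusal_noneligible, p_unable, refusal_prob,
             age_group_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(exit_rate_per_h < 0)) stop("exit rates must be nonnegative")
  if (abs(sum(age_group_probs) - 1) > 1e-8) {
    stop("age_group_probs must sum to 1")
  }
  if (abs(sum(templates$weight) - 1) > 1e-8) {
    stop("template weights must sum to 1")
  }
  if (is.data.frame(intent_prob)) {
    stopifnot(all(c("sex", "age_group", "geo_stratum", "prob") %in%
                    names(intent_prob)))
    if (any(intent_prob$prob < 0 | intent_prob$prob > 1)) {
      stop("intention probabilities must lie in [0, 1]")
    }
  } else if (!(is.numeric(intent_prob) && length(intent_prob) == 1L &&
               intent_prob >= 0 && intent_prob <= 1)) {
    stop("'intent_prob' must be a single probability or a 12-cell table")
  }
  structure(list(n_cea = n_cea, n_cea_sample = n_cea_sample,
                 outlet_lambda = outlet_lambda, outlet_min = outlet_min,
                 templates = templates, p_open_day = p_open_day,
                 exit_rate_per_h = exit_rate_per_h,
                 p_age_ok = p_age_ok, p_resident = p_resident,
                 p_claims_prior = p_claims_prior, p_driver = p_driver,
                 p_drank = p_drank, p_men = p_men,
                 age_group_probs = age_group_probs,
                 intent_prob = intent_prob, refusal_prob = refusal_prob,
                 p_refusal_noneligible = p_refusal_noneligible,
                 p_unable = p_unable, quota_override = quota_override),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_schedule_templates <- function() {
  data.frame(
    name = c("evening_bar", "afternoon_bar", "dinner_late", "pub",
             "mixed", "restaurant_long", "lunch"),
    open_h = c(21, 15, 18, 17, 15, 12, 11),
    close_h = c(27, 21, 27, 25, 23, 20, 13),
    weight = c(0.40, 0.10, 0.20, 0.12, 0.08, 0.03, 0.07))
}

#' @rdname sim_config
#' @export
default_intent_probs <- function() {
  # cell-level intention probabilities patterned on the calibrated
  # post-stratum counts (share going to drive within each cell)
  expand <- expand.grid(sex = c("men", "women"), age_group = AGE_GROUPS,
                        geo_stratum = GEO_STRATA,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(expand$sex, expand$age_group, expand$geo_stratum)
  probs <- c(
    "men 18-29 high_concentration" = 0.4285,
    "men 30-44 high_concentration" = 0.5640,
    "men 45+ high_concentration" = 0.4732,
    "men 18-29 low_concentration" = 0.6900,
    "men 30-44 low_concentration" = 0.5904,
    "men 45+ low_concentration" = 0.6878,
    "women 18-29 high_concentration" = 0.3137,
    "women 30-44 high_concentration" = 0.4692,
    "women 45+ high_concentration" = 0.3987,
    "women 18-29 low_concentration" = 0.5299,
    "women 30-44 low_concentration" = 0.3229,
    "women 45+ low_concentration" = 0.0400)
  expand$prob <- unname(probs[key])
  expand
}

#' Generate a synthetic city frame
#'
#' Draws census enumeration areas in two outlet-density strata, assigns each
#' a number of alcohol outlets, and gives every outlet a weekly opening
#' schedule drawn from the configured templates.  Deterministic given the
#' seed.
#'
#' @param config a [sim_config()] list.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return list with data.frames \code{ceas} (\code{cea_id},
#'   \code{geo_stratum}, \code{n_outlets}), \code{outlets}
#'   (\code{outlet_id}, \code{cea_id}) and \code{schedules}
#'   (\code{outlet_id}, \code{weekday}, \code{open_h}, \code{close_h}).
#' @export
generate_city <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ceas <- do.call(rbind, lapply(names(config$n_cea), function(g) {
    n <- config$n_cea[[g]]
    data.frame(cea_id = sprintf("%s_cea%03d", substr(g, 1, 4), seq_len(n)),
               geo_stratum = g,
               n_outlets = config$outlet_min[[g]] +
                 stats::rpois(n, config$outlet_lambda[[g]]))
  }))
  outlets <- data.frame(
    cea_id = rep(ceas$cea_id, ceas$n_outlets),
    geo_stratum = rep(ceas$geo_stratum, ceas$n_outlets))
  outlets$outlet_id <- sprintf("ao%04d", seq_len(nrow(outlets)))

  tpl_idx <- sample.int(nrow(config$templates), nrow(outlets),
                        replace = TRUE, prob = config$templates$weight)
  sched <- lapply(seq_len(nrow(outlets)), function(i) {
    open_days <- which(stats::runif(7L) < config$p_open_day) - 1L
    if (length(open_days) == 0L) open_days <- sample.int(7L, 1L) - 1L
    data.frame(outlet_id = outlets$outlet_id[i], weekday = open_days,
               open_h = config$templates$open_h[tpl_idx[i]],
               close_h = config$templates$close_h[tpl_idx[i]])
  })
  list(ceas = ceas,
       outlets = outlets[, c("outlet_id", "cea_id", "geo_stratum")],
       schedules = do.call(rbind, sched))
}

intent_prob_lookup <- function(config, sex, age_group, geo_stratum) {
  ip <- config$intent_prob
  if (!is.data.frame(ip)) return(rep(ip, length(sex)))
  key <- paste(sex, age_group, geo_stratum)
  tkey <- paste(ip$sex, ip$age_group, ip$geo_stratum)
  p <- ip$prob[match(key, tkey)]
  if (anyNA(p)) stop("intent_prob table does not cover every cell")
  p
}

#' Generate time-ordered exit streams for a COS frame
#'
#' Exits at each outlet-shift combination follow a homogeneous Poisson
#' process over the shift at the configured per-hour rate of its ARTC
#' stratum.  Every exit carries the screening attributes (age, sex,
#' residence, prior-participation claim, driver and drank-on-premises
#' status) and, for drinking drivers, the latent intention to drive — for
#' every exit, screened or not, so ground truth is exact.
#'
#' @param cos_frame COS frame (see [build_cos_frame()]) with a
#'   \code{geo_stratum} column attached.
#' @param config a [sim_config()] list.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return data.frame of exits ordered within COS by \code{exit_time_h}
#'   (hours from shift start), with columns \code{cos_id}, \code{exit_id},
#'   \code{exit_time_h}, \code{sex}, \code{age}, \code{age_group},
#'   \code{age_ok}, \code{resident}, \code{not_prior}, \code{driver},
#'   \code{drank}, \code{intent}, \code{refuses}, \code{unable},
#'   \code{geo_stratum}.
#' @export
generate_exit_streams <- function(cos_frame, config = sim_config(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!"geo_stratum" %in% names(cos_frame)) {
    stop("'cos_frame' needs a geo_stratum column (join the CEA frame)")
  }
  rate <- config$exit_rate_per_h[as.character(cos_frame$arc_stratum)]
  if (anyNA(rate)) stop("exit_rate_per_h must cover every ARTC stratum")
  n_exit <- stats::rpois(nrow(cos_frame), rate * cos_frame$duration_h)
  total <- sum(n_exit)
  if (total == 0L) return(empty_exit_stream())

  idx <- rep(seq_len(nrow(cos_frame)), n_exit)
  x <- data.frame(cos_id = cos_frame$cos_id[idx],
                  geo_stratum = cos_frame$geo_stratum[idx],
                  exit_time_h = stats::runif(total) * cos_frame$duration_h[idx])
  ord <- order(idx, x$exit_time_h)
  x <- x[ord, , drop = FALSE]
  x$exit_id <- sprintf("ex%07d", seq_len(total))

  x$sex <- ifelse(stats::runif(total) < config$p_men, "men", "women")
  grp <- sample.int(3L, total, replace = TRUE,
                    prob = config$age_group_probs)
  lo <- c(18, 30, 45)[grp]
  hi <- c(30, 45, 75)[grp]
  x$age <- lo + stats::runif(total) * (hi - lo)
  x$age_group <- as.character(age_group_of(x$age))
  x$age_ok <- stats::runif(total) < config$p_age_ok
  x$resident <- stats::runif(total) < config$p_resident
  x$not_prior <- stats::runif(total) >= config$p_claims_prior
  x$driver <- stats::runif(total) < config$p_driver
  x$drank <- stats::runif(total) < config$p_drank
  p_int <- intent_prob_lookup(config, x$sex, x$age_group, x$geo_stratum)
  x$intent <- ifelse(x$driver & x$drank,
                     stats::runif(total) < p_int, NA)
  p_ref <- ifelse(x$driver & x$drank,
                  unname(config$refusal_prob[
                    ifelse(x$intent %in% TRUE, "going", "not_going")]),
                  config$p_refusal_noneligible)
  x$refuses <- stats::runif(total) < p_ref
  x$unable <- stats::runif(total) < config$p_unable
  rownames(x) <- NULL
  x
}

empty_exit_stream <- function() {
  data.frame(cos_id = character(), geo_stratum = character(),
             exit_time_h = numeric(), exit_id = character(),
             sex = character(), age = numeric(), age_group = character(),
             age_ok = logical(), resident = logical(),
             not_prior = logical(), driver = logical(), drank = logical(),
             intent = logical(), refuses = logical(), unable = logical())
}

#' Ground-truth summary of a generated population
#'
#' Exact tallies of the latent population of eligible drinking drivers (of
#' legal age, resident, not previously interviewed, drove in the last
#' 12 months, drank on the premises) over one or more exit streams: totals
#' and DUI-intention prevalence overall and by sex, age group and
#' geographic stratum.
#'
#' @param exits exit stream(s) from [generate_exit_streams()].
#' @return list with \code{total}, \code{prevalence_pct}, \code{by_domain}
#'   (data.frame: domain, total, prevalence_pct) and \code{by_cos}
#'   (data.frame: cos_id, n_eligible, n_going).
#' @export
truth_summary <- function(exits) {
  elig <- exits$age_ok & exits$resident & exits$not_prior &
    exits$driver & exits$drank
  e <- exits[elig, , drop = FALSE]
  dom_row <- function(name, idx) {
    n <- sum(idx)
    data.frame(domain = name, total = n,
               prevalence_pct = if (n > 0)
                 100 * mean(e$intent[idx]) else NA_real_)
  }
  doms <- rbind(
    dom_row("All", rep(TRUE, nrow(e))),
    dom_row("men", e$sex == "men"),
    dom_row("women", e$sex == "women"),
    do.call(rbind, lapply(AGE_GROUPS,
                          function(a) dom_row(a, e$age_group == a))),
    do.call(rbind, lapply(GEO_STRATA,
                          function(g) dom_row(g, e$geo_stratum == g))))
  rownames(doms) <- NULL
  by_cos <- if (nrow(e)) {
    m <- rowsum(cbind(n_eligible = rep(1L, nrow(e)),
                      n_going = as.integer(e$intent)), e$cos_id)
    data.frame(cos_id = rownames(m), n_eligible = m[, "n_eligible"],
               n_going = m[, "n_going"], row.names = NULL)
  } else data.frame(cos_id = character(), n_eligible = integer(),
                    n_going = integer())
  list(total = nrow(e),
       prevalence_pct = if (nrow(e)) 100 * mean(e$intent) else NA_real_,
       by_domain = doms, by_cos = by_cos)
}
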