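# Design-based domain estimation: weighted totals, DUI prevalence as a
# ratio estimator, and ultimate-cluster standard errors that account for
# post-stratification through calibration residuals.

#' Estimated population total over a domain
#'
#' Horvitz-Thompson / calibration estimator of a count: the sum of weights
#' over the records falling in the domain.
#'
#' @param weights numeric vector of (base or calibrated) weights, \code{>= 0}.
#' @param domain logical vector marking domain membership (default: all).
#' @return estimated total (0 for an empty domain).
#' @export
estimate_total <- function(weights, domain = NULL) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (is.null(domain)) domain <- rep(TRUE, length(weights))
  if (anyNA(domain)) stop("'domain' must not contain NA")
  sum(weights[domain])
}

#' Estimated prevalence (percentage) over a domain
#'
#' Ratio estimator \code{100 * sum(w * y) / sum(w)} of the prevalence of a
#' binary indicator within a domain.
#'
#' @param weights numeric vector of weights, \code{>= 0}.
#' @param y binary (logical or 0/1) indicator, e.g. intention to drive.
#' @param domain logical vector marking domain membership (default: all).
#' @return prevalence in percent.
#' @export
estimate_prevalence <- function(weights, y, domain = NULL) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (is.null(domain)) domain <- rep(TRUE, length(weights))
  y <- as.numeric(y)
  if (anyNA(y[domain]) || !all(y[domain] %in% c(0, 1))) {
    stop("'y' must be binary over the domain")
  }
  wd <- sum(weights[domain])
  if (wd <= 0) stop("domain has zero weight; prevalence undefined")
  100 * sum(weights[domain] * y[domain]) / wd
}

#' Ultimate-cluster standard error with calibration residuals
#'
#' Design-based standard error of a weighted total or of a domain prevalence
#' under the with-replacement (ultimate-cluster) approximation for the first
#' sampling stage.  The statistic is linearised to a per-record score
#' \code{z}; when calibration cells are supplied the score is replaced by
#' its calibration residual \code{z - zbar(cell)} (weighted cell mean), which
#' is how post-stratification enters the variance.  Scores are aggregated to
#' weighted PSU totals \code{t_hi} and the variance is the stratified
#' between-PSU sum \code{sum_h n_h/(n_h - 1) * sum_i (t_hi - tbar_h)^2}.
#'
#' Design strata containing a single PSU are treated as certainty selections
#' and contribute zero variance (reported via a warning).
#'
#' @param records data.frame of analysis records.
#' @param weight name of the weight column (calibrated weights for
#'   calibrated estimates).
#' @param psu name of the column holding primary-sampling-unit ids (CEA).
#' @param stratum name of the column holding first-stage design strata.
#' @param statistic \code{"total"} (of \code{y}, or of the weights when
#'   \code{y} is NULL) or \code{"prevalence"} (ratio, in percent).
#' @param y name of the indicator/variable column, or NULL for a total of
#'   the weights (an estimated count).
#' @param domain optional logical vector marking domain membership.
#' @param calibration_cells optional character vector naming the columns
#'   whose cross-classification defines the calibration cells; when given,
#'   residuals are taken within these cells.
#' @return standard error (scalar).
#' @export
se_ultimate_cluster <- function(records, weight, psu, stratum,
                                statistic = c("total", "prevalence"),
                                y = NULL, domain = NULL,
                                calibration_cells = NULL) {
  statistic <- match.arg(statistic)
  w <- records[[weight]]
  if (is.null(w)) stop("weight column '", weight, "' not found")
  if (is.null(domain)) domain <- rep(TRUE, nrow(records))
  d <- as.numeric(domain)
  yv <- if (is.null(y)) rep(1, nrow(records)) else as.numeric(records[[y]])

  if (statistic == "total") {
    z <- d * yv
  } else {
    wd <- sum(w * d)
    if (wd <= 0) stop("domain has zero weight")
    p <- sum(w * d * yv) / wd
    z <- 100 * d * (yv - p) / wd
  }

  if (!is.null(calibration_cells)) {
    cell <- do.call(paste, c(records[calibration_cells], sep = "|"))
    zbar <- tapply(w * z, cell, sum) / tapply(w, cell, sum)
    z <- z - unname(zbar[cell])
  }

  wt <- w * z
  psu_id <- paste(records[[stratum]], records[[psu]], sep = "|")
  t_hi <- tapply(wt, psu_id, sum)
  h_of <- sub("\\|.*$", "", names(t_hi))
  v <- 0
  lonely <- character(0)
  for (h in unique(records[[stratum]])) {
    t_h <- t_hi[h_of == as.character(h)]
    n_h <- length(t_h)
    if (n_h < 2L) {
      lonely <- c(lonely, as.character(h))
      next
    }
    v <- v + n_h / (n_h - 1) * sum((t_h - mean(t_h))^2)
  }
  if (length(lonely)) {
    warning("stratum with a single PSU treated as certainty (zero variance ",
            "contribution): ", paste(lonely, collapse = ", "))
  }
  sqrt(v)
}

#' Domain estimates of drinking-driver totals and DUI prevalence
#'
#' Produces the standard reporting table: for all drivers and for each sex
#' and age-group domain, the estimated number of drivers who drank at an
#' outlet (in thousands) and the prevalence of intention to drive, each with
#' an ultimate-cluster standard error.
#'
#' Point estimates use the calibrated driver weights.  The variance
#' treatment depends on where the post-stratum targets came from.  When the
#' targets are estimated from the survey's own screening phase (the usual
#' situation here), every statistic determined by the 24 cells — including
#' all the totals and prevalences in this table, since sex, age group and
#' intention are cell dimensions — coincides exactly with the corresponding
#' screening-weighted estimate, and its design variance is the variance of
#' that screening estimator; pass the screening drinking-driver records via
#' \code{screening} to obtain these standard errors.  Without
#' \code{screening} the targets are treated as fixed known totals and
#' standard errors use calibration residuals on the driver records, which
#' is appropriate for external calibration totals but collapses to zero for
#' cell-determined statistics.
#'
#' @param drivers data.frame of responding drivers with calibrated weights
#'   (\code{calibrated_weight}), cell labels (\code{geo_stratum},
#'   \code{sex}, \code{age_group}, \code{intent}) and design identifiers
#'   (\code{cea_id}).
#' @param screening optional data.frame of screened drinking drivers with
#'   \code{screen_weight}, logical \code{intent}, \code{sex},
#'   \code{age_group} and the design identifier columns.
#' @param weight,psu,stratum column names (defaults match the pipeline
#'   output).
#' @return data.frame with columns \code{domain}, \code{total_thousands},
#'   \code{total_se_thousands}, \code{prevalence_pct}, \code{prevalence_se}.
#' @export
estimate_dui_table <- function(drivers, screening = NULL,
                               weight = "calibrated_weight",
                               psu = "cea_id", stratum = "geo_stratum") {
  cells <- c("geo_stratum", "sex", "age_group", "intent")
  drivers$.dui <- as.numeric(drivers$intent == "going")
  se_src <- if (is.null(screening)) drivers else screening
  se_w <- if (is.null(screening)) weight else "screen_weight"
  se_cells <- if (is.null(screening)) cells else NULL
  se_src$.dui <- if (is.null(screening)) drivers$.dui
  else as.numeric(se_src$intent)

  dom_list <- function(x) {
    c(list(All = rep(TRUE, nrow(x))),
      lapply(stats::setNames(nm = c("men", "women")),
             function(s) x$sex == s),
      lapply(stats::setNames(nm = AGE_GROUPS),
             function(a) x$age_group == a))
  }
  domains <- dom_list(drivers)
  se_domains <- dom_list(se_src)
  rows <- lapply(names(domains), function(nm) {
    dom <- domains[[nm]]
    se_dom <- se_domains[[nm]]
    tot <- estimate_total(drivers[[weight]], dom)
    tot_se <- se_ultimate_cluster(se_src, se_w, psu, stratum,
                                  statistic = "total", domain = se_dom,
                                  calibration_cells = se_cells)
    prev <- estimate_prevalence(drivers[[weight]], drivers$.dui, dom)
    prev_se <- se_ultimate_cluster(se_src, se_w, psu, stratum,
                                   statistic = "prevalence", y = ".dui",
                                   domain = se_dom,
                                   calibration_cells = se_cells)
    data.frame(domain = nm, total_thousands = tot / 1000,
               total_se_thousands = tot_se / 1000,
               prevalence_pct = prev, prevalence_se = prev_se)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
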