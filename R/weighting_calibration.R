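# Horvitz-Thompson base weights for screening contacts and interviewed
# drivers, and post-stratification calibration of driver weights to 24
# cell totals (geo stratum x sex x age group x intention).

#' Horvitz-Thompson base weight of an interviewed driver
#'
#' The natural sampling weight is the inverse of the product of the stage
#' inclusion probabilities: the CEA probability \code{pi1}, the conditional
#' COS probability \code{pi2}, the fraction \code{f} of the shift covered by
#' the interviewing window, and the intention sampling rate (1 for drivers
#' going to drive, 1/4 for drivers not going to drive under the one-in-four
#' rule).  A screening contact's weight omits the intention rate, i.e. it is
#' \code{1 / (pi1 * pi2 * f)} (see [screening_weight()]).
#'
#' @param pi1,pi2 stage inclusion probabilities in (0, 1].
#' @param f interviewing-window fraction in (0, 1].
#' @param dui logical: intends to drive after drinking.
#' @return base weight \code{1/(pi1*pi2*f)} for DUI drivers,
#'   \code{4/(pi1*pi2*f)} for non-DUI drivers.
#' @examples
#' base_weight(0.5, 0.5, 1, dui = TRUE)    # 4
#' base_weight(0.5, 0.5, 1, dui = FALSE)   # 16
#' @export
base_weight <- function(pi1, pi2, f, dui) {
  w <- screening_weight(pi1, pi2, f)
  if (anyNA(dui)) stop("'dui' must be TRUE or FALSE")
  w * ifelse(dui, 1, 4)
}

#' @rdname base_weight
#' @export
screening_weight <- function(pi1, pi2, f) {
  bad <- function(x) !is.numeric(x) || anyNA(x) || any(x <= 0) || any(x > 1)
  if (bad(pi1) || bad(pi2)) stop("inclusion probabilities must lie in (0, 1]")
  if (!is.numeric(f) || anyNA(f) || any(f <= 0)) {
    stop("window fraction must be positive")
  }
  1 / (pi1 * pi2 * f)
}

#' Read a post-stratum target table
#'
#' @param path CSV with columns \code{geo_stratum}, \code{sex},
#'   \code{age_group}, \code{intent}, \code{target_total} — 24 rows covering
#'   the full cross-classification.
#' @return validated data.frame.
#' @export
read_poststrata <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("geo_stratum", "sex", "age_group", "intent",
                  "target_total") %in% names(x)))
  if (nrow(x) != 24L) stop("expected exactly 24 post-strata")
  if (any(x$target_total < 0)) stop("targets must be nonnegative")
  if (anyDuplicated(x[, c("geo_stratum", "sex", "age_group", "intent")])) {
    stop("duplicated post-stratum cell")
  }
  x
}

#' Build post-stratum targets from screening-based proportions
#'
#' Multiplies the screening-estimated proportion of drivers in each
#' post-stratum by the screening-estimated population total, so the targets
#' sum exactly to the total.
#'
#' @param proportions data.frame with the cell label columns
#'   (\code{geo_stratum}, \code{sex}, \code{age_group}, \code{intent}) and a
#'   \code{proportion} column summing to 1.
#' @param total estimated population total of eligible drinking drivers.
#' @param tol tolerance for the sum-to-one check.
#' @return data.frame of cells with \code{target_total}.
#' @export
poststratum_targets <- function(proportions, total, tol = 1e-8) {
  if (any(proportions$proportion < 0)) stop("proportions must be nonnegative")
  if (abs(sum(proportions$proportion) - 1) > tol) {
    stop("proportions must sum to 1")
  }
  out <- proportions
  out$target_total <- out$proportion * total
  out$proportion <- NULL
  out
}

#' Age group of a driver
#'
#' Closed-open groups [18, 30), [30, 45), [45, Inf), labelled
#' \code{"18-29"}, \code{"30-44"}, \code{"45+"}.
#'
#' @param age numeric vector of ages (>= 18).
#' @return factor of age-group labels.
#' @export
age_group_of <- function(age) {
  if (any(age < 18)) stop("survey population is aged 18 or more")
  cut(age, breaks = c(18, 30, 45, Inf), labels = AGE_GROUPS, right = FALSE)
}

poststratum_key <- function(x) {
  paste(x$geo_stratum, x$sex, x$age_group, x$intent, sep = "|")
}

# Collapse a positive-target cell with no respondents into the adjacent age
# cell of the same geo stratum, sex and intention (nearer age group
# preferred, younger first for the middle group).  Returns a vector mapping
# every original cell key to the key of the (possibly merged) group.
collapse_empty_cells <- function(targets, have_respondents) {
  key <- poststratum_key(targets)
  group <- stats::setNames(key, key)
  empty <- which(targets$target_total > 0 & !have_respondents)
  for (i in empty) {
    idx <- match(targets$age_group[i], AGE_GROUPS)
    for (j in c(idx - 1L, idx + 1L, idx - 2L, idx + 2L)) {
      if (j < 1L || j > length(AGE_GROUPS)) next
      cand <- which(targets$geo_stratum == targets$geo_stratum[i] &
                      targets$sex == targets$sex[i] &
                      targets$intent == targets$intent[i] &
                      targets$age_group == AGE_GROUPS[j])
      if (length(cand) == 1L && have_respondents[cand]) {
        group[key[i]] <- group[key[cand]]
        break
      }
    }
    if (group[key[i]] == key[i]) {
      stop("post-stratum ", key[i], " has a positive target, no respondents",
           " and no age-adjacent cell to collapse into")
    }
  }
  group
}

#' Post-stratification calibration of driver weights
#'
#' Rescales base weights so that, within each post-stratum cell, the
#' calibrated weights sum exactly to the cell target: the calibration factor
#' is \code{g = target / sum(base weights in cell)}.  Cells with a positive
#' target and no respondents are collapsed into the age-adjacent cell of the
#' same geo stratum, sex and intention (recorded in the \code{"collapsed"}
#' attribute); cells with respondents but a zero target get \code{g = 0}.
#'
#' @param drivers data.frame of responding drivers with a
#'   \code{base_weight} column and the cell label columns
#'   \code{geo_stratum}, \code{sex}, \code{age_group}, \code{intent}.
#' @param targets post-stratum table with \code{target_total} (see
#'   [read_poststrata()] / [poststratum_targets()]).
#' @return \code{drivers} with added columns \code{g_factor} and
#'   \code{calibrated_weight}; attributes \code{"g_table"} (per-cell
#'   factors) and \code{"collapsed"} (cells merged for lack of respondents,
#'   or NULL).
#' @examples
#' d <- data.frame(geo_stratum = "high_concentration", sex = "men",
#'                 age_group = "18-29", intent = "going",
#'                 base_weight = c(3, 7))
#' t <- data.frame(geo_stratum = "high_concentration", sex = "men",
#'                 age_group = "18-29", intent = "going", target_total = 20)
#' poststratify(d, t)$calibrated_weight   # 6 14
#' @export
poststratify <- function(drivers, targets) {
  if (!"base_weight" %in% names(drivers)) stop("'drivers' needs base_weight")
  if (any(drivers$base_weight <= 0)) stop("base weights must be positive")
  dkey <- poststratum_key(drivers)
  tkey <- poststratum_key(targets)
  if (!all(dkey %in% tkey)) {
    stop("driver cell(s) missing from the target table: ",
         paste(unique(dkey[!dkey %in% tkey]), collapse = ", "))
  }
  group <- collapse_empty_cells(targets, tkey %in% dkey)
  gt <- tapply(targets$target_total, group[tkey], sum)
  wsum <- tapply(drivers$base_weight, group[dkey], sum)
  g <- gt[names(gt)] / ifelse(is.na(wsum[names(gt)]), NA, wsum[names(gt)])
  # groups with target 0 and no respondents are vacuous; target 0 with
  # respondents gives g = 0
  g[is.na(g)] <- NA_real_
  drivers$g_factor <- as.numeric(g[group[dkey]])
  drivers$calibrated_weight <- drivers$g_factor * drivers$base_weight
  merged <- group[group != names(group)]
  attr(drivers, "g_table") <- data.frame(group = names(gt),
                                         target = as.numeric(gt),
                                         weight_sum = as.numeric(wsum[names(gt)]),
                                         g = as.numeric(g))
  attr(drivers, "collapsed") <- if (length(merged))
    data.frame(cell = names(merged), merged_into = unname(merged)) else NULL
  drivers
}
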