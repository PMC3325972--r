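# Third stage: field screening of clients exiting a selected outlet-shift
# combination.  All drinking drivers intending to drive are interviewed;
# drinking drivers not intending to drive are interviewed one-in-four with a
# random start; the session stops at a preset interview quota or at the end
# of the shift (inverse sampling).

SCREENING_OUTCOMES <- c("interviewed", "non_dui_skipped", "refused_driver",
                        "refused_noneligible", "unable",
                        "noneligible_nodrink_nodrive", "noneligible_other")

#' Draw the per-session field randomisers
#'
#' Each screening session gets (a) a random start between 1 and 4 for the
#' one-in-four selection of drivers not intending to drive, and (b) a
#' screening start time drawn uniformly between 0 and 60 minutes after the
#' shift opens, rounded to the nearest half hour (so the offset is 0, 30 or
#' 60 minutes with probabilities 1/4, 1/2, 1/4; the measure-zero midpoints
#' round half-up).
#'
#' @return list with \code{start_offset_min} (0, 30 or 60) and
#'   \code{nondui_random_start} (integer in 1..4).
#' @export
draw_session_randomizers <- function() {
  u <- stats::runif(1L, 0, 60)
  offset <- 30 * floor(u / 30 + 0.5)
  list(start_offset_min = offset,
       nondui_random_start = sample.int(4L, 1L))
}

#' Classify one screening contact
#'
#' Deterministic mapping from eligibility flags to the screening outcome
#' taxonomy, for contacts that do not reach the driver-selection step:
#' failing the age, residence or prior-participation filter is
#' \code{noneligible_other}; an eligible person who does not drive or did
#' not drink on the premises is \code{noneligible_nodrink_nodrive}.
#' Eligible drinking drivers are returned as \code{"eligible_drank_driver"}
#' and are resolved to interviewed / skipped / refused by [run_screening()].
#'
#' @param age_ok,resident,not_prior,driver,drank logical vectors (recycled
#'   to common length).
#' @return character vector of outcomes / \code{"eligible_drank_driver"}.
#' @export
classify_exit <- function(age_ok, resident, not_prior, driver, drank) {
  n <- max(length(age_ok), length(resident), length(not_prior),
           length(driver), length(drank))
  flags <- data.frame(age_ok = rep_len(age_ok, n),
                      resident = rep_len(resident, n),
                      not_prior = rep_len(not_prior, n),
                      driver = rep_len(driver, n),
                      drank = rep_len(drank, n))
  if (anyNA(flags)) stop("eligibility flags must be complete (no NA)")
  ifelse(!flags$age_ok | !flags$resident | !flags$not_prior,
         "noneligible_other",
         ifelse(!flags$driver | !flags$drank,
                "noneligible_nodrink_nodrive",
                "eligible_drank_driver"))
}

#' Run the inverse-sampling screening protocol at one COS
#'
#' Walks the time-ordered exit stream from the screening start time,
#' classifying every approached client.  Drinking drivers intending to drive
#' are all selected; drinking drivers not intending to drive are selected
#' when their within-session counter falls on \code{r, r + 4, r + 8, ...}
#' where \code{r} is the session's random start.  Selected drivers may
#' refuse (the \code{refuses} column); completed interviews count toward the
#' quota and the session stops when the quota is reached or the shift ends.
#'
#' The session's \code{window_fraction} is the interviewing window relative
#' to the shift duration: \code{(duration - offset/60) / duration} when the
#' session runs to the end of the shift, and \code{W / duration} when the
#' quota stops it after an elapsed window \code{W}.  Because a quota stop is
#' event-triggered, weighted screening counts that simply divide by the
#' elapsed window are biased (the waiting-time paradox: the stopping exit is
#' always an interview).  The returned records therefore carry a
#' \code{counts_for_screening} flag that is \code{FALSE} for the stopping
#' exit of a quota-limited session: dropping that exit and weighting the
#' remaining \code{K - 1} approaches by \code{duration / W} is the
#' inverse-sampling estimator in the tradition of Haldane's \code{(k-1)}
#' rule, and it is exactly unbiased for the total number of exits and for
#' every screening category under time-homogeneous exits.
#'
#' @param stream data.frame of exits ordered by \code{exit_time_h} (hours
#'   from the start of the shift) with logical columns \code{age_ok},
#'   \code{resident}, \code{not_prior}, \code{driver}, \code{drank},
#'   \code{intent} (NA unless a drinking driver), \code{refuses},
#'   \code{unable}.
#' @param duration_h shift duration in hours.
#' @param quota preset number of completed interviews (\code{Inf} to
#'   disable).
#' @param start_offset_min screening start offset (0, 30 or 60 minutes).
#' @param random_start integer in 1..4, first not-going-to-drive driver to
#'   interview.
#' @return list with \code{records} (the approached subset of \code{stream}
#'   plus \code{outcome}, \code{selected} and \code{counts_for_screening})
#'   and \code{session} (list: \code{stop_reason}, \code{window_fraction},
#'   \code{n_approached}, \code{n_interviewed}, \code{start_offset_min},
#'   \code{random_start}, \code{quota}).
#' @export
run_screening <- function(stream, duration_h, quota, start_offset_min,
                          random_start) {
  if (!random_start %in% 1:4) stop("'random_start' must be in 1..4")
  if (quota < 1) stop("'quota' must be at least 1")
  start_h <- start_offset_min / 60
  session <- list(start_offset_min = start_offset_min,
                  random_start = random_start, quota = quota)

  if (duration_h - start_h <= 0) {
    session$stop_reason <- "impossible"
    session$window_fraction <- NA_real_
    session$n_approached <- 0L
    session$n_interviewed <- 0L
    return(list(records = stream[0, , drop = FALSE], session = session))
  }

  stream <- stream[order(stream$exit_time_h), , drop = FALSE]
  stream <- stream[stream$exit_time_h >= start_h &
                     stream$exit_time_h <= duration_h, , drop = FALSE]
  n <- nrow(stream)
  outcome <- character(n)
  selected <- logical(n)
  nondui_counter <- 0L
  interviews <- 0L
  stop_reason <- NA_character_
  k_stop <- n

  base <- if (n) classify_exit(stream$age_ok, stream$resident,
                               stream$not_prior, stream$driver,
                               stream$drank) else character(0)
  s_unable <- stream$unable
  s_refuses <- stream$refuses
  s_intent <- stream$intent
  for (k in seq_len(n)) {
    if (s_unable[k]) {
      outcome[k] <- "unable"
    } else if (base[k] != "eligible_drank_driver") {
      outcome[k] <- if (isTRUE(s_refuses[k]))
        "refused_noneligible" else base[k]
    } else {
      if (is.na(s_intent[k])) {
        stop("intent must be known for every eligible drinking driver")
      }
      if (s_intent[k]) {
        sel <- TRUE
      } else {
        nondui_counter <- nondui_counter + 1L
        sel <- (nondui_counter - random_start) %% 4L == 0L &&
          nondui_counter >= random_start
      }
      if (!sel) {
        outcome[k] <- "non_dui_skipped"
      } else {
        selected[k] <- TRUE
        if (isTRUE(s_refuses[k])) {
          outcome[k] <- "refused_driver"
        } else {
          outcome[k] <- "interviewed"
          interviews <- interviews + 1L
          if (interviews >= quota) {
            stop_reason <- "quota_reached"
            k_stop <- k
            break
          }
        }
      }
    }
  }

  records <- stream[seq_len(k_stop), , drop = FALSE]
  records$outcome <- factor(outcome[seq_len(k_stop)],
                            levels = SCREENING_OUTCOMES)
  records$selected <- selected[seq_len(k_stop)]
  records$counts_for_screening <- rep(TRUE, k_stop)

  dur_window <- duration_h - start_h
  if (is.na(stop_reason)) {
    stop_reason <- if (interviews > 0L) "shift_ended_with_interviews"
    else "shift_ended_no_interviews"
    f <- dur_window / duration_h
  } else {
    w <- stream$exit_time_h[k_stop] - start_h
    f <- if (w > 0) w / duration_h else dur_window / duration_h
    records$counts_for_screening[k_stop] <- FALSE
  }
  session$stop_reason <- stop_reason
  session$window_fraction <- min(f, 1)
  session$n_approached <- k_stop
  session$n_interviewed <- interviews
  list(records = records, session = session)
}

#' Tally screening outcomes
#'
#' Summarises a set of screening records into the nested screening margins
#' (approached, resident and of age and not previously interviewed, driver,
#' drank on premises, going / not going to drive) broken down by outcome
#' category, so that the rows partition the approached total.
#'
#' @param records data.frame of screening records bearing the eligibility
#'   flags, \code{intent} and \code{outcome}.
#' @return data.frame with one row per outcome category plus a total row.
#' @export
screening_tally <- function(records) {
  in_scope <- records$age_ok & records$resident & records$not_prior
  eligible <- in_scope & records$driver & records$drank
  cols <- function(idx) {
    c(approached = sum(idx),
      in_scope = sum(idx & in_scope),
      driver = sum(idx & in_scope & records$driver),
      drank_driver = sum(idx & eligible),
      going = sum(idx & eligible & records$intent %in% TRUE),
      not_going = sum(idx & eligible & records$intent %in% FALSE))
  }
  rows <- t(vapply(SCREENING_OUTCOMES,
                   function(o) cols(records$outcome == o),
                   numeric(6L)))
  out <- as.data.frame(rows)
  out <- rbind(total = as.data.frame(t(cols(rep(TRUE, nrow(records))))), out)
  out$outcome <- rownames(out)
  rownames(out) <- NULL
  out[, c("outcome", "approached", "in_scope", "driver", "drank_driver",
          "going", "not_going")]
}
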