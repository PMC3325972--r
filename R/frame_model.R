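# City frame: census enumeration areas, outlets, opening schedules, and the
# derived frame of outlet-by-shift combinations (COS) used as secondary
# sampling units.

GEO_STRATA <- c("high_concentration", "low_concentration")
ARC_STRATA <- c("low", "intermediate", "high")
AGE_GROUPS <- c("18-29", "30-44", "45+")

# Generic shift grid: four 6-hour windows starting 03:00, 09:00, 15:00,
# 21:00; the last crosses midnight and is written as [21, 27) on the
# starting weekday.
GENERIC_SHIFT_STARTS <- c(3, 9, 15, 21)

#' Quartile cut-offs for crash-prevalence stratification
#'
#' Computes the first and third quartiles of a distribution of
#' alcohol-related traffic-crash (ARTC) prevalences, used as cut-off points
#' to stratify outlet-by-shift combinations into low, intermediate and high
#' crash-prevalence strata.
#'
#' Quartiles use linear interpolation between order statistics at positions
#' \code{1 + p(n - 1)} (the default "type 7" rule of [stats::quantile()]),
#' declared explicitly so stratification is deterministic.
#'
#' @param values numeric vector of prevalences (percentages), nonempty.
#' @return An object of class \code{quartile_cutoffs}: a list with elements
#'   \code{q1} and \code{q3} (\code{q1 <= q3}).
#' @examples
#' compute_quartile_cutoffs(c(1, 2, 3, 4))
#' @export
compute_quartile_cutoffs <- function(values) {
  if (length(values) == 0L || !is.numeric(values)) {
    stop("'values' must be a nonempty numeric vector")
  }
  if (anyNA(values)) stop("'values' must not contain NA")
  q <- stats::quantile(values, probs = c(0.25, 0.75), type = 7, names = FALSE)
  structure(list(q1 = q[1L], q3 = q[2L]), class = "quartile_cutoffs")
}

#' @export
print.quartile_cutoffs <- function(x, ...) {
  cat(sprintf("ARTC quartile cut-offs: Q1 = %g, Q3 = %g\n", x$q1, x$q3))
  invisible(x)
}

#' Classify a crash prevalence into an ARTC stratum
#'
#' Maps an ARTC prevalence to one of three strata: \code{low} (p <= Q1),
#' \code{intermediate} (Q1 < p <= Q3) or \code{high} (p > Q3).  Both
#' boundaries are inclusive on the lower side, so a prevalence exactly at Q1
#' is \code{low} and one exactly at Q3 is \code{intermediate}.
#'
#' @param p numeric vector of prevalences (percentages), all \code{>= 0}.
#' @param cutoffs a \code{quartile_cutoffs} object (or list with \code{q1},
#'   \code{q3}).
#' @return factor with levels \code{low}, \code{intermediate}, \code{high}.
#' @export
classify_arc_stratum <- function(p, cutoffs) {
  if (!is.numeric(p) || anyNA(p)) stop("'p' must be numeric without NA")
  if (any(p < 0)) stop("prevalence must be nonnegative")
  if (is.null(cutoffs$q1) || is.null(cutoffs$q3)) {
    stop("'cutoffs' must provide q1 and q3")
  }
  out <- ifelse(p <= cutoffs$q1, "low",
                ifelse(p <= cutoffs$q3, "intermediate", "high"))
  factor(out, levels = ARC_STRATA)
}

#' Size measure for PPS selection of outlet-shift combinations
#'
#' The squared shift duration in hours.  Squaring makes short shifts (which
#' rarely yield the preset number of interviews) much less likely to be
#' drawn than proportional-to-duration selection would.
#'
#' @param duration_h shift duration in hours, \code{> 0}.
#' @return \code{duration_h^2}.
#' @export
cos_size_measure <- function(duration_h) {
  if (!is.numeric(duration_h) || anyNA(duration_h) || any(duration_h <= 0)) {
    stop("'duration_h' must be positive")
  }
  duration_h^2
}

# Generic shift start (3, 9, 15 or 21) containing a time point on the
# [3, 27) axis; clock times before 03:00 are mapped into the previous
# evening's 21-03(+1) window of the same recorded weekday.
generic_shift_of <- function(hour) {
  h <- ifelse(hour < 3, hour + 24, hour)
  h <- ifelse(h >= 27, h - 24, h)
  GENERIC_SHIFT_STARTS[findInterval(h, GENERIC_SHIFT_STARTS)]
}

# Split one contiguous opening interval [start, end) of a single
# outlet-weekday at the generic shift boundaries and merge fragments shorter
# than 1 h into the chronologically adjacent fragment (preceding preferred).
# Returns a data.frame with start_h, end_h, duration_h and the per-generic-
# shift contribution needed for majority attribution, or NULL when the whole
# interval is a lone sub-hour fragment.
split_interval_to_shifts <- function(start_h, end_h) {
  a <- ifelse(start_h < 3, start_h + 24, start_h)
  b <- ifelse(end_h <= a, end_h + 24, end_h)
  if (start_h < 3) b <- end_h + 24  # both shifted together
  if (b <= a) stop("opening interval must have positive length")
  bounds <- c(GENERIC_SHIFT_STARTS, 27, 33)
  cuts <- sort(unique(c(a, b, bounds[bounds > a & bounds < b])))
  frag <- data.frame(start = cuts[-length(cuts)], end = cuts[-1L])
  frag$dur <- frag$end - frag$start
  frag$shift <- generic_shift_of(frag$start)

  # merge sub-hour fragments into a neighbour within the same interval
  repeat {
    short <- which(frag$dur < 1)
    if (length(short) == 0L) break
    if (nrow(frag) == 1L) return(NULL)  # lone sub-hour interval: dropped
    i <- short[1L]
    j <- if (i > 1L) i - 1L else i + 1L
    keep <- frag[j, ]
    merged_start <- min(frag$start[c(i, j)])
    merged_end <- max(frag$end[c(i, j)])
    # majority attribution of the merged piece, ties to the later shift
    contrib <- tapply(frag$dur[c(i, j)], frag$shift[c(i, j)], sum)
    best <- max(contrib)
    winners <- as.numeric(names(contrib)[contrib == best])
    keep$shift <- max(winners)
    keep$start <- merged_start
    keep$end <- merged_end
    keep$dur <- merged_end - merged_start
    frag <- frag[-c(i, j), , drop = FALSE]
    frag <- rbind(frag, keep)
    frag <- frag[order(frag$start), , drop = FALSE]
  }
  frag
}

#' Build the frame of outlet-by-shift combinations (COS)
#'
#' Intersects every outlet's weekday opening intervals with the generic
#' 6-hour shift grid (03-09, 09-15, 15-21, 21-03(+1)), merges fragments
#' shorter than one hour into the adjacent piece of the same opening
#' interval, and attaches the ARTC prevalence stratum of the generic shift
#' that contributes the majority of each resulting shift's span (ties broken
#' toward the later shift).  Midnight-crossing shifts belong to the starting
#' weekday.
#'
#' @param outlets data.frame with columns \code{outlet_id}, \code{cea_id}.
#' @param schedules data.frame with columns \code{outlet_id}, \code{weekday}
#'   (0 = Sunday .. 6 = Saturday), \code{open_h}, \code{close_h} (clock
#'   hours; \code{close_h} may exceed 24 for midnight-crossing intervals).
#' @param arc_table data.frame with columns \code{weekday},
#'   \code{shift_start} (3, 9, 15, 21) and \code{prevalence_pct} — the
#'   weekday-by-shift ARTC prevalence grid (28 cells).
#' @param cutoffs \code{quartile_cutoffs} used to stratify the shifts.
#' @return data.frame with one row per COS: \code{cos_id}, \code{outlet_id},
#'   \code{cea_id}, \code{weekday}, \code{start_h}, \code{end_h},
#'   \code{duration_h}, \code{generic_shift}, \code{arc_prevalence},
#'   \code{arc_stratum}, \code{size_measure}.
#' @export
build_cos_frame <- function(outlets, schedules, arc_table, cutoffs) {
  stopifnot(all(c("outlet_id", "cea_id") %in% names(outlets)),
            all(c("outlet_id", "weekday", "open_h", "close_h") %in%
                  names(schedules)))
  validate_schedules(schedules)
  if (nrow(schedules) == 0L) return(empty_cos_frame())

  pieces <- vector("list", nrow(schedules))
  for (k in seq_len(nrow(schedules))) {
    fr <- split_interval_to_shifts(schedules$open_h[k], schedules$close_h[k])
    if (is.null(fr)) next
    fr$outlet_id <- schedules$outlet_id[k]
    fr$weekday <- schedules$weekday[k]
    pieces[[k]] <- fr
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1L))]
  if (length(pieces) == 0L) return(empty_cos_frame())
  cos <- do.call(rbind, pieces)

  # back to clock hours on the starting weekday
  cos$start_h <- ifelse(cos$start >= 24, cos$start - 24, cos$start)
  cos$end_h <- ifelse(cos$start >= 24, cos$end - 24, cos$end)
  cos$duration_h <- cos$dur
  cos$generic_shift <- cos$shift

  key <- paste(cos$weekday, cos$generic_shift)
  akey <- paste(arc_table$weekday, arc_table$shift_start)
  idx <- match(key, akey)
  if (anyNA(idx)) stop("arc_table does not cover every weekday x shift cell")
  cos$arc_prevalence <- arc_table$prevalence_pct[idx]
  cos$arc_stratum <- classify_arc_stratum(cos$arc_prevalence, cutoffs)
  cos$size_measure <- cos_size_measure(cos$duration_h)
  cos$cea_id <- outlets$cea_id[match(cos$outlet_id, outlets$outlet_id)]
  if (anyNA(cos$cea_id)) stop("schedule refers to an outlet not in 'outlets'")

  cos <- cos[order(cos$outlet_id, cos$weekday, cos$start_h), ]
  cos$cos_id <- sprintf("cos_%05d", seq_len(nrow(cos)))
  rownames(cos) <- NULL
  cos[, c("cos_id", "outlet_id", "cea_id", "weekday", "start_h", "end_h",
          "duration_h", "generic_shift", "arc_prevalence", "arc_stratum",
          "size_measure")]
}

empty_cos_frame <- function() {
  data.frame(cos_id = character(), outlet_id = character(),
             cea_id = character(), weekday = integer(),
             start_h = numeric(), end_h = numeric(), duration_h = numeric(),
             generic_shift = numeric(), arc_prevalence = numeric(),
             arc_stratum = factor(character(), levels = ARC_STRATA),
             size_measure = numeric())
}

validate_schedules <- function(schedules) {
  with(schedules, {
    if (any(open_h < 0 | open_h >= 24)) stop("open_h must lie in [0, 24)")
    if (any(close_h <= open_h)) stop("close_h must exceed open_h")
    if (any(weekday < 0 | weekday > 6)) stop("weekday must be 0..6")
  })
  # intervals within an outlet-weekday must be disjoint
  sp <- split(schedules, paste(schedules$outlet_id, schedules$weekday))
  for (s in sp) {
    if (nrow(s) < 2L) next
    s <- s[order(s$open_h), ]
    if (any(s$close_h[-nrow(s)] > s$open_h[-1L])) {
      stop("overlapping opening intervals within an outlet-weekday")
    }
  }
  invisible(TRUE)
}

#' Read frame files
#'
#' Plain-CSV readers for the frame inputs: census enumeration areas
#' (\code{cea_id}, \code{geo_stratum}), outlets (\code{outlet_id},
#' \code{cea_id}), opening schedules (\code{outlet_id}, \code{weekday},
#' \code{open_h}, \code{close_h}) and the weekday-by-shift ARTC prevalence
#' grid (\code{weekday}, \code{shift_start}, \code{prevalence_pct}).
#'
#' @param path path to a CSV file with a header row.
#' @return data.frame with validated columns.
#' @name frame_readers
NULL

#' @rdname frame_readers
#' @export
read_cea_frame <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cea_id", "geo_stratum") %in% names(x)))
  if (!all(x$geo_stratum %in% GEO_STRATA)) {
    stop("geo_stratum must be one of: ", paste(GEO_STRATA, collapse = ", "))
  }
  x
}

#' @rdname frame_readers
#' @export
read_outlets <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("outlet_id", "cea_id") %in% names(x)))
  x
}

#' @rdname frame_readers
#' @export
read_schedules <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("outlet_id", "weekday", "open_h", "close_h") %in% names(x)))
  validate_schedules(x)
  x
}

#' @rdname frame_readers
#' @export
read_arc_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("weekday", "shift_start", "prevalence_pct") %in% names(x)))
  if (nrow(x) != 28L) stop("ARTC table must have exactly 28 weekday x shift cells")
  if (any(x$prevalence_pct < 0)) stop("prevalences must be nonnegative")
  x
}

#' Attach outlet counts to a CEA frame
#'
#' Derives the first-stage size measure (number of alcohol outlets per CEA)
#' from the outlet register; CEAs without outlets get a zero count and are
#' never selected.
#'
#' @param ceas data.frame with \code{cea_id}, \code{geo_stratum}.
#' @param outlets data.frame with \code{outlet_id}, \code{cea_id}.
#' @return \code{ceas} with an \code{n_outlets} column.
#' @export
add_outlet_counts <- function(ceas, outlets) {
  if (!all(outlets$cea_id %in% ceas$cea_id)) {
    stop("outlet register refers to CEA(s) missing from the frame")
  }
  tab <- table(factor(outlets$cea_id, levels = ceas$cea_id))
  ceas$n_outlets <- as.integer(tab[ceas$cea_id])
  ceas
}

#' Packaged fixture tables
#'
#' Accessors for the three tables shipped with the package: the
#' weekday-by-shift ARTC prevalence grid used to stratify shifts, the
#' per-stratum sample-size allocation (COS and drivers per selected CEA),
#' and the 24 post-stratum calibrated driver counts.
#'
#' @return data.frame (see [read_arc_table()], [read_allocation()],
#'   [read_poststrata()] for the schemas).
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
dui_arc_table <- function() {
  read_arc_table(system.file("extdata", "arc_table.csv",
                             package = "duisurvey", mustWork = TRUE))
}

#' @rdname fixtures
#' @export
dui_allocation <- function() {
  read_allocation(system.file("extdata", "allocation.csv",
                              package = "duisurvey", mustWork = TRUE))
}

#' @rdname fixtures
#' @export
dui_poststrata <- function() {
  read_poststrata(system.file("extdata", "poststrata.csv",
                              package = "duisurvey", mustWork = TRUE))
}
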