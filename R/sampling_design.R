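# First two sampling stages: PPS systematic selection of census enumeration
# areas (size = outlet count) and of outlet-shift combinations within
# CEA x crash-prevalence stratum (size = squared shift duration), plus the
# sample-size arithmetic.

#' Systematic PPS sample with exact first-order inclusion probabilities
#'
#' Draws a probability-proportional-to-size systematic sample from a freshly
#' randomised frame order.  Units whose size share would give
#' \code{n * size / sum(size) >= 1} are taken with certainty (\code{pi = 1})
#' and the procedure recurses on the remaining units with \code{n} reduced,
#' so the returned \code{pi} are the exact first-order inclusion
#' probabilities of the final pass.
#'
#' @param frame data.frame with columns \code{unit_id} and \code{size}
#'   (all sizes \code{> 0}).
#' @param n number of units to draw, \code{1 <= n <= nrow(frame)}.
#' @return data.frame of the \code{n} selected units with columns
#'   \code{unit_id}, \code{size}, \code{pi}.  Within the frame the
#'   probabilities sum to \code{n} exactly.
#' @examples
#' set.seed(1)
#' pps_systematic_sample(data.frame(unit_id = 1:4, size = c(4, 16, 36, 64)), 2)
#' @export
pps_systematic_sample <- function(frame, n) {
  if (!all(c("unit_id", "size") %in% names(frame))) {
    stop("'frame' needs columns unit_id and size")
  }
  size <- as.numeric(frame$size)
  if (anyNA(size) || any(size <= 0)) stop("all sizes must be positive")
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be at least 1")
  if (n > nrow(frame)) stop("'n' exceeds the number of frame units")

  id <- frame$unit_id
  sel_id <- vector(mode(id), 0L)
  sel_size <- numeric(0L)
  sel_pi <- numeric(0L)

  # peel off certainty units until none remain
  repeat {
    if (n == 0L || length(id) == 0L) {
      return(data.frame(unit_id = sel_id, size = sel_size, pi = sel_pi))
    }
    pi <- n * size / sum(size)
    certain <- pi >= 1
    if (!any(certain)) break
    sel_id <- c(sel_id, id[certain])
    sel_size <- c(sel_size, size[certain])
    sel_pi <- c(sel_pi, rep(1, sum(certain)))
    id <- id[!certain]
    size <- size[!certain]
    n <- n - sum(certain)
  }

  ord <- sample.int(length(id))
  id <- id[ord]
  size <- size[ord]
  step <- sum(size) / n
  points <- stats::runif(1L, 0, step) + step * (0L:(n - 1L))
  hit <- findInterval(points, cumsum(size)) + 1L
  pi <- n * size / sum(size)
  data.frame(unit_id = c(sel_id, id[hit]),
             size = c(sel_size, size[hit]),
             pi = c(sel_pi, pi[hit]))
}

#' Read a per-stratum allocation table
#'
#' @param path CSV with columns \code{geo_stratum}, \code{arc_stratum},
#'   \code{n_cos_per_cea}, \code{n_drivers_per_cos}.
#' @return validated data.frame (one row per geo x ARTC stratum cell).
#' @export
read_allocation <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("geo_stratum", "arc_stratum", "n_cos_per_cea",
                  "n_drivers_per_cos") %in% names(x)))
  if (any(x$n_cos_per_cea < 0) || any(x$n_drivers_per_cos < 0)) {
    stop("allocation counts must be nonnegative")
  }
  if (!all(x$geo_stratum %in% GEO_STRATA) ||
      !all(x$arc_stratum %in% ARC_STRATA)) {
    stop("unknown stratum label in allocation table")
  }
  x
}

#' Planned sample totals implied by an allocation table
#'
#' Multiplies the per-CEA allocation (number of COS, and drivers per COS, in
#' each geo x ARTC stratum cell) by the number of CEAs sampled per
#' geographic stratum.
#'
#' @param alloc allocation data.frame (see [read_allocation()]).
#' @param n_cea_by_geo named vector or list: CEAs sampled per geo stratum.
#' @return list with \code{total_cos}, \code{total_drivers} and
#'   \code{by_geo}, a data.frame with per-geo-stratum COS and driver counts.
#' @examples
#' allocate_totals(dui_allocation(),
#'                 c(high_concentration = 23, low_concentration = 25))
#' @export
allocate_totals <- function(alloc, n_cea_by_geo) {
  n_cea_by_geo <- unlist(n_cea_by_geo)
  if (is.null(names(n_cea_by_geo)) ||
      !all(names(n_cea_by_geo) %in% GEO_STRATA)) {
    stop("unknown geographic stratum key")
  }
  geos <- names(n_cea_by_geo)
  per_geo <- lapply(geos, function(g) {
    a <- alloc[alloc$geo_stratum == g, ]
    if (nrow(a) == 0L) stop("allocation table has no rows for stratum ", g)
    data.frame(geo_stratum = g,
               n_cea = unname(n_cea_by_geo[g]),
               n_cos = unname(n_cea_by_geo[g]) * sum(a$n_cos_per_cea),
               n_drivers = unname(n_cea_by_geo[g]) *
                 sum(a$n_cos_per_cea * a$n_drivers_per_cos))
  })
  by_geo <- do.call(rbind, per_geo)
  list(total_cos = sum(by_geo$n_cos),
       total_drivers = sum(by_geo$n_drivers),
       by_geo = by_geo)
}

#' Simple-random-sampling planning margin
#'
#' Maximum half-width of a 95\% (by default) confidence interval for a
#' proportion under simple random sampling — the planning calculation behind
#' the interview budget.
#'
#' @param n planned number of completed interviews.
#' @param p anticipated proportion (worst case 0.5).
#' @param conf confidence level.
#' @return margin of error on the proportion scale.
#' @examples
#' srs_margin(600)        # ~0.04
#' @export
srs_margin <- function(n, p = 0.5, conf = 0.95) {
  if (n <= 0) stop("'n' must be positive")
  stats::qnorm(1 - (1 - conf) / 2) * sqrt(p * (1 - p) / n)
}

#' Inflate a target sample size for anticipated losses
#'
#' @param n target number of completed interviews.
#' @param loss anticipated fraction of selected units lost (refusals,
#'   impossible collection, empty shifts).
#' @return sample size to select so that \code{n} completions are expected.
#' @examples
#' inflate_for_loss(600, 0.25)  # 800
#' @export
inflate_for_loss <- function(n, loss = 0.25) {
  if (loss < 0 || loss >= 1) stop("'loss' must lie in [0, 1)")
  n / (1 - loss)
}

#' Select census enumeration areas (first stage)
#'
#' Independent PPS systematic samples within each geographic stratum, with
#' size equal to the number of alcohol outlets in the CEA.  CEAs without
#' outlets have selection probability zero and are excluded from the frame.
#'
#' @param ceas data.frame with \code{cea_id}, \code{geo_stratum},
#'   \code{n_outlets}.
#' @param n_by_geo named vector: number of CEAs to draw per geo stratum.
#' @return data.frame of selected CEAs: \code{cea_id}, \code{geo_stratum},
#'   \code{n_outlets}, \code{pi1}.
#' @export
select_ceas <- function(ceas, n_by_geo) {
  n_by_geo <- unlist(n_by_geo)
  out <- lapply(names(n_by_geo), function(g) {
    fr <- ceas[ceas$geo_stratum == g & ceas$n_outlets > 0, ]
    n <- n_by_geo[[g]]
    if (nrow(fr) < n) {
      stop("stratum ", g, " has only ", nrow(fr),
           " CEAs with outlets; cannot draw ", n)
    }
    s <- pps_systematic_sample(
      data.frame(unit_id = fr$cea_id, size = fr$n_outlets), n)
    data.frame(cea_id = s$unit_id, geo_stratum = g,
               n_outlets = s$size, pi1 = s$pi)
  })
  do.call(rbind, out)
}

#' Select outlet-shift combinations within sampled CEAs (second stage)
#'
#' Within every selected CEA and ARTC prevalence stratum, draws the
#' allocated number of COS with probability proportional to squared shift
#' duration.  Cells holding fewer COS than allocated are taken entirely
#' (certainty selection); empty cells yield no draws and are reported as
#' shortfalls, mirroring field situations where selection was impossible.
#'
#' @param cos_frame COS frame (see [build_cos_frame()]) restricted by the
#'   caller or not; only rows whose \code{cea_id} appears in
#'   \code{selected_ceas} are used.
#' @param selected_ceas output of [select_ceas()].
#' @param alloc allocation data.frame (see [read_allocation()]).
#' @return data.frame of selected COS joined with \code{pi1}, \code{pi2} and
#'   the per-COS driver quota; attribute \code{"shortfall"} lists CEA x
#'   stratum cells that could not supply the allocated draws.
#' @export
select_cos <- function(cos_frame, selected_ceas, alloc) {
  sel <- list()
  shortfall <- list()
  for (i in seq_len(nrow(selected_ceas))) {
    cea <- selected_ceas$cea_id[i]
    geo <- selected_ceas$geo_stratum[i]
    frame_cea <- cos_frame[cos_frame$cea_id == cea, ]
    a <- alloc[alloc$geo_stratum == geo, ]
    for (j in seq_len(nrow(a))) {
      arc <- a$arc_stratum[j]
      n_want <- a$n_cos_per_cea[j]
      if (n_want == 0L) next
      cell <- frame_cea[frame_cea$arc_stratum == arc, ]
      if (nrow(cell) == 0L) {
        shortfall[[length(shortfall) + 1L]] <-
          data.frame(cea_id = cea, arc_stratum = arc,
                     allocated = n_want, available = 0L)
        next
      }
      n_draw <- min(n_want, nrow(cell))
      if (n_draw < n_want) {
        shortfall[[length(shortfall) + 1L]] <-
          data.frame(cea_id = cea, arc_stratum = arc,
                     allocated = n_want, available = nrow(cell))
      }
      s <- pps_systematic_sample(
        data.frame(unit_id = cell$cos_id, size = cell$size_measure), n_draw)
      picked <- cell[match(s$unit_id, cell$cos_id), ]
      picked$pi1 <- selected_ceas$pi1[i]
      picked$pi2 <- s$pi
      picked$geo_stratum <- geo
      picked$driver_quota <- a$n_drivers_per_cos[j]
      sel[[length(sel) + 1L]] <- picked
    }
  }
  out <- if (length(sel)) do.call(rbind, sel) else
    cbind(empty_cos_frame(),
          data.frame(pi1 = numeric(), pi2 = numeric(),
                     geo_stratum = character(), driver_quota = integer()))
  rownames(out) <- NULL
  attr(out, "shortfall") <- if (length(shortfall))
    do.call(rbind, shortfall) else NULL
  out
}
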