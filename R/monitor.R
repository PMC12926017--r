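## Per-animal longitudinal monitoring: aberrant-record filtering, smoothed
## trajectories, method comparison (device vs. manual BCS) and herd summary.
##
## Records are held in a plain data.frame with columns `animal_id`, `date`
## (Date or ISO-8601 string), `source` ("bcs3d", "bcsm" or "bw") and `value`
## (BCS points or kg). Filtering adds a `flag` column ("kept"/"removed").

.asRecords <- function(records) {
  need <- c("animal_id", "date", "source", "value")
  if (!all(need %in% names(records)))
    bcsStop("invalidArgument",
            paste("records need columns", paste(need, collapse = ", ")))
  records$date <- as.Date(records$date)
  records
}

#' Flag aberrant records in a longitudinal series
#'
#' A record is flagged `removed` iff its deviation exceeds the threshold
#' against BOTH its previous and its subsequent neighbour in date order
#' (an isolated spike): for BCS sources an absolute difference above
#' `bcsThresh` points, for body weight a relative change above `bwFrac`.
#' Endpoints are never removed; the single pass uses the original
#' neighbours, which makes the filter idempotent. Series with fewer than 3
#' records are returned unchanged with a warning.
#'
#' @param records records data.frame (see module header).
#' @param sources sources the rule applies to; the 0.5-point rule
#'   historically applied to manual scores and scale weights, so the default
#'   is `c("bcsm", "bw")`.
#' @param bcsThresh BCS spike threshold, points.
#' @param bwFrac body-weight spike threshold, relative.
#' @return the records with a `flag` column ("kept"/"removed").
#' @export
filterAberrant <- function(records, sources = c("bcsm", "bw"),
                           bcsThresh = 0.5, bwFrac = 0.20) {
  records <- .asRecords(records)
  if (is.null(records$flag)) records$flag <- "kept"
  for (id in unique(records$animal_id)) {
    for (src in intersect(sources, unique(records$source))) {
      sel <- which(records$animal_id == id & records$source == src &
                     records$flag == "kept")
      if (length(sel) < 3) {
        if (length(sel) > 0 && length(sel) < 3)
          warning(sprintf("animal %s source %s: only %d records, filter skipped",
                          id, src, length(sel)))
        next
      }
      sel <- sel[order(records$date[sel])]
      v <- records$value[sel]
      n <- length(v)
      mid <- 2:(n - 1)
      bad <- if (src == "bw") {
        abs(v[mid] / v[mid - 1] - 1) > bwFrac & abs(v[mid] / v[mid + 1] - 1) > bwFrac
      } else {
        abs(v[mid] - v[mid - 1]) > bcsThresh & abs(v[mid] - v[mid + 1]) > bcsThresh
      }
      records$flag[sel[mid][bad]] <- "removed"
    }
  }
  records
}

#' Compare device and manual BCS
#'
#' Pairs each manual score (`bcsm`) with the nearest device score (`bcs3d`)
#' of the same animal within `tolDays` days, then fits the through-origin
#' least-squares line `bcs3d = slope x bcsm`
#' (`slope = sum(bcsm * bcs3d) / sum(bcsm^2)`). The reported R^2 uses the
#' uncentered sum of squares, the convention forced by the no-intercept
#' model form.
#'
#' @param records records data.frame; removed flags are respected.
#' @param tolDays pairing tolerance, days.
#' @return list with `slope`, `r_squared`, `n`, and the matched `pairs`
#'   data.frame.
#' @export
compareMethods <- function(records, tolDays = 3) {
  records <- .asRecords(records)
  if (!is.null(records$flag)) records <- records[records$flag == "kept", ]
  pairs <- NULL
  for (id in unique(records$animal_id)) {
    m <- records[records$animal_id == id & records$source == "bcsm", ]
    d <- records[records$animal_id == id & records$source == "bcs3d", ]
    if (!nrow(m) || !nrow(d)) next
    for (i in seq_len(nrow(m))) {
      dd <- abs(as.numeric(d$date - m$date[i]))
      j <- which.min(dd)
      if (dd[j] <= tolDays)
        pairs <- rbind(pairs, data.frame(animal_id = id, date = m$date[i],
                                         bcsm = m$value[i], bcs3d = d$value[j]))
    }
  }
  if (is.null(pairs) || nrow(pairs) < 2)
    bcsStop("insufficientData", "fewer than 2 matched (bcsm, bcs3d) pairs")
  slope <- sum(pairs$bcsm * pairs$bcs3d) / sum(pairs$bcsm^2)
  ss_res <- sum((pairs$bcs3d - slope * pairs$bcsm)^2)
  ss_tot <- sum(pairs$bcs3d^2)  # uncentered: through-origin convention
  list(slope = slope, r_squared = 1 - ss_res / ss_tot, n = nrow(pairs),
       pairs = pairs)
}

#' Column means and sample SDs of a herd table
#'
#' Arithmetic mean and sample (n - 1 denominator) standard deviation for
#' every numeric column, excluding missing values per column with the used
#' count reported. No rounding is applied; presentation rounding (mm columns
#' to integers, BCS to 2 decimals) is the caller's concern.
#'
#' @param herd data.frame with one row per animal.
#' @return data.frame with columns `column`, `mean`, `sd`, `n`.
#' @export
summarizeHerd <- function(herd) {
  if (nrow(herd) < 2) bcsStop("invalidArgument", "need at least 2 rows")
  num <- names(herd)[vapply(herd, is.numeric, logical(1))]
  out <- lapply(num, function(cn) {
    x <- herd[[cn]]
    x <- x[!is.na(x)]
    data.frame(column = cn, mean = mean(x), sd = stats::sd(x), n = length(x))
  })
  do.call(rbind, out)
}

#' Change in a smoothed series between two dates
#'
#' Difference of LOESS-fitted values at the two dates (days are counted from
#' the animal's first kept record) and the per-day rate; body-weight rates
#' are reported in g/d.
#'
#' @param records records data.frame for one animal (or filtered to one via
#'   `animal_id`).
#' @param source one of `"bcs3d"`, `"bcsm"`, `"bw"`.
#' @param from,to dates (coerced with [as.Date()]); must lie within the span
#'   of kept records.
#' @param animal_id optional animal filter when `records` holds several.
#' @param span,degree LOESS parameters.
#' @return list with `change`, `rate_per_day`, `unit`, `fit_from`, `fit_to`.
#' @export
seriesChange <- function(records, source, from, to, animal_id = NULL,
                         span = 0.75, degree = 2L) {
  records <- .asRecords(records)
  if (!is.null(animal_id)) records <- records[records$animal_id == animal_id, ]
  if (!is.null(records$flag)) records <- records[records$flag == "kept", ]
  records <- records[records$source == source, ]
  records <- records[order(records$date), ]
  if (nrow(records) < degree + 2)
    bcsStop("insufficientData", "too few kept records for the smoother")
  from <- as.Date(from); to <- as.Date(to)
  if (from < min(records$date) || to > max(records$date) ||
      to < min(records$date) || from > max(records$date))
    bcsStop("invalidArgument", "dates outside the record range")
  t0 <- min(records$date)
  x <- as.numeric(records$date - t0)
  keep <- !duplicated(x)
  fit <- loessPredict(x[keep], records$value[keep],
                      as.numeric(c(from, to) - t0), span, degree)
  change <- fit[2] - fit[1]
  days <- as.numeric(to - from)
  rate <- if (days > 0) change / days else NA_real_
  if (source == "bw") {
    list(change = change, rate_per_day = rate * 1000, unit = "g/d",
         fit_from = fit[1], fit_to = fit[2])
  } else {
    list(change = change, rate_per_day = rate, unit = "BCS points/d",
         fit_from = fit[1], fit_to = fit[2])
  }
}
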