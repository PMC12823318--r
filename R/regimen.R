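#' Define a repeated inhaled dosing regimen
#'
#' Regimens are clock-time based: the same dose is inhaled at the given
#' hours of each day for `days` days. The permitted therapeutic maximum is
#' 200 micrograms in any 24-h period; the regimens studied for the minimum
#' reporting level are available from [standard_regimens()].
#'
#' @param dose_ug Dose per administration, micrograms of salmeterol base.
#' @param times_of_day Clock hours of administration within a day (0-24).
#' @param days Number of days (default 7, i.e. one week at steady state).
#' @param label Optional label; a readable default is built.
#' @return Object of class `dose_regimen`.
#' @examples
#' dose_regimen(100, c(8, 16)) # 100 ug twice daily for a week
#' @export
dose_regimen <- function(dose_ug, times_of_day, days = 7, label = NULL) {
  stopifnot(dose_ug > 0, days >= 1)
  if (any(times_of_day < 0 | times_of_day >= 24)) {
    stop("`times_of_day` must lie within a 24-h clock", call. = FALSE)
  }
  times_of_day <- sort(unique(times_of_day))
  if (is.null(label)) {
    label <- paste0(
      dose_ug, " ug at ", paste(times_of_day, collapse = "/"), " h"
    )
  }
  structure(
    list(
      dose_ug = dose_ug, times_of_day = times_of_day,
      days = days, label = label
    ),
    class = "dose_regimen"
  )
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(
    "<dose_regimen> ", x$label, ", ", x$days, " day(s), ",
    round(dose_to_nmol(x$dose_ug), 1), " nmol per dose\n",
    sep = ""
  )
  invisible(x)
}

#' Expand a regimen into absolute-time bolus dose events
#'
#' @param regimen A [dose_regimen()].
#' @return A [dose_events()] tibble (times in hours from the start of day
#'   1, amounts in nmol).
#' @export
regimen_events <- function(regimen) {
  stopifnot(inherits(regimen, "dose_regimen"))
  times <- sort(as.vector(outer(
    regimen$times_of_day, (seq_len(regimen$days) - 1) * 24, `+`
  )))
  dose_events(times, dose_to_nmol(regimen$dose_ug))
}

#' Regimens evaluated against the salmeterol minimum reporting level
#'
#' The three maximum permitted regimens (100 ug twice daily at 8/16 h or
#' 8/20 h, 200 ug once daily) and the two prohibited ones (200 ug twice
#' daily at 8/16 h or 8/20 h), each over one week.
#'
#' @return Named list of [dose_regimen()] objects with a `permitted`
#'   attribute on each element.
#' @export
standard_regimens <- function() {
  spec <- list(
    list(100, c(8, 16), TRUE),
    list(100, c(8, 20), TRUE),
    list(200, 8, TRUE),
    list(200, c(8, 16), FALSE),
    list(200, c(8, 20), FALSE)
  )
  out <- lapply(spec, function(s) {
    r <- dose_regimen(s[[1]], s[[2]], days = 7)
    attr(r, "permitted") <- s[[3]]
    r
  })
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

#' Bladder voiding schedule for a dosing regimen
#'
#' Voiding is assumed to occur every `interval` hours (from time 0) and
#' additionally immediately prior to each inhalation; the bladder empties
#' completely and instantaneously at each void.
#'
#' @param regimen A [dose_regimen()], a [dose_events()] tibble, or `NULL`
#'   for a pure grid.
#' @param interval Hours between scheduled voids (default 4).
#' @param horizon End of the schedule (h); must cover the regimen.
#' @return Sorted numeric vector of void times, deduplicated to 1e-9 h.
#' @examples
#' void_schedule(dose_regimen(100, c(8, 16), days = 1), horizon = 24)
#' @export
void_schedule <- function(regimen = NULL, interval = 4, horizon) {
  dose_times <- numeric(0)
  if (inherits(regimen, "dose_regimen")) {
    dose_times <- regimen_events(regimen)$time
  } else if (is.data.frame(regimen)) {
    dose_times <- regimen$time
  }
  if (length(dose_times) && max(dose_times) > horizon) {
    stop("`horizon` must cover the dosing regimen", call. = FALSE)
  }
  times <- sort(c(seq(0, horizon, by = interval), dose_times))
  times[!duplicated(round(times / 1e-9))]
}
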