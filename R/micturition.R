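#' Urine sample concentrations from cumulative excreted amounts
#'
#' A urine sample collected at `t_end` after a complete void at `t_start`
#' contains the amounts excreted over the interval,
#' `delta_a4 = a4(t_end) - a4(t_start)` for salmeterol and likewise
#' `delta_a5` for the metabolite. The sample volume is the recorded
#' collection volume when available, otherwise the constant urine
#' production `ur_prod * (t_end - t_start)`.
#'
#' A zero-length interval represents a sample taken directly after a
#' pre-dose void followed by inhalation: concentrations are then the
#' analytic limits `k14 * a1(t+)/ur_prod` and `k35 * a3(t+)/ur_prod`
#' (excretion rate over urine production rate), which is what a
#' continuously-plotted "urine PK profile" converges to immediately after
#' voiding.
#'
#' @param p A [structural_params()] object.
#' @param doses A [dose_events()] tibble.
#' @param t_start,t_end Interval bounds (h), vectors of equal length;
#'   `t_start` should be void times, `t_end >= t_start`.
#' @param recorded_volume Optional recorded collection volumes (L); `NA`
#'   elements fall back to the constant-production volume.
#' @return Tibble with `t_start`, `t_end`, `volume_l`, excreted amounts
#'   `delta_a4`/`delta_a5` (nmol), and concentrations `conc_salm`,
#'   `conc_metab` (ng/mL).
#' @examples
#' p <- default_population_model()$typicals
#' urine_samples(p, dose_events(0, dose_to_nmol(100)),
#'   t_start = c(0, 0, 4), t_end = c(0, 4, 8)
#' )
#' @export
urine_samples <- function(p, doses, t_start, t_end, recorded_volume = NULL) {
  validate_structural_params(p)
  stopifnot(length(t_start) == length(t_end))
  if (any(t_end < t_start)) stop("`t_end` must be >= `t_start`", call. = FALSE)
  if (!is.null(recorded_volume) && any(recorded_volume <= 0, na.rm = TRUE)) {
    stop("recorded volumes must be > 0", call. = FALSE)
  }
  times <- sort(unique(c(t_start, t_end)))
  st <- pk_state(p, doses, times)
  i0 <- match(t_start, times)
  i1 <- match(t_end, times)
  da4 <- st$a4[i1] - st$a4[i0]
  da5 <- st$a5[i1] - st$a5[i0]
  dt <- t_end - t_start
  vol <- p$ur_prod * dt
  if (!is.null(recorded_volume)) {
    vol <- ifelse(is.na(recorded_volume), vol, recorded_volume)
  }
  cs <- cm <- numeric(length(dt))
  pos <- vol > 0
  cs[pos] <- da4[pos] / vol[pos]
  cm[pos] <- da5[pos] / vol[pos]
  if (any(!pos)) {
    # instantaneous limit right after a void (and dose) at t_start
    lim <- which(!pos)
    cs[lim] <- p$k14 * st$a1[i1[lim]] / p$ur_prod
    cm[lim] <- p$k35 * st$a3[i1[lim]] / p$ur_prod
  }
  tibble::tibble(
    t_start = t_start, t_end = t_end, volume_l = vol,
    delta_a4 = da4, delta_a5 = da5,
    conc_salm = conc_to_ng_per_ml(cs, "salmeterol"),
    conc_metab = conc_to_ng_per_ml(cm, "alpha-hydroxysalmeterol")
  )
}
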