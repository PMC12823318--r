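#' Monte Carlo simulation of urine concentrations under a dosing regimen
#'
#' Simulates `n` virtual individuals drawn from the population model under
#' a one-week (by default) inhaled regimen with bladder voiding every 4 h
#' and prior to each inhalation, and returns urine concentrations of
#' salmeterol and alpha-hydroxysalmeterol on the USG-standardized ng/mL
#' scale. Two reporting points hang off the last dose (for twice-daily
#' regimens, the second dose of the final day): `"direct"`, the
#' instantaneous concentration right after the pre-dose void and
#' inhalation, and `"post30"`, the sample accumulated from the pre-dose
#' void to 30 minutes post-dose. With `output = "profile"`, the
#' concentration at the end of every voiding interval across the full
#' regimen is returned as well.
#'
#' Residual variability defaults to the log-normal (`"exponential"`) form
#' so that prediction intervals stay symmetric on the log scale (see
#' [apply_ruv()]); the urine residual-error group defaults to `"mid"`.
#' No urine-production IIV is drawn because outputs are USG-standardized.
#'
#' @param pop A [population_model()].
#' @param ruv A [ruv_spec()]; only used when `include_ruv = TRUE`.
#' @param regimen A [dose_regimen()].
#' @param subject_type `"athlete"`, `"healthy"`, or `"asthmatic"`.
#' @param n Number of virtual individuals (>= 1); 10,000 for stable
#'   extreme percentiles.
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @param include_iiv,include_ruv Switch the two variability levels.
#' @param ruv_form Passed to [apply_ruv()].
#' @param urine_ruv_group Residual-error magnitude group used for
#'   simulated urine samples.
#' @param output `"last_dose"` (default) or `"profile"`.
#' @return A tibble of class `salm_sim`: `id`, `regimen`, `subject_type`,
#'   `compound`, `sample`, `t_start`, `time`, `conc_true` and `conc`
#'   (ng/mL, USG-standardized).
#' @examples
#' pop <- default_population_model()
#' sim <- simulate_population(pop, default_ruv_spec(),
#'   dose_regimen(100, c(8, 16)), "athlete",
#'   n = 200, seed = 1
#' )
#' percentile_table(sim)
#' @export
simulate_population <- function(pop, ruv, regimen, subject_type, n,
                                seed = NULL,
                                include_iiv = TRUE, include_ruv = TRUE,
                                ruv_form = c("exponential", "proportional"),
                                urine_ruv_group = "mid",
                                output = c("last_dose", "profile")) {
  output <- match.arg(output)
  ruv_form <- match.arg(ruv_form)
  stopifnot(inherits(pop, "population_model"), inherits(regimen, "dose_regimen"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!include_iiv) {
    pop$omega[] <- 0
    pop$omega_cv[] <- 0
  }
  pars <- sample_individuals(pop, n, subject_type, usg_corrected = TRUE)
  events <- regimen_events(regimen)
  t_last <- max(events$time)
  horizon <- regimen$days * 24
  voids <- void_schedule(regimen, interval = 4, horizon = horizon)

  times <- c(t_last, t_last + 0.5)
  if (output == "profile") times <- sort(unique(c(voids, times)))
  pl <- lapply(pars[.param_names], as.numeric)
  am <- .amounts(pl, events$time, events$amount_nmol, times, lean = TRUE)

  i_last <- match(t_last, times)
  i_30 <- match(t_last + 0.5, times)
  rows <- list(
    tibble::tibble(
      id = pars$id, sample = "direct", t_start = t_last, time = t_last,
      compound = "salmeterol",
      conc = pl$k14 * am$a1[, i_last] / pl$ur_prod
    ),
    tibble::tibble(
      id = pars$id, sample = "direct", t_start = t_last, time = t_last,
      compound = "alpha-hydroxysalmeterol",
      conc = pl$k35 * am$a3[, i_last] / pl$ur_prod
    ),
    tibble::tibble(
      id = pars$id, sample = "post30", t_start = t_last, time = t_last + 0.5,
      compound = "salmeterol",
      conc = (am$a4[, i_30] - am$a4[, i_last]) / (pl$ur_prod * 0.5)
    ),
    tibble::tibble(
      id = pars$id, sample = "post30", t_start = t_last, time = t_last + 0.5,
      compound = "alpha-hydroxysalmeterol",
      conc = (am$a5[, i_30] - am$a5[, i_last]) / (pl$ur_prod * 0.5)
    )
  )
  if (output == "profile") {
    iv <- match(voids, times)
    for (j in seq_len(length(voids) - 1L)) {
      i0 <- iv[j]
      i1 <- iv[j + 1L]
      dt <- voids[j + 1L] - voids[j]
      if (dt <= 0) next
      rows <- c(rows, list(
        tibble::tibble(
          id = pars$id, sample = "interval",
          t_start = voids[j], time = voids[j + 1L],
          compound = "salmeterol",
          conc = (am$a4[, i1] - am$a4[, i0]) / (pl$ur_prod * dt)
        ),
        tibble::tibble(
          id = pars$id, sample = "interval",
          t_start = voids[j], time = voids[j + 1L],
          compound = "alpha-hydroxysalmeterol",
          conc = (am$a5[, i1] - am$a5[, i0]) / (pl$ur_prod * dt)
        )
      ))
    }
  }
  sim <- dplyr::bind_rows(rows)
  # nmol/L -> USG-standardized ng/mL
  sim$conc <- ifelse(
    sim$compound == "salmeterol",
    conc_to_ng_per_ml(sim$conc, "salmeterol"),
    conc_to_ng_per_ml(sim$conc, "alpha-hydroxysalmeterol")
  )
  sim$conc_true <- sim$conc
  if (include_ruv) {
    df <- tibble::tibble(
      conc = sim$conc_true,
      matrix = "urine",
      compound = sim$compound,
      ruv_group = urine_ruv_group,
      pair_id = paste(sim$id, sim$sample, sim$time),
      correlated = TRUE
    )
    sim$conc <- apply_ruv(df, ruv, form = ruv_form)$obs
  }
  out <- dplyr::bind_cols(
    tibble::tibble(
      regimen = regimen$label,
      subject_type = subject_type
    )[rep(1, nrow(sim)), ],
    sim[, c("id", "compound", "sample", "t_start", "time", "conc_true", "conc")]
  )
  class(out) <- c("salm_sim", class(out))
  attr(out, "n_individuals") <- n
  attr(out, "seed") <- seed
  out
}

#' Empirical percentiles of simulated urine concentrations
#'
#' The estimator is the inclusive linear-interpolation empirical quantile
#' (`stats::quantile()` type 7); at n = 10,000 the 99.9th percentile
#' interpolates between the 9990th and 9991st order statistics. The extreme
#' tail is inherently imprecise and sensitive to distributional
#' assumptions; treat the 99.9th percentile as an order of magnitude.
#'
#' @param sim A [simulate_population()] result (or any tibble with
#'   `regimen`, `subject_type`, `compound`, `sample`, `conc`).
#' @param levels Percentile levels, in percent.
#' @param samples Which sampling points to tabulate.
#' @return Tibble with one row per (regimen, subject type, compound,
#'   sampling point) and one `p<level>` column per level (ng/mL), plus `n`.
#' @export
percentile_table <- function(sim, levels = c(2.5, 50, 97.5, 99, 99.9),
                             samples = c("direct", "post30")) {
  stopifnot(nrow(sim) > 0, all(levels > 0 & levels < 100))
  sim <- dplyr::filter(sim, .data$sample %in% samples)
  if (!nrow(sim)) stop("no rows at the requested sampling points", call. = FALSE)
  out <- sim |>
    dplyr::group_by(
      .data$regimen, .data$subject_type, .data$compound, .data$sample
    ) |>
    dplyr::reframe(
      level = levels,
      value = stats::quantile(.data$conc, levels / 100, type = 7, names = FALSE),
      n = dplyr::n()
    ) |>
    tidyr::pivot_wider(
      names_from = "level", values_from = "value", names_prefix = "p"
    )
  out
}

#' Probability of exceeding the urinary minimum reporting level
#'
#' Fraction of virtual individuals whose urine salmeterol concentration
#' exceeds the MRL at the requested sampling point.
#'
#' @param sim A [simulate_population()] result.
#' @param mrl Threshold, ng/mL (default [salm_mrl], 10 ng/mL).
#' @param sample_time `"post30"` (the practical doping-control condition,
#'   default), `"direct"`, or `"interval"`.
#' @param compound Compound to test against the threshold.
#' @return Tibble with `regimen`, `subject_type`, `sample`, `mrl`,
#'   `exceedance` (fraction in \[0, 1\]) and `n`.
#' @export
mrl_exceedance <- function(sim, mrl = salm_mrl, sample_time = "post30",
                           compound = "salmeterol") {
  stopifnot(mrl >= 0)
  sub <- dplyr::filter(
    sim, .data$sample == sample_time, .data$compound == !!compound
  )
  if (!nrow(sub)) stop("requested sampling time not present in `sim`", call. = FALSE)
  sub |>
    dplyr::group_by(.data$regimen, .data$subject_type, .data$sample) |>
    dplyr::summarise(
      mrl = mrl,
      exceedance = mean(.data$conc > mrl),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Percentile-ribbon plot of a simulated urine concentration profile
#'
#' Median with 50% and 95% prediction ribbons over time, faceted by
#' compound, for `output = "profile"` simulations. The dashed line marks
#' the salmeterol minimum reporting level.
#'
#' @param object A `salm_sim` tibble from
#'   [simulate_population()]`(..., output = "profile")`.
#' @param mrl Reference line (ng/mL); `NULL` suppresses it.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.salm_sim <- function(object, mrl = salm_mrl, ...) {
  prof <- dplyr::filter(object, .data$sample == "interval")
  if (!nrow(prof)) {
    stop('ribbon plots need `output = "profile"` simulations', call. = FALSE)
  }
  bands <- prof |>
    dplyr::group_by(.data$regimen, .data$compound, .data$time) |>
    dplyr::summarise(
      p2.5 = stats::quantile(.data$conc, 0.025, type = 7),
      p25 = stats::quantile(.data$conc, 0.25, type = 7),
      p50 = stats::quantile(.data$conc, 0.50, type = 7),
      p75 = stats::quantile(.data$conc, 0.75, type = 7),
      p97.5 = stats::quantile(.data$conc, 0.975, type = 7),
      .groups = "drop"
    )
  gg <- ggplot2::ggplot(bands, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$p2.5, ymax = .data$p97.5),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$p25, ymax = .data$p75),
      fill = "steelblue", alpha = 0.5
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p50), linewidth = 0.7) +
    ggplot2::facet_grid(
      ggplot2::vars(.data$compound),
      ggplot2::vars(.data$regimen),
      scales = "free_y"
    ) +
    ggplot2::labs(
      x = "Time (h)", y = "Urine concentration (ng/mL, USG-standardized)"
    ) +
    ggplot2::theme_bw()
  if (!is.null(mrl)) {
    gg <- gg + ggplot2::geom_hline(yintercept = mrl, linetype = "dashed")
  }
  gg
}
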