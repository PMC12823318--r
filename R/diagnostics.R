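# ---------------------------------------------------------------------------
# Model evaluation: nonparametric bootstrap and visual predictive check.
# ---------------------------------------------------------------------------

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement (stratified by study so every
#' replicate keeps the pooled design structure), refits the free
#' parameters on each replicate, and summarizes medians and percentile
#' confidence intervals. Non-converging replicates are dropped and
#' counted. Published analyses of this kind use thousands of replicates;
#' choose `n_reps` to match the available budget.
#'
#' @param records Pooled event-record dataset.
#' @param pop,ruv Initial model (typically the point estimates).
#' @param free Free parameters, as in [fit_population()].
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param bql,error_model,settings Passed to [fit_population()].
#' @param stratify Stratify resampling by the `STUDY` column (default
#'   `TRUE`).
#' @return Object of class `pk_boot`: `replicates` (per-rep estimates),
#'   `summary` (median and 2.5/97.5 percentiles per parameter),
#'   `n_failed`.
#' @export
pk_bootstrap <- function(records, pop, ruv, free, n_reps, seed = 1,
                         bql = "m1", error_model = "proportional",
                         settings = list(), stratify = TRUE) {
  if (n_reps < 1) {
    return(structure(
      list(replicates = tibble::tibble(), summary = tibble::tibble(), n_failed = 0L),
      class = "pk_boot"
    ))
  }
  records <- validate_pk_dataset(records)
  set.seed(seed)
  ids <- unique(records$ID)
  strata <- if (stratify && "STUDY" %in% names(records)) {
    tapply(records$STUDY, records$ID, `[`, 1)[as.character(ids)]
  } else {
    rep("all", length(ids))
  }
  reps <- list()
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    take <- unlist(lapply(split(ids, strata), function(s) {
      sample(s, length(s), replace = TRUE)
    }), use.names = FALSE)
    # resampled subjects get fresh IDs so duplicates stay distinct
    boot <- dplyr::bind_rows(lapply(seq_along(take), function(k) {
      sub <- records[records$ID == take[k], ]
      sub$ID <- k
      sub
    }))
    fit <- tryCatch(
      fit_population(boot, pop, ruv, free,
        bql = bql, error_model = error_model, settings = settings
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || fit$convergence != 0) {
      n_failed <- n_failed + 1L
      next
    }
    reps[[length(reps) + 1L]] <- tibble::tibble(
      rep = r, term = free, estimate = unname(fit$estimates)
    )
  }
  replicates <- dplyr::bind_rows(reps)
  summary <- if (nrow(replicates)) {
    replicates |>
      dplyr::group_by(.data$term) |>
      dplyr::summarise(
        median = stats::median(.data$estimate),
        ci_lo = stats::quantile(.data$estimate, 0.025, type = 7, names = FALSE),
        ci_hi = stats::quantile(.data$estimate, 0.975, type = 7, names = FALSE),
        n = dplyr::n(),
        .groups = "drop"
      )
  } else {
    tibble::tibble()
  }
  structure(
    list(replicates = replicates, summary = summary, n_failed = n_failed),
    class = "pk_boot"
  )
}

#' @export
print.pk_boot <- function(x, ...) {
  cat("<pk_boot> ", length(unique(x$replicates$rep)), " converged replicates, ",
    x$n_failed, " failed\n",
    sep = ""
  )
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}

# simulate replacement DVs for every observation row of a dataset, drawing
# new etas per subject and fresh residual error (the simulation step of the
# VPC); returns the records with DV replaced, on the standardized scale
.simulate_dataset <- function(records, pop, ruv, ruv_form = "proportional") {
  out <- records
  obs_idx <- which(records$EVID == 0L)
  for (sub in split(seq_len(nrow(records)), records$ID)) {
    rec <- records[sub, ]
    prep <- .prepare_subject(rec, ruv, bql = "none")
    typ <- .subject_typicals(pop, prep$group)
    eta_nm <- .subject_eta_names(prep, pop)
    pars <- typ
    for (nm in eta_nm) {
      pars[[nm]] <- pars[[nm]] * exp(stats::rnorm(1, 0, pop$omega[[nm]]))
    }
    pred <- .subject_pred(prep, pars)
    oi <- sub[rec$EVID == 0L & !is.na(rec$DV)]
    df <- tibble::tibble(
      conc = pmax(pred, 0),
      matrix = records$matrix[oi],
      compound = records$compound[oi],
      ruv_group = records$RUVGRP[oi],
      pair_id = paste(records$matrix[oi], records$TIME[oi]),
      correlated = records$CORR[oi] == 1L
    )
    dv_nmol <- apply_ruv(df, ruv, form = ruv_form)$obs
    out$DV[oi] <- ifelse(
      records$compound[oi] == "salmeterol",
      conc_to_ng_per_ml(dv_nmol, "salmeterol"),
      conc_to_ng_per_ml(dv_nmol, "alpha-hydroxysalmeterol")
    )
  }
  out
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets from the population model at the
#' observed design (same subjects, doses, sampling scheme, error groups),
#' bins observations by time after the most recent dose, and compares the
#' observed 5th/50th/95th percentiles per bin with the distribution of the
#' same statistics across simulations. This is a plain (not
#' prediction-corrected) VPC.
#'
#' @param records Pooled event-record dataset.
#' @param pop,ruv The model to check.
#' @param n_sim Number of simulated replicates (>= 1).
#' @param bins Either the number of time-after-dose bins (quantile-spaced)
#'   or an explicit vector of bin edges.
#' @param seed Integer seed.
#' @param ruv_form Residual form used in the simulation step, see
#'   [apply_ruv()].
#' @return Object of class `pk_vpc` with `table` (per matrix/compound/bin:
#'   observed percentiles and simulation bands), `n_sim`, and the bin
#'   edges; empty bins are dropped with a warning. Use [autoplot.pk_vpc()].
#' @export
pk_vpc <- function(records, pop, ruv, n_sim = 200, bins = 6, seed = 1,
                   ruv_form = "proportional") {
  stopifnot(n_sim >= 1)
  records <- validate_pk_dataset(records)
  set.seed(seed)
  obs <- records[records$EVID == 0L & !is.na(records$DV), ]
  if (!nrow(obs)) stop("no observations in `records`", call. = FALSE)
  # time after most recent dose, per subject
  dose_times <- split(records$TIME[records$EVID == 1L], records$ID[records$EVID == 1L])
  tad <- vapply(seq_len(nrow(obs)), function(i) {
    dt <- dose_times[[as.character(obs$ID[i])]]
    dt <- dt[dt <= obs$TIME[i]]
    if (!length(dt)) obs$TIME[i] else obs$TIME[i] - max(dt)
  }, numeric(1))
  if (length(bins) == 1L) {
    edges <- unique(stats::quantile(tad, seq(0, 1, length.out = bins + 1), type = 7))
  } else {
    edges <- sort(unique(bins))
  }
  bin <- cut(tad, edges, include.lowest = TRUE)
  strat <- paste(obs$matrix, obs$compound)

  pctl <- function(dv) {
    stats::quantile(dv, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  }
  cells <- tibble::tibble(strat = strat, bin = bin, dv = obs$DV, tad = tad)
  observed <- cells |>
    dplyr::group_by(.data$strat, .data$bin) |>
    dplyr::summarise(
      tad_mid = stats::median(.data$tad),
      obs_p5 = pctl(.data$dv)[1], obs_p50 = pctl(.data$dv)[2],
      obs_p95 = pctl(.data$dv)[3], n = dplyr::n(),
      .groups = "drop"
    )
  sims <- vector("list", n_sim)
  for (r in seq_len(n_sim)) {
    sim_rec <- .simulate_dataset(records, pop, ruv, ruv_form)
    sdv <- sim_rec$DV[sim_rec$EVID == 0L & !is.na(records$DV)]
    sims[[r]] <- tibble::tibble(strat = strat, bin = bin, dv = sdv) |>
      dplyr::group_by(.data$strat, .data$bin) |>
      dplyr::summarise(
        p5 = pctl(.data$dv)[1], p50 = pctl(.data$dv)[2], p95 = pctl(.data$dv)[3],
        .groups = "drop"
      ) |>
      dplyr::mutate(rep = r)
  }
  band <- dplyr::bind_rows(sims) |>
    tidyr::pivot_longer(c("p5", "p50", "p95"), names_to = "stat") |>
    dplyr::group_by(.data$strat, .data$bin, .data$stat) |>
    dplyr::summarise(
      lo = stats::quantile(.data$value, 0.025, type = 7, names = FALSE),
      mid = stats::median(.data$value),
      hi = stats::quantile(.data$value, 0.975, type = 7, names = FALSE),
      .groups = "drop"
    )
  structure(
    list(table = dplyr::left_join(observed, band, by = c("strat", "bin")),
         n_sim = n_sim, edges = edges),
    class = "pk_vpc"
  )
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat("<pk_vpc> ", x$n_sim, " simulated replicates\n", sep = "")
  print(x$table, n = 20)
  invisible(x)
}

#' Plot a visual predictive check
#'
#' Observed 5/50/95th percentiles per time-after-dose bin (points and
#' lines) over the 95% simulation bands of the same statistics (ribbons),
#' faceted by matrix/compound stratum.
#'
#' @param object A [pk_vpc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_vpc <- function(object, ...) {
  obs <- object$table |>
    dplyr::distinct(
      .data$strat, .data$bin, .data$tad_mid,
      .data$obs_p5, .data$obs_p50, .data$obs_p95
    ) |>
    tidyr::pivot_longer(
      c("obs_p5", "obs_p50", "obs_p95"),
      names_to = "stat", values_to = "observed"
    ) |>
    dplyr::mutate(stat = sub("^obs_", "", .data$stat))
  band <- dplyr::select(
    object$table, "strat", "bin", "tad_mid", "stat", "lo", "hi"
  )
  ggplot2::ggplot(
    dplyr::left_join(obs, band, by = c("strat", "bin", "tad_mid", "stat")),
    ggplot2::aes(x = .data$tad_mid)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi, group = .data$stat),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed, group = .data$stat)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$strat), scales = "free") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Time after dose (h)",
      y = "Concentration (ng/mL, standardized)"
    ) +
    ggplot2::theme_bw()
}
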