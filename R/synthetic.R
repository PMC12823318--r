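#' Describe one synthetic study arm
#'
#' A study arm is a homogeneous group of subjects sharing a dosing plan,
#' sampling schedule, assay limits, and metadata availability. The pooled
#' default ([default_pooled_design()]) mirrors the heterogeneous
#' multi-study designs typical of aggregated anti-doping PK data: single
#' and repeated inhaled doses of 50-400 ug, plasma and/or urine sampling,
#' study-specific quantification limits, urine specific gravity recorded
#' in some studies only, and measured urine collection volumes in two.
#'
#' @param study Study label (shared across arms of one study).
#' @param n Number of subjects in the arm.
#' @param subject_type `"athlete"`, `"healthy"`, or `"asthmatic"`.
#' @param device `"DPI"` or `"MDI"` (carried as metadata only; no device
#'   effect exists in the model).
#' @param doses Tibble with `time` (absolute h) and `dose_ug`.
#' @param plasma_times Absolute times of plasma samples (h); `NULL` if no
#'   plasma sampling.
#' @param urine_bounds Absolute boundaries of consecutive urine collection
#'   intervals; may be a list of vectors (one per occasion); `NULL` if no
#'   urine sampling.
#' @param plasma_metab,urine_metab Is the metabolite quantified in each
#'   matrix?
#' @param lloq Named list of quantification limits (ng/mL):
#'   `plasma_salm`, `plasma_metab`, `urine_salm`, `urine_metab`.
#' @param usg_available Is urine specific gravity recorded?
#' @param urine_volume_recorded Are urine collection volumes recorded?
#' @param ruv_group Urine residual-error magnitude group
#'   (`"low"`/`"mid"`/`"high"`).
#' @param correlated Are parent and metabolite residual errors correlated
#'   within a sample in this study?
#' @return A one-row tibble (list-columns for the schedules).
#' @export
study_design <- function(study, n, subject_type, device = "DPI",
                         doses,
                         plasma_times = NULL, urine_bounds = NULL,
                         plasma_metab = FALSE, urine_metab = FALSE,
                         lloq = list(
                           plasma_salm = 0.01, plasma_metab = 0.005,
                           urine_salm = 0.1, urine_metab = 0.1
                         ),
                         usg_available = FALSE,
                         urine_volume_recorded = FALSE,
                         ruv_group = "mid",
                         correlated = FALSE) {
  stopifnot(n >= 1, all(doses$dose_ug > 0), all(doses$time >= 0))
  if (!is.null(urine_bounds) && !is.list(urine_bounds)) {
    urine_bounds <- list(urine_bounds)
  }
  tibble::tibble(
    study = study, n = as.integer(n), subject_type = subject_type,
    device = device,
    doses = list(doses),
    plasma_times = list(plasma_times),
    urine_bounds = list(urine_bounds),
    plasma_metab = plasma_metab, urine_metab = urine_metab,
    lloq = list(lloq),
    usg_available = usg_available,
    urine_volume_recorded = urine_volume_recorded,
    ruv_group = ruv_group,
    correlated = correlated
  )
}

#' The default pooled multi-study design (92 subjects, 6 studies)
#'
#' Six synthetic studies: a urine-only study with healthy and athlete
#' arms at 100/200 ug; a richly sampled endurance-trained study with three
#' occasions (400 ug, 200 ug, 200 ug once daily for a week), plasma and
#' urine for both compounds, recorded collection volumes, USG, and
#' correlated parent-metabolite errors; two single-dose healthy arms at
#' 50 ug (MDI) and 200 ug (DPI) with urine salmeterol only; healthy and
#' asthmatic arms at 100 ug with plasma salmeterol and urine for both
#' compounds; a small healthy study with recorded urine volumes; and a
#' larger two-occasion healthy study at 100 ug. Sampling grids are chosen
#' on a 0-24 h scale covering the 0.13 h distribution and ~5 h terminal
#' phases, with per-study observation counts calibrated to the pooled
#' totals of the source design.
#'
#' @return Tibble of study arms, one row per [study_design()] arm.
#' @export
default_pooled_design <- function() {
  sd1 <- function(dose_ug) tibble::tibble(time = 0, dose_ug = dose_ug)
  dplyr::bind_rows(
    study_design("study_A", 7, "healthy",
      doses = sd1(100),
      urine_bounds = c(0, 2, 4, 8), urine_metab = TRUE,
      usg_available = TRUE, ruv_group = "high"
    ),
    study_design("study_A", 14, "athlete",
      doses = sd1(200),
      urine_bounds = c(0, 2, 4, 8), urine_metab = TRUE,
      usg_available = TRUE, ruv_group = "high"
    ),
    study_design("study_B", 11, "athlete",
      doses = tibble::tibble(
        time = c(0, 168, 336 + 24 * (0:6)),
        dose_ug = c(400, 200, rep(200, 7))
      ),
      plasma_times = c(
        outer(c(0.05, 0.25, 0.5, 1, 2, 4, 8, 12), c(0, 168), `+`),
        480 + c(1, 4)
      ),
      urine_bounds = list(
        c(0, 2, 4, 8), 168 + c(0, 2, 4, 8), 480 + c(0, 2, 4, 8)
      ),
      plasma_metab = TRUE, urine_metab = TRUE,
      usg_available = TRUE, urine_volume_recorded = TRUE,
      ruv_group = "mid", correlated = TRUE
    ),
    study_design("study_D", 6, "healthy",
      device = "MDI", doses = sd1(50),
      urine_bounds = c(0, 2, 4, 8, 12), ruv_group = "low"
    ),
    study_design("study_D", 4, "healthy",
      doses = sd1(200),
      urine_bounds = c(0, 2, 4, 8, 12), ruv_group = "low"
    ),
    study_design("study_E", 10, "healthy",
      doses = sd1(100),
      plasma_times = c(0.25, 1, 4),
      urine_bounds = c(0, 2, 4, 8), urine_metab = TRUE,
      usg_available = TRUE, ruv_group = "mid"
    ),
    study_design("study_E", 10, "asthmatic",
      doses = sd1(100),
      plasma_times = c(0.25, 1, 4),
      urine_bounds = c(0, 2, 4, 8), urine_metab = TRUE,
      usg_available = TRUE, ruv_group = "mid"
    ),
    study_design("study_F", 6, "healthy",
      device = "MDI", doses = sd1(100),
      urine_bounds = c(0, 1, 2, 4, 8, 12, 24),
      urine_volume_recorded = TRUE, ruv_group = "low"
    ),
    study_design("study_G", 24, "healthy",
      doses = tibble::tibble(time = c(0, 168), dose_ug = c(100, 100)),
      plasma_times = c(0.5, 2),
      urine_bounds = list(c(0, 2, 4, 8), 168 + c(0, 2, 4, 8)),
      urine_metab = TRUE,
      usg_available = TRUE, ruv_group = "mid"
    )
  )
}

# truncated-normal USG draws: plausible physiologic hydration spread
.draw_usg <- function(n) {
  u <- stats::rnorm(n, 1.018, 0.006)
  pmin(pmax(u, 1.002), 1.035)
}

#' Generate event records for one study arm
#'
#' Per subject: draw individual parameters from the population model
#' (urine-production IIV only when no USG correction will be applied),
#' evaluate the closed-form kinetics at the arm's schedule, form urine
#' concentrations over the collection intervals, apply proportional
#' residual error (correlated within parent-metabolite pairs where the
#' design says so), attach USG (when available) such that the recorded raw
#' value standardizes back to the simulated one, and append LLOQ metadata.
#' Below-LLOQ rows are retained uncensored; censoring is a downstream
#' choice ([censor_bql()] or the M3 likelihood).
#'
#' @param design A one-row [study_design()] tibble.
#' @param pop A [population_model()].
#' @param ruv A [ruv_spec()].
#' @param seed Integer seed.
#' @param id_offset First subject ID minus one (for pooling arms).
#' @param ruv_form Residual form, see [apply_ruv()]: `"proportional"`
#'   (matches the arithmetic-scale Gaussian estimation model) or
#'   `"exponential"` (matches `error_model = "lognormal"`).
#' @return List of class `pk_synth`: `records` (validated event-record
#'   tibble), `truth` (per-subject parameters and etas), `seed`.
#' @export
generate_study <- function(design, pop, ruv, seed = NULL, id_offset = 0L,
                           ruv_form = c("proportional", "exponential")) {
  ruv_form <- match.arg(ruv_form)
  stopifnot(nrow(design) == 1L)
  if (!is.null(seed)) set.seed(seed)
  d <- as.list(design)
  for (nm in c("doses", "plasma_times", "urine_bounds", "lloq")) {
    d[[nm]] <- d[[nm]][[1]]
  }
  truth <- sample_individuals(
    pop, d$n, d$subject_type,
    usg_corrected = d$usg_available
  )
  truth$id <- truth$id + id_offset
  truth$study <- d$study
  doses <- dose_events(d$doses$time, dose_to_nmol(d$doses$dose_ug))

  recs <- list()
  for (i in seq_len(d$n)) {
    p <- row_to_params(truth[i, ])
    id <- truth$id[i]
    if (!is.null(d$plasma_times)) {
      st <- plasma_concentrations(p, pk_state(p, doses, d$plasma_times))
      recs <- c(recs, list(tibble::tibble(
        ID = id, TIME = d$plasma_times, CMT = 1L,
        conc_nmol = st$conc_plasma_salm,
        compound = "salmeterol", matrix = "plasma",
        LLOQ = d$lloq$plasma_salm,
        UINT_START = NA_real_, UVOL = NA_real_
      )))
      if (d$plasma_metab) {
        recs <- c(recs, list(tibble::tibble(
          ID = id, TIME = d$plasma_times, CMT = 3L,
          conc_nmol = st$conc_plasma_metab,
          compound = "alpha-hydroxysalmeterol", matrix = "plasma",
          LLOQ = d$lloq$plasma_metab,
          UINT_START = NA_real_, UVOL = NA_real_
        )))
      }
    }
    if (!is.null(d$urine_bounds)) {
      for (bounds in d$urine_bounds) {
        t0 <- bounds[-length(bounds)]
        t1 <- bounds[-1]
        us <- urine_samples(p, doses, t0, t1)
        uvol <- if (d$urine_volume_recorded) us$volume_l else NA_real_
        recs <- c(recs, list(tibble::tibble(
          ID = id, TIME = t1, CMT = 4L,
          conc_nmol = conc_to_nmol_per_l(us$conc_salm, "salmeterol"),
          compound = "salmeterol", matrix = "urine",
          LLOQ = d$lloq$urine_salm,
          UINT_START = t0, UVOL = uvol
        )))
        if (d$urine_metab) {
          recs <- c(recs, list(tibble::tibble(
            ID = id, TIME = t1, CMT = 5L,
            conc_nmol = conc_to_nmol_per_l(us$conc_metab, "alpha-hydroxysalmeterol"),
            compound = "alpha-hydroxysalmeterol", matrix = "urine",
            LLOQ = d$lloq$urine_metab,
            UINT_START = t0, UVOL = uvol
          )))
        }
      }
    }
  }
  obs <- dplyr::bind_rows(recs)
  # residual error on the assay (ng/mL) scale, proportional form
  conc_ng <- ifelse(
    obs$compound == "salmeterol",
    conc_to_ng_per_ml(obs$conc_nmol, "salmeterol"),
    conc_to_ng_per_ml(obs$conc_nmol, "alpha-hydroxysalmeterol")
  )
  err_in <- tibble::tibble(
    conc = conc_ng, matrix = obs$matrix, compound = obs$compound,
    ruv_group = d$ruv_group,
    pair_id = paste(obs$ID, obs$matrix, obs$TIME),
    correlated = d$correlated
  )
  dv_std <- apply_ruv(err_in, ruv, form = ruv_form)$obs
  usg <- rep(NA_real_, nrow(obs))
  dv_raw <- dv_std
  if (d$usg_available) {
    ur <- obs$matrix == "urine"
    usg[ur] <- .draw_usg(sum(ur))
    dv_raw[ur] <- dv_std[ur] * (usg[ur] + 0.002 - 1) / 0.020
  }
  obs_rec <- tibble::tibble(
    ID = obs$ID, TIME = obs$TIME, EVID = 0L, AMT = NA_real_,
    DV = dv_raw, CMT = obs$CMT, MDV = 0L, LLOQ = obs$LLOQ,
    USG = usg, UINT_START = obs$UINT_START, UVOL = obs$UVOL
  )
  dose_rec <- tidyr::crossing(ID = truth$id, doses) |>
    dplyr::transmute(
      .data$ID,
      TIME = .data$time, EVID = 1L, AMT = .data$amount_nmol,
      DV = NA_real_, CMT = 1L, MDV = 1L, LLOQ = NA_real_,
      USG = NA_real_, UINT_START = NA_real_, UVOL = NA_real_
    )
  records <- dplyr::bind_rows(dose_rec, obs_rec) |>
    dplyr::arrange(.data$ID, .data$TIME, .data$EVID, .data$CMT) |>
    dplyr::mutate(
      STUDY = d$study, TYPE = d$subject_type, DEVICE = d$device,
      RUVGRP = d$ruv_group, CORR = as.integer(d$correlated)
    )
  structure(
    list(records = validate_pk_dataset(records), truth = truth, seed = seed),
    class = "pk_synth"
  )
}

#' Generate the full pooled synthetic dataset
#'
#' Runs [generate_study()] over every arm of a pooled design with
#' deterministic per-arm sub-seeds and unique subject IDs.
#'
#' @param pop,ruv Population model and residual-error specification.
#' @param seed Integer seed.
#' @param designs A design tibble, default [default_pooled_design()].
#' @param ruv_form Passed to [generate_study()].
#' @return A `pk_synth` list: pooled `records`, pooled `truth`, `seed`.
#' @export
generate_pooled_study <- function(pop, ruv, seed = 1,
                                  designs = default_pooled_design(),
                                  ruv_form = c("proportional", "exponential")) {
  ruv_form <- match.arg(ruv_form)
  offset <- 0L
  out <- vector("list", nrow(designs))
  for (j in seq_len(nrow(designs))) {
    out[[j]] <- generate_study(
      designs[j, ], pop, ruv,
      seed = seed + 1000L * j, id_offset = offset, ruv_form = ruv_form
    )
    offset <- offset + designs$n[j]
  }
  structure(
    list(
      records = dplyr::bind_rows(lapply(out, `[[`, "records")),
      truth = dplyr::bind_rows(lapply(out, `[[`, "truth")),
      seed = seed
    ),
    class = "pk_synth"
  )
}

#' @export
print.pk_synth <- function(x, ...) {
  cat(
    "<pk_synth> ", length(unique(x$truth$id)), " subjects, ",
    sum(x$records$EVID == 0), " observations, ",
    sum(x$records$EVID == 1), " dose records\n",
    sep = ""
  )
  invisible(x)
}
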