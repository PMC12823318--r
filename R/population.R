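#' Population pharmacokinetic model: typical values, covariates, variability
#'
#' Bundles the typical structural parameters, the multiplicative athlete
#' covariate effects, and the log-normal inter-individual variability (IIV)
#' terms. IIV magnitudes are supplied as CV% and converted once to log-scale
#' standard deviations via `omega = sqrt(ln(1 + CV^2))`; both representations
#' are kept. Parameters without an entry in `omega_cv` have no IIV (here:
#' `cla_f` and `k35`).
#'
#' The IIV on the urine production rate is special: it applies only to
#' observations that are \emph{not} standardized for urine specific gravity,
#' because the USG correction itself absorbs most hydration-driven
#' variability in urine volume.
#'
#' @param typicals A [structural_params()] object of typical values.
#' @param theta_cls_athlete Multiplier on `cls_f` for athletes/
#'   endurance-trained subjects (1.63 = 63% higher clearance).
#' @param theta_k14_athlete Multiplier on `k14` for athletes (2.91 = 191%
#'   higher urinary excretion rate constant).
#' @param omega_cv Named numeric vector of IIV magnitudes as CV%.
#' @param ur_prod_iiv_usg_uncorrected_only Logical flag, see Details.
#' @return Object of class `population_model`.
#' @seealso [default_population_model()] for the packaged estimates.
#' @export
population_model <- function(typicals,
                             theta_cls_athlete = 1,
                             theta_k14_athlete = 1,
                             omega_cv = c(),
                             ur_prod_iiv_usg_uncorrected_only = TRUE) {
  validate_structural_params(typicals)
  stopifnot(theta_cls_athlete > 0, theta_k14_athlete > 0)
  omega_cv <- unlist(omega_cv)
  if (length(omega_cv)) {
    bad <- setdiff(names(omega_cv), .param_names)
    if (length(bad)) stop("unknown IIV parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    if (any(omega_cv < 0)) stop("IIV CV% must be >= 0", call. = FALSE)
  }
  omega <- sqrt(log(1 + (omega_cv / 100)^2))
  structure(
    list(
      typicals = typicals,
      theta_cls_athlete = theta_cls_athlete,
      theta_k14_athlete = theta_k14_athlete,
      omega_cv = omega_cv,
      omega = omega,
      ur_prod_iiv_usg_uncorrected_only = isTRUE(ur_prod_iiv_usg_uncorrected_only)
    ),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model>\n typicals:\n")
  print(tibble::as_tibble(unclass(x$typicals)[.param_names]))
  cat(
    " athlete multipliers: cls_f x", x$theta_cls_athlete,
    ", k14 x", x$theta_k14_athlete, "\n IIV CV%:\n"
  )
  print(x$omega_cv)
  invisible(x)
}

#' Residual unexplained variability specification
#'
#' Proportional residual errors by matrix, compound and (for urine)
#' variability group, with optional correlation between parent and
#' metabolite errors measured in the same sample (NONMEM's L2 construct).
#' Which studies carry correlated pairs is data-driven: observation rows
#' flagged `correlated = TRUE` get the matrix-specific correlation.
#'
#' @param cv Named numeric vector of proportional error CVs (fractions, not
#'   percent). Names are `<matrix>_<compound>[_<group>]` with matrix
#'   `plasma`/`urine`, compound `salm`/`metab`, group `low`/`mid`/`high`.
#' @param corr_plasma,corr_urine Parent-metabolite error correlations per
#'   matrix, in (-1, 1).
#' @return Object of class `ruv_spec`.
#' @export
ruv_spec <- function(cv, corr_plasma = 0, corr_urine = 0) {
  cv <- unlist(cv)
  if (any(cv <= 0)) stop("residual error CVs must be > 0", call. = FALSE)
  if (abs(corr_plasma) >= 1 || abs(corr_urine) >= 1) {
    stop("correlations must lie in (-1, 1)", call. = FALSE)
  }
  structure(
    list(cv = cv, corr_plasma = corr_plasma, corr_urine = corr_urine),
    class = "ruv_spec"
  )
}

# resolve the residual-error CV for observation rows
.ruv_key <- function(matrix, compound, group) {
  cmp <- ifelse(compound == "salmeterol", "salm", "metab")
  ifelse(matrix == "plasma",
    paste0("plasma_", cmp),
    paste0("urine_", cmp, "_", group)
  )
}

.ruv_cv <- function(spec, matrix, compound, group) {
  key <- .ruv_key(matrix, compound, group)
  cv <- unname(spec$cv[key])
  if (any(is.na(cv))) {
    stop(
      "no residual error defined for: ",
      paste(unique(key[is.na(cv)]), collapse = ", "),
      call. = FALSE
    )
  }
  cv
}

#' Subject categories and their reduced covariate coding
#'
#' Subjects are healthy participants, chronic asthmatics, or healthy
#' endurance-trained individuals/athletes. Healthy and asthmatic subjects
#' are statistically indistinguishable on clearance and urinary excretion
#' and are regrouped as `"other"`; the athlete multipliers apply to the
#' `"athlete"` group only.
#'
#' @param category Character vector in `c("athlete", "healthy", "asthmatic")`
#'   (`"endurance"` is accepted as an alias for `"athlete"`).
#' @return Character vector, `"athlete"` or `"other"`.
#' @export
subject_group <- function(category) {
  category <- ifelse(category == "endurance", "athlete", category)
  ok <- category %in% c("athlete", "healthy", "asthmatic")
  if (!all(ok)) {
    stop("unknown subject category: ", paste(unique(category[!ok]), collapse = ", "), call. = FALSE)
  }
  ifelse(category == "athlete", "athlete", "other")
}

#' Draw individual parameter sets from the population model
#'
#' Each parameter is `typical x covariate multiplier x exp(eta)` with
#' `eta ~ N(0, omega^2)`. Athlete multipliers apply to `cls_f` and `k14`
#' only. The `ur_prod` random effect is drawn only when `usg_corrected`
#' is `FALSE` (see [population_model()]).
#'
#' @param pop A [population_model()].
#' @param n Number of individuals.
#' @param subject_type Category, see [subject_group()].
#' @param usg_corrected Are downstream urine concentrations on the
#'   USG-standardized scale? Default `TRUE`.
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble with one row per individual: `id`, `subject_type`, the
#'   nine structural parameters, and the sampled `eta_*` columns.
#' @examples
#' pop <- default_population_model()
#' sample_individuals(pop, 3, "athlete", seed = 1)
#' @export
sample_individuals <- function(pop, n, subject_type = "healthy",
                               usg_corrected = TRUE, seed = NULL) {
  stopifnot(inherits(pop, "population_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  grp <- subject_group(subject_type)
  typ <- unclass(pop$typicals)[.param_names]
  out <- tibble::tibble(id = seq_len(n), subject_type = subject_type)
  omega <- pop$omega
  if (pop$ur_prod_iiv_usg_uncorrected_only && usg_corrected) {
    omega <- omega[names(omega) != "ur_prod"]
  }
  for (nm in .param_names) {
    val <- rep(typ[[nm]], n)
    if (grp == "athlete" && nm == "cls_f") val <- val * pop$theta_cls_athlete
    if (grp == "athlete" && nm == "k14") val <- val * pop$theta_k14_athlete
    if (nm %in% names(omega) && omega[[nm]] > 0) {
      eta <- stats::rnorm(n, 0, omega[[nm]])
    } else {
      eta <- rep(0, n)
    }
    out[[nm]] <- val * exp(eta)
    out[[paste0("eta_", nm)]] <- eta
  }
  out
}

# one row of a sample_individuals() tibble -> structural_params
row_to_params <- function(row) {
  do.call(structural_params, as.list(row[.param_names]))
}

#' Apply proportional residual error to true concentrations
#'
#' Two functional forms are available. `"proportional"` is the
#' estimation-model form, `obs = true * (1 + eps)` with
#' `eps ~ N(0, cv^2)`; draws that fall below zero are floored at zero and
#' counted (attribute `n_truncated`). `"exponential"` is the Monte-Carlo
#' simulation form, `obs = true * exp(eta)` with
#' `eta ~ N(0, ln(1 + cv^2))`, which has the same CV, cannot go negative,
#' and keeps prediction intervals symmetric on the log scale.
#'
#' Rows sharing a non-missing `pair_id` with `correlated = TRUE` (a parent
#' and its metabolite measured in the same sample) receive jointly drawn
#' errors with the matrix-specific correlation.
#'
#' @param df Tibble with columns `conc` (true value), `matrix`, `compound`,
#'   `ruv_group` (urine rows), and optionally `pair_id` and `correlated`.
#' @param spec A [ruv_spec()].
#' @param form `"proportional"` or `"exponential"`.
#' @param seed Optional seed.
#' @return `df` with an `obs` column appended; attribute `n_truncated`
#'   counts zero-floored draws (proportional form only).
#' @export
apply_ruv <- function(df, spec, form = c("proportional", "exponential"),
                      seed = NULL) {
  form <- match.arg(form)
  stopifnot(inherits(spec, "ruv_spec"), all(c("conc", "matrix", "compound") %in% names(df)))
  if (any(df$conc < 0)) stop("true concentrations must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(df)
  group <- if ("ruv_group" %in% names(df)) df$ruv_group else rep(NA_character_, n)
  cv <- .ruv_cv(spec, df$matrix, df$compound, group)
  z <- stats::rnorm(n)
  pair_id <- if ("pair_id" %in% names(df)) df$pair_id else rep(NA, n)
  correlated <- if ("correlated" %in% names(df)) df$correlated else rep(FALSE, n)
  use <- !is.na(pair_id) & correlated
  if (any(use)) {
    key <- paste(df$matrix, pair_id)
    w <- which(use)
    first <- w[!duplicated(key[w])]
    second <- w[duplicated(key[w])]
    mate <- first[match(key[second], key[first])]
    rho <- ifelse(df$matrix[second] == "plasma", spec$corr_plasma, spec$corr_urine)
    z[second] <- rho * z[mate] + sqrt(1 - rho^2) * z[second]
  }
  if (form == "proportional") {
    obs <- df$conc * (1 + cv * z)
    n_trunc <- sum(obs < 0)
    obs <- pmax(obs, 0)
  } else {
    obs <- df$conc * exp(sqrt(log(1 + cv^2)) * z)
    n_trunc <- 0L
  }
  df$obs <- obs
  attr(df, "n_truncated") <- n_trunc
  df
}

#' Censor below-quantification-limit observations (M1 / M6)
#'
#' M1 discards every observation row whose `DV` falls below its `LLOQ`.
#' M6 walks each subject/compartment series in time order and, within each
#' maximal consecutive run of BQL rows, keeps the first row with `DV`
#' replaced by `LLOQ/2` and discards the rest. Dose rows (`EVID == 1`)
#' always pass through. Censoring by likelihood (M3) is not a data
#' preparation rule; it is an option of the estimation likelihood, see
#' [individual_loglik()].
#'
#' @param records Event-record tibble with at least `ID`, `TIME`, `DV`,
#'   `LLOQ`, `CMT`, and ideally `EVID`.
#' @param method `"M1"` or `"M6"` (case-insensitive).
#' @return Filtered tibble; attributes `n_dropped` and (M6) `n_imputed`.
#' @examples
#' rec <- tibble::tibble(
#'   ID = 1, TIME = 1:4, EVID = 0, CMT = 4,
#'   DV = c(5, 0.3, 0.2, 2), LLOQ = 1
#' )
#' censor_bql(rec, "M1")$DV # 5 2
#' censor_bql(rec, "M6")$DV # 5 0.5 2
#' @export
censor_bql <- function(records, method = c("M1", "M6")) {
  method <- toupper(match.arg(toupper(method), c("M1", "M6")))
  stopifnot(all(c("ID", "TIME", "DV", "LLOQ", "CMT") %in% names(records)))
  evid <- if ("EVID" %in% names(records)) records$EVID else rep(0L, nrow(records))
  is_obs <- evid == 0
  if (any(is_obs & is.na(records$LLOQ))) {
    stop("observation rows with missing LLOQ", call. = FALSE)
  }
  bql <- is_obs & !is.na(records$DV) & records$DV < records$LLOQ
  if (method == "M1") {
    out <- records[!bql, , drop = FALSE]
    attr(out, "n_dropped") <- sum(bql)
    return(out)
  }
  # M6: per (ID, CMT) series ordered by time, impute the first row of each
  # consecutive BQL run and drop the others
  ord <- order(records$ID, records$CMT, records$TIME)
  keep <- rep(TRUE, nrow(records))
  impute <- rep(FALSE, nrow(records))
  key <- paste(records$ID, records$CMT)
  for (k in unique(key[is_obs])) {
    idx <- ord[key[ord] == k & is_obs[ord]]
    run_start <- TRUE
    for (i in idx) {
      if (bql[i]) {
        if (run_start) impute[i] <- TRUE else keep[i] <- FALSE
        run_start <- FALSE
      } else {
        run_start <- TRUE
      }
    }
  }
  records$DV[impute] <- records$LLOQ[impute] / 2
  out <- records[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "n_imputed") <- sum(impute)
  out
}
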