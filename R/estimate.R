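# ---------------------------------------------------------------------------
# Likelihood machinery: per-subject data preparation, proportional/correlated
# Gaussian likelihood with optional M3 censoring, MAP inner problem, Laplace
# marginal likelihood, and population fitting.
# ---------------------------------------------------------------------------

# flatten one subject's records into plain vectors for fast repeated
# evaluation inside the optimizers
.prepare_subject <- function(rec, ruv, bql, error_model = "proportional") {
  dose <- rec[rec$EVID == 1L, ]
  obs <- rec[rec$EVID == 0L & !is.na(rec$DV), ]
  bql_flag <- rep(FALSE, nrow(obs))
  if (bql == "m3") {
    bql_flag <- obs$DV_NMOL < obs$LLOQ_NMOL
  }
  times <- sort(unique(c(obs$TIME, obs$UINT_START[!is.na(obs$UINT_START)])))
  it <- match(obs$TIME, times)
  it0 <- match(obs$UINT_START, times)
  cv <- .ruv_cv(ruv, obs$matrix, obs$compound, obs$RUVGRP)
  # correlated parent-metabolite pairs: same sample, both quantified
  pair_i <- pair_j <- integer(0)
  pair_rho <- numeric(0)
  cand <- which(obs$CORR == 1L & !bql_flag)
  if (length(cand) > 1L) {
    key <- paste(obs$matrix[cand], obs$TIME[cand])
    for (k in unique(key[duplicated(key)])) {
      idx <- cand[key == k]
      sal <- idx[obs$compound[idx] == "salmeterol"]
      met <- idx[obs$compound[idx] != "salmeterol"]
      if (length(sal) == 1L && length(met) == 1L) {
        pair_i <- c(pair_i, sal)
        pair_j <- c(pair_j, met)
        pair_rho <- c(
          pair_rho,
          if (obs$matrix[sal] == "plasma") ruv$corr_plasma else ruv$corr_urine
        )
      }
    }
  }
  paired <- seq_len(nrow(obs)) %in% c(pair_i, pair_j)
  urine <- obs$CMT %in% c(4L, 5L)
  dt_u <- obs$TIME - obs$UINT_START
  # per-dose evaluation segments, precomputed once (parameter-independent)
  dose_seg <- lapply(seq_along(dose$TIME), function(d) {
    on <- which(times >= dose$TIME[d])
    list(on = on, dt = times[on] - dose$TIME[d], amt = dose$AMT[d])
  })
  list(
    dose_seg = dose_seg,
    n_times = length(times),
    # index vectors for the vectorized prediction path
    r_p1 = which(obs$CMT == 1L), r_p3 = which(obs$CMT == 3L),
    r_u4 = which(obs$CMT == 4L & dt_u > 0),
    r_u5 = which(obs$CMT == 5L & dt_u > 0),
    r_l4 = which(obs$CMT == 4L & dt_u <= 0),
    r_l5 = which(obs$CMT == 5L & dt_u <= 0),
    dt_u = dt_u,
    id = rec$ID[1],
    group = subject_group(rec$TYPE[1]),
    dose_time = dose$TIME, dose_amt = dose$AMT,
    n_obs = nrow(obs),
    times = times, it = it, it0 = it0,
    cmt = obs$CMT, dv = obs$DV_NMOL, lloq = obs$LLOQ_NMOL,
    cv = cv, bql = bql_flag, paired = paired,
    error_model = error_model,
    sigln = sqrt(log(1 + cv^2)),
    uvol = obs$UVOL,
    pair_i = pair_i, pair_j = pair_j, pair_rho = pair_rho,
    has_metab = any(obs$CMT %in% c(3L, 5L)),
    # the urine-production random effect only acts on USG-uncorrected,
    # unmeasured-volume urine samples
    ur_eta = any(urine & is.na(obs$UVOL) & is.na(obs$USG))
  )
}

.prepare_subjects <- function(records, ruv, bql, error_model = "proportional") {
  if (!"DV_NMOL" %in% names(records)) records <- validate_pk_dataset(records)
  lapply(split(records, records$ID), .prepare_subject,
    ruv = ruv, bql = bql, error_model = error_model
  )
}

# model predictions (nmol/L) at one subject's observation rows.
# A scalar closed-form path keeps the optimizer inner loop cheap; nearly
# degenerate eigenvalue spectra fall back to the generic dispatcher (ODE).
.subject_pred <- function(prep, pars) {
  k10 <- pars$cls_f / pars$v1_f
  k12 <- pars$q_f / pars$v1_f
  k21 <- pars$q_f / pars$v2_f
  k30 <- pars$cla_f / pars$v1_f
  kel <- k10 + pars$k14
  s <- kel + k12 + k21
  disc <- s^2 - 4 * kel * k21
  k30s <- k30 + pars$k35
  al <- (s + sqrt(max(disc, 0))) / 2
  be <- (s - sqrt(max(disc, 0))) / 2
  gap <- min(
    abs(al - be) / al,
    abs(k30s - al) / max(k30s, al),
    abs(k30s - be) / max(k30s, be)
  )
  if (!is.finite(gap) || gap < 1e-9) {
    am <- .amounts(
      pars[.param_names], prep$dose_time, prep$dose_amt, prep$times,
      lean = TRUE
    )
    a1 <- am$a1[1, ]
    a3 <- am$a3[1, ]
    a4 <- am$a4[1, ]
    a5 <- am$a5[1, ]
  } else {
    c1 <- (k21 - al) / (be - al)
    c2 <- (k21 - be) / (al - be)
    g1 <- c1 / (k30s - al)
    g2 <- c2 / (k30s - be)
    a1 <- a3 <- a4 <- a5 <- numeric(prep$n_times)
    for (seg in prep$dose_seg) {
      if (!length(seg$on)) next
      ea <- exp(-al * seg$dt)
      eb <- exp(-be * seg$dt)
      ec <- exp(-k30s * seg$dt)
      ia <- (1 - ea) / al
      ib <- (1 - eb) / be
      ic <- (1 - ec) / k30s
      a1[seg$on] <- a1[seg$on] + seg$amt * (c1 * ea + c2 * eb)
      a3[seg$on] <- a3[seg$on] + seg$amt * pars$k13 * (g1 * (ea - ec) + g2 * (eb - ec))
      a4[seg$on] <- a4[seg$on] + pars$k14 * seg$amt * (c1 * ia + c2 * ib)
      a5[seg$on] <- a5[seg$on] +
        pars$k35 * seg$amt * pars$k13 * (g1 * (ia - ic) + g2 * (ib - ic))
    }
  }
  pred <- numeric(prep$n_obs)
  if (length(prep$r_p1)) {
    pred[prep$r_p1] <- a1[prep$it[prep$r_p1]] / pars$v1_f
  }
  if (length(prep$r_p3)) {
    pred[prep$r_p3] <- a3[prep$it[prep$r_p3]] / pars$v1_f
  }
  if (length(prep$r_u4)) {
    r <- prep$r_u4
    vol <- ifelse(is.finite(prep$uvol[r]), prep$uvol[r], pars$ur_prod * prep$dt_u[r])
    pred[r] <- (a4[prep$it[r]] - a4[prep$it0[r]]) / vol
  }
  if (length(prep$r_u5)) {
    r <- prep$r_u5
    vol <- ifelse(is.finite(prep$uvol[r]), prep$uvol[r], pars$ur_prod * prep$dt_u[r])
    pred[r] <- (a5[prep$it[r]] - a5[prep$it0[r]]) / vol
  }
  if (length(prep$r_l4)) {
    pred[prep$r_l4] <- pars$k14 * a1[prep$it[prep$r_l4]] / pars$ur_prod
  }
  if (length(prep$r_l5)) {
    pred[prep$r_l5] <- pars$k35 * a3[prep$it[prep$r_l5]] / pars$ur_prod
  }
  pred
}

# residual log-likelihood with optional M3 censored terms and bivariate
# terms for correlated parent-metabolite pairs. Two error models:
# "proportional": y ~ N(f, cv*f) (SD floored at 1e-10 nmol/L);
# "lognormal":    log y ~ N(log f, sqrt(ln(1+cv^2))) — same CV, no
#                 eta-in-variance interaction (see methods vignette).
.subject_ll <- function(prep, pars) {
  pred <- .subject_pred(prep, pars)
  ll <- 0
  solo <- which(!prep$paired & !prep$bql)
  cens <- which(prep$bql)
  i <- prep$pair_i
  j <- prep$pair_j
  rho <- prep$pair_rho
  if (prep$error_model == "lognormal") {
    if (any(pred[prep$dv > 0 | prep$bql] <= 0)) {
      return(-1e15)
    }
    lf <- log(pred)
    ldv <- suppressWarnings(log(prep$dv))
    s <- prep$sigln
    if (length(solo)) {
      if (any(!is.finite(ldv[solo]))) {
        return(-1e15)
      }
      ll <- ll + sum(stats::dnorm(ldv[solo], lf[solo], s[solo], log = TRUE) - ldv[solo])
    }
    if (length(cens)) {
      ll <- ll + sum(stats::pnorm(log(prep$lloq[cens]), lf[cens], s[cens], log.p = TRUE))
    }
    if (length(i)) {
      zi <- (ldv[i] - lf[i]) / s[i]
      zj <- (ldv[j] - lf[j]) / s[j]
      q <- (zi^2 - 2 * rho * zi * zj + zj^2) / (1 - rho^2)
      ll <- ll + sum(
        -log(2 * pi) - log(s[i]) - log(s[j]) - ldv[i] - ldv[j] -
          0.5 * log(1 - rho^2) - q / 2
      )
    }
  } else {
    sd <- pmax(prep$cv * abs(pred), 1e-10)
    if (length(solo)) {
      ll <- ll + sum(stats::dnorm(prep$dv[solo], pred[solo], sd[solo], log = TRUE))
    }
    if (length(cens)) {
      ll <- ll + sum(stats::pnorm(prep$lloq[cens], pred[cens], sd[cens], log.p = TRUE))
    }
    if (length(i)) {
      zi <- (prep$dv[i] - pred[i]) / sd[i]
      zj <- (prep$dv[j] - pred[j]) / sd[j]
      q <- (zi^2 - 2 * rho * zi * zj + zj^2) / (1 - rho^2)
      ll <- ll + sum(
        -log(2 * pi) - log(sd[i]) - log(sd[j]) -
          0.5 * log(1 - rho^2) - q / 2
      )
    }
  }
  if (!is.finite(ll)) ll <- -1e15
  ll
}

#' Log-likelihood of one subject's records at given structural parameters
#'
#' Quantified observations contribute Gaussian densities with proportional
#' SD (`cv * prediction`, floored at 1e-10 nmol/L); correlated
#' parent-metabolite pairs contribute a bivariate normal density. Under
#' `bql = "m3"` rows below their LLOQ contribute the normal probability
#' mass below the limit instead (the censored-likelihood method); under
#' `"m1"` the input is expected to be already censored with
#' [censor_bql()], and any remaining BQL rows are treated as quantified.
#'
#' @param records Event records of a single subject (any validated or raw
#'   dialect tibble).
#' @param p A [structural_params()] object.
#' @param ruv A [ruv_spec()].
#' @param bql `"m1"` (default) or `"m3"`.
#' @param error_model `"proportional"` (Gaussian on the arithmetic scale,
#'   SD = cv x prediction; the default) or `"lognormal"` (Gaussian on the
#'   log scale with matched CV, which keeps the random effects out of the
#'   residual variance).
#' @return The log-likelihood (scalar).
#' @export
individual_loglik <- function(records, p, ruv, bql = c("m1", "m3"),
                              error_model = c("proportional", "lognormal")) {
  bql <- match.arg(bql)
  error_model <- match.arg(error_model)
  records <- validate_pk_dataset(records)
  if (length(unique(records$ID)) != 1L) {
    stop("`records` must contain a single subject", call. = FALSE)
  }
  validate_structural_params(p)
  prep <- .prepare_subjects(records, ruv, bql, error_model)[[1]]
  .subject_ll(prep, unclass(p))
}

# economical Hessian: central diagonal, forward cross terms
# (1 + 2p + p(p-1)/2 evaluations); accurate enough for the Laplace
# log-determinant, which varies smoothly along the outer search path
.num_hess_fast <- function(f, x, f0 = NULL, h = 1e-3) {
  p <- length(x)
  hh <- h * (1 + abs(x))
  if (is.null(f0)) f0 <- f(x)
  fp <- fm <- numeric(p)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, hh[i])
    fp[i] <- f(x + ei)
    fm[i] <- f(x - ei)
  }
  H <- matrix(0, p, p)
  diag(H) <- (fp - 2 * f0 + fm) / hh^2
  if (p > 1) {
    for (i in 2:p) {
      ei <- replace(numeric(p), i, hh[i])
      for (j in seq_len(i - 1)) {
        ej <- replace(numeric(p), j, hh[j])
        fij <- f(x + ei + ej)
        H[i, j] <- H[j, i] <- (fij - fp[i] - fp[j] + f0) / (hh[i] * hh[j])
      }
    }
  }
  H
}

# central-difference Hessian (2p diagonal + 2p(p-1) cross evaluations)
.num_hess <- function(f, x, h = 1e-3) {
  p <- length(x)
  hh <- h * (1 + abs(x))
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, hh[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hh[i]^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- replace(numeric(p), j, hh[j])
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
            (4 * hh[i] * hh[j])
      }
    }
  }
  H
}

.logdet_pd <- function(H) {
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (!is.null(ch)) {
    return(list(logdet = 2 * sum(log(diag(ch))), pd = TRUE))
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  list(logdet = sum(log(pmax(ev, 1e-8))), pd = FALSE)
}

# typical values for one subject after covariate multipliers
.subject_typicals <- function(pop, group) {
  typ <- unclass(pop$typicals)[.param_names]
  if (group == "athlete") {
    typ$cls_f <- typ$cls_f * pop$theta_cls_athlete
    typ$k14 <- typ$k14 * pop$theta_k14_athlete
  }
  typ
}

# which random effects act on this subject (flat dimensions integrate to 1
# exactly, so pruning them changes nothing but the runtime)
.subject_eta_names <- function(prep, pop) {
  nm <- names(pop$omega)[pop$omega > 0]
  if (!prep$ur_eta) nm <- setdiff(nm, "ur_prod")
  if (!prep$has_metab) nm <- setdiff(nm, c("k13", "k35"))
  nm
}

# inner problem: joint log density of (data, eta); returns MAP eta, the
# Laplace-approximated log marginal likelihood, and diagnostics
.subject_laplace <- function(prep, pop, eta_start = NULL, n_starts = 1) {
  typ <- .subject_typicals(pop, prep$group)
  eta_nm <- .subject_eta_names(prep, pop)
  d <- length(eta_nm)
  make_pars <- function(eta) {
    p <- typ
    if (d) for (k in seq_len(d)) p[[eta_nm[k]]] <- p[[eta_nm[k]]] * exp(eta[k])
    p
  }
  if (d == 0L) {
    ll <- .subject_ll(prep, typ)
    return(list(loglik = ll, eta = numeric(0), eta_names = character(0), conv = 0L))
  }
  om <- pop$omega[eta_nm]
  negjoint <- function(eta) {
    -(.subject_ll(prep, make_pars(eta)) + sum(stats::dnorm(eta, 0, om, log = TRUE)))
  }
  starts <- list(if (is.null(eta_start)) numeric(d) else eta_start)
  if (n_starts > 1) {
    for (s in seq_len(n_starts - 1)) {
      starts <- c(starts, list(starts[[1]] + stats::rnorm(d, 0, 0.2)))
    }
  }
  best <- NULL
  for (st in starts) {
    opt <- stats::nlminb(st, negjoint,
      lower = -8, upper = 8,
      control = list(iter.max = 200, rel.tol = 1e-10)
    )
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  H <- .num_hess_fast(negjoint, best$par, f0 = best$objective)
  ld <- .logdet_pd(H)
  list(
    loglik = -best$objective + d / 2 * log(2 * pi) - ld$logdet / 2,
    eta = stats::setNames(best$par, eta_nm),
    eta_names = eta_nm,
    joint = -best$objective,
    hess_pd = ld$pd,
    conv = best$convergence
  )
}

#' Maximum a posteriori (MAP) Bayesian individual estimation
#'
#' Maximizes the sum of the subject's data log-likelihood and the
#' log-density of the random effects under the population prior. With no
#' data (or uninformative data for a given effect) the estimate shrinks to
#' the prior mode, eta = 0. This is the empirical-Bayes step used both for
#' individual exposure assessment from repeated doping-control samples and
#' as the inner problem of the Laplace population fit.
#'
#' @param records One subject's event records.
#' @param pop A [population_model()] (the prior).
#' @param ruv A [ruv_spec()].
#' @param bql `"m1"` or `"m3"`.
#' @param error_model See [individual_loglik()].
#' @return List with `eta` (named MAP random effects), `params` (the
#'   subject's [structural_params()]), `objective` (joint log density at
#'   the mode), and `convergence` (0 = clean).
#' @export
map_estimate <- function(records, pop, ruv, bql = c("m1", "m3"),
                         error_model = c("proportional", "lognormal")) {
  bql <- match.arg(bql)
  error_model <- match.arg(error_model)
  records <- validate_pk_dataset(records)
  prep <- .prepare_subjects(records, ruv, bql, error_model)[[1]]
  res <- .subject_laplace(prep, pop)
  typ <- .subject_typicals(pop, prep$group)
  pars <- typ
  for (nm in names(res$eta)) pars[[nm]] <- pars[[nm]] * exp(res$eta[[nm]])
  eta_full <- stats::setNames(numeric(length(pop$omega)), names(pop$omega))
  eta_full[names(res$eta)] <- res$eta
  list(
    eta = eta_full,
    params = do.call(structural_params, pars),
    objective = if (length(res$eta)) res$joint else res$loglik,
    convergence = res$conv
  )
}

# free-parameter bookkeeping: names may be structural parameters, covariate
# thetas ("theta_cls_athlete"), log-normal SDs ("omega_<param>"), or
# residual error CVs ("sigma_<key>"); all estimated on the log scale
.free_get <- function(pop, ruv, free) {
  vapply(free, function(nm) {
    if (nm %in% .param_names) {
      pop$typicals[[nm]]
    } else if (nm %in% c("theta_cls_athlete", "theta_k14_athlete")) {
      pop[[nm]]
    } else if (startsWith(nm, "omega_")) {
      om <- pop$omega[[sub("^omega_", "", nm)]]
      if (is.null(om) || om <= 0) {
        stop("free omega must exist and be positive at init: ", nm, call. = FALSE)
      }
      om
    } else if (startsWith(nm, "sigma_")) {
      key <- sub("^sigma_", "", nm)
      if (!key %in% names(ruv$cv)) stop("unknown sigma: ", nm, call. = FALSE)
      ruv$cv[[key]]
    } else {
      stop("unknown free parameter: ", nm, call. = FALSE)
    }
  }, numeric(1))
}

.free_set <- function(pop, ruv, free, values) {
  for (k in seq_along(free)) {
    nm <- free[k]
    v <- values[k]
    if (nm %in% .param_names) {
      pop$typicals[[nm]] <- v
    } else if (nm %in% c("theta_cls_athlete", "theta_k14_athlete")) {
      pop[[nm]] <- v
    } else if (startsWith(nm, "omega_")) {
      pop$omega[[sub("^omega_", "", nm)]] <- v
    } else {
      ruv$cv[[sub("^sigma_", "", nm)]] <- v
    }
  }
  list(pop = pop, ruv = ruv)
}

#' Fit the population model by Laplace-approximated marginal likelihood
#'
#' The marginal likelihood of each subject is approximated by a
#' second-order Laplace expansion around the subject's MAP random effects
#' (finite-difference Hessians); the objective function value (OFV) is -2
#' times the summed log marginal likelihood, and any subset of fixed
#' effects, covariate multipliers, random-effect SDs, and residual-error
#' CVs can be freed. Free parameters are optimized on the log scale by a
#' bounded quasi-Newton method with warm-started inner problems. Numerical
#' equality with other estimation software is not claimed; nested models
#' fitted this way are compared on their OFV difference ([compare_models()]).
#'
#' @param records A pooled event-record dataset (>= 10 subjects advised
#'   for stable variance estimation).
#' @param pop Initial [population_model()] (also supplies everything that
#'   stays fixed).
#' @param ruv Initial [ruv_spec()].
#' @param free Character vector of free parameters, e.g.
#'   `c("cls_f", "k13", "k14", "omega_cls_f", "theta_cls_athlete",
#'   "sigma_urine_salm_mid")`.
#' @param bql `"m1"` (rows below the LLOQ are discarded before fitting)
#'   or `"m3"` (censored likelihood).
#' @param error_model See [individual_loglik()]; `"lognormal"` avoids the
#'   Laplace interaction bias of the proportional form and is recommended
#'   for data generated with exponential residuals.
#' @param settings List: `se` (compute standard errors from the numerical
#'   Hessian of the OFV; default `FALSE`), `n_starts` (jittered inner
#'   multi-starts, default 1), `iter_max` (outer iterations, default 150),
#'   `rel_tol` (outer relative tolerance, default 1e-6).
#' @return Object of class `pk_fit`; see [tidy.pk_fit()] / [glance.pk_fit()].
#' @export
fit_population <- function(records, pop, ruv, free,
                           bql = c("m1", "m3"),
                           error_model = c("proportional", "lognormal"),
                           settings = list()) {
  bql <- match.arg(bql)
  error_model <- match.arg(error_model)
  stopifnot(inherits(pop, "population_model"), inherits(ruv, "ruv_spec"))
  set_def <- list(se = FALSE, n_starts = 1, iter_max = 150, rel_tol = 1e-6)
  settings <- utils::modifyList(set_def, settings)
  records <- validate_pk_dataset(records)
  if (bql == "m1") records <- censor_bql(records, "M1")
  n_subj <- length(unique(records$ID[records$EVID == 0L]))
  if (n_subj < 10) {
    message("fit_population: only ", n_subj, " subjects; variance estimates may be unstable")
  }
  init <- .free_get(pop, ruv, free)
  if (length(free) && any(init <= 0)) {
    stop("free parameters must start positive", call. = FALSE)
  }
  x0 <- log(init)

  # prepared subjects are invariant to sigma changes only through ruv$cv
  # lookups done at preparation time, so re-resolve CVs inside the objective
  # when sigmas are free
  sigma_free <- any(startsWith(free, "sigma_"))
  preps <- .prepare_subjects(records, ruv, bql, error_model)
  warm <- new.env(parent = emptyenv())
  n_eval <- 0L

  ofv_fun <- function(x) {
    mod <- .free_set(pop, ruv, free, exp(x))
    cur_preps <- preps
    if (sigma_free) cur_preps <- .prepare_subjects(records, mod$ruv, bql, error_model)
    total <- 0
    for (s in seq_along(cur_preps)) {
      key <- as.character(s)
      la <- .subject_laplace(
        cur_preps[[s]], mod$pop,
        eta_start = warm[[key]], n_starts = settings$n_starts
      )
      if (length(la$eta)) warm[[key]] <- unname(la$eta)
      total <- total - 2 * la$loglik
    }
    n_eval <<- n_eval + 1L
    total
  }

  ofv0 <- ofv_fun(x0)
  if (!is.finite(ofv0)) stop("non-finite OFV at initial values", call. = FALSE)
  if (length(free) == 0L) {
    # evaluation-only mode: OFV of the supplied model, nothing estimated
    opt <- list(par = x0, objective = ofv0, convergence = 0L, message = "evaluated")
  } else {
    # explicit finite-difference gradient: the step must sit well above the
    # numerical noise of the warm-started inner problems, which defeats the
    # optimizer's own (much smaller) default differencing step. The
    # objective value at the expansion point is cached and reused.
    last <- new.env(parent = emptyenv())
    ofv_cached <- function(x) {
      f <- ofv_fun(x)
      last$x <- x
      last$f <- f
      f
    }
    grad_fun <- function(x) {
      h <- 1e-3
      f0 <- if (!is.null(last$x) && identical(last$x, x)) last$f else ofv_fun(x)
      vapply(seq_along(x), function(k) {
        e <- replace(numeric(length(x)), k, h)
        (ofv_fun(x + e) - f0) / h
      }, numeric(1))
    }
    opt <- stats::nlminb(
      x0, ofv_cached,
      gradient = grad_fun,
      control = list(iter.max = settings$iter_max, rel.tol = settings$rel_tol)
    )
  }
  est <- stats::setNames(exp(opt$par), free)
  mod <- .free_set(pop, ruv, free, est)

  # final pass at the optimum: per-subject MAP etas and shrinkage
  eta_rows <- list()
  final_ll <- 0
  for (s in seq_along(preps)) {
    cur <- if (sigma_free) .prepare_subjects(records, mod$ruv, bql, error_model)[[s]] else preps[[s]]
    la <- .subject_laplace(cur, mod$pop, eta_start = warm[[as.character(s)]])
    final_ll <- final_ll + la$loglik
    if (length(la$eta)) {
      eta_rows[[length(eta_rows) + 1L]] <- tibble::tibble(
        id = preps[[s]]$id, effect = names(la$eta), eta = unname(la$eta)
      )
    }
  }
  etas <- dplyr::bind_rows(eta_rows)
  shrink <- NULL
  if (nrow(etas)) {
    shrink <- etas |>
      dplyr::group_by(.data$effect) |>
      dplyr::summarise(sd_eta = stats::sd(.data$eta), .groups = "drop") |>
      dplyr::mutate(
        omega = mod$pop$omega[.data$effect],
        shrinkage_pct = 100 * (1 - .data$sd_eta / .data$omega)
      )
  }

  se <- rse <- rep(NA_real_, length(free))
  cond <- NA_real_
  if (isTRUE(settings$se)) {
    H <- .num_hess(ofv_fun, opt$par, h = 1e-3)
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
    cond <- max(ev) / max(min(ev), 1e-300)
    cov_log <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cov_log) && all(diag(cov_log) > 0)) {
      se_log <- sqrt(diag(cov_log))
      se <- est * se_log # delta method back to the natural scale
      rse <- 100 * se_log
    }
  }

  structure(
    list(
      estimates = est, free = free, pop = mod$pop, ruv = mod$ruv,
      ofv = opt$objective, se = se, rse = rse,
      shrinkage = shrink, etas = etas,
      convergence = opt$convergence, message = opt$message,
      n_eval = n_eval, n_subjects = n_subj,
      n_obs = sum(records$EVID == 0L & !is.na(records$DV)),
      bql = bql, settings = settings, hess_condition = cond,
      loglik_at_opt = final_ll
    ),
    class = "pk_fit"
  )
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(
    "<pk_fit> OFV ", format(x$ofv, digits = 8), ", ",
    x$n_subjects, " subjects, ", x$n_obs, " observations, ",
    "convergence code ", x$convergence, "\n",
    sep = ""
  )
  print(tidy(x))
  invisible(x)
}

#' Tidy a population fit
#'
#' @param x A `pk_fit` object.
#' @param ... Unused.
#' @return One row per free parameter: `term`, `estimate`, `std_error`,
#'   `rse_pct` (relative standard error, percent).
#' @export
tidy.pk_fit <- function(x, ...) {
  tibble::tibble(
    term = x$free,
    estimate = unname(x$estimates),
    std_error = unname(x$se),
    rse_pct = unname(x$rse)
  )
}

#' @rdname tidy.pk_fit
#' @return For `glance()`: a one-row tibble with the OFV, AIC, counts and
#'   convergence diagnostics.
#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(
    ofv = x$ofv,
    aic = x$ofv + 2 * length(x$free),
    n_subjects = x$n_subjects,
    n_obs = x$n_obs,
    n_free = length(x$free),
    convergence = x$convergence
  )
}

#' Compare two fitted models
#'
#' For nested models the OFV difference (extended minus reference) is
#' judged against chi-squared thresholds: addition of parameters is
#' accepted at alpha = 0.05 (for 1 df, delta OFV < -3.84) during forward
#' building, and removal must worsen the OFV by more than the alpha = 0.01
#' threshold (6.63 for 1 df) during backward deletion. Non-nested models
#' are compared on AIC.
#'
#' @param reference,extended `pk_fit` objects or bare OFV values; the
#'   extended model has `df` more parameters.
#' @param df Number of added parameters (default: difference of free
#'   parameter counts).
#' @param direction `"forward"` (addition, alpha 0.05) or `"backward"`
#'   (removal, alpha 0.01).
#' @param type `"nested"` or `"aic"`.
#' @return One-row tibble: `delta_ofv`, `df`, `threshold`, `p_value`,
#'   `decision` (`"accept"` means keep the extended model).
#' @examples
#' compare_models(100, 86, df = 1) # delta -14: accept
#' @export
compare_models <- function(reference, extended, df = NULL,
                           direction = c("forward", "backward"),
                           type = c("nested", "aic")) {
  direction <- match.arg(direction)
  type <- match.arg(type)
  ofv_of <- function(x) if (inherits(x, "pk_fit")) x$ofv else as.numeric(x)
  nfree <- function(x) if (inherits(x, "pk_fit")) length(x$free) else NA_integer_
  delta <- ofv_of(extended) - ofv_of(reference)
  if (is.null(df)) {
    df <- nfree(extended) - nfree(reference)
    if (is.na(df)) stop("`df` must be given for bare OFV inputs", call. = FALSE)
  }
  if (type == "aic") {
    d_aic <- delta + 2 * df
    return(tibble::tibble(
      delta_ofv = delta, df = df, threshold = NA_real_,
      p_value = NA_real_, delta_aic = d_aic,
      decision = ifelse(d_aic < 0, "accept", "reject")
    ))
  }
  alpha <- if (direction == "forward") 0.05 else 0.01
  thr <- stats::qchisq(1 - alpha, df)
  p <- stats::pchisq(max(-delta, 0), df, lower.tail = FALSE)
  tibble::tibble(
    delta_ofv = delta, df = df, threshold = thr, p_value = p,
    decision = ifelse(-delta > thr, "accept", "reject")
  )
}
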