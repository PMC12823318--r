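# shared fixtures and independent oracles for the test suite

published_typicals <- function() {
  structural_params(
    v1_f = 446, v2_f = 871, q_f = 1490, cls_f = 193, cla_f = 233,
    k13 = 0.30, k14 = 0.00094, k35 = 0.015, ur_prod = 0.079
  )
}

random_params <- function() {
  # log-uniform draws over generous physiologic ranges
  runif1 <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  structural_params(
    v1_f = runif1(50, 2000), v2_f = runif1(100, 5000), q_f = runif1(100, 5000),
    cls_f = runif1(20, 1000), cla_f = runif1(20, 1000),
    k13 = runif1(0.01, 2), k14 = runif1(1e-4, 0.1), k35 = runif1(1e-3, 0.5),
    ur_prod = runif1(0.02, 0.3)
  )
}

# independent brute-force oracle: numerically integrate the kinetic system
# with deSolve, written directly from the rate equations (separate from the
# package's closed form and from its own lsoda fallback wiring)
oracle_ode <- function(p, dose_time, dose_amt, times) {
  k10 <- p$cls_f / p$v1_f
  k12 <- p$q_f / p$v1_f
  k21 <- p$q_f / p$v2_f
  k30 <- p$cla_f / p$v1_f
  rhs <- function(t, y, parms) {
    list(c(
      -(k10 + k12 + p$k14) * y[1] + k21 * y[2],
      k12 * y[1] - k21 * y[2],
      p$k13 * y[1] - (k30 + p$k35) * y[3],
      p$k14 * y[1],
      p$k35 * y[3],
      k10 * y[1],
      k30 * y[3],
      p$k13 * y[1]
    ))
  }
  nms <- c(
    "a1", "a2", "a3", "a4", "a5",
    "eliminated_parent", "eliminated_metabolite", "formed_metabolite"
  )
  grid <- sort(unique(c(0, dose_time, times)))
  ev <- data.frame(
    var = "a1", time = dose_time, value = dose_amt, method = "add"
  )
  sol <- deSolve::lsoda(
    stats::setNames(rep(0, 8), nms), grid, rhs,
    events = list(data = ev), rtol = 1e-11, atol = 1e-13
  )
  out <- sol[match(times, grid), -1, drop = FALSE]
  colnames(out) <- nms
  out
}

# a tiny single-subject event-record fixture with plasma and urine rows
small_subject_records <- function(dose_ug = 100, type = "healthy",
                                  corr = 0L, usg = NA_real_) {
  tibble::tibble(
    ID = 1L,
    TIME = c(0, 0.5, 2, 2, 4, 4),
    EVID = c(1L, 0L, 0L, 0L, 0L, 0L),
    AMT = c(dose_to_nmol(dose_ug), rep(NA_real_, 5)),
    DV = c(NA, 0.15, 2.2, 1.9, 1.1, 1.4),
    CMT = c(1L, 1L, 4L, 5L, 4L, 5L),
    MDV = c(1L, rep(0L, 5)),
    LLOQ = c(NA, 0.01, 0.1, 0.1, 0.1, 0.1),
    USG = c(NA, NA, usg, usg, usg, usg),
    UINT_START = c(NA, NA, 0, 0, 2, 2),
    UVOL = NA_real_,
    STUDY = "study_X", TYPE = type, DEVICE = "DPI",
    RUVGRP = "mid", CORR = corr
  )
}
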