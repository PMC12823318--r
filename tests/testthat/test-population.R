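test_that("zero-variability draws return typicals with covariate multipliers", {
  pop <- default_population_model()
  pop$omega[] <- 0
  ath <- sample_individuals(pop, 2, "athlete", seed = 1)
  expect_equal(ath$cls_f, rep(193 * 1.63, 2))
  expect_equal(ath$cls_f, rep(314.59, 2), tolerance = 1e-6)
  expect_equal(ath$k14, rep(0.00094 * 2.91, 2))
  expect_equal(ath$v1_f, rep(446, 2)) # multipliers touch cls_f and k14 only
  hea <- sample_individuals(pop, 1, "healthy", seed = 1)
  for (nm in c("v1_f", "v2_f", "q_f", "cls_f", "cla_f", "k13", "k14", "k35", "ur_prod")) {
    expect_equal(hea[[nm]], pop$typicals[[nm]], label = nm)
  }
  # asthmatics are regrouped with healthy: no multiplier
  ast <- sample_individuals(pop, 1, "asthmatic", seed = 1)
  expect_equal(ast$cls_f, 193)
  expect_equal(subject_group(c("athlete", "healthy", "asthmatic", "endurance")),
    c("athlete", "other", "other", "athlete")
  )
  expect_error(subject_group("plant"), "unknown")
})

test_that("log-normal sampler has the specified median and CV", {
  pop <- default_population_model()
  draws <- sample_individuals(pop, 1e5, "healthy", seed = 7)
  # median of a log-normal equals the typical value
  expect_equal(stats::median(draws$cls_f) / 193, 1, tolerance = 0.01)
  # CV% back-transforms as sqrt(exp(omega^2) - 1)
  cv_emp <- stats::sd(draws$cls_f) / mean(draws$cls_f)
  expect_equal(cv_emp, 0.33, tolerance = 0.02)
  # geometric means reproduce typicals for every parameter
  for (nm in c("v1_f", "q_f", "v2_f", "cls_f", "k13", "k14")) {
    gm <- exp(mean(log(draws[[nm]])))
    expect_equal(gm / pop$typicals[[nm]], 1,
      tolerance = 0.015,
      label = paste("geometric mean of", nm)
    )
  }
  # no IIV on the metabolite clearance and excretion constants
  expect_equal(stats::sd(draws$cla_f), 0)
  expect_equal(stats::sd(draws$k35), 0)
})

test_that("urine-production IIV is tied to USG-uncorrected data", {
  pop <- default_population_model()
  cor_draws <- sample_individuals(pop, 100, "healthy", usg_corrected = TRUE, seed = 3)
  unc_draws <- sample_individuals(pop, 100, "healthy", usg_corrected = FALSE, seed = 3)
  expect_equal(stats::sd(cor_draws$ur_prod), 0)
  expect_gt(stats::sd(unc_draws$ur_prod), 0)
})

test_that("proportional residual error has the right SD and correlation", {
  ruv <- default_ruv_spec()
  n <- 1e5
  df <- tibble::tibble(
    conc = rep(10, 2 * n),
    matrix = "urine",
    compound = rep(c("salmeterol", "alpha-hydroxysalmeterol"), n),
    ruv_group = "mid",
    pair_id = rep(seq_len(n), each = 2),
    correlated = TRUE
  )
  out <- apply_ruv(df, ruv, form = "proportional", seed = 11)
  eps <- out$obs / out$conc - 1
  eps_s <- eps[df$compound == "salmeterol"]
  eps_m <- eps[df$compound != "salmeterol"]
  expect_equal(stats::sd(eps_s), 0.41, tolerance = 0.01)
  expect_equal(stats::sd(eps_m), 0.38, tolerance = 0.01)
  expect_equal(stats::cor(eps_s, eps_m), 0.61, tolerance = 0.02)
  # plasma pairing uses the plasma correlation
  dfp <- dplyr::mutate(df, matrix = "plasma", ruv_group = NA_character_)
  outp <- apply_ruv(dfp, ruv, form = "proportional", seed = 12)
  epsp <- outp$obs / outp$conc - 1
  expect_equal(
    stats::cor(
      epsp[dfp$compound == "salmeterol"],
      epsp[dfp$compound != "salmeterol"]
    ),
    0.53,
    tolerance = 0.02
  )
})

test_that("degenerate residual-error settings behave as limits", {
  ruv <- ruv_spec(
    cv = c(urine_salm_mid = 1e-12, urine_metab_mid = 1e-12),
    corr_urine = 0.99
  )
  df <- tibble::tibble(
    conc = c(3, 7), matrix = "urine",
    compound = c("salmeterol", "alpha-hydroxysalmeterol"),
    ruv_group = "mid", pair_id = 1, correlated = TRUE
  )
  out <- apply_ruv(df, ruv, seed = 1)
  expect_equal(out$obs, out$conc, tolerance = 1e-9)
  # correlation ~1 with equal CVs makes relative errors equal draw-by-draw
  ruv2 <- ruv_spec(
    cv = c(urine_salm_mid = 0.3, urine_metab_mid = 0.3),
    corr_urine = 1 - 1e-12
  )
  df2 <- dplyr::bind_rows(rep(list(df), 50)) |>
    dplyr::mutate(pair_id = rep(1:50, each = 2))
  out2 <- apply_ruv(df2, ruv2, seed = 2)
  rel <- matrix(out2$obs / out2$conc, nrow = 2)
  expect_equal(rel[1, ], rel[2, ], tolerance = 1e-5)
})

test_that("exponential residual form matches CV and never goes negative", {
  ruv <- default_ruv_spec()
  df <- tibble::tibble(
    conc = rep(5, 1e5), matrix = "urine", compound = "salmeterol",
    ruv_group = "mid"
  )
  out <- apply_ruv(df, ruv, form = "exponential", seed = 5)
  expect_true(all(out$obs > 0))
  expect_equal(attr(out, "n_truncated"), 0L)
  expect_equal(stats::median(out$obs), 5, tolerance = 0.02)
  expect_equal(stats::sd(log(out$obs)), sqrt(log(1 + 0.41^2)), tolerance = 0.01)
})

test_that("unknown residual-error keys are rejected", {
  ruv <- default_ruv_spec()
  df <- tibble::tibble(
    conc = 1, matrix = "urine", compound = "alpha-hydroxysalmeterol",
    ruv_group = "low" # the metabolite has no low-variability urine group
  )
  expect_error(apply_ruv(df, ruv), "no residual error")
})

test_that("M1 drops BQL rows and M6 imputes the first of each run", {
  rec <- tibble::tibble(
    ID = 1L, TIME = 1:3, EVID = 0L, CMT = 4L,
    DV = c(5, 0.3, 2), LLOQ = 1
  )
  m1 <- censor_bql(rec, "M1")
  expect_equal(m1$DV, c(5, 2))
  expect_equal(attr(m1, "n_dropped"), 1L)
  expect_equal(nrow(m1) + attr(m1, "n_dropped"), nrow(rec))

  rec2 <- tibble::tibble(
    ID = 1L, TIME = 1:4, EVID = 0L, CMT = 4L,
    DV = c(5, 0.3, 0.2, 2), LLOQ = 1
  )
  m6 <- censor_bql(rec2, "M6")
  expect_equal(m6$DV, c(5, 0.5, 2))
  expect_equal(attr(m6, "n_imputed"), 1L)
  # two separate BQL runs each get one imputed row
  rec3 <- tibble::tibble(
    ID = 1L, TIME = 1:5, EVID = 0L, CMT = 4L,
    DV = c(0.4, 0.3, 2, 0.6, 0.1), LLOQ = 1
  )
  m6b <- censor_bql(rec3, "M6")
  expect_equal(m6b$DV, c(0.5, 2, 0.5))
  expect_equal(attr(m6b, "n_imputed"), 2L)

  # untouched when nothing is censored; series kept separate by ID/CMT
  clean <- tibble::tibble(
    ID = c(1L, 1L, 2L), TIME = c(1, 2, 1), EVID = 0L,
    CMT = c(4L, 5L, 4L), DV = c(5, 4, 3), LLOQ = 1
  )
  expect_equal(censor_bql(clean, "M1")$DV, clean$DV)
  expect_equal(censor_bql(clean, "M6")$DV, clean$DV)
  expect_error(
    censor_bql(dplyr::mutate(clean, LLOQ = NA_real_), "M1"),
    "missing LLOQ"
  )
})
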