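test_that("micro-constants are the defining clearance/volume ratios", {
  p <- published_typicals()
  mc <- micro_constants(p)
  expect_equal(mc$k10, 193 / 446)
  expect_equal(mc$k12, 1490 / 446)
  expect_equal(mc$k21, 1490 / 871)
  expect_equal(mc$k30, 233 / 446)
  expect_equal(round(unlist(mc), 4),
    c(k10 = 0.4327, k12 = 3.3408, k21 = 1.7107, k30 = 0.5224)
  )
  unit <- structural_params(1, 1, 1, 1, 1, k13 = 1, k14 = 1, k35 = 1, ur_prod = 1)
  expect_equal(unlist(micro_constants(unit)), c(k10 = 1, k12 = 1, k21 = 1, k30 = 1))
  # athlete-adjusted clearance raises k10 proportionally
  pa <- published_typicals()
  pa$cls_f <- 193 * 1.63
  expect_equal(micro_constants(pa)$k10, 0.7054, tolerance = 1e-4)
  expect_error(structural_params(-1, 1, 1, 1, 1, 1, 1, 1, 1), "positive")
})

test_that("disposition half-lives reproduce the published 0.13 and 5.0 h", {
  p <- published_typicals()
  hl <- half_lives(p, "disposition")
  expect_equal(signif(hl$t_half_alpha, 2), 0.13)
  expect_equal(signif(hl$t_half_beta, 2), 5.0)
  # the total-elimination variant is shorter in the terminal phase
  ht <- half_lives(p, "total")
  expect_equal(ht$t_half_alpha, 0.1247, tolerance = 1e-3)
  expect_equal(ht$t_half_beta, 3.07, tolerance = 1e-2)
  # the implemented parent system slope is indistinguishable from
  # disposition because k14 is tiny
  hm <- half_lives(p, "model")
  expect_equal(hm$t_half_beta, hl$t_half_beta, tolerance = 3e-3)
})

test_that("one-compartment limit: vanishing Q leaves t_half = ln2 V1/CL", {
  # with Q -> 0 the peripheral mode carries no mass; the mode associated
  # with central elimination has the one-compartment half-life
  p <- published_typicals()
  p$q_f <- 1e-9
  hl <- half_lives(p, "disposition")
  expect_equal(hl$t_half_alpha, log(2) * 446 / 193, tolerance = 1e-5)
  st <- pk_state(p, dose_events(0, 100), c(1, 3))
  expect_equal(st$a1[2] / st$a1[1],
    exp(-(193 / 446 + p$k14) * 2),
    tolerance = 1e-6
  )
})

test_that("bolus initial condition and conservation limit hold", {
  p <- published_typicals()
  D <- dose_to_nmol(100)
  st <- pk_state(p, dose_events(0, D), times = 0)
  expect_equal(st$a1, D)
  expect_equal(st$a2 + st$a3 + st$a4 + st$a5, 0)
  # 50 terminal half-lives out, the parent pool is fully accounted for
  far <- pk_state(p, dose_events(0, D), times = 50 * 5)
  expect_lt(far$a1 + far$a2, 1e-8 * D)
  expect_equal(far$a4 + far$eliminated_parent, D, tolerance = 1e-8)
  expect_equal(far$a5 + far$eliminated_metabolite, far$formed_metabolite,
    tolerance = 1e-8
  )
})

test_that("closed form matches an independent ODE oracle on random draws", {
  set.seed(101)
  for (i in 1:100) {
    p <- random_params()
    doses_t <- c(0, stats::runif(1, 1, 12))
    doses_a <- dose_to_nmol(c(100, 200))
    times <- sort(stats::runif(4, 0, 30))
    st <- pk_state(p, dose_events(doses_t, doses_a), times)
    orc <- oracle_ode(p, doses_t, doses_a, times)
    for (nm in colnames(orc)) {
      expect_equal(st[[nm]], unname(orc[, nm]),
        tolerance = 1e-8,
        label = paste("draw", i, nm)
      )
    }
  }
})

test_that("mass balance holds for every draw and time", {
  set.seed(202)
  for (i in 1:20) {
    p <- random_params()
    D <- dose_to_nmol(c(100, 50))
    tt <- c(0.1, 1, 7, 24, 96)
    st <- pk_state(p, dose_events(c(0, 6), D), times = tt)
    given <- ifelse(tt >= 6, sum(D), D[1])
    expect_equal(
      st$a1 + st$a2 + st$a4 + st$eliminated_parent, given,
      tolerance = 1e-8
    )
    expect_equal(st$a3 + st$a5 + st$eliminated_metabolite, st$formed_metabolite,
      tolerance = 1e-8
    )
  }
})

test_that("superposition: multi-dose state is the sum of shifted singles", {
  set.seed(303)
  p <- random_params()
  D <- dose_to_nmol(c(100, 200, 50))
  tt <- c(5, 13, 40)
  multi <- pk_state(p, dose_events(c(0, 4, 12), D), tt)
  single <- lapply(1:3, function(k) {
    pk_state(p, dose_events(c(0, 4, 12)[k], D[k]), tt)
  })
  for (nm in c("a1", "a2", "a3", "a4", "a5")) {
    expect_equal(
      multi[[nm]],
      single[[1]][[nm]] + single[[2]][[nm]] + single[[3]][[nm]],
      tolerance = 1e-10
    )
  }
})

test_that("cumulative urine amounts are non-decreasing in time", {
  set.seed(404)
  p <- random_params()
  st <- pk_state(
    p, dose_events(c(0, 8), dose_to_nmol(c(100, 100))),
    times = seq(0, 48, by = 0.5)
  )
  expect_true(all(diff(st$a4) >= -1e-12))
  expect_true(all(diff(st$a5) >= -1e-12))
})

test_that("doses after the evaluation time are ignored", {
  p <- published_typicals()
  D <- dose_to_nmol(100)
  one <- pk_state(p, dose_events(0, D), 5)
  two <- pk_state(p, dose_events(c(0, 10), c(D, D)), 5)
  expect_equal(one$a1, two$a1)
})

test_that("plasma concentrations use the shared central volume", {
  p <- published_typicals()
  st <- tibble::tibble(a1 = 446, a3 = 0)
  cc <- plasma_concentrations(p, st)
  expect_equal(cc$conc_plasma_salm, 1)
  expect_equal(cc$conc_plasma_metab, 0)
  # bolus of 240.6 nmol dilutes to ~0.5395 nmol/L at time zero
  st0 <- pk_state(p, dose_events(0, 240.6), 0)
  expect_equal(
    plasma_concentrations(p, st0)$conc_plasma_salm, 0.5395,
    tolerance = 1e-3
  )
})

test_that("the ODE fallback engages on a degenerate eigen-spectrum", {
  # k30 + k35 collides with the terminal disposition rate
  p <- published_typicals()
  hl <- half_lives(p, "model")
  beta <- log(2) / hl$t_half_beta
  p$k35 <- 1e-12
  p$cla_f <- beta * p$v1_f * (1 - 1e-12)
  st <- pk_state(p, dose_events(0, 100), c(1, 10))
  expect_equal(st$solver[1], "ode")
  orc <- oracle_ode(p, 0, 100, c(1, 10))
  expect_equal(st$a3, unname(orc[, "a3"]), tolerance = 1e-6)
})
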