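test_that("initialization splits pools by conditional membership (independence)", {
  inp <- toy_inputs(pop_men = c(1000, 10), t2d_men = c(0, 0.1),
                    ob = c(0.3, 0.3), sm = c(0.2, 0.2))
  st <- initialize_cohort(toy_spec(inp), 2000)
  expect_equal(unname(st$counts[1, "men", c("healthy", "obese", "smoker",
                                            "obese_smoker")]),
               c(560, 240, 140, 60), tolerance = 1e-12)
  expect_equal(sum(st$counts[, , c("dead_t2d", "dead_other")]), 0)
  # Tunisian men 25-34 in 1997: T2D pool = 0.080 x 733 thousand
  tinp <- tunisia_inputs()
  tspec <- build_model_spec(tinp)
  tst <- initialize_cohort(tspec, 1997)
  bc <- band_counts(tst)
  expect_equal(bc["25-34", "men", "t2d"], 733 * 0.080, tolerance = 1e-9)
  df <- 733 * 0.92
  expect_equal(bc["25-34", "men", "healthy"],
               df * (1 - 0.049) * (1 - 0.588), tolerance = 1e-9)
  # O = S = 0 puts everyone in healthy or t2d
  inp0 <- toy_inputs(ob = c(0, 0), sm = c(0, 0))
  st0 <- initialize_cohort(toy_spec(inp0), 2000)
  expect_equal(sum(st0$counts[, , c("obese", "smoker", "obese_smoker")]), 0)
})

test_that("a null cycle leaves totals unchanged (conservation in the small)", {
  # a closed population: no deaths, and the youngest band's demographic
  # target shrinks exactly as fast as fractional ageing advances people out
  # of it, so no entrants are needed
  inp <- toy_inputs(t2d_men = c(0.05, 0.12), mort_men = c(0, 0),
                    mort_women = c(0, 0), growth = -0.1)
  inp$parameters$rr_mortality[] <- 1
  trends <- toy_trends(inp, rate_ob = 0, rate_sm = 0)
  spec <- toy_spec(inp, trends)
  spec$rates[["2000"]]$i_pop$values[] <- 0
  run <- suppressWarnings(run_model(spec))
  tot0 <- sum(run$states[[1]]$counts)
  for (st in run$states) {
    expect_equal(sum(st$counts), tot0, tolerance = 1e-12)
    expect_equal(sum(st$counts[, , c("dead_t2d", "dead_other")]), 0)
  }
  # t2d pool totals unchanged (only the ageing shuffle moves people)
  expect_equal(sum(run$states[[4]]$counts[, , "t2d"]),
               sum(run$states[[1]]$counts[, , "t2d"]), tolerance = 1e-12)
})

test_that("incidence moves the expected count into the T2D pool", {
  # single open band, no deaths, no trends: i = 0.02 on 1000 disease-free
  bands <- "25+"
  pop <- strat_table(matrix(1000, 1, 2, dimnames = list(bands,
                                                        c("men", "women"))),
                     "count")
  zero <- strat_table(matrix(0, 1, 2, dimnames = list(bands,
                                                      c("men", "women"))),
                      "proportion")
  snap <- survey_snapshot(2000, pop, zero, zero, zero)
  demog <- list("2000" = pop, "2002" = pop)
  mort <- strat_table(matrix(0, 1, 2, dimnames = list(bands,
                                                      c("men", "women"))),
                      "rate")
  pars <- model_parameters(rr_mortality = c("25+" = 1),
                           mortality_improvement = 0)
  inp <- study_inputs(list(snap), demog, mort, 2002, pars)
  trends <- list(obesity = trend_spec("obesity", 0, 2000, zero),
                 smoking = trend_spec("smoking", 0, 2000, zero))
  spec <- build_model_spec(inp, trend_specs = trends, obesity_targets = NULL,
                           ageing_method = "fractional")
  spec$rates[["2000"]]$i_pop$values[] <- 0.02
  run <- run_model(spec, 2000, 2001)
  expect_equal(sum(run$states[["2001"]]$counts[, "men", "t2d"]), 20,
               tolerance = 1e-9)
})

test_that("the Markov step equals an independent brute-force enumeration", {
  for (cfg in list(list(rate_ob = 0.03, rate_sm = 0.01, growth = 0.01),
                   list(rate_ob = 0.10, rate_sm = -0.02, growth = 0.03),
                   list(rate_ob = 0, rate_sm = 0, growth = 0))) {
    inp <- toy_inputs(growth = cfg$growth)
    trends <- toy_trends(inp, cfg$rate_ob, cfg$rate_sm)
    spec <- toy_spec(inp, trends)
    run <- suppressWarnings(run_model(spec, 2000, 2003))
    i_pop <- spec$rates[["2000"]]$i_pop$values
    oracle <- oracle_run(inp, trends, i_pop, 3)
    final <- run$states[["2003"]]$counts
    for (sex in c("men", "women")) {
      expect_equal(max(abs(final[, sex, ] - oracle[[sex]])), 0,
                   tolerance = 1e-9)
    }
  }
})

test_that("persons are conserved on randomised specifications", {
  set.seed(99)
  for (k in 1:8) {
    inp <- toy_inputs(pop_men = runif(2, 50, 500),
                      pop_women = runif(2, 50, 500),
                      t2d_men = runif(2, 0, 0.3),
                      t2d_women = runif(2, 0, 0.3),
                      ob = runif(2, 0, 0.5), sm = runif(2, 0, 0.6),
                      mort_men = runif(2, 0, 0.05),
                      mort_women = runif(2, 0, 0.05),
                      growth = runif(1, -0.01, 0.04))
    trends <- toy_trends(inp, runif(1, -0.05, 0.1), runif(1, -0.05, 0.1))
    run <- suppressWarnings(run_model(toy_spec(inp, trends)))
    expect_lt(conservation_error(run), 1e-9)
  }
  # and on the full Tunisian run
  trun <- suppressWarnings(run_model(build_model_spec(tunisia_inputs())))
  expect_lt(conservation_error(trun), 1e-9)
})

test_that("non-reversibility: no flow out of T2D except to death, dead pools absorb", {
  inp <- toy_inputs(growth = 0)
  run <- suppressWarnings(run_model(toy_spec(inp)))
  yrs <- names(run$states)
  for (k in seq_along(yrs)[-1]) {
    a <- run$states[[k - 1]]$counts
    b <- run$states[[k]]$counts
    # dead pools never shrink
    expect_true(all(b[, , "dead_t2d"] >= a[, , "dead_t2d"] - 1e-12))
    expect_true(all(b[, , "dead_other"] >= a[, , "dead_other"] - 1e-12))
    # t2d + its cumulative deaths never shrink (nobody leaves T2D alive)
    expect_gte(sum(b[, , c("t2d", "dead_t2d", "dead_other")]) -
                 sum(a[, , c("t2d", "dead_t2d", "dead_other")]),
               sum(b[, , "t2d"]) * 0 - 1e-12)
    expect_gte(sum(b[, , "t2d"] + b[, , "dead_t2d"]),
               sum(a[, , "t2d"] + a[, , "dead_t2d"]) - 1e-12)
  }
})

test_that("raising the obesity trajectory never lowers T2D prevalence", {
  # tested within one rate regime (run started at the last anchor): the
  # re-partitioning of pool incidence at an anchor refresh normalises the
  # population incidence to the anchor's back-calculated level, which can
  # reorder later years between runs by a few hundredths of a point
  inp <- tunisia_inputs()
  base_trends <- fit_trends(inp, obesity_targets = NULL)
  hi_trends <- base_trends
  hi_trends$obesity <- trend_spec("obesity",
                                  base_trends$obesity$annual_rate + 0.01,
                                  base_trends$obesity$reference_year,
                                  base_trends$obesity$reference_level)
  lo <- suppressWarnings(
    run_model(build_model_spec(inp, trend_specs = base_trends,
                               start = 2005), 2005))
  hi <- suppressWarnings(
    run_model(build_model_spec(inp, trend_specs = hi_trends,
                               start = 2005), 2005))
  for (y in seq(2005, 2027, 2)) {
    expect_gte(run_prevalence(hi, y), run_prevalence(lo, y) - 1e-12)
  }
  expect_gt(run_prevalence(hi, 2027), run_prevalence(lo, 2027))
})

test_that("modelled live totals track the demographic anchors within 2%", {
  inp <- tunisia_inputs()
  run <- suppressWarnings(run_model(build_model_spec(inp)))
  s <- run$summary
  for (y in c(2005, 2027)) {
    d <- colSums(interpolate_demography(inp, y)$values)
    for (sex in c("men", "women")) {
      got <- s$live[s$year == y & s$sex == sex]
      expect_lt(abs(got - d[[sex]]) / d[[sex]], 0.02)
    }
  }
  # between anchors the geometric interpolation is only an approximation of
  # the (decelerating) census path; the model stays within 5% of it
  for (y in seq(1998, 2026, 4)) {
    d <- colSums(interpolate_demography(inp, y)$values)
    got <- c(s$live[s$year == y & s$sex == "men"],
             s$live[s$year == y & s$sex == "women"])
    expect_lt(max(abs(got - d) / d), 0.05)
  }
})

test_that("run summaries are recomputable from the states", {
  run <- suppressWarnings(run_model(toy_spec()))
  s <- run$summary
  for (ynm in names(run$states)) {
    st <- run$states[[ynm]]
    live <- sum(st$counts[, , c("healthy", "obese", "smoker",
                                "obese_smoker", "t2d")])
    expect_equal(s$live[s$year == st$year & s$sex == "total"], live,
                 tolerance = 1e-12)
    expect_equal(s$t2d[s$year == st$year & s$sex == "total"],
                 sum(st$counts[, , "t2d"]), tolerance = 1e-12)
  }
  # a zero-length horizon returns the baseline state only
  single <- run_model(toy_spec(), 2000, 2000)
  expect_equal(length(single$states), 1)
  expect_equal(run_prevalence(single, 2000, "total"),
               sum(single$states[[1]]$counts[, , "t2d"]) /
                 sum(single$states[[1]]$counts), tolerance = 1e-12)
})
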