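test_that("mortality split matches the closed form and its consistency identity", {
  sp <- split_mortality(0.010, 0.10, 2.0)
  expect_equal(sp$m_nondiseased, 0.010 / 1.1, tolerance = 1e-12)
  expect_equal(sp$m_diseased, 2 * 0.010 / 1.1, tolerance = 1e-12)
  # boundary cases
  expect_equal(split_mortality(0.02, 0.5, 1), list(m_nondiseased = 0.02,
                                                   m_diseased = 0.02))
  sp0 <- split_mortality(0.02, 0, 3)
  expect_equal(sp0$m_nondiseased, 0.02)
  expect_equal(sp0$m_diseased, 0.06)
  # consistency identity over a random grid
  set.seed(7)
  m <- runif(200, 0, 0.2); p <- runif(200, 0, 0.95); rr <- runif(200, 0.5, 5)
  sp <- split_mortality(m, p, rr)
  expect_equal(p * sp$m_diseased + (1 - p) * sp$m_nondiseased, m,
               tolerance = 1e-12)
  expect_error(split_mortality(0.01, 1, 2), "degenerate")
})

test_that("incidence partition preserves population incidence exactly", {
  rr <- c(healthy = 1, obese = 2, smoker = 1, obese_smoker = 2)
  sh <- c(healthy = 0.6, obese = 0.4, smoker = 0, obese_smoker = 0)
  i <- partition_incidence(0.01, sh, rr)
  expect_equal(i[["healthy"]], 0.01 / 1.4, tolerance = 1e-12)
  expect_equal(i[["obese"]], 0.02 / 1.4, tolerance = 1e-12)
  # spec'd arithmetic identity case
  sh <- c(healthy = .5, obese = .2, smoker = .2, obese_smoker = .1)
  rr <- c(healthy = 1, obese = 3, smoker = 1.4, obese_smoker = 4.2)
  i <- partition_incidence(0.037, sh, rr)
  expect_equal(sum(sh * i), 0.037, tolerance = 1e-12)
  # all rr = 1 gives every pool the population incidence
  i1 <- partition_incidence(0.02, sh, c(healthy = 1, obese = 1, smoker = 1,
                                        obese_smoker = 1))
  expect_true(all(abs(i1 - 0.02) < 1e-15))
  # conservation for random shares/rrs
  set.seed(11)
  for (k in 1:20) {
    s <- runif(4); s <- s / sum(s); names(s) <- names(rr)
    r <- c(1, runif(3, 1, 6)); names(r) <- names(rr)
    ii <- partition_incidence(0.05, s, r)
    expect_equal(sum(s * ii), 0.05, tolerance = 1e-12)
  }
  expect_error(partition_incidence(0.01, c(healthy = 0, obese = 0,
                                           smoker = 0, obese_smoker = 0),
                                   rr), "shares")
})

test_that("forward prevalence oracle has the stated closed forms", {
  bands <- c("25-34", "35+")
  inc <- mk_tab(c(0.01, 0.01), c(0.01, 0.01), "rate")
  m0 <- mk_tab(c(0, 0), c(0, 0), "rate")
  rr <- c("25-34" = 2, "35+" = 2)
  fp <- forward_prevalence(inc, m0, rr)
  ages <- attr(fp, "ages")
  # no mortality: P(35) = 1 - 0.99^10
  expect_equal(unname(ages[ages[, "age"] == 35, "men"]), 1 - 0.99^10,
               tolerance = 1e-12)
  # zero incidence everywhere gives zero prevalence
  fp0 <- forward_prevalence(mk_tab(c(0, 0), c(0, 0), "rate"), m0, rr)
  expect_true(all(fp0$values == 0))
  # non-differential mortality (rr = 1) cancels: P independent of m level
  rr1 <- c("25-34" = 1, "35+" = 1)
  fa <- forward_prevalence(inc, mk_tab(c(.01, .05), c(.01, .05), "rate"), rr1)
  fb <- forward_prevalence(inc, mk_tab(c(.2, .3), c(.2, .3), "rate"), rr1)
  expect_equal(fa$values, fb$values, tolerance = 1e-12)
})

test_that("forward and backward incidence calculations round-trip within 5%", {
  bands <- default_age_bands()
  mk6 <- function(men, women, kind) {
    m <- cbind(men = men, women = women); rownames(m) <- bands
    strat_table(m, kind)
  }
  # smooth synthetic truth
  inc <- mk6(c(.004, .008, .012, .010, .008, .006),
             c(.003, .007, .011, .012, .009, .006), "rate")
  mort <- mk6(c(.0018, .0025, .0055, .013, .032, .095),
              c(.001, .0016, .0035, .0085, .024, .085), "rate")
  rr <- c("25-34" = 3, "35-44" = 2.8, "45-54" = 2.3, "55-64" = 1.9,
          "65-74" = 1.6, "75+" = 1.4)
  prev <- forward_prevalence(inc, mort, rr)
  rec <- backcalculate_incidence(prev, mort, rr)
  # within 5% relative at every interior band; the first band's
  # entry-condition solve and the open band's zero-gradient solve are
  # boundary approximations and are excluded from the discretisation bound
  interior <- 2:5
  rel <- abs(rec$values - inc$values)[interior, ] / inc$values[interior, ]
  expect_lt(max(rel), 0.05)
  expect_lt(max(abs(rec$values[1, ] - inc$values[1, ]) / inc$values[1, ]),
            0.05)  # the entry-condition solve is also accurate here
  # and the other direction: prevalence reproduced within 5% relative at
  # interior midpoints
  prev2 <- forward_prevalence(rec, mort, rr)
  expect_lt(max(abs(prev2$values - prev$values)[interior, ] /
                  prev$values[interior, ]), 0.05)
  # constant-incidence case from the illness-death balance (i = .01, m =
  # .005, rr = 2): recovery within 5% at every interior band
  inc_c <- mk6(rep(.01, 6), rep(.01, 6), "rate")
  mort_c <- mk6(rep(.005, 6), rep(.005, 6), "rate")
  rr2 <- setNames(rep(2, 6), bands)
  rec_c <- backcalculate_incidence(forward_prevalence(inc_c, mort_c, rr2),
                                   mort_c, rr2)
  expect_lt(max(abs(rec_c$values[interior, ] - .01) / .01), 0.05)
})

test_that("flat prevalence with no excess mortality back-calculates to zero", {
  bands <- c("25-34", "35-44", "45+")
  m <- matrix(0.2, 3, 2, dimnames = list(bands, c("men", "women")))
  prev <- strat_table(m, "proportion")
  mort <- strat_table(matrix(0.01, 3, 2, dimnames = dimnames(m)), "rate")
  rr1 <- setNames(rep(1, 3), bands)
  inc <- backcalculate_incidence(prev, mort, rr1)
  expect_equal(inc$values[2, ], c(men = 0, women = 0), tolerance = 1e-15)
})

test_that("falling prevalence floors incidence at zero, naming the stratum", {
  bands <- c("25-34", "35-44", "45+")
  # men's prevalence falls steeply between the 35-44 and 45+ midpoints:
  # more than the (tiny) excess mortality explains
  m <- cbind(men = c(0.05, 0.20, 0.05), women = c(0.1, 0.12, 0.14))
  rownames(m) <- bands
  mort <- strat_table(matrix(0.001, 3, 2, dimnames = dimnames(m)), "rate")
  rr <- setNames(rep(2, 3), bands)
  expect_warning(
    inc <- backcalculate_incidence(strat_table(m, "proportion"), mort, rr),
    "men, 35-44")
  expect_equal(unname(inc$values["35-44", "men"]), 0)
  expect_gt(inc$values["35-44", "women"], 0)
})

test_that("raising relative mortality raises incidence where prevalence rises", {
  inp <- tunisia_inputs()
  snap <- inp$anchor_surveys[[1]]
  rr_lo <- inp$parameters$rr_mortality
  rr_hi <- rr_lo * 1.5
  i_lo <- suppressWarnings(
    backcalculate_incidence(snap$t2d, inp$mortality, rr_lo))
  i_hi <- suppressWarnings(
    backcalculate_incidence(snap$t2d, inp$mortality, rr_hi))
  # interior bands with a rising forward gradient (band 1's entry-condition
  # solve is independent of the mortality ratio)
  rising <- setdiff(which(diff(snap$t2d$values[, "women"]) > 0), 1)
  expect_true(all(i_hi$values[rising, "women"] >=
                    i_lo$values[rising, "women"] - 1e-15))
  expect_gt(max(i_hi$values[rising, "women"] - i_lo$values[rising, "women"]),
            0)
})
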