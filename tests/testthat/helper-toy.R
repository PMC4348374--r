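# Small builders and an independent brute-force oracle for the Markov step.

mk_tab <- function(men, women, kind, bands = c("25-34", "35+")) {
  m <- cbind(men = men, women = women)
  rownames(m) <- bands
  strat_table(m, kind)
}

# A 2-band toy study: one anchor survey, geometric demography, constant
# mortality, explicit trend specs (so no fitting is needed).
toy_inputs <- function(year = 2000, horizon = 2003,
                       pop_men = c(100, 50), pop_women = c(110, 60),
                       t2d_men = c(0.05, 0.12), t2d_women = c(0.04, 0.10),
                       ob = c(0.10, 0.15), sm = c(0.30, 0.25),
                       mort_men = c(0.002, 0.02), mort_women = c(0.001, 0.015),
                       growth = 0.01) {
  bands <- c("25-34", "35+")
  pop <- mk_tab(pop_men, pop_women, "count", bands)
  snap <- survey_snapshot(year, pop,
                          mk_tab(t2d_men, t2d_women, "proportion", bands),
                          mk_tab(ob, ob, "proportion", bands),
                          mk_tab(sm, sm, "proportion", bands))
  demog <- list(pop,
                mk_tab(pop_men * (1 + growth)^(horizon - year),
                       pop_women * (1 + growth)^(horizon - year), "count",
                       bands))
  names(demog) <- c(year, horizon)
  pars <- model_parameters(
    rr_mortality = c("25-34" = 2.5, "35+" = 1.8),
    mortality_improvement = 0)
  study_inputs(list(snap), demog,
               mk_tab(mort_men, mort_women, "rate", bands), horizon, pars)
}

toy_trends <- function(inputs, rate_ob = 0.03, rate_sm = 0.01, cap = NULL) {
  snap <- inputs$anchor_surveys[[1]]
  list(obesity = trend_spec("obesity", rate_ob, snap$year, snap$obesity,
                            cap),
       smoking = trend_spec("smoking", rate_sm, snap$year, snap$smoking))
}

toy_spec <- function(inputs = toy_inputs(), trends = toy_trends(inputs),
                     ...) {
  build_model_spec(inputs, trend_specs = trends, obesity_targets = NULL,
                   ageing_method = "fractional", ...)
}

# Independent brute-force enumeration of the annual cycle on the toy
# (documented order: incidence, deaths, drift, fractional ageing, entrants).
# Written with plain loops and its own arithmetic; takes the same rate
# inputs the engine consumes.
oracle_run <- function(inputs, trends, i_pop, n_years) {
  snap <- inputs$anchor_surveys[[1]]
  bands <- band_labels(snap$population)
  nb <- length(bands)
  pars <- inputs$parameters
  rr_inc <- pars$rr_incidence
  pools <- c("healthy", "obese", "smoker", "obese_smoker")
  # initialization by independence
  X <- list()
  for (sex in c("men", "women")) {
    X[[sex]] <- matrix(0, nb, 7,
                       dimnames = list(bands, c(pools, "t2d", "dead_t2d",
                                                "dead_other")))
    for (b in 1:nb) {
      N <- snap$population$values[b, sex]
      P <- snap$t2d$values[b, sex]
      O <- snap$obesity$values[b, sex]
      S <- snap$smoking$values[b, sex]
      df <- N * (1 - P)
      X[[sex]][b, ] <- c(df * (1 - O) * (1 - S), df * O * (1 - S),
                         df * (1 - O) * S, df * O * S, N * P, 0, 0)
    }
  }
  # pool rates partitioned once at initialization
  prate <- list()
  for (sex in c("men", "women")) {
    prate[[sex]] <- matrix(0, nb, 4, dimnames = list(bands, pools))
    for (b in 1:nb) {
      sh <- X[[sex]][b, pools] / sum(X[[sex]][b, pools])
      ih <- i_pop[b, sex] / sum(sh * rr_inc[pools])
      prate[[sex]][b, ] <- ih * rr_inc[pools]
    }
  }
  rr_m <- pars$rr_mortality[bands]
  level <- function(ts, y) {
    lv <- ts$reference_level$values * (1 + ts$annual_rate)^(y - ts$reference_year)
    if (!is.null(ts$cap)) lv <- pmin(lv, ts$cap)
    pmin(pmax(lv, 0), 1)
  }
  demo_at <- function(y) {
    ys <- as.integer(names(inputs$demography))
    a <- inputs$demography[[1]]$values; b <- inputs$demography[[2]]$values
    a * (b / a)^((y - ys[1]) / (ys[2] - ys[1]))
  }
  y <- snap$year
  for (k in seq_len(n_years)) {
    O_t <- level(trends$obesity, y + 1)
    S_t <- level(trends$smoking, y + 1)
    for (sex in c("men", "women")) {
      M <- X[[sex]]
      for (b in 1:nb) {
        P <- snap$t2d$values[b, sex]  # anchor prevalence fixes the split
        m_all <- inputs$mortality$values[b, sex]
        m_nd <- m_all / (1 + P * (rr_m[b] - 1))
        m_d <- rr_m[b] * m_nd
        # incidence
        new <- M[b, pools] * prate[[sex]][b, ]
        M[b, pools] <- M[b, pools] - new
        M[b, "t2d"] <- M[b, "t2d"] + sum(new)
        # deaths
        dd <- M[b, pools] * m_nd
        M[b, pools] <- M[b, pools] - dd
        tb <- M[b, "t2d"] * m_nd
        tx <- M[b, "t2d"] * (m_d - m_nd)
        M[b, "t2d"] <- M[b, "t2d"] - tb - tx
        M[b, "dead_other"] <- M[b, "dead_other"] + sum(dd) + tb
        M[b, "dead_t2d"] <- M[b, "dead_t2d"] + tx
        # drift (one-way)
        df <- sum(M[b, pools])
        if (df > 0) {
          need <- O_t[b, sex] * df - (M[b, "obese"] + M[b, "obese_smoker"])
          avail <- M[b, "healthy"] + M[b, "smoker"]
          if (need > 0 && avail > 0) {
            f <- min(need / avail, 1)
            M[b, "obese"] <- M[b, "obese"] + f * M[b, "healthy"]
            M[b, "obese_smoker"] <- M[b, "obese_smoker"] + f * M[b, "smoker"]
            M[b, "healthy"] <- M[b, "healthy"] * (1 - f)
            M[b, "smoker"] <- M[b, "smoker"] * (1 - f)
          }
          need <- S_t[b, sex] * df - (M[b, "smoker"] + M[b, "obese_smoker"])
          avail <- M[b, "healthy"] + M[b, "obese"]
          if (need > 0 && avail > 0) {
            f <- min(need / avail, 1)
            M[b, "smoker"] <- M[b, "smoker"] + f * M[b, "healthy"]
            M[b, "obese_smoker"] <- M[b, "obese_smoker"] + f * M[b, "obese"]
            M[b, "healthy"] <- M[b, "healthy"] * (1 - f)
            M[b, "obese"] <- M[b, "obese"] * (1 - f)
          }
        }
      }
      # fractional ageing: 1/10 of band 1 advances; last band terminal
      live <- c(pools, "t2d")
      if (nb > 1) {
        adv <- M[1, live] / 10
        M[1, live] <- M[1, live] - adv
        M[2, live] <- M[2, live] + adv
      }
      # entrants
      target <- demo_at(y + 1)[1, sex]
      e <- max(0, target - sum(M[1, live]))
      O1 <- O_t[1, sex]; S1 <- S_t[1, sex]
      M[1, pools] <- M[1, pools] +
        e * c((1 - O1) * (1 - S1), O1 * (1 - S1), (1 - O1) * S1, O1 * S1)
      X[[sex]] <- M
    }
    y <- y + 1
  }
  X
}
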