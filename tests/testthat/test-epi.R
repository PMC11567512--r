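# Monte-Carlo agreement of the daily epidemiological steps with
# closed-form binomial / exponential / Poisson-growth oracles, plus the
# engine's conservation invariants.

test_that("all-zero rates are a fixed point of the daily loop", {
  b <- tiny_bundle(initial_size = 50, base_incidence = 0,
                   crude_birth_rate = 0, background_hazard = 0,
                   horizon_years = 2)
  res <- run_scenario(b, "NP", 1)
  expect_equal(res$final_population, 50)
  expect_equal(nrow(res$events), 0)
  expect_equal(nrow(res$deliveries), 0)
  expect_equal(total_dalys(res$ledger), 0)
})

test_that("incidence matches the per-day binomial hazard oracle", {
  # h = 0.2/yr, tc = 0, episodes last one day, nobody seeks care:
  # expected episodes ~= person-days x (1 - exp(-h/365))
  b <- tiny_bundle(initial_size = 1000, base_incidence = 0.2,
                   untreated_duration = 1 / 365,
                   care_seeking_probability = 0)
  st <- sim_init(b, "NP", 1)
  for (day in 0:364) {
    step_incidence(st, day)
    step_progression(st, day)
  }
  n_epi <- st$ne
  p <- 1 - exp(-0.2 / 365)
  expected <- 1000 * 365 * p
  se <- sqrt(expected * (1 - p))
  # small downward bias: a person is insusceptible on an active day
  expect_lt(abs(n_epi - expected), 3 * se + 0.002 * expected)
  # zero hazard -> zero episodes
  b0 <- tiny_bundle(initial_size = 500, base_incidence = 0)
  expect_equal(nrow(run_scenario(b0, "NP", 1)$events), 0)
})

test_that("episode mortality matches the exponential survival oracle", {
  mort_frac <- function(hazard, seed = 1, unvacc = 0) {
    b <- tiny_bundle(initial_size = 1000, base_incidence = 0,
                     untreated_death_hazard = hazard,
                     untreated_duration = 2, initial_prevalence = 1,
                     care_seeking_probability = 0, master_seed = seed)
    if (unvacc > 0) {
      b$population$flag_prevalence$unvaccinated <- unvacc
      b$causes$flu$risk_modifiers <- c(unvaccinated = 3)
    }
    st <- sim_init(b, "NP", 1)
    unv <- st$unvaccinated[1:1000]
    for (day in 0:364) step_progression(st, day)
    died <- rep(FALSE, 1000)
    d <- prioritysim:::log_df(st$deaths)
    died[d$person_id] <- TRUE
    list(all = mean(died), unvacc = mean(died[unv]),
         vacc = mean(died[!unv]))
  }
  for (h in c(0.05, 0.5)) {
    p <- 1 - exp(-h)
    frac <- mort_frac(h)$all
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 1000))
  }
  # treated cohorts die less: compare the two closed forms directly
  expect_lt(mort_frac(0.05)$all, mort_frac(0.5, seed = 2)$all)
  # unvaccinated risk modifier (x3 hazard)
  m <- mort_frac(0.2, seed = 3, unvacc = 0.5)
  p3 <- 1 - exp(-0.6); p1 <- 1 - exp(-0.2)
  expect_lt(abs(m$unvacc - p3), 3 * sqrt(p3 * (1 - p3) / 400))
  expect_lt(abs(m$vacc - p1), 3 * sqrt(p1 * (1 - p1) / 400))
})

test_that("hazard-free episodes all recover and none die", {
  b <- tiny_bundle(initial_size = 400, base_incidence = 0.5,
                   untreated_death_hazard = 0, untreated_duration = 0.1,
                   care_seeking_probability = 0, horizon_years = 1)
  res <- run_scenario(b, "NP", 1)
  ev <- res$events
  expect_equal(sum(ev$type == "death"), 0)
  # every episode with >= 37 days of runway recovered
  expect_gt(sum(ev$type == "recovery"), 0)
  expect_equal(nrow(res$deaths), 0)
})

test_that("care seeking is binomial at the configured probability", {
  b <- tiny_bundle(initial_size = 3000, base_incidence = 1.2,
                   care_seeking_probability = 0.6, untreated_duration = 0.02,
                   horizon_years = 1)
  res <- run_scenario(b, "NP", 1)
  n_epi <- sum(res$events$type == "incidence")
  n_seek <- sum(res$deliveries$attempt == 1)  # one row per care episode
  expect_gt(n_epi, 1000)
  se <- sqrt(0.6 * 0.4 / n_epi)
  expect_lt(abs(n_seek / n_epi - 0.6), 3 * se)
  # probability 1: every episode generates exactly one care episode
  b1 <- tiny_bundle(initial_size = 500, base_incidence = 0.5,
                    care_seeking_probability = 1, untreated_duration = 0.02)
  r1 <- run_scenario(b1, "NP", 1)
  expect_equal(sum(r1$deliveries$attempt == 1),
               sum(r1$events$type == "incidence"))
})

test_that("births follow the crude-birth-rate growth oracle", {
  b <- tiny_bundle(initial_size = 10000, base_incidence = 0,
                   crude_birth_rate = 0.03, horizon_years = 1)
  st <- sim_init(b, "NP", 1)
  for (day in 0:364) step_demography(st, day)
  births <- st$np - 10000
  expected <- 10000 * (exp(0.03) - 1)  # newborns themselves count
  expect_lt(abs(births - expected), 3 * sqrt(expected))
  # newborns carry the under-5 risk flag set (unvaccinated)
  expect_true(all(st$unvaccinated[10001:st$np]))
  expect_true(all(st$birth_day[10001:st$np] >= 0))
})

test_that("person count is conserved: alive = initial + births - deaths", {
  b <- make_default_scenario(5, horizon_years = 3, initial_size = 400)
  res <- run_scenario(b, "NP", 1)
  ev <- res$events
  expect_equal(res$final_population,
               400 + sum(ev$type == "birth") - sum(ev$type == "death"))
})

test_that("dead individuals generate no further events", {
  b <- make_default_scenario(6, horizon_years = 3, initial_size = 400)
  res <- run_scenario(b, "NP", 1)
  ev <- res$events
  deaths <- ev[ev$type == "death", ]
  expect_gt(nrow(deaths), 0)
  first_death <- tapply(deaths$day, deaths$person_id, min)
  for (type in c("incidence", "death", "birth")) {
    sub <- ev[ev$type == type & ev$person_id %in% names(first_death), ]
    lim <- first_death[as.character(sub$person_id)]
    expect_true(all(sub$day <= lim),
                info = sprintf("event type %s after death", type))
  }
  # and delivered HSIs never postdate death either
  del <- res$deliveries
  del <- del[del$person_id %in% names(first_death), ]
  expect_true(all(del$day <= first_death[as.character(del$person_id)]))
})

test_that("withholding treatment of an infectious cause raises incidence", {
  # common-random-number pairs; transmission feedback makes untreated
  # prevalence, and hence incidence, escalate when treatment is withheld
  n_rep <- 30
  inc <- matrix(NA_real_, n_rep, 2, dimnames = list(NULL, c("NP", "EXCL")))
  b <- tiny_bundle(initial_size = 150, base_incidence = 0.12,
                   transmission_coefficient = 8, untreated_duration = 0.5,
                   untreated_death_hazard = 0.05,
                   care_seeking_probability = 1, horizon_years = 2)
  b$policies$EXCL <- policy("EXCL", stats::setNames(character(), character()),
                            excluded = "flu_clinic")
  for (r in seq_len(n_rep)) {
    for (pid in c("NP", "EXCL")) {
      res <- run_scenario(b, pid, r)
      inc[r, pid] <- sum(res$events$type == "incidence")
    }
  }
  expect_gt(mean(inc[, "EXCL"]), mean(inc[, "NP"]))
  # and the paired contrast is decisive, not a tie
  expect_gt(mean(inc[, "EXCL"] - inc[, "NP"]),
            2 * stats::sd(inc[, "EXCL"] - inc[, "NP"]) / sqrt(n_rep))
})

test_that("full contraception coverage lowers the birth count", {
  b <- make_default_scenario(9, horizon_years = 3, initial_size = 500)
  # crank preventive family-planning demand so coverage saturates
  b$treatments$contraception_services$demand_rate <- 3
  b$treatments$contraception_services$effectiveness <- 1
  b$treatments$contraception_services$consumables$availability <- 1
  b$capabilities$minutes <- 1e9
  no_fp <- policy("NOFP",
                  b$policies$NP$tier_of[names(b$policies$NP$tier_of) !=
                                          "contraception_services"],
                  excluded = "contraception_services")
  b$policies$NOFP <- no_fp
  births <- vapply(c("NP", "NOFP"), function(pid) {
    ev <- run_scenario(b, pid, 1)$events
    sum(ev$type == "birth")
  }, 1)
  expect_lt(births[["NP"]], births[["NOFP"]])
})
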