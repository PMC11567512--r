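test_that("default bundle satisfies its own invariants and is rich enough", {
  b <- make_default_scenario(1)
  expect_silent(validate_bundle(b))
  expect_gte(length(b$causes), 5)
  expect_gte(length(b$treatments), 8)
  expect_gte(length(unique(vapply(b$treatments, `[[`, "",
                                  "facility_level"))), 2)
  expect_true(any(vapply(b$treatments, `[[`, TRUE, "emergency")))
  expect_true(any(vapply(b$treatments, `[[`, TRUE, "preventive")))
  expect_setequal(names(b$policies),
                  c("NP", "LCOA", "HSSP3", "VP", "RMNCH", "CMD", "CV"))
  # a residual cause outside resource constraints
  expect_true(any(!vapply(b$causes, `[[`, TRUE, "resource_constrained")))
})

test_that("generator output validates across many seeds (property)", {
  for (s in seq_len(100)) {
    expect_silent(validate_bundle(make_default_scenario(s)))
  }
})

test_that("same master seed gives byte-identical serialised bundles", {
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_scenario(make_default_scenario(7), f1)
  write_scenario(make_default_scenario(7), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("default world: leading cause shifts over 20 unconstrained years", {
  # the generator's trend structure: an initially dominant chronic
  # infectious cause is overtaken by the demographically rising child
  # respiratory cause; checked under No Policy with unconstrained
  # capability at a documented 1500-person desk scale
  b <- make_default_scenario(1, initial_size = 1500)
  b$capabilities$minutes <- 1e9
  res <- run_scenario(b, "NP", 1)
  led <- res$ledger
  led$daly <- led$yll + led$yld
  resid <- names(b$causes)[!vapply(b$causes, `[[`, TRUE,
                                   "resource_constrained")]
  led <- led[!led$cause %in% resid, ]
  yrs <- sort(unique(led$year))
  top_in <- function(y) {
    sub <- led[led$year == y, ]
    sub$cause[which.max(sub$daly)]
  }
  expect_false(top_in(yrs[1]) == top_in(yrs[20]))
  # and the population grows over the horizon (births exceed deaths)
  expect_gt(res$final_population, b$population$initial_size)
})

test_that("spec validation errors name the offending field", {
  expect_error(population_spec(0, data.frame(band = "a", lo = 0, hi = 70,
                                             prob = 1),
                               0.03, data.frame(band = "a", lo = 0, hi = 70,
                                                hazard = 0.01), 100),
               "initial_size")
  ad <- data.frame(band = c("a", "b"), lo = c(0, 5), hi = c(5, 70),
                   prob = c(0.5, 0.4))
  expect_error(population_spec(10, ad, 0.03,
                               data.frame(band = "a", lo = 0, hi = 70,
                                          hazard = 0), 100),
               "sum to 1")
  expect_error(cause_spec("x", "non-communicable", 0.1,
                          transmission_coefficient = 2),
               "transmission_coefficient")
  expect_error(cause_spec("x", "infectious", 0.1,
                          untreated_death_hazard = 0.1,
                          treated_death_hazard = 0.2),
               "treated_death_hazard")
  b <- make_default_scenario(1)
  b$causes <- list()
  expect_error(validate_bundle(b), "causes")
})

test_that("sampled populations match the configured age structure", {
  spec <- build_default_population()
  expect_error(sample_population(
    population_spec(0, spec$age_distribution, 0.03,
                    spec$background_mortality, 1000)), "initial_size")
  pop <- sample_population(spec, seed = 11)
  expect_equal(nrow(pop), spec$initial_size)
  expect_true(all(pop$alive))
  # under-5 fraction within 3 binomial standard errors of the band prob
  p <- spec$age_distribution$prob[1]
  n <- nrow(pop)
  frac <- mean(-pop$birth_day / 365 < 5)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
  # determinism
  expect_identical(pop, sample_population(spec, seed = 11))
  expect_false(identical(pop, sample_population(spec, seed = 12)))
})

test_that("scenario files round-trip field-for-field", {
  b <- make_default_scenario(3)
  f <- withr::local_tempfile(fileext = ".json")
  write_scenario(b, f)
  b2 <- read_scenario(f)
  expect_equal(b2, b, tolerance = 1e-12)
  # and the round trip is idempotent at the byte level
  f2 <- withr::local_tempfile(fileext = ".json")
  write_scenario(b2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed scenario files are rejected with context", {
  b <- make_default_scenario(3)
  f <- withr::local_tempfile(fileext = ".json")
  # policy naming an unknown treatment
  b$policies$NP$tier_of <- c(b$policies$NP$tier_of, ghost_clinic = "low")
  expect_error(write_scenario(b, f), "ghost_clinic")
  writeLines("{not json", f)
  expect_error(read_scenario(f), "parse")
  writeLines("{}", f)
  expect_error(read_scenario(f), "schema_version")
})
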