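# Shared fixtures: tiny deterministic worlds for unit and property tests.
# Everything is built in code; no files are read.

# one-cause, one-treatment world with every rate controllable
tiny_bundle <- function(initial_size = 200,
                        base_incidence = 0.2,
                        transmission_coefficient = 0,
                        untreated_death_hazard = 0,
                        treated_death_hazard = 0,
                        untreated_duration = 0.1,
                        care_seeking_probability = 1,
                        emergency_probability = 0,
                        crude_birth_rate = 0,
                        background_hazard = 0,
                        capability_minutes = 1e9,
                        availability = 1,
                        effectiveness = 1,
                        horizon_years = 1,
                        disability_weight = 0.1,
                        initial_prevalence = 0,
                        master_seed = 42) {
  pop <- population_spec(
    initial_size = initial_size,
    age_distribution = data.frame(band = c("0-4", "5+"),
                                  lo = c(0, 5), hi = c(5, 70),
                                  prob = c(0.2, 0.8)),
    crude_birth_rate = crude_birth_rate,
    background_mortality = data.frame(band = c("0-4", "5+"),
                                      lo = c(0, 5), hi = c(5, 70),
                                      hazard = rep(background_hazard, 2)),
    national_population = initial_size * 10,
    flag_prevalence = list(hiv_diagnosed = 0, tb_diagnosed = 0,
                           unvaccinated = 0))
  causes <- list(flu = cause_spec(
    "flu", "infectious",
    base_incidence = base_incidence,
    transmission_coefficient = transmission_coefficient,
    disability_weight = disability_weight,
    untreated_death_hazard = untreated_death_hazard,
    treated_death_hazard = treated_death_hazard,
    untreated_duration = untreated_duration,
    care_seeking_probability = care_seeking_probability,
    emergency_probability = emergency_probability,
    initial_prevalence = initial_prevalence))
  trs <- list(flu_clinic = treatment_spec(
    "flu_clinic", "flu", "1a", c(nurse = 10),
    consumables = data.frame(item_id = "drug", availability = availability),
    effectiveness = effectiveness, alt_effectiveness = 0))
  caps <- data.frame(facility = "1a", cadre = "nurse",
                     minutes = capability_minutes)
  pols <- list(NP = policy("NP", c(flu_clinic = "low")))
  scenario_bundle(pop, causes, trs, caps, pols,
                  horizon_years = horizon_years, replicates = 1,
                  master_seed = master_seed)
}

# random single-day queue instance for oracle / monotonicity tests
random_day_instance <- function(seed, n_treatments = 4, n_episodes = 12,
                                n_cadres = 2) {
  set.seed(seed)
  cadres <- paste0("cadre", seq_len(n_cadres))
  trs <- lapply(seq_len(n_treatments), function(i) {
    k <- sample(n_cadres, sample(1:n_cadres, 1))
    treatment_spec(paste0("t", i), NA, "f1",
                   stats::setNames(round(stats::runif(length(k), 5, 60), 1),
                                   cadres[k]),
                   effectiveness = 1)
  })
  names(trs) <- vapply(trs, `[[`, "", "treatment_id")
  caps <- data.frame(facility = "f1", cadre = cadres,
                     minutes = round(stats::runif(n_cadres, 30, 150)))
  q <- data.frame(
    care_id = seq_len(n_episodes),
    person_id = sample(1000, n_episodes),
    treatment_id = sample(names(trs), n_episodes, replace = TRUE),
    facility = "f1",
    attempts_used = sample(0:3, n_episodes, replace = TRUE),
    priority = sample(0:3, n_episodes, replace = TRUE),
    first_seek_date = sample(0:5, n_episodes, replace = TRUE),
    tiebreak = stats::runif(n_episodes))
  list(treatments = trs, capabilities = caps, queue = q)
}

# independent brute-force reference for run_day: walk the sorted queue,
# deliver iff every required cadre has > 0 minutes remaining, commit the
# full footprint (no consumable failures: availability defaults to 1)
oracle_run_day <- function(queue, treatments, capabilities) {
  rem <- stats::setNames(capabilities$minutes, capabilities$cadre)
  ord <- order(queue$priority, queue$first_seek_date, queue$tiebreak,
               queue$person_id)
  delivered <- logical(nrow(queue))
  for (i in ord) {
    fp <- treatments[[queue$treatment_id[i]]]$footprint
    if (all(rem[names(fp)] > 0)) {
      rem[names(fp)] <- rem[names(fp)] - fp
      delivered[i] <- TRUE
    }
  }
  sort(queue$care_id[delivered])
}
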