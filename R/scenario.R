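# Synthetic scenario generation: population, cause and treatment
# catalogues, capability schedules and policies, bundled into a single
# serialisable, human-editable document.  The default bundle is the stated
# world for all structural tests: a dominant infectious cause with a
# declining trend and transmission feedback (so that withholding its
# treatment escalates incidence), a demographically rising child
# respiratory cause, a perinatal cause, an immunisation-sensitive
# infectious cause, a slow chronic cause, and a residual "other" cause not
# subject to resource constraints.

SCHEMA_VERSION <- 1L

#' Construct a population specification
#'
#' @param initial_size Number of simulated individuals at day 0 (>= 1).
#' @param age_distribution Data frame `band`, `lo`, `hi`, `prob`; band
#'   probabilities must sum to 1.
#' @param crude_birth_rate Births per person-year among alive,
#'   non-contracepting individuals.
#' @param background_mortality Data frame `band`, `lo`, `hi`, `hazard`:
#'   per-year all-other-cause death hazard by age band.
#' @param national_population Real-population count the reported DALY
#'   totals are scaled to (>= `initial_size`).
#' @param flag_prevalence Named list of initial prevalences for the
#'   `hiv_diagnosed`, `tb_diagnosed` and `unvaccinated` flags.
#' @return List of class `population_spec`.
#' @export
population_spec <- function(initial_size, age_distribution,
                            crude_birth_rate, background_mortality,
                            national_population,
                            flag_prevalence = list(hiv_diagnosed = 0.04,
                                                   tb_diagnosed = 0.015,
                                                   unvaccinated = 0.25)) {
  spec <- list(initial_size = as.integer(initial_size),
               age_distribution = age_distribution,
               crude_birth_rate = as.numeric(crude_birth_rate),
               background_mortality = background_mortality,
               national_population = as.numeric(national_population),
               flag_prevalence = flag_prevalence)
  class(spec) <- "population_spec"
  validate_population(spec)
  spec
}

validate_population <- function(spec) {
  fail <- function(field, msg)
    stop(sprintf("population: field '%s' %s", field, msg), call. = FALSE)
  if (is.na(spec$initial_size) || spec$initial_size < 1L)
    fail("initial_size", "must be >= 1")
  ad <- spec$age_distribution
  if (!all(c("band", "lo", "hi", "prob") %in% names(ad)))
    fail("age_distribution", "needs columns band, lo, hi, prob")
  if (abs(sum(ad$prob) - 1) > 1e-9)
    fail("age_distribution", "probabilities must sum to 1")
  if (any(ad$prob < 0)) fail("age_distribution", "probabilities must be >= 0")
  if (spec$crude_birth_rate < 0) fail("crude_birth_rate", "must be >= 0")
  if (any(spec$background_mortality$hazard < 0))
    fail("background_mortality", "hazards must be >= 0")
  if (spec$national_population < spec$initial_size)
    fail("national_population", "must be >= initial_size")
  pv <- unlist(spec$flag_prevalence)
  if (length(pv) && (any(pv < 0) || any(pv > 1)))
    fail("flag_prevalence", "must be probabilities in [0, 1]")
  invisible(spec)
}

#' Construct a cause specification
#'
#' A cause is one source of disease episodes with its own incidence,
#' natural history, disability weight and care-seeking behaviour.
#' Incidence is piecewise-linear in calendar year:
#' `h(year) = max(0, base_incidence + incidence_trend * (year - 1))`,
#' multiplied for infectious causes by
#' `1 + transmission_coefficient * prevalence of untreated active cases`.
#'
#' @param cause_id Label.
#' @param kind One of `"infectious"`, `"non-communicable"`, `"perinatal"`,
#'   `"other-residual"`.
#' @param base_incidence Per-person per-year hazard in simulation year 1.
#' @param incidence_trend Additive change in the hazard per elapsed year.
#' @param under5_multiplier Incidence multiplier for under-fives (1 =
#'   age-neutral, 0 = adults only).
#' @param transmission_coefficient Dimensionless coupling of incidence to
#'   untreated prevalence; must be 0 unless `kind == "infectious"`.
#' @param disability_weight Disability weight in `[0, 1]`.
#' @param untreated_death_hazard,treated_death_hazard Per-year death hazard
#'   while the episode is ongoing; treated must not exceed untreated.
#' @param untreated_duration,treated_duration Episode duration in years
#'   (deterministic; treated episodes resolve no later).
#' @param risk_modifiers Named numeric vector, person flag -> multiplier on
#'   the death hazard (e.g. `c(unvaccinated = 3)`).
#' @param care_seeking_probability Probability an incident routine episode
#'   seeks care; emergencies always seek care the same day.
#' @param emergency_probability Probability an incident episode presents as
#'   an emergency.
#' @param reinfection_multiplier Incidence multiplier after a prior
#'   recovery from this cause (prior-treatment/natural-immunity effect).
#' @param requires_flag Flag a person must hold to be at risk (`NA` for
#'   none); e.g. perinatal causes apply to `fertile` individuals.
#' @param resource_constrained `FALSE` for residual causes whose burden is
#'   accounted but not mediated by the healthcare system.
#' @param initial_prevalence Fraction of the at-risk population starting
#'   the simulation with a prevalent untreated episode (chronic causes).
#' @return List of class `cause_spec`.
#' @export
cause_spec <- function(cause_id, kind, base_incidence, incidence_trend = 0,
                       under5_multiplier = 1, transmission_coefficient = 0,
                       disability_weight = 0.1,
                       untreated_death_hazard = 0,
                       treated_death_hazard = 0,
                       untreated_duration = 1, treated_duration = NULL,
                       risk_modifiers = numeric(),
                       care_seeking_probability = 0.8,
                       emergency_probability = 0,
                       reinfection_multiplier = 1,
                       requires_flag = NA_character_,
                       resource_constrained = TRUE,
                       initial_prevalence = 0) {
  if (is.null(treated_duration)) treated_duration <- untreated_duration
  if (!length(risk_modifiers)) risk_modifiers <- numeric()  # drop names
  spec <- list(cause_id = as.character(cause_id),
               kind = as.character(kind),
               base_incidence = as.numeric(base_incidence),
               incidence_trend = as.numeric(incidence_trend),
               under5_multiplier = as.numeric(under5_multiplier),
               transmission_coefficient = as.numeric(transmission_coefficient),
               disability_weight = as.numeric(disability_weight),
               untreated_death_hazard = as.numeric(untreated_death_hazard),
               treated_death_hazard = as.numeric(treated_death_hazard),
               untreated_duration = as.numeric(untreated_duration),
               treated_duration = as.numeric(treated_duration),
               risk_modifiers = risk_modifiers,
               care_seeking_probability = as.numeric(care_seeking_probability),
               emergency_probability = as.numeric(emergency_probability),
               reinfection_multiplier = as.numeric(reinfection_multiplier),
               requires_flag = as.character(requires_flag),
               resource_constrained = isTRUE(resource_constrained),
               initial_prevalence = as.numeric(initial_prevalence))
  class(spec) <- "cause_spec"
  validate_cause(spec)
  spec
}

validate_cause <- function(spec) {
  fail <- function(field, msg)
    stop(sprintf("cause '%s': field '%s' %s", spec$cause_id, field, msg),
         call. = FALSE)
  kinds <- c("infectious", "non-communicable", "perinatal", "other-residual")
  if (!spec$kind %in% kinds)
    fail("kind", sprintf("must be one of %s", paste(kinds, collapse = ", ")))
  if (spec$disability_weight < 0 || spec$disability_weight > 1)
    fail("disability_weight", "must be in [0, 1]")
  for (f in c("base_incidence", "under5_multiplier",
              "untreated_death_hazard", "treated_death_hazard",
              "untreated_duration", "treated_duration",
              "reinfection_multiplier"))
    if (spec[[f]] < 0) fail(f, "must be >= 0")
  if (spec$treated_death_hazard > spec$untreated_death_hazard)
    fail("treated_death_hazard", "must not exceed untreated_death_hazard")
  if (spec$transmission_coefficient != 0 && spec$kind != "infectious")
    fail("transmission_coefficient", "must be 0 for non-infectious causes")
  if (spec$transmission_coefficient < 0)
    fail("transmission_coefficient", "must be >= 0")
  for (f in c("care_seeking_probability", "emergency_probability",
              "initial_prevalence"))
    if (spec[[f]] < 0 || spec[[f]] > 1) fail(f, "must be in [0, 1]")
  if (length(spec$risk_modifiers) &&
      (is.null(names(spec$risk_modifiers)) || any(spec$risk_modifiers < 0)))
    fail("risk_modifiers", "must be a named non-negative vector")
  invisible(spec)
}

#' Assemble and validate a scenario bundle
#'
#' @param population A `population_spec`.
#' @param causes Named list of `cause_spec`.
#' @param treatments Named list of `treatment_spec`.
#' @param capabilities Data frame `facility`, `cadre`, `minutes`.
#' @param policies Named list of `policy`.
#' @param horizon_years Simulated horizon (>= 1).
#' @param replicates Monte-Carlo replicates (>= 1).
#' @param master_seed Integer master seed; all run randomness derives from
#'   it via [stream_seed()].
#' @param start_year First calendar year of the horizon (labelling only).
#' @param branch_probs Consumable branch probabilities
#'   (substituted, repeat visit, default from care).
#' @param max_attempts Maximum consecutive care-seeking attempts.
#' @param reference_life_expectancy Years; reference for YLL.
#' @return List of class `scenario_bundle`.
#' @export
scenario_bundle <- function(population, causes, treatments, capabilities,
                            policies, horizon_years, replicates,
                            master_seed, start_year = 2023,
                            branch_probs = c(substituted = 0.5,
                                             repeat_visit = 0.3,
                                             default_from_care = 0.2),
                            max_attempts = 7,
                            reference_life_expectancy = 70) {
  b <- list(schema_version = SCHEMA_VERSION,
            population = population,
            causes = causes,
            treatments = treatments,
            capabilities = capabilities,
            policies = policies,
            horizon_years = as.integer(horizon_years),
            replicates = as.integer(replicates),
            master_seed = as.integer(master_seed),
            start_year = as.integer(start_year),
            branch_probs = branch_probs,
            max_attempts = as.integer(max_attempts),
            reference_life_expectancy = as.numeric(reference_life_expectancy))
  class(b) <- "scenario_bundle"
  validate_bundle(b)
  b
}

#' Validate a scenario bundle against all type and referential invariants
#'
#' @param b A `scenario_bundle`.
#' @return The bundle, invisibly; errors name the offending field.
#' @export
validate_bundle <- function(b) {
  fail <- function(msg) stop(sprintf("scenario bundle: %s", msg),
                             call. = FALSE)
  validate_population(b$population)
  if (!length(b$causes)) fail("field 'causes' must be a non-empty list")
  for (cs in b$causes) validate_cause(cs)
  if (!length(b$treatments)) fail("field 'treatments' must be non-empty")
  for (tr in b$treatments) validate_treatment(tr)
  cause_ids <- vapply(b$causes, `[[`, "", "cause_id")
  for (tr in b$treatments) {
    if (!is.na(tr$target_cause) && !tr$target_cause %in% cause_ids)
      fail(sprintf("treatment '%s' targets unknown cause '%s'",
                   tr$treatment_id, tr$target_cause))
  }
  # every (facility_level, cadre) referenced by a footprint has capability
  for (tr in b$treatments) {
    for (cad in names(tr$footprint)) {
      hit <- b$capabilities$facility == tr$facility_level &
        b$capabilities$cadre == cad
      if (!any(hit))
        fail(sprintf("no capability entry for facility '%s', cadre '%s' (treatment '%s')",
                     tr$facility_level, cad, tr$treatment_id))
    }
  }
  if (any(b$capabilities$minutes < 0)) fail("capability minutes must be >= 0")
  tids <- names(b$treatments)
  for (p in b$policies) {
    validate_policy(p)
    bad <- setdiff(c(names(p$tier_of), p$excluded, names(p$fasttrack)), tids)
    if (length(bad))
      fail(sprintf("policy '%s' references unknown treatment(s): %s",
                   p$policy_id, paste(bad, collapse = ", ")))
  }
  if (b$horizon_years < 1L) fail("field 'horizon_years' must be >= 1")
  if (b$replicates < 1L) fail("field 'replicates' must be >= 1")
  if (length(b$branch_probs) != 3 || abs(sum(b$branch_probs) - 1) > 1e-9 ||
      any(b$branch_probs < 0))
    fail("field 'branch_probs' must be 3 probabilities summing to 1")
  if (b$max_attempts < 1L) fail("field 'max_attempts' must be >= 1")
  if (b$reference_life_expectancy <= 0)
    fail("field 'reference_life_expectancy' must be > 0")
  invisible(b)
}

#' Default cause catalogue
#'
#' Six causes engineered to reproduce the structural features the policy
#' analysis depends on: `hiv` (initially dominant, chronic, infectious with
#' strong transmission feedback and a declining incidence trend), `lri`
#' (acute child respiratory infections with a rising trend -- overtakes
#' `hiv` as leading DALY cause within the horizon), `neonatal` (perinatal
#' episodes among fertile individuals), `measles` (vaccine-preventable,
#' with an unvaccinated-risk modifier on mortality), `cmd` (slow chronic
#' cardiometabolic disease) and `other` (residual burden, not subject to
#' resource constraints).
#'
#' @return Named list of `cause_spec`.
#' @export
build_default_causes <- function() {
  specs <- list(
    cause_spec("hiv", "infectious",
               base_incidence = 0.035, incidence_trend = -0.0012,
               under5_multiplier = 0.3, transmission_coefficient = 3,
               disability_weight = 0.27,
               untreated_death_hazard = 0.2, treated_death_hazard = 0.006,
               untreated_duration = 4, treated_duration = 4,
               care_seeking_probability = 0.85,
               emergency_probability = 0.05,
               reinfection_multiplier = 1,
               initial_prevalence = 0.20),
    cause_spec("lri", "infectious",
               base_incidence = 0.055, incidence_trend = 0.005,
               under5_multiplier = 5, transmission_coefficient = 0.5,
               disability_weight = 0.13,
               untreated_death_hazard = 1.2, treated_death_hazard = 0.12,
               untreated_duration = 0.04, treated_duration = 0.02,
               risk_modifiers = c(under5 = 4),
               care_seeking_probability = 0.8,
               emergency_probability = 0.10,
               reinfection_multiplier = 1),
    cause_spec("neonatal", "perinatal",
               base_incidence = 0.12, incidence_trend = 0.002,
               under5_multiplier = 0,
               disability_weight = 0.30,
               untreated_death_hazard = 1.5, treated_death_hazard = 0.15,
               untreated_duration = 0.08, treated_duration = 0.05,
               care_seeking_probability = 0.9,
               emergency_probability = 0.25,
               requires_flag = "fertile"),
    cause_spec("measles", "infectious",
               base_incidence = 0.02, incidence_trend = 0,
               under5_multiplier = 4, transmission_coefficient = 3,
               disability_weight = 0.15,
               untreated_death_hazard = 0.5, treated_death_hazard = 0.1,
               untreated_duration = 0.05, treated_duration = 0.03,
               risk_modifiers = c(unvaccinated = 3),
               care_seeking_probability = 0.7,
               emergency_probability = 0.05,
               reinfection_multiplier = 0.05),
    cause_spec("cmd", "non-communicable",
               base_incidence = 0.012, incidence_trend = 0.0004,
               under5_multiplier = 0,
               disability_weight = 0.22,
               untreated_death_hazard = 0.05, treated_death_hazard = 0.015,
               untreated_duration = 15, treated_duration = 15,
               care_seeking_probability = 0.6,
               emergency_probability = 0.08,
               initial_prevalence = 0.05),
    cause_spec("other", "other-residual",
               base_incidence = 0.06, incidence_trend = 0,
               disability_weight = 0.10,
               untreated_death_hazard = 0.02,
               untreated_duration = 1,
               care_seeking_probability = 0,
               resource_constrained = FALSE)
  )
  names(specs) <- vapply(specs, `[[`, "", "cause_id")
  specs
}

#' Default population specification
#'
#' A young, high-fertility population (broad-based age pyramid) at desk
#' scale:
#' 4,000 simulated individuals standing in for a national population of
#' 580,000 (scale factor 145, the ratio used when a 100,000-person
#' simulation represents 14.5 million people).
#'
#' @return A `population_spec`.
#' @export
build_default_population <- function() {
  population_spec(
    initial_size = 4000,
    age_distribution = data.frame(
      band = c("0-4", "5-14", "15-49", "50+"),
      lo = c(0, 5, 15, 50), hi = c(5, 15, 50, 90),
      prob = c(0.17, 0.27, 0.43, 0.13)),
    crude_birth_rate = 0.033,
    background_mortality = data.frame(
      band = c("0-4", "5-14", "15-49", "50+"),
      lo = c(0, 5, 15, 50), hi = c(5, 15, 50, 90),
      hazard = c(0.008, 0.0015, 0.004, 0.035)),
    national_population = 580000)
}

#' Build the default synthetic scenario bundle
#'
#' The fully populated, self-validating default world: six causes, twelve
#' treatments over three facility levels and three cadres (including
#' emergency and preventive services), the default capability schedule, and
#' all seven policy presets. Deterministic: the same master seed always
#' yields an identical bundle.
#'
#' @param master_seed Integer master seed recorded in the bundle.
#' @param horizon_years,replicates Experiment defaults (20 years, 10
#'   replicates).
#' @param initial_size Optional override of the default population size;
#'   the national population is rescaled to keep the scale factor at 145
#'   and capability minutes are rescaled proportionally, so the
#'   demand-to-capacity ratio (the quantity that drives queue dynamics) is
#'   preserved at any desk scale.
#' @return A validated `scenario_bundle`.
#' @export
make_default_scenario <- function(master_seed, horizon_years = 20,
                                  replicates = 10, initial_size = NULL) {
  pop <- build_default_population()
  caps <- build_default_capabilities()
  if (!is.null(initial_size)) {
    scale <- as.integer(initial_size) / pop$initial_size
    pop$initial_size <- as.integer(initial_size)
    pop$national_population <- 145 * pop$initial_size
    caps$minutes <- caps$minutes * scale
  }
  scenario_bundle(
    population = pop,
    causes = build_default_causes(),
    treatments = build_default_footprints(),
    capabilities = caps,
    policies = policy_presets(build_default_footprints()),
    horizon_years = horizon_years,
    replicates = replicates,
    master_seed = master_seed)
}

#' Sample an initial population
#'
#' Ages are drawn from the banded age distribution (uniform within band),
#' sexes equiprobably, and the diagnosed/vaccination flags at their
#' configured prevalences. The `under5` category is not stored: it is
#' recomputed from age whenever used. `fertile` marks females aged 15-49
#' (the risk group for perinatal episodes and the population whose births
#' contraception averts).
#'
#' @param spec A `population_spec`.
#' @param seed Integer seed.
#' @return Data frame with one row per person: `person_id`, `birth_day`
#'   (negative = born before day 0), `alive`, `sex`, and logical flag
#'   columns `pregnant`, `hiv_diagnosed`, `tb_diagnosed`, `unvaccinated`,
#'   `contracepting`.
#' @export
sample_population <- function(spec, seed) {
  validate_population(spec)
  set.seed(seed)
  n <- spec$initial_size
  ad <- spec$age_distribution
  band <- sample.int(nrow(ad), n, replace = TRUE, prob = ad$prob)
  age <- ad$lo[band] + stats::runif(n) * (ad$hi[band] - ad$lo[band])
  pv <- spec$flag_prevalence
  data.frame(
    person_id = seq_len(n),
    birth_day = -round(age * 365),
    alive = TRUE,
    sex = sample(c("f", "m"), n, replace = TRUE),
    pregnant = FALSE,
    hiv_diagnosed = stats::runif(n) < (pv$hiv_diagnosed %||% 0),
    tb_diagnosed = stats::runif(n) < (pv$tb_diagnosed %||% 0),
    unvaccinated = stats::runif(n) < (pv$unvaccinated %||% 0),
    contracepting = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Serialization: one JSON document per bundle, schema-versioned, diffable.

#' Write a scenario bundle to a JSON document
#'
#' @param bundle A `scenario_bundle`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(bundle, path) {
  validate_bundle(bundle)
  named_list <- function(x)  # empty named vectors stay JSON objects
    if (length(x)) as.list(x) else structure(list(), names = character())
  ser <- unclass(bundle)
  ser$population <- unclass(ser$population)
  ser$causes <- lapply(ser$causes, function(cs) {
    cs <- unclass(cs)
    cs$risk_modifiers <- named_list(cs$risk_modifiers)
    cs
  })
  ser$treatments <- lapply(ser$treatments, function(tr) {
    tr <- unclass(tr)
    tr$footprint <- named_list(tr$footprint)
    tr
  })
  ser$policies <- lapply(ser$policies, function(p) {
    p <- unclass(p)
    p$tier_of <- named_list(p$tier_of)
    p
  })
  ser$branch_probs <- as.list(ser$branch_probs)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read and validate a scenario bundle from a JSON document
#'
#' Round-trip identity with [write_scenario()]: reading a written bundle
#' reproduces it field-for-field. Malformed or referentially inconsistent
#' files raise errors naming the offending field.
#'
#' @param path File path.
#' @return A validated `scenario_bundle`.
#' @export
read_scenario <- function(path) {
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = TRUE),
    error = function(e) stop(sprintf("cannot parse scenario file '%s': %s",
                                     path, conditionMessage(e)),
                             call. = FALSE))
  if (is.null(raw$schema_version))
    stop(sprintf("scenario file '%s': missing field 'schema_version'", path),
         call. = FALSE)
  num_vec <- function(x) {
    v <- unlist(x)
    if (is.null(v)) stats::setNames(numeric(), character()) else v
  }
  pop <- raw$population
  pop$flag_prevalence <- as.list(pop$flag_prevalence)
  population <- population_spec(pop$initial_size, pop$age_distribution,
                                pop$crude_birth_rate,
                                pop$background_mortality,
                                pop$national_population,
                                pop$flag_prevalence)
  causes <- lapply(raw$causes, function(cs) {
    cause_spec(cs$cause_id, cs$kind, cs$base_incidence, cs$incidence_trend,
               cs$under5_multiplier, cs$transmission_coefficient,
               cs$disability_weight, cs$untreated_death_hazard,
               cs$treated_death_hazard, cs$untreated_duration,
               cs$treated_duration, num_vec(cs$risk_modifiers),
               cs$care_seeking_probability, cs$emergency_probability,
               cs$reinfection_multiplier,
               cs$requires_flag %||% NA_character_,
               cs$resource_constrained,
               cs$initial_prevalence %||% 0)
  })
  treatments <- lapply(raw$treatments, function(tr) {
    cons <- tr$consumables
    if (is.null(cons) || !length(cons))
      cons <- data.frame(item_id = character(), availability = numeric())
    treatment_spec(tr$treatment_id, tr$target_cause, tr$facility_level,
                   num_vec(tr$footprint), tr$emergency, tr$preventive,
                   tr$clears_flag %||% NA_character_,
                   tr$sets_flag %||% NA_character_,
                   tr$demand_rate, cons, tr$effectiveness,
                   tr$alt_effectiveness)
  })
  policies <- lapply(raw$policies, function(p) {
    ft <- lapply(p$fasttrack, unlist)
    policy(p$policy_id,
           stats::setNames(unlist(p$tier_of), names(p$tier_of)),
           unlist(p$excluded) %||% character(), ft)
  })
  scenario_bundle(population, causes, treatments, raw$capabilities,
                  policies, raw$horizon_years, raw$replicates,
                  raw$master_seed, raw$start_year, num_vec(raw$branch_probs),
                  raw$max_attempts, raw$reference_life_expectancy)
}
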