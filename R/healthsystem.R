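# Supply side: treatment specifications (per-cadre minute footprints),
# facility capability schedules, the daily capability ledger, and the
# stochastic consumable-availability model.

#' Construct a treatment specification
#'
#' A treatment is one type of healthcare system interaction (HSI): a service
#' delivered at one facility level with a fixed time footprint on one or
#' more healthcare-worker cadres. Footprints are rigid: an HSI always takes
#' its full stated minutes and cannot be shortened.
#'
#' @param treatment_id Label, unique within the catalogue.
#' @param target_cause Cause id the treatment addresses (`NA` for purely
#'   preventive services not tied to an episode-generating cause).
#' @param facility_level Facility level label, e.g. `"1a"`, `"1b"`, `"2"`.
#' @param footprint Named numeric vector, cadre -> minutes required (> 0).
#' @param emergency Logical; emergency HSIs receive engine-reserved top
#'   priority tiers that policies cannot alter.
#' @param preventive Logical; preventive HSIs act on a person's risk flags
#'   rather than on a disease episode.
#' @param clears_flag,sets_flag For preventive treatments, the person flag
#'   cleared (e.g. `"unvaccinated"`) or set (e.g. `"contracepting"`) on
#'   effective delivery; `NA` otherwise.
#' @param demand_rate For preventive treatments, per-person per-year rate at
#'   which eligible individuals seek the service; 0 for curative ones.
#' @param consumables Data frame with columns `item_id`,
#'   `availability` (per-attempt probability each item is in stock).
#' @param effectiveness Probability a delivered HSI converts the episode to
#'   treated status (or applies the flag effect).
#' @param alt_effectiveness Effectiveness when delivered with substituted
#'   consumables; must not exceed `effectiveness`.
#' @return A list of class `treatment_spec`.
#' @export
treatment_spec <- function(treatment_id, target_cause, facility_level,
                           footprint, emergency = FALSE, preventive = FALSE,
                           clears_flag = NA_character_,
                           sets_flag = NA_character_,
                           demand_rate = 0,
                           consumables = data.frame(item_id = character(),
                                                    availability = numeric()),
                           effectiveness = 0.9,
                           alt_effectiveness = 0.6) {
  spec <- list(
    treatment_id = as.character(treatment_id),
    target_cause = as.character(target_cause),
    facility_level = as.character(facility_level),
    footprint = footprint,
    emergency = isTRUE(emergency),
    preventive = isTRUE(preventive),
    clears_flag = as.character(clears_flag),
    sets_flag = as.character(sets_flag),
    demand_rate = as.numeric(demand_rate),
    consumables = consumables,
    effectiveness = as.numeric(effectiveness),
    alt_effectiveness = as.numeric(alt_effectiveness)
  )
  class(spec) <- "treatment_spec"
  validate_treatment(spec)
  spec
}

validate_treatment <- function(spec) {
  fail <- function(field, msg) {
    stop(sprintf("treatment '%s': field '%s' %s", spec$treatment_id, field,
                 msg), call. = FALSE)
  }
  if (!length(spec$footprint) || is.null(names(spec$footprint)) ||
      any(!nzchar(names(spec$footprint))))
    fail("footprint", "must be a named cadre -> minutes vector")
  if (any(spec$footprint <= 0)) fail("footprint", "minutes must all be > 0")
  for (f in c("effectiveness", "alt_effectiveness")) {
    v <- spec[[f]]
    if (!is.finite(v) || v < 0 || v > 1) fail(f, "must be in [0, 1]")
  }
  if (spec$alt_effectiveness > spec$effectiveness)
    fail("alt_effectiveness", "must not exceed effectiveness")
  av <- spec$consumables$availability
  if (length(av) && (any(av < 0) || any(av > 1)))
    fail("consumables", "availability probabilities must be in [0, 1]")
  if (spec$demand_rate < 0) fail("demand_rate", "must be >= 0")
  invisible(spec)
}

#' Default synthetic treatment catalogue
#'
#' Twelve treatments over three facility levels (1a, 1b, 2) and three cadres
#' (clinical officer, nurse, pharmacist), covering curative, emergency and
#' preventive services for the default six-cause scenario. The catalogue
#' includes the canonical worked example: a standard outpatient appointment
#' for a patient over five at level 1a requiring 27 minutes of clinical
#' officer time, 18 minutes of nurse time and 9.5 minutes of pharmacist
#' time.
#'
#' @return Named list of `treatment_spec` objects.
#' @export
build_default_footprints <- function() {
  cons <- function(ids, avail) data.frame(item_id = ids, availability = avail)
  specs <- list(
    treatment_spec("hiv_treatment", "hiv", "1b",
      c(clinical_officer = 20, nurse = 15, pharmacist = 10),
      consumables = cons("arv_drugs", 0.90),
      effectiveness = 0.95, alt_effectiveness = 0.55),
    treatment_spec("hiv_emergency_care", "hiv", "2",
      c(clinical_officer = 30, nurse = 30, pharmacist = 10),
      emergency = TRUE,
      consumables = cons(c("arv_drugs", "iv_fluids"), c(0.90, 0.85)),
      effectiveness = 0.85, alt_effectiveness = 0.50),
    treatment_spec("outpatient_over5", "lri", "1a",
      c(clinical_officer = 27, nurse = 18, pharmacist = 9.5),
      consumables = cons("antibiotics", 0.80),
      effectiveness = 0.90, alt_effectiveness = 0.60),
    treatment_spec("outpatient_under5", "lri", "1a",
      c(clinical_officer = 20, nurse = 15, pharmacist = 7),
      consumables = cons("antibiotics", 0.80),
      effectiveness = 0.90, alt_effectiveness = 0.60),
    treatment_spec("lri_emergency_admission", "lri", "2",
      c(clinical_officer = 40, nurse = 60, pharmacist = 10),
      emergency = TRUE,
      consumables = cons(c("antibiotics", "oxygen"), c(0.80, 0.70)),
      effectiveness = 0.85, alt_effectiveness = 0.45),
    treatment_spec("perinatal_delivery_care", "neonatal", "1b",
      c(clinical_officer = 30, nurse = 90),
      consumables = cons(c("delivery_kit", "oxytocin"), c(0.75, 0.70)),
      effectiveness = 0.85, alt_effectiveness = 0.55),
    treatment_spec("neonatal_emergency_care", "neonatal", "2",
      c(clinical_officer = 45, nurse = 60, pharmacist = 5),
      emergency = TRUE,
      consumables = cons(c("delivery_kit", "oxygen"), c(0.75, 0.70)),
      effectiveness = 0.80, alt_effectiveness = 0.45),
    treatment_spec("measles_treatment", "measles", "1a",
      c(clinical_officer = 15, nurse = 10, pharmacist = 5),
      consumables = cons("vitamin_a", 0.85),
      effectiveness = 0.90, alt_effectiveness = 0.60),
    treatment_spec("measles_vaccination", "measles", "1a",
      c(nurse = 8, pharmacist = 2),
      preventive = TRUE, clears_flag = "unvaccinated", demand_rate = 0.30,
      consumables = cons("measles_vaccine", 0.85),
      effectiveness = 0.95, alt_effectiveness = 0.0),
    treatment_spec("contraception_services", "neonatal", "1a",
      c(nurse = 12, pharmacist = 4),
      preventive = TRUE, sets_flag = "contracepting", demand_rate = 0.10,
      consumables = cons("contraceptives", 0.85),
      effectiveness = 0.90, alt_effectiveness = 0.40),
    treatment_spec("cmd_management", "cmd", "1b",
      c(clinical_officer = 25, nurse = 10, pharmacist = 8),
      consumables = cons("antihypertensives", 0.80),
      effectiveness = 0.85, alt_effectiveness = 0.50),
    treatment_spec("cmd_emergency_care", "cmd", "2",
      c(clinical_officer = 35, nurse = 40, pharmacist = 10),
      emergency = TRUE,
      consumables = cons(c("antihypertensives", "iv_fluids"), c(0.80, 0.85)),
      effectiveness = 0.80, alt_effectiveness = 0.45)
  )
  names(specs) <- vapply(specs, `[[`, "", "treatment_id")
  specs
}

#' Default capability schedule
#'
#' Daily minutes per (facility, cadre); one facility per level. Constant
#' over the whole horizon (capabilities are not assumed to grow with the
#' population), which is the source of the demographic-divergence
#' diagnostic exposed by the experiment module.
#'
#' @return Data frame with columns `facility`, `cadre`, `minutes`.
#' @export
build_default_capabilities <- function() {
  data.frame(
    facility = rep(c("1a", "1b", "2"), each = 3),
    cadre = rep(c("clinical_officer", "nurse", "pharmacist"), times = 3),
    minutes = c(
      15, 17,  7,   # 1a: outpatient, measles, vaccination, contraception
      20, 28,  8,   # 1b: HIV treatment, perinatal care, CMD management
      16, 22,  4    # 2: emergency admissions
    )
  )
}

# ---------------------------------------------------------------------------
# Capability ledger: per-day remaining minutes, reset from the schedule at
# each day boundary.  Balances may go negative: overtime is sanctioned only
# to complete the last HSI of the day, which the delivery rule realises as
# "deliverable iff every required cadre has remaining minutes > 0; commit
# the full footprint afterwards".

#' Initialise a capability ledger for one day
#'
#' @param capabilities Data frame `facility`, `cadre`, `minutes`.
#' @return An environment holding matrices `schedule` and `remaining`
#'   (rows = facilities, cols = cadres).
#' @export
new_day_ledger <- function(capabilities) {
  stopifnot(all(c("facility", "cadre", "minutes") %in% names(capabilities)))
  if (any(capabilities$minutes < 0))
    stop("capability minutes must be >= 0", call. = FALSE)
  facs <- unique(capabilities$facility)
  cads <- unique(capabilities$cadre)
  m <- matrix(NA_real_, length(facs), length(cads),
              dimnames = list(facs, cads))
  m[cbind(match(capabilities$facility, facs),
          match(capabilities$cadre, cads))] <- capabilities$minutes
  led <- new.env(parent = emptyenv())
  led$schedule <- m
  led$remaining <- m
  led
}

#' Remaining minutes for one facility/cadre today
#'
#' May be negative after the sanctioned last-HSI overtime.
#'
#' @param ledger Ledger from [new_day_ledger()].
#' @param facility Facility id.
#' @param cadre Cadre label.
#' @return Numeric minutes remaining (capability minus minutes committed).
#' @export
remaining_minutes <- function(ledger, facility, cadre) {
  if (!facility %in% rownames(ledger$remaining) ||
      !cadre %in% colnames(ledger$remaining) ||
      is.na(ledger$schedule[facility, cadre]))
    stop(sprintf("no capability entry for facility '%s', cadre '%s'",
                 facility, cadre), call. = FALSE)
  ledger$remaining[facility, cadre]
}

# reset remaining balances to the schedule (day boundary)
reset_ledger <- function(ledger) {
  ledger$remaining <- ledger$schedule
  invisible(ledger)
}

#' Draw the consumable outcome for one HSI attempt
#'
#' Every required item is drawn independently at its availability
#' probability. If all are in stock the outcome is `"available"`; otherwise
#' one of `"substituted"`, `"repeat_visit"` or `"default_from_care"` is
#' sampled from `branch_probs`. Draws are per attempt: a repeat visit
#' re-draws on its next attempt.
#'
#' @param spec A `treatment_spec`.
#' @param branch_probs Numeric length-3 probability vector over
#'   (substituted, repeat_visit, default_from_care), summing to 1.
#' @param u_items Optional uniforms, one per consumable item (defaults to
#'   fresh `runif` draws); supply keyed uniforms for order-independence.
#' @param u_branch Optional uniform for the branch draw.
#' @return One of `"available"`, `"substituted"`, `"repeat_visit"`,
#'   `"default_from_care"`.
#' @export
draw_consumables <- function(spec, branch_probs, u_items = NULL,
                             u_branch = NULL) {
  if (length(branch_probs) != 3 || any(branch_probs < 0) ||
      abs(sum(branch_probs) - 1) > 1e-9)
    stop("branch_probs must be 3 non-negative probabilities summing to 1",
         call. = FALSE)
  avail <- spec$consumables$availability
  n <- length(avail)
  if (n == 0L) return("available")
  if (is.null(u_items)) u_items <- stats::runif(n)
  if (all(u_items[seq_len(n)] < avail)) return("available")
  if (is.null(u_branch)) u_branch <- stats::runif(1)
  branches <- c("substituted", "repeat_visit", "default_from_care")
  branches[findInterval(u_branch, cumsum(branch_probs),
                        rightmost.closed = TRUE) + 1L]
}
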