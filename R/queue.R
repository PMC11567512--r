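# Demand-side mediation: prioritisation policies, the strict total order on
# the daily facility queue, rigid capability-constrained delivery, and
# bounded care-seeking persistence.
#
# Engine priority tiers (smaller = served earlier):
#   0  emergency, patient under five
#   1  emergency, all other patients
#   2  high (policy-assigned, or promoted via a fast-track rule)
#   3  low
# Tiers 0 and 1 are reserved by the engine: policies only control how
# non-emergency treatments are prioritised (high/low), which patients are
# fast-tracked, and which treatments are excluded outright.

#' Vulnerable patient categories eligible for fast-tracking
#' @export
VULNERABLE_FLAGS <- c("under5", "pregnant", "hiv_diagnosed", "tb_diagnosed")

#' Construct a prioritisation policy
#'
#' A policy is a declarative statement of relative priority: a high/low tier
#' for every non-emergency treatment, an optional set of excluded treatments
#' (never delivered, consuming no capability), and optional fast-track rules
#' promoting members of vulnerable categories to the high tier for specific
#' treatments.
#'
#' @param policy_id Label.
#' @param tier_of Named character vector, treatment id -> `"high"`/`"low"`,
#'   covering every non-excluded, non-emergency treatment.
#' @param excluded Character vector of treatment ids excluded from delivery.
#' @param fasttrack Named list, treatment id -> character vector of
#'   vulnerable-category flags whose members are promoted to high tier.
#' @return A list of class `policy`.
#' @export
policy <- function(policy_id, tier_of, excluded = character(),
                   fasttrack = list()) {
  p <- list(policy_id = as.character(policy_id),
            tier_of = tier_of,
            excluded = as.character(excluded),
            fasttrack = fasttrack)
  class(p) <- "policy"
  validate_policy(p)
  p
}

validate_policy <- function(p) {
  fail <- function(msg) stop(sprintf("policy '%s': %s", p$policy_id, msg),
                             call. = FALSE)
  if (length(p$tier_of) && is.null(names(p$tier_of)))
    fail("tier_of must be named by treatment id")
  if (!all(p$tier_of %in% c("high", "low")))
    fail("tiers must be 'high' or 'low'")
  bad <- intersect(p$excluded, names(p$tier_of))
  if (length(bad))
    fail(sprintf("excluded treatments must not carry tiers: %s",
                 paste(bad, collapse = ", ")))
  badft <- intersect(names(p$fasttrack), p$excluded)
  if (length(badft))
    fail(sprintf("fasttrack references excluded treatments: %s",
                 paste(badft, collapse = ", ")))
  if (length(p$fasttrack)) {
    flags <- unique(unlist(p$fasttrack))
    bad <- setdiff(flags, VULNERABLE_FLAGS)
    if (length(bad))
      fail(sprintf("unknown vulnerable categories: %s",
                   paste(bad, collapse = ", ")))
  }
  invisible(p)
}

#' The seven shipped prioritisation-policy presets
#'
#' Encodes, against a treatment catalogue, the seven policy archetypes
#' evaluated in the analysis: `NP` (benchmark equal priority), `LCOA`
#' (selective high tier plus outright exclusion of HIV treatment), `HSSP3`
#' (broad strategic-plan package), `VP` (vertical programmes: HIV, measles
#' and immunisation services), `RMNCH` (reproductive/maternal/neonatal/child
#' services), `CMD` (cardiometabolic disorders) and `CV` (patient-centred:
#' every treatment fast-tracked for all vulnerable categories).
#'
#' @param treatments Treatment catalogue (named list of `treatment_spec`),
#'   default [build_default_footprints()].
#' @return Named list of `policy` objects.
#' @export
policy_presets <- function(treatments = build_default_footprints()) {
  non_emerg <- names(treatments)[!vapply(treatments, `[[`, TRUE, "emergency")]
  tiers <- function(high = character(), excluded = character()) {
    ids <- setdiff(non_emerg, excluded)
    stats::setNames(ifelse(ids %in% high, "high", "low"), ids)
  }
  lcoa_excl <- "hiv_treatment"
  list(
    NP = policy("NP", tiers()),
    LCOA = policy("LCOA",
      tiers(high = c("outpatient_under5", "outpatient_over5",
                     "measles_vaccination", "measles_treatment"),
            excluded = lcoa_excl),
      excluded = lcoa_excl),
    HSSP3 = policy("HSSP3",
      tiers(high = c("outpatient_under5", "perinatal_delivery_care",
                     "hiv_treatment", "measles_vaccination"))),
    VP = policy("VP",
      tiers(high = c("hiv_treatment", "measles_vaccination",
                     "measles_treatment"))),
    RMNCH = policy("RMNCH",
      tiers(high = c("perinatal_delivery_care", "outpatient_under5",
                     "measles_vaccination", "measles_treatment",
                     "contraception_services"))),
    CMD = policy("CMD", tiers(high = "cmd_management")),
    CV = policy("CV", tiers(),
      fasttrack = stats::setNames(
        rep(list(VULNERABLE_FLAGS), length(non_emerg)), non_emerg))
  )
}

#' Assign the engine priority tier to one care episode
#'
#' Emergencies take the engine-reserved tiers (0 for under-fives, 1
#' otherwise) regardless of policy. Otherwise the episode gets tier 2 when
#' the policy marks the treatment high, or when the patient belongs to any
#' vulnerable category fast-tracked for that treatment; else tier 3.
#'
#' @param treatment_id Treatment requested.
#' @param policy A `policy`.
#' @param emergency Logical; is this an emergency HSI (emergency-flagged
#'   treatment or emergency-severity episode)?
#' @param under5 Logical; is the patient under five years old?
#' @param person_flags Character vector of the patient's current flags.
#' @return Integer tier in 0:3.
#' @export
assign_priority <- function(treatment_id, policy, emergency, under5,
                            person_flags = character()) {
  if (emergency) return(if (isTRUE(under5)) 0L else 1L)
  tier <- if (treatment_id %in% names(policy$tier_of))
    policy$tier_of[[treatment_id]] else NULL
  if (is.null(tier))
    stop(sprintf("policy '%s' assigns no tier to treatment '%s'",
                 policy$policy_id, treatment_id), call. = FALSE)
  ft <- policy$fasttrack[[treatment_id]]
  flags <- c(person_flags, if (isTRUE(under5)) "under5")
  if (identical(tier, "high") || (length(ft) && any(flags %in% ft)))
    2L else 3L
}

#' Exclusion filter applied before an episode can enter any queue
#'
#' @param treatment_id Treatment requested.
#' @param policy A `policy`.
#' @return `"excluded"` if the policy excludes the treatment (the episode
#'   never queues and consumes no capability), else `"queued"`.
#' @export
apply_policy_filter <- function(treatment_id, policy) {
  if (treatment_id %in% policy$excluded) "excluded" else "queued"
}

#' Order a day's queue at one facility
#'
#' Strict total order: priority tier ascending, then first-seek date
#' ascending (patients seeking care longest go first within a tier), then
#' the episode's fixed unit-interval tiebreak, then person id. The tiebreak
#' is drawn once at episode creation, so the order is deterministic given
#' the episodes.
#'
#' @param episodes Data frame with columns `priority`, `first_seek_date`,
#'   `tiebreak`, `person_id` (and any payload columns).
#' @param seed Optional seed used to draw tiebreaks if the `tiebreak`
#'   column is absent.
#' @return The data frame reordered by the queue key.
#' @export
order_queue <- function(episodes, seed = NULL) {
  if (!nrow(episodes)) return(episodes)
  if (is.null(episodes$tiebreak)) {
    if (!is.null(seed)) set.seed(seed)
    episodes$tiebreak <- stats::runif(nrow(episodes))
  }
  episodes[order(episodes$priority, episodes$first_seek_date,
                 episodes$tiebreak, episodes$person_id), , drop = FALSE]
}

#' Deliver one day's ordered queue under the rigid capability rule
#'
#' Scans the queue in order. An episode is deliverable iff every cadre in
#' its treatment footprint has strictly positive remaining minutes at the
#' episode's facility; if so the full footprint is committed (balances may
#' go negative -- the sanctioned last-HSI overtime) and consumables are
#' drawn; if not, the episode is postponed and the scan continues, so
#' lower-priority HSIs still run while capabilities remain. Footprints are
#' never shortened.
#'
#' @param queue Data frame already in queue order, with columns `care_id`,
#'   `person_id`, `treatment_id`, `facility`, `attempts_used`.
#' @param ledger Capability ledger from [new_day_ledger()] (mutated).
#' @param treatments Treatment catalogue (named list of `treatment_spec`).
#' @param branch_probs Consumable branch probabilities, see
#'   [draw_consumables()].
#' @param draw_seed Optional integer; when supplied, consumable uniforms are
#'   keyed on `(draw_seed, care_id, attempts_used)` via [hash_u()] so that
#'   outcomes do not depend on queue order. When `NULL`, fresh `runif`
#'   draws are used.
#' @return The queue with an added `outcome` column (one of `delivered`,
#'   `delivered_substituted`, `repeat_visit`, `default_from_care`,
#'   `postponed`) and a `minutes_committed` column (total minutes over all
#'   cadres; 0 when postponed).
#' @export
run_day <- function(queue, ledger, treatments, branch_probs,
                    draw_seed = NULL) {
  n <- nrow(queue)
  outcome <- character(n)
  committed <- numeric(n)
  if (!n) {
    queue$outcome <- outcome
    queue$minutes_committed <- committed
    return(queue)
  }
  for (i in seq_len(n)) {
    tr <- treatments[[queue$treatment_id[i]]]
    if (is.null(tr))
      stop(sprintf("unknown treatment '%s' in queue", queue$treatment_id[i]),
           call. = FALSE)
    fp <- tr$footprint
    fac <- queue$facility[i]
    rem <- ledger$remaining[fac, names(fp)]
    if (anyNA(rem))
      stop(sprintf("no capability entry for facility '%s', cadres: %s", fac,
                   paste(names(fp)[is.na(rem)], collapse = ", ")),
           call. = FALSE)
    if (all(rem > 0)) {
      ledger$remaining[fac, names(fp)] <- rem - fp
      committed[i] <- sum(fp)
      nitem <- nrow(tr$consumables)
      if (is.null(draw_seed)) {
        ui <- if (nitem) stats::runif(nitem) else numeric()
        ub <- stats::runif(1)
      } else {
        ui <- if (nitem)
          hash_u(draw_seed, rep(queue$care_id[i], nitem),
                 queue$attempts_used[i], 10 + seq_len(nitem)) else numeric()
        ub <- hash_u(draw_seed, queue$care_id[i], queue$attempts_used[i], 2)
      }
      res <- draw_consumables(tr, branch_probs, u_items = ui, u_branch = ub)
      outcome[i] <- switch(res,
        available = "delivered",
        substituted = "delivered_substituted",
        repeat_visit = "repeat_visit",
        default_from_care = "default_from_care")
    } else {
      outcome[i] <- "postponed"
    }
  }
  queue$outcome <- outcome
  queue$minutes_committed <- committed
  queue
}

#' Close the day: persistence and default from care
#'
#' Each episode that went unserved today uses up one attempt. Once the
#' configured maximum number of consecutive daily attempts is exhausted the
#' patient defaults from care entirely and the treatment is never
#' delivered; otherwise the episode re-queues the next day at the same
#' facility with its original first-seek date (so it outranks newer
#' episodes of equal priority).
#'
#' @param postponed Data frame of unserved episodes with an
#'   `attempts_used` column.
#' @param max_attempts Maximum consecutive daily attempts (default 7).
#' @return List with elements `retried` (episodes that will re-queue, with
#'   `attempts_used` incremented) and `defaulted`.
#' @export
close_day <- function(postponed, max_attempts = 7) {
  postponed$attempts_used <- postponed$attempts_used + 1L
  done <- postponed$attempts_used >= max_attempts
  list(retried = postponed[!done, , drop = FALSE],
       defaulted = postponed[done, , drop = FALSE])
}
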