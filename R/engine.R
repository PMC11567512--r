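# Individual-based daily engine: demography, incidence with transmission
# feedback, care seeking, queue delivery, progression and DALY accrual.
#
# State is held in an environment of parallel vectors (persons, disease
# episodes, care episodes) for speed; the exported step functions operate
# on this state so each stage can be exercised and oracle-tested in
# isolation.  Per-day randomness comes from labelled streams derived from
# (master_seed, replicate, stage, day); consumable and effectiveness draws
# are counter-based and keyed on (care episode, attempt), making delivery
# outcomes independent of queue order.

STATUS_QUEUED <- 0L
STATUS_DELIVERED <- 1L
STATUS_DEFAULTED <- 2L
STATUS_EXCLUDED <- 3L
STATUS_CANCELLED <- 4L  # patient died or recovered before delivery

RES_ONGOING <- 0L
RES_RECOVERED_UNTREATED <- 1L
RES_RECOVERED_TREATED <- 2L
RES_DIED <- 3L
RES_CENSORED <- 4L

#' Initialise simulation state for one (policy, replicate) run
#'
#' Samples the initial population and initial disease stock (chronic causes
#' may start with prevalent untreated episodes), builds treatment lookup
#' tables and the capability ledger, and derives all random streams from
#' the bundle's master seed and the replicate index. The policy id is not
#' part of any seed derivation, so different policies run on common random
#' numbers.
#'
#' @param bundle A validated `scenario_bundle`.
#' @param policy_id Name of a policy in `bundle$policies`.
#' @param replicate_id Replicate index (1-based).
#' @return Simulation state environment.
#' @export
sim_init <- function(bundle, policy_id, replicate_id = 1L) {
  validate_bundle(bundle)
  if (!policy_id %in% names(bundle$policies))
    stop(sprintf("unknown policy '%s'", policy_id), call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$bundle <- bundle
  st$policy <- bundle$policies[[policy_id]]
  st$replicate <- as.integer(replicate_id)
  st$master_seed <- bundle$master_seed
  st$horizon_days <- bundle$horizon_years * 365L
  st$max_attempts <- bundle$max_attempts
  st$branch_probs <- bundle$branch_probs

  cs <- bundle$causes
  st$cause_ids <- vapply(cs, `[[`, "", "cause_id")
  st$nc <- length(cs)
  st$causes <- cs
  # residual row for background (all-other-cause) deaths
  resid <- which(vapply(cs, `[[`, "", "kind") == "other-residual")
  st$background_ci <- if (length(resid)) resid[1] else NA_integer_

  trs <- bundle$treatments
  st$treatments <- trs
  st$tr_ids <- names(trs)
  st$tr_facility <- vapply(trs, `[[`, "", "facility_level")
  st$tr_emergency <- vapply(trs, `[[`, TRUE, "emergency")
  st$tr_preventive <- vapply(trs, `[[`, TRUE, "preventive")
  st$tr_eff <- vapply(trs, `[[`, 1, "effectiveness")
  st$tr_alt_eff <- vapply(trs, `[[`, 1, "alt_effectiveness")
  # per-cause treatment choice: emergency, routine under-5, routine default
  pick <- function(ci) {
    idx <- which(vapply(trs, `[[`, "", "target_cause") == st$cause_ids[ci] &
                   !st$tr_preventive)
    em <- idx[st$tr_emergency[idx]]
    ro <- idx[!st$tr_emergency[idx]]
    u5 <- ro[grepl("under5", st$tr_ids[ro])]
    rd <- ro[!grepl("under5", st$tr_ids[ro])]
    c(emergency = if (length(em)) em[1] else 0L,
      routine_u5 = if (length(u5)) u5[1] else if (length(rd)) rd[1] else 0L,
      routine = if (length(rd)) rd[1] else if (length(u5)) u5[1] else 0L)
  }
  st$tr_choice <- vapply(seq_len(st$nc), pick,
                         c(emergency = 0L, routine_u5 = 0L, routine = 0L))
  st$prev_trs <- which(st$tr_preventive)

  st$ledger <- new_day_ledger(bundle$capabilities)

  # persons ------------------------------------------------------------
  pop <- sample_population(bundle$population,
                           stream_seed(bundle$master_seed, replicate_id,
                                       "population"))
  n <- nrow(pop)
  cap <- max(2L * n, 256L)
  st$np <- n
  st$pcap <- cap
  pad <- function(x, fill) c(x, rep(fill, cap - n))
  st$birth_day <- pad(pop$birth_day, NA_real_)
  st$alive <- pad(pop$alive, FALSE)
  st$sex_f <- pad(pop$sex == "f", FALSE)
  st$pregnant <- pad(pop$pregnant, FALSE)
  st$hiv_diagnosed <- pad(pop$hiv_diagnosed, FALSE)
  st$tb_diagnosed <- pad(pop$tb_diagnosed, FALSE)
  st$unvaccinated <- pad(pop$unvaccinated, FALSE)
  st$contracepting <- pad(pop$contracepting, FALSE)
  st$prior <- matrix(FALSE, cap, st$nc)
  st$active_ep <- matrix(0L, cap, st$nc)   # episode id of open episode
  st$open_care <- matrix(0L, cap, st$nc)   # care id of open curative episode
  st$open_prev <- matrix(0L, cap, length(trs))  # open preventive care

  # episodes -----------------------------------------------------------
  ecap <- 4096L
  st$ne <- 0L
  st$ecap <- ecap
  st$e_person <- integer(ecap); st$e_cause <- integer(ecap)
  st$e_onset <- numeric(ecap); st$e_end <- numeric(ecap)
  st$e_emerg <- logical(ecap); st$e_treated <- logical(ecap)
  st$e_resolved <- logical(ecap); st$e_resolution <- integer(ecap)
  st$active <- integer(0)

  # care episodes ------------------------------------------------------
  ccap <- 4096L
  st$ncc <- 0L
  st$ccap <- ccap
  st$c_episode <- integer(ccap); st$c_person <- integer(ccap)
  st$c_tr <- integer(ccap); st$c_first <- numeric(ccap)
  st$c_attempts <- integer(ccap); st$c_tier <- integer(ccap)
  st$c_tiebreak <- numeric(ccap); st$c_status <- integer(ccap)
  st$queued <- integer(0)

  # outcome ledgers ----------------------------------------------------
  ny <- bundle$horizon_years
  st$yll <- matrix(0, st$nc + 1L, ny,
                   dimnames = list(c(st$cause_ids, ".background"), NULL))
  st$yld <- matrix(0, st$nc + 1L, ny,
                   dimnames = list(c(st$cause_ids, ".background"), NULL))

  st$events <- new_log(c("day", "person_id", "cause", "type"))
  st$deliveries <- new_log(c("day", "facility", "treatment_id", "person_id",
                             "tier", "first_seek_date", "attempt", "outcome",
                             "minutes_committed"))
  st$deaths <- new_log(c("day", "person_id", "cause", "age"))

  st$draw_seed <- stream_seed(bundle$master_seed, replicate_id, "consumables")
  st$eff_seed <- stream_seed(bundle$master_seed, replicate_id,
                             "effectiveness")

  # initial prevalent stock for chronic causes; prevalent cases seek care
  # staggered over the first simulated year rather than all at once
  set_stream(bundle$master_seed, replicate_id, "initial-stock")
  init_prev <- vapply(cs, function(x) x$initial_prevalence %||% 0, 1)
  st$new_eps <- integer(0)
  for (ci in seq_len(st$nc)) {
    p0 <- init_prev[ci]
    if (p0 <= 0) next
    elig <- which(st$alive[seq_len(st$np)] & at_risk(st, ci, 0))
    u5 <- person_age(st, elig, 0) < 5
    pr <- p0 * ifelse(u5, min(st$causes[[ci]]$under5_multiplier, 1), 1)
    hit <- elig[stats::runif(length(elig)) < pr]
    if (!length(hit)) next
    dur <- st$causes[[ci]]$untreated_duration * 365
    onset <- -floor(stats::runif(length(hit)) * (dur / 2))
    for (j in seq_along(hit))
      add_episode(st, hit[j], ci, onset[j], emerg = FALSE, day0 = TRUE)
  }
  st$initial_eps <- st$new_eps
  seekday <- floor(stats::runif(length(st$initial_eps)) * 365)
  st$stock_by_day <- unname(split(st$initial_eps, seekday))
  names(st$stock_by_day) <- as.character(sort(unique(seekday)))
  st
}

# simple growable column log
new_log <- function(cols) {
  lg <- new.env(parent = emptyenv())
  lg$cols <- cols
  lg$buf <- vector("list", 256L)
  lg$n <- 0L
  lg
}
log_add <- function(lg, rec) {
  lg$n <- lg$n + 1L
  if (lg$n > length(lg$buf)) lg$buf <- c(lg$buf, vector("list", length(lg$buf)))
  lg$buf[[lg$n]] <- rec
  invisible(lg)
}
log_df <- function(lg) {
  if (!lg$n) {
    out <- lapply(lg$cols, function(x) logical(0))
    names(out) <- lg$cols
    return(as.data.frame(out))
  }
  recs <- lg$buf[seq_len(lg$n)]
  out <- lapply(seq_along(lg$cols), function(j)
    unlist(lapply(recs, `[[`, j), use.names = FALSE))
  names(out) <- lg$cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

person_age <- function(st, ids, day) (day - st$birth_day[ids]) / 365

# draw the subset of idx experiencing an event of probability p (scalar):
# binomial count then uniform subsampling -- equivalent in distribution to
# per-person Bernoulli draws, much cheaper for small p
sample_hits <- function(idx, p) {
  m <- length(idx)
  if (!m || p <= 0) return(integer(0))
  n <- stats::rbinom(1L, m, p)
  if (!n) return(integer(0))
  idx[sample.int(m, n)]
}

at_risk <- function(st, ci, day) {
  rf <- st$causes[[ci]]$requires_flag
  n <- st$np
  if (is.na(rf) || !nzchar(rf)) return(rep(TRUE, n))
  if (rf == "fertile") {
    age <- (day - st$birth_day[seq_len(n)]) / 365
    return(st$sex_f[seq_len(n)] & age >= 15 & age < 50)
  }
  flag_vec(st, rf)[seq_len(n)]
}

flag_vec <- function(st, flag) {
  switch(flag,
         pregnant = st$pregnant,
         hiv_diagnosed = st$hiv_diagnosed,
         tb_diagnosed = st$tb_diagnosed,
         unvaccinated = st$unvaccinated,
         contracepting = st$contracepting,
         stop(sprintf("unknown flag '%s'", flag), call. = FALSE))
}

grow_persons <- function(st, need) {
  while (st$np + need > st$pcap) {
    add <- st$pcap
    st$birth_day <- c(st$birth_day, rep(NA_real_, add))
    st$alive <- c(st$alive, rep(FALSE, add))
    st$sex_f <- c(st$sex_f, rep(FALSE, add))
    st$pregnant <- c(st$pregnant, rep(FALSE, add))
    st$hiv_diagnosed <- c(st$hiv_diagnosed, rep(FALSE, add))
    st$tb_diagnosed <- c(st$tb_diagnosed, rep(FALSE, add))
    st$unvaccinated <- c(st$unvaccinated, rep(FALSE, add))
    st$contracepting <- c(st$contracepting, rep(FALSE, add))
    st$prior <- rbind(st$prior, matrix(FALSE, add, st$nc))
    st$active_ep <- rbind(st$active_ep, matrix(0L, add, st$nc))
    st$open_care <- rbind(st$open_care, matrix(0L, add, st$nc))
    st$open_prev <- rbind(st$open_prev,
                          matrix(0L, add, ncol(st$open_prev)))
    st$pcap <- st$pcap + add
  }
}

grow_episodes <- function(st, need) {
  while (st$ne + need > st$ecap) {
    add <- st$ecap
    st$e_person <- c(st$e_person, integer(add))
    st$e_cause <- c(st$e_cause, integer(add))
    st$e_onset <- c(st$e_onset, numeric(add))
    st$e_end <- c(st$e_end, numeric(add))
    st$e_emerg <- c(st$e_emerg, logical(add))
    st$e_treated <- c(st$e_treated, logical(add))
    st$e_resolved <- c(st$e_resolved, logical(add))
    st$e_resolution <- c(st$e_resolution, integer(add))
    st$ecap <- st$ecap + add
  }
}

grow_care <- function(st, need) {
  while (st$ncc + need > st$ccap) {
    add <- st$ccap
    st$c_episode <- c(st$c_episode, integer(add))
    st$c_person <- c(st$c_person, integer(add))
    st$c_tr <- c(st$c_tr, integer(add))
    st$c_first <- c(st$c_first, numeric(add))
    st$c_attempts <- c(st$c_attempts, integer(add))
    st$c_tier <- c(st$c_tier, integer(add))
    st$c_tiebreak <- c(st$c_tiebreak, numeric(add))
    st$c_status <- c(st$c_status, integer(add))
    st$ccap <- st$ccap + add
  }
}

add_episode <- function(st, person, ci, onset, emerg, day0 = FALSE) {
  grow_episodes(st, 1L)
  st$ne <- st$ne + 1L
  id <- st$ne
  dur <- st$causes[[ci]]$untreated_duration
  st$e_person[id] <- person
  st$e_cause[id] <- ci
  st$e_onset[id] <- onset
  st$e_end[id] <- onset + max(1, round(dur * 365))
  st$e_emerg[id] <- emerg
  st$e_treated[id] <- FALSE
  st$e_resolved[id] <- FALSE
  st$e_resolution[id] <- RES_ONGOING
  st$active <- c(st$active, id)
  st$active_ep[person, ci] <- id
  if (st$causes[[ci]]$kind == "perinatal") st$pregnant[person] <- TRUE
  st$new_eps <- c(st$new_eps, id)
  log_add(st$events, list(if (day0) 0 else onset, person,
                          st$cause_ids[ci], "incidence"))
  id
}

# pro-rata YLD accrual of weight over simulation days [a, b), clipped to
# the horizon, split across 365-day calendar years
accrue_yld <- function(st, row, a, b) {
  a <- max(0, a)
  b <- min(b, st$horizon_days)
  if (b <= a) return(invisible())
  ci <- st$e_cause[row]
  w <- st$causes[[ci]]$disability_weight
  if (w <= 0) return(invisible())
  y1 <- a %/% 365 + 1
  y2 <- (b - 1) %/% 365 + 1
  for (y in y1:y2) {
    lo <- max(a, (y - 1) * 365)
    hi <- min(b, y * 365)
    st$yld[ci, y] <- st$yld[ci, y] + w * (hi - lo) / 365
  }
  invisible()
}

# resolve an episode (recovery / death / censoring), with YLD accrual
resolve_episode <- function(st, id, day, resolution) {
  p <- st$e_person[id]
  ci <- st$e_cause[id]
  accrue_yld(st, id, st$e_onset[id], day)
  st$e_resolved[id] <- TRUE
  st$e_resolution[id] <- resolution
  st$active_ep[p, ci] <- 0L
  if (resolution %in% c(RES_RECOVERED_UNTREATED, RES_RECOVERED_TREATED)) {
    st$prior[p, ci] <- TRUE
    log_add(st$events, list(day, p, st$cause_ids[ci], "recovery"))
  }
  if (st$causes[[ci]]$kind == "perinatal") st$pregnant[p] <- FALSE
  # a pending care request for a resolved episode is cancelled
  cid <- st$open_care[p, ci]
  if (cid > 0L && st$c_status[cid] == STATUS_QUEUED) {
    st$c_status[cid] <- STATUS_CANCELLED
    st$open_care[p, ci] <- 0L
  }
  invisible()
}

kill_person <- function(st, p, day, cause_row, cause_label) {
  st$alive[p] <- FALSE
  age <- (day - st$birth_day[p]) / 365
  y <- min(day %/% 365 + 1, st$bundle$horizon_years)
  st$yll[cause_row, y] <- st$yll[cause_row, y] +
    compute_yll(age, st$bundle$reference_life_expectancy)
  log_add(st$deaths, list(day, p, cause_label, age))
  log_add(st$events, list(day, p, cause_label, "death"))
  # censor other ongoing episodes and cancel any pending care
  for (ci in which(st$active_ep[p, ] > 0L)) {
    id <- st$active_ep[p, ci]
    accrue_yld(st, id, st$e_onset[id], day)
    st$e_resolved[id] <- TRUE
    st$e_resolution[id] <- RES_CENSORED
    st$active_ep[p, ci] <- 0L
  }
  cids <- c(st$open_care[p, ], st$open_prev[p, ])
  cids <- cids[cids > 0L]
  if (length(cids)) {
    cids <- cids[st$c_status[cids] == STATUS_QUEUED]
    st$c_status[cids] <- STATUS_CANCELLED
  }
  st$open_care[p, ] <- 0L
  st$open_prev[p, ] <- 0L
  invisible()
}

#' Daily demography step: births and background mortality
#'
#' Births occur at the crude birth rate among alive, non-contracepting
#' individuals (daily probability `1 - exp(-rate/365)`); newborns start
#' unvaccinated. Background deaths occur at the age-band hazard and are
#' attributed to the residual ("other") cause.
#'
#' @param st Simulation state from [sim_init()].
#' @param day Simulation day (0-based).
#' @return Invisibly, `list(births, background_deaths)` (counts).
#' @export
step_demography <- function(st, day) {
  set_stream(st$master_seed, st$replicate, paste0("demography:", day))
  pop <- st$bundle$population
  idx <- which(st$alive[seq_len(st$np)])
  # births
  nbirth <- 0L
  cbr <- pop$crude_birth_rate
  if (cbr > 0 && length(idx)) {
    fert <- idx[!st$contracepting[idx]]
    nbirth <- length(sample_hits(fert, 1 - exp(-cbr / 365)))
    if (nbirth > 0) {
      grow_persons(st, nbirth)
      ids <- st$np + seq_len(nbirth)
      st$np <- st$np + nbirth
      st$birth_day[ids] <- day
      st$alive[ids] <- TRUE
      st$sex_f[ids] <- stats::runif(nbirth) < 0.5
      st$unvaccinated[ids] <- TRUE
      for (p in ids)
        log_add(st$events, list(day, p, NA_character_, "birth"))
    }
  }
  # background mortality by age band
  ndeath <- 0L
  bm <- pop$background_mortality
  if (any(bm$hazard > 0) && length(idx)) {
    age <- (day - st$birth_day[idx]) / 365
    band <- findInterval(age, bm$lo)
    band[band < 1L] <- 1L
    band[band > nrow(bm)] <- nrow(bm)
    hit <- integer(0)
    for (bd in seq_len(nrow(bm))) {
      if (bm$hazard[bd] <= 0) next
      hit <- c(hit, sample_hits(idx[band == bd],
                                1 - exp(-bm$hazard[bd] / 365)))
    }
    ndeath <- length(hit)
    row <- if (is.na(st$background_ci)) st$nc + 1L else st$background_ci
    label <- if (is.na(st$background_ci)) ".background" else
      st$cause_ids[st$background_ci]
    for (p in hit) kill_person(st, p, day, row, label)
  }
  invisible(list(births = nbirth, background_deaths = ndeath))
}

#' Daily incidence step with transmission feedback
#'
#' Each alive, susceptible, at-risk person acquires cause `c` with daily
#' probability `1 - exp(-h/365)`, where `h` is the year's base hazard times
#' the under-5 multiplier, times `1 + transmission_coefficient * prevalence
#' of untreated active cases` (prevalence computed once at the start of the
#' step, synchronously for all causes), times the reinfection multiplier
#' for people with a prior recovery from the cause.
#'
#' @param st Simulation state.
#' @param day Simulation day (0-based).
#' @return Invisibly, integer vector of new episode ids.
#' @export
step_incidence <- function(st, day) {
  set_stream(st$master_seed, st$replicate, paste0("incidence:", day))
  # prevalent stock episodes enter the care-seeking pool on their
  # staggered first-seek day
  st$new_eps <- st$stock_by_day[[as.character(day)]] %||% integer(0)
  st$new_eps <- st$new_eps[!st$e_resolved[st$new_eps]]
  ali <- which(st$alive[seq_len(st$np)])
  n_alive <- length(ali)
  if (!n_alive) return(invisible(integer(0)))
  yr <- day %/% 365 + 1
  # synchronous untreated prevalence per cause
  act <- st$active
  act <- act[!st$e_resolved[act] & !st$e_treated[act]]
  prev <- tabulate(st$e_cause[act], nbins = st$nc) / n_alive
  age <- (day - st$birth_day[ali]) / 365
  for (ci in seq_len(st$nc)) {
    cs <- st$causes[[ci]]
    h0 <- max(0, cs$base_incidence + cs$incidence_trend * (yr - 1))
    if (h0 <= 0) next
    sel <- st$active_ep[ali, ci] == 0L
    rf <- cs$requires_flag
    if (!is.na(rf) && nzchar(rf)) {
      sel <- sel & (if (rf == "fertile")
        st$sex_f[ali] & age >= 15 & age < 50
        else flag_vec(st, rf)[ali])
    }
    elig <- ali[sel]
    if (!length(elig)) next
    h <- h0 * (1 + cs$transmission_coefficient * prev[ci])
    # stratify by the discrete hazard multipliers (age band, prior
    # recovery) and draw binomial counts per stratum
    stratum <- (age[sel] < 5) + 0L
    if (cs$reinfection_multiplier != 1)
      stratum <- stratum + 2L * (st$prior[elig, ci] + 0L)
    hits <- integer(0)
    for (sgrp in unique(stratum)) {
      mult <- if (sgrp %% 2L == 1L) cs$under5_multiplier else 1
      if (sgrp >= 2L) mult <- mult * cs$reinfection_multiplier
      p <- 1 - exp(-h * mult / 365)
      hits <- c(hits, sample_hits(elig[stratum == sgrp], p))
    }
    if (!length(hits)) next
    emerg <- stats::runif(length(hits)) < cs$emergency_probability
    for (j in seq_along(hits))
      add_episode(st, hits[j], ci, day, emerg[j])
  }
  invisible(st$new_eps)
}

#' Daily care-seeking step
#'
#' Converts today's new episodes of resource-constrained causes into care
#' episodes (HSI requests): emergencies always seek care the same day,
#' routine episodes do so with the cause's care-seeking probability. Also
#' generates demand for preventive services among eligible individuals. A
#' person holds at most one open care episode per cause (and per preventive
#' treatment); priorities are assigned under the run's policy, and excluded
#' treatments are filtered out before entering any queue.
#'
#' @param st Simulation state.
#' @param day Simulation day.
#' @return Invisibly, integer vector of new care episode ids.
#' @export
step_care_seeking <- function(st, day) {
  set_stream(st$master_seed, st$replicate, paste0("careseek:", day))
  created <- integer(0)
  pol <- st$policy
  new_eps <- st$new_eps
  for (id in new_eps) {
    p <- st$e_person[id]
    if (!st$alive[p]) next
    ci <- st$e_cause[id]
    cs <- st$causes[[ci]]
    if (!cs$resource_constrained) next
    emerg <- st$e_emerg[id]
    useek <- stats::runif(1)  # drawn unconditionally: stable stream usage
    if (!emerg && useek >= cs$care_seeking_probability) next
    if (st$open_care[p, ci] > 0L) next  # coalesced
    under5 <- (day - st$birth_day[p]) / 365 < 5
    tri <- if (emerg && st$tr_choice["emergency", ci] > 0L)
      st$tr_choice["emergency", ci]
    else if (under5) st$tr_choice["routine_u5", ci]
    else st$tr_choice["routine", ci]
    if (tri == 0L) {
      log_add(st$events, list(day, p, st$cause_ids[ci], "no_treatment"))
      next
    }
    if (ci == match("hiv", st$cause_ids, nomatch = 0L))
      st$hiv_diagnosed[p] <- TRUE  # diagnosis at first care contact
    created <- c(created, new_care(st, id, p, tri, day, emerg, under5))
  }
  # preventive demand
  set_stream(st$master_seed, st$replicate, paste0("prevent:", day))
  n <- st$np
  age <- (day - st$birth_day[seq_len(n)]) / 365
  for (tri in st$prev_trs) {
    tr <- st$treatments[[tri]]
    if (tr$demand_rate <= 0) next
    elig <- st$alive[seq_len(n)]
    if (!is.na(tr$clears_flag))
      elig <- elig & flag_vec(st, tr$clears_flag)[seq_len(n)]
    if (!is.na(tr$sets_flag))
      elig <- elig & !flag_vec(st, tr$sets_flag)[seq_len(n)]
    ci <- match(tr$target_cause, st$cause_ids, nomatch = 0L)
    if (ci > 0L) elig <- elig & at_risk(st, ci, day)
    elig <- which(elig & st$open_prev[seq_len(n), tri] == 0L)
    if (!length(elig)) next
    hit <- sample_hits(elig, 1 - exp(-tr$demand_rate / 365))
    for (p in hit)
      created <- c(created, new_care(st, 0L, p, tri, day, FALSE,
                                     age[p] < 5))
  }
  invisible(created)
}

new_care <- function(st, episode, person, tri, day, emerg, under5) {
  pol <- st$policy
  trid <- st$tr_ids[tri]
  grow_care(st, 1L)
  st$ncc <- st$ncc + 1L
  cid <- st$ncc
  st$c_episode[cid] <- episode
  st$c_person[cid] <- person
  st$c_tr[cid] <- tri
  st$c_first[cid] <- day
  st$c_attempts[cid] <- 0L
  st$c_tiebreak[cid] <- stats::runif(1)
  if (apply_policy_filter(trid, pol) == "excluded") {
    st$c_status[cid] <- STATUS_EXCLUDED
    st$c_tier[cid] <- NA_integer_
    log_add(st$deliveries, list(day, st$tr_facility[tri], trid, person,
                                NA_integer_, day, 0L, "excluded", 0))
    return(cid)
  }
  flags <- c(if (st$pregnant[person]) "pregnant",
             if (st$hiv_diagnosed[person]) "hiv_diagnosed",
             if (st$tb_diagnosed[person]) "tb_diagnosed")
  st$c_tier[cid] <- assign_priority(trid, pol,
                                    emergency = emerg || st$tr_emergency[tri],
                                    under5 = under5,
                                    person_flags = flags)
  st$c_status[cid] <- STATUS_QUEUED
  if (episode > 0L) st$open_care[person, st$e_cause[episode]] <- cid
  else st$open_prev[person, tri] <- cid
  st$queued <- c(st$queued, cid)
  cid
}

#' Daily queue step: order, deliver under rigid constraints, close the day
#'
#' Resets the capability ledger, orders each facility's queue by (tier,
#' first-seek date, tiebreak), delivers via [run_day()], applies treatment
#' effectiveness (keyed draws) to delivered HSIs, and closes the day:
#' unserved episodes use one attempt and default once `max_attempts` is
#' reached.
#'
#' @param st Simulation state.
#' @param day Simulation day.
#' @return Invisibly, the day's delivery data frame.
#' @export
step_queue <- function(st, day) {
  reset_ledger(st$ledger)
  q <- st$queued
  q <- q[st$c_status[q] == STATUS_QUEUED]
  if (!length(q)) {
    st$queued <- q
    return(invisible(NULL))
  }
  df <- structure(list(care_id = q,
                       person_id = st$c_person[q],
                       treatment_id = st$tr_ids[st$c_tr[q]],
                       facility = unname(st$tr_facility[st$c_tr[q]]),
                       attempts_used = st$c_attempts[q],
                       priority = st$c_tier[q],
                       first_seek_date = st$c_first[q],
                       tiebreak = st$c_tiebreak[q]),
                  class = "data.frame", row.names = seq_along(q))
  out <- NULL
  for (fac in sort(unique(df$facility))) {
    sub <- order_queue(df[df$facility == fac, , drop = FALSE])
    res <- run_day(sub, st$ledger, st$treatments, st$branch_probs,
                   draw_seed = st$draw_seed)
    out <- if (is.null(out)) res else rbind(out, res)
  }
  still <- integer(0)
  for (i in seq_len(nrow(out))) {
    cid <- out$care_id[i]
    oc <- out$outcome[i]
    tri <- st$c_tr[cid]
    p <- st$c_person[cid]
    delivered <- oc %in% c("delivered", "delivered_substituted")
    if (delivered) {
      st$c_status[cid] <- STATUS_DELIVERED
      eff <- if (oc == "delivered") st$tr_eff[tri] else st$tr_alt_eff[tri]
      ueff <- hash_u(st$eff_seed, cid, st$c_attempts[cid], 3)
      if (ueff < eff) apply_treatment(st, cid, tri, day)
      clear_open(st, cid, p, tri)
    } else if (oc == "default_from_care") {
      st$c_status[cid] <- STATUS_DEFAULTED
      clear_open(st, cid, p, tri)
    } else {  # postponed (capacity) or repeat_visit (consumables)
      st$c_attempts[cid] <- st$c_attempts[cid] + 1L
      if (st$c_attempts[cid] >= st$max_attempts) {
        st$c_status[cid] <- STATUS_DEFAULTED
        clear_open(st, cid, p, tri)
      } else {
        still <- c(still, cid)
      }
    }
    log_add(st$deliveries,
            list(day, out$facility[i], out$treatment_id[i], p,
                 out$priority[i], out$first_seek_date[i],
                 out$attempts_used[i] + 1L, oc, out$minutes_committed[i]))
  }
  st$queued <- still
  invisible(out)
}

clear_open <- function(st, cid, p, tri) {
  ep <- st$c_episode[cid]
  if (ep > 0L) {
    ci <- st$e_cause[ep]
    if (st$open_care[p, ci] == cid) st$open_care[p, ci] <- 0L
  } else if (st$open_prev[p, tri] == cid) {
    st$open_prev[p, tri] <- 0L
  }
}

apply_treatment <- function(st, cid, tri, day) {
  tr <- st$treatments[[tri]]
  p <- st$c_person[cid]
  if (tr$preventive) {
    if (!is.na(tr$clears_flag))
      assign_flag(st, p, tr$clears_flag, FALSE)
    if (!is.na(tr$sets_flag))
      assign_flag(st, p, tr$sets_flag, TRUE)
    return(invisible())
  }
  ep <- st$c_episode[cid]
  if (ep == 0L || st$e_resolved[ep]) return(invisible())
  ci <- st$e_cause[ep]
  st$e_treated[ep] <- TRUE
  td <- st$causes[[ci]]$treated_duration
  st$e_end[ep] <- min(st$e_end[ep], day + max(1, round(td * 365)))
  invisible()
}

assign_flag <- function(st, p, flag, value) {
  switch(flag,
         pregnant = st$pregnant[p] <- value,
         hiv_diagnosed = st$hiv_diagnosed[p] <- value,
         tb_diagnosed = st$tb_diagnosed[p] <- value,
         unvaccinated = st$unvaccinated[p] <- value,
         contracepting = st$contracepting[p] <- value,
         stop(sprintf("unknown flag '%s'", flag), call. = FALSE))
  invisible()
}

#' Daily progression step: deaths and recoveries among active episodes
#'
#' Each ongoing episode resolves by death with daily probability
#' `1 - exp(-h/365)` where `h` is the treated or untreated per-year death
#' hazard times the product of the cause's risk modifiers the person
#' currently triggers; surviving episodes recover once their (treated or
#' untreated) duration has elapsed.
#'
#' @param st Simulation state.
#' @param day Simulation day.
#' @return Invisibly, `list(deaths, recoveries)` (counts).
#' @export
step_progression <- function(st, day) {
  set_stream(st$master_seed, st$replicate, paste0("progression:", day))
  act <- st$active
  act <- act[!st$e_resolved[act]]
  ndeath <- 0L; nrec <- 0L
  if (length(act)) {
    ci <- st$e_cause[act]
    h <- numeric(length(act))
    for (k in seq_len(st$nc)) {
      sel <- ci == k
      if (!any(sel)) next
      cs <- st$causes[[k]]
      hk <- rep(cs$untreated_death_hazard, sum(sel))
      hk[st$e_treated[act[sel]]] <- cs$treated_death_hazard
      if (length(cs$risk_modifiers)) {
        pers <- st$e_person[act[sel]]
        for (fl in names(cs$risk_modifiers)) {
          trig <- if (fl == "under5")
            (day - st$birth_day[pers]) / 365 < 5
          else flag_vec(st, fl)[pers]
          hk[trig] <- hk[trig] * cs$risk_modifiers[[fl]]
        }
      }
      h[sel] <- hk
    }
    u <- stats::runif(length(act))
    dies <- u < (1 - exp(-h / 365))
    for (id in act[dies]) {
      if (!st$alive[st$e_person[id]]) next
      p <- st$e_person[id]
      k <- st$e_cause[id]
      resolve_episode(st, id, day, RES_DIED)
      kill_person(st, p, day, k, st$cause_ids[k])
      ndeath <- ndeath + 1L
    }
    rec <- act[!dies & day >= st$e_end[act]]
    for (id in rec) {
      if (st$e_resolved[id]) next
      resolve_episode(st, id, day,
                      if (st$e_treated[id]) RES_RECOVERED_TREATED
                      else RES_RECOVERED_UNTREATED)
      nrec <- nrec + 1L
    }
  }
  st$active <- st$active[!st$e_resolved[st$active]]
  invisible(list(deaths = ndeath, recoveries = nrec))
}

#' Run one full simulation replicate under one policy
#'
#' Executes the daily loop (demography, incidence, care seeking, queue
#' delivery, persistence, progression) over the bundle's horizon and
#' returns the DALY ledger plus the audit logs. Fully deterministic given
#' `(bundle, policy_id, replicate_id)`; the policy never enters seed
#' derivation, so replicate `r` uses common random numbers across policies.
#'
#' @param bundle A validated `scenario_bundle`.
#' @param policy_id Policy name in `bundle$policies`.
#' @param replicate_id Replicate index (1-based).
#' @param horizon_years Optional override of the bundle horizon.
#' @return List with `ledger` (a `daly_ledger` data frame), `events`,
#'   `deliveries` and `deaths` data frames, and `final_population` (alive
#'   count at horizon end).
#' @export
run_scenario <- function(bundle, policy_id, replicate_id = 1L,
                         horizon_years = NULL) {
  if (!is.null(horizon_years)) {
    bundle$horizon_years <- as.integer(horizon_years)
    validate_bundle(bundle)
  }
  st <- sim_init(bundle, policy_id, replicate_id)
  for (day in 0:(st$horizon_days - 1L)) {
    step_demography(st, day)
    step_incidence(st, day)
    step_care_seeking(st, day)
    step_queue(st, day)
    step_progression(st, day)
  }
  # censor still-ongoing disability at horizon end
  for (id in st$active) {
    if (st$e_resolved[id]) next
    accrue_yld(st, id, st$e_onset[id], st$horizon_days)
    st$e_resolution[id] <- RES_ONGOING  # left ongoing; YLD censored
  }
  ledger <- state_ledger(st, policy_id, replicate_id)
  list(ledger = ledger,
       events = log_df(st$events),
       deliveries = log_df(st$deliveries),
       deaths = log_df(st$deaths),
       final_population = sum(st$alive[seq_len(st$np)]),
       state = st)
}

state_ledger <- function(st, policy_id, replicate_id) {
  ny <- st$bundle$horizon_years
  rows <- rownames(st$yll)
  keep <- rowSums(st$yll) > 0 | rowSums(st$yld) > 0 |
    rows %in% st$cause_ids
  led <- data.frame(
    cause = rep(rows[keep], ny),
    year = rep(st$bundle$start_year + seq_len(ny) - 1L, each = sum(keep)),
    yll = as.vector(st$yll[keep, , drop = FALSE]),
    yld = as.vector(st$yld[keep, , drop = FALSE]))
  daly_ledger(led, policy_id = policy_id, replicate_id = replicate_id,
              scale_factor = st$bundle$population$national_population /
                st$bundle$population$initial_size)
}
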