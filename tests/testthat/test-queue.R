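presets <- policy_presets()

test_that("priority assignment realises engine-reserved emergency tiers", {
  np <- presets$NP
  # emergencies outrank everything; child emergencies outrank adult ones
  expect_identical(assign_priority("lri_emergency_admission", np,
                                   emergency = TRUE, under5 = TRUE), 0L)
  expect_identical(assign_priority("lri_emergency_admission", np,
                                   emergency = TRUE, under5 = FALSE), 1L)
  # NP: one tier for every non-emergency treatment, whoever the patient is
  tiers <- vapply(names(np$tier_of), function(tid)
    assign_priority(tid, np, FALSE, FALSE), 1L)
  expect_true(all(tiers == tiers[1]))
  expect_error(assign_priority("nonexistent", np, FALSE, FALSE),
               "nonexistent")
})

test_that("CV fast-tracks vulnerable patients on every treatment", {
  cv <- presets$CV
  for (tid in names(cv$tier_of)) {
    expect_identical(assign_priority(tid, cv, FALSE, FALSE,
                                     person_flags = "tb_diagnosed"), 2L)
    expect_identical(assign_priority(tid, cv, FALSE, under5 = TRUE), 2L)
    expect_identical(assign_priority(tid, cv, FALSE, FALSE), 3L)
  }
})

test_that("policy validation enforces exclusion/tier/fasttrack coherence", {
  expect_error(policy("bad", c(a = "high"), excluded = "a"), "excluded")
  expect_error(policy("bad", c(a = "high"), excluded = "b",
                      fasttrack = list(b = "under5")), "fasttrack")
  expect_error(policy("bad", c(a = "mid")), "high")
  expect_error(policy("bad", c(a = "high"),
                      fasttrack = list(a = "left_handed")), "vulnerable")
  # the LCOA preset excludes HIV treatment and the filter honours it
  expect_identical(apply_policy_filter("hiv_treatment", presets$LCOA),
                   "excluded")
  expect_identical(apply_policy_filter("hiv_treatment", presets$NP),
                   "queued")
})

test_that("queue ordering follows (tier, first-seek date, tiebreak)", {
  q <- data.frame(care_id = 1:3, person_id = 1:3,
                  priority = c(3L, 2L, 0L),
                  first_seek_date = c(0, 0, 0),
                  tiebreak = c(0.5, 0.5, 0.5))
  expect_equal(order_queue(q)$care_id, c(3L, 2L, 1L))
  q2 <- data.frame(care_id = 1:2, person_id = 1:2,
                   priority = c(2L, 2L),
                   first_seek_date = c(8, 5), tiebreak = c(0.1, 0.9))
  expect_equal(order_queue(q2)$care_id, c(2L, 1L))  # day-5 seeker first
})

test_that("queue order matches an exhaustive comparison-sort oracle", {
  # QueueKey must be a strict total order realised exactly by order_queue
  for (s in 1:25) {
    set.seed(s)
    n <- 40
    q <- data.frame(care_id = seq_len(n), person_id = sample(500, n),
                    priority = sample(0:3, n, TRUE),
                    first_seek_date = sample(0:4, n, TRUE),
                    tiebreak = round(stats::runif(n), 2))
    key_lt <- function(i, j) {
      a <- q[i, ]; b <- q[j, ]
      if (a$priority != b$priority) return(a$priority < b$priority)
      if (a$first_seek_date != b$first_seek_date)
        return(a$first_seek_date < b$first_seek_date)
      if (a$tiebreak != b$tiebreak) return(a$tiebreak < b$tiebreak)
      a$person_id < b$person_id
    }
    # selection sort under the comparator
    ids <- seq_len(n)
    for (i in seq_len(n - 1)) {
      m <- i
      for (j in (i + 1):n) if (key_lt(ids[j], ids[m])) m <- j
      tmp <- ids[i]; ids[i] <- ids[m]; ids[m] <- tmp
    }
    expect_equal(order_queue(q)$care_id, q$care_id[ids])
  }
})

test_that("rigid delivery: greedy scan, skip-and-continue, one-HSI overtime", {
  tr40 <- treatment_spec("t40", "c", "f", c(nurse = 40), effectiveness = 1)
  trs <- list(t40 = tr40)
  led <- new_day_ledger(data.frame(facility = "f", cadre = "nurse",
                                   minutes = 100))
  q <- data.frame(care_id = 1:4, person_id = 1:4, treatment_id = "t40",
                  facility = "f", attempts_used = 0L,
                  priority = 3L, first_seek_date = 0, tiebreak = 1:4 / 10)
  out <- run_day(order_queue(q), led, trs, c(1, 0, 0))
  # 100 minutes, 40-minute HSIs: three delivered (overtime on the third,
  # 20 > 0 minutes remained), fourth postponed
  expect_equal(out$outcome, c(rep("delivered", 3), "postponed"))
  expect_equal(remaining_minutes(led, "f", "nurse"), -20)

  # two-cadre HSI: exhausting one cadre blocks it even with surplus in the
  # other, but a later single-cadre HSI can still be delivered
  trs2 <- list(
    big = treatment_spec("big", "c", "f", c(a = 50, b = 10),
                         effectiveness = 1),
    small = treatment_spec("small", "c", "f", c(b = 10), effectiveness = 1))
  led2 <- new_day_ledger(data.frame(facility = "f", cadre = c("a", "b"),
                                    minutes = c(50, 100)))
  q2 <- data.frame(care_id = 1:3, person_id = 1:3,
                   treatment_id = c("big", "big", "small"), facility = "f",
                   attempts_used = 0L, priority = c(2L, 2L, 3L),
                   first_seek_date = 0, tiebreak = c(0.1, 0.2, 0.3))
  out2 <- run_day(order_queue(q2), led2, trs2, c(1, 0, 0))
  expect_equal(out2$outcome, c("delivered", "postponed", "delivered"))

  # empty queue leaves the ledger untouched
  led3 <- new_day_ledger(data.frame(facility = "f", cadre = "nurse",
                                    minutes = 77))
  out3 <- run_day(q[0, ], led3, trs, c(1, 0, 0))
  expect_equal(nrow(out3), 0)
  expect_equal(remaining_minutes(led3, "f", "nurse"), 77)
})

test_that("persistence: attempts accumulate and default at max_attempts", {
  q <- data.frame(care_id = 1L, attempts_used = 0L)
  for (k in 1:6) {
    r <- close_day(q, max_attempts = 7)
    expect_equal(nrow(r$defaulted), 0)
    q <- r$retried
  }
  r <- close_day(q, max_attempts = 7)  # 7th consecutive failure
  expect_equal(nrow(r$retried), 0)
  expect_equal(r$defaulted$attempts_used, 7L)
  # the illustrative three-attempt configuration defaults after 3 failures
  q3 <- data.frame(care_id = 1L, attempts_used = 2L)
  expect_equal(nrow(close_day(q3, max_attempts = 3)$defaulted), 1)
})
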