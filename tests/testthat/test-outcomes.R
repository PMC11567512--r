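test_that("YLL closed form: floor at zero, reference default of 70", {
  expect_equal(compute_yll(0), 70)
  expect_equal(compute_yll(30), 40)
  expect_equal(compute_yll(70), 0)
  expect_equal(compute_yll(85), 0)
  expect_equal(compute_yll(c(0, 25.5), 62.5), c(62.5, 37))
  expect_error(compute_yll(-1), ">= 0")
})

test_that("YLD is weight times duration, conserved across year splits", {
  causes <- list(a = cause_spec("a", "non-communicable", 0.1,
                                disability_weight = 0.5),
                 z = cause_spec("z", "non-communicable", 0.1,
                                disability_weight = 0))
  # weight 0.5 held exactly two years -> 1.0 years
  one <- data.frame(cause_id = "a", onset_day = 0, end_day = 730)
  expect_equal(sum(compute_yld(one, causes)$yld), 1.0)
  # zero weight -> nothing, regardless of duration
  expect_equal(nrow(compute_yld(
    data.frame(cause_id = "z", onset_day = 0, end_day = 3650), causes)), 0)
  # an episode spanning a year boundary splits conservatively
  span <- data.frame(cause_id = "a", onset_day = 300, end_day = 475)
  flat <- data.frame(cause_id = "a", onset_day = 0, end_day = 175)
  ys <- compute_yld(span, causes)
  expect_equal(nrow(ys), 2)
  expect_equal(sum(ys$yld), sum(compute_yld(flat, causes)$yld))
})

test_that("ledger aggregation reproduces the hand-computed mean and CI", {
  mk <- function(total, rep)
    daly_ledger(data.frame(cause = "a", year = 1, yll = total, yld = 0),
                policy_id = "NP", replicate_id = rep, scale_factor = 1)
  rep3 <- aggregate_replicates(list(mk(10, 1), mk(12, 2), mk(14, 3)))
  expect_equal(rep3$totals$mean, 12)
  expect_equal(rep3$totals$lo, 12 - 1.96 * 2 / sqrt(3))
  expect_equal(rep3$totals$hi, 12 + 1.96 * 2 / sqrt(3))
  expect_equal(rep3$totals$pct_change, 0)  # benchmark vs itself
  # identical replicates: zero-width interval
  same <- aggregate_replicates(list(mk(5, 1), mk(5, 2)))
  expect_equal(same$totals$lo, same$totals$hi)
  # single replicate: degenerate CI flagged
  one <- aggregate_replicates(list(mk(5, 1)))
  expect_true(one$degenerate_ci)
  expect_true(is.na(one$totals$lo))
})

test_that("scaling linearity: scale factor multiplies totals exactly", {
  cells <- data.frame(cause = c("a", "b"), year = c(1, 1),
                      yll = c(2, 3), yld = c(0.5, 0))
  l1 <- daly_ledger(cells, "NP", 1, scale_factor = 1)
  lk <- daly_ledger(cells, "NP", 1, scale_factor = 145)
  expect_equal(total_dalys(lk), 145 * total_dalys(l1))
  expect_error(daly_ledger(data.frame(cause = "a", year = 1, yll = -1,
                                      yld = 0), "NP", 1), ">= 0")
})

test_that("horizon views recompute on truncated years and validate input", {
  mk <- function(pol, rep, y1, y2, y3)
    daly_ledger(data.frame(cause = "a", year = 2023:2025,
                           yll = c(y1, y2, y3), yld = 0),
                policy_id = pol, replicate_id = rep, scale_factor = 1)
  led <- list(mk("NP", 1, 10, 10, 10), mk("NP", 2, 12, 10, 8),
              mk("X", 1, 20, 5, 4), mk("X", 2, 22, 5, 1))
  rep <- aggregate_replicates(led)
  h3 <- horizon_view(rep, 3)
  expect_equal(h3$totals$mean, rep$totals$mean)
  h1 <- horizon_view(rep, 1)
  # X is worse than NP in year 1 but better over all three years
  pct <- function(r) r$totals$pct_change[r$totals$policy == "X"]
  expect_gt(pct(h1), 0)
  expect_lt(pct(h3), 0)
  expect_error(horizon_view(rep, 0), ">= 1")
  expect_error(horizon_view(rep, 4), "exceeds")
  expect_error(aggregate_replicates(list(mk("NP", 1, 1, 1, 1),
    daly_ledger(data.frame(cause = "a", year = 2023, yll = 1, yld = 0),
                "X", 1))), "mismatched")
})

test_that("cause ranking: benchmark-descending with residual last", {
  mk <- function(cause, tot)
    data.frame(cause = cause, year = 2023, yll = tot, yld = 0)
  l <- daly_ledger(rbind(mk("big", 100), mk("small", 50),
                         mk("other", 400)), "NP", 1)
  rep <- aggregate_replicates(list(l))
  # "other" is the largest contributor but is still appended last
  expect_equal(rank_causes(rep), c("big", "small", "other"))
  # ties break stably by cause id
  l2 <- daly_ledger(rbind(mk("bb", 10), mk("aa", 10)), "NP", 1)
  expect_equal(rank_causes(aggregate_replicates(list(l2))), c("aa", "bb"))
})
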