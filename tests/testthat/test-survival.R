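# the printed study survival times: treated arm censored at the 66-day
# horizon, sham and control arms all reaching the endpoint
g1 <- list(time = rep(66, 5), event = rep(0, 5))
g2 <- list(time = c(9, 8, 9), event = c(1, 1, 1))
ctl <- list(time = c(8, 6, 8), event = c(1, 1, 1))

test_that("truncated means match the reported group summaries", {
  expect_equal(truncatedMean(g2$time), 8.6)
  expect_equal(truncatedMean(ctl$time), 7.3)
  expect_equal(truncatedMean(66), 66)
  expect_equal(truncatedMean(c(9, 8, 9), decimals = 2), 8.66)
  expect_error(truncatedMean(numeric(0)), "non-empty")
  # medians differ from the truncated means for these small groups
  expect_equal(stats::median(g2$time), 9)
  expect_equal(stats::median(ctl$time), 8)
})

test_that("product-limit estimator handles censoring, ties and steps", {
  kmC <- kmEstimate(g1$time, g1$event)
  expect_true(all(kmC$surv == 1))
  expect_equal(kmSurvivalAt(kmC, 66), 1)
  km <- kmEstimate(c(6, 8, 8), c(1, 1, 1))
  expect_equal(kmSurvivalAt(km, 7), 2 / 3)
  expect_equal(kmSurvivalAt(km, 8), 0)
  kmTie <- kmEstimate(c(5, 5, 5), c(1, 1, 1))
  expect_equal(nrow(kmTie), 1)
  expect_equal(kmTie$surv, 0)
  expect_error(kmEstimate(numeric(0), numeric(0)), "records")
})

test_that("KM equals the empirical survival function without censoring", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      t <- sample(1:10, 8, replace = TRUE)
      km <- kmEstimate(t, rep(1, 8))
      for (tt in 0:11)
        expect_equal(kmSurvivalAt(km, tt), mean(t > tt))
    }
  })
})

test_that("chi-square tail matches the erfc identity and the reference", {
  expect_equal(chi2UpperTail(0), 1)
  expect_equal(chi2UpperTail(3.841), 0.05, tolerance = 1e-3)
  xs <- c(0.01, 0.5, 1, 2.77, 3.84, 7.34, 15)
  expect_equal(chi2UpperTail(xs),
               stats::pchisq(xs, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(all(diff(chi2UpperTail(xs)) < 0))
  expect_error(chi2UpperTail(-1), "x")
})

test_that("Mantel-Cox test reproduces the hand-computed study contrasts", {
  # sham vs control: O-E = -1.3, V = 0.61 -> chi2 = 2.7705, p ~ 0.096
  r <- logrankTest(g2$time, g2$event, ctl$time, ctl$event)
  expect_equal(r@statistic, 1.69 / 0.61, tolerance = 1e-9)
  expect_equal(r@p, 0.0960, tolerance = 1e-3)
  expect_equal(r@pReported, "0.09")
  expect_equal(unname(r@observed["A"]), 3)
  expect_equal(unname(r@expected["A"]), 4.3, tolerance = 1e-9)
  # treated vs each: chi2 ~ 7.34, p < 0.01
  for (other in list(g2, ctl)) {
    ro <- logrankTest(g1$time, g1$event, other$time, other$event)
    expect_equal(ro@statistic, 7.3404, tolerance = 1e-3)
    expect_lt(ro@p, 0.01)
    expect_equal(ro@pReported, "<0.01")
  }
})

test_that("log-rank agrees with the survival-package implementation", {
  skip_if_not_installed("survival")
  cases <- list(list(a = g2, b = ctl), list(a = g1, b = g2),
                list(a = g1, b = ctl),
                list(a = list(time = c(3, 5, 7, 9), event = c(1, 0, 1, 1)),
                     b = list(time = c(2, 4, 8, 8), event = c(1, 1, 1, 0))))
  for (cs in cases) {
    mine <- logrankTest(cs$a$time, cs$a$event, cs$b$time, cs$b$event)
    time <- c(cs$a$time, cs$b$time); event <- c(cs$a$event, cs$b$event)
    grp <- rep(1:2, c(length(cs$a$time), length(cs$b$time)))
    ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(mine@statistic, unname(ref$chisq), tolerance = 1e-9)
    expect_equal(mine@p, stats::pchisq(ref$chisq, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("log-rank p is consistent with the exact permutation oracle", {
  # at 6-8 animals the exact permutation p is granular (multiples of
  # 1/C(n, nA)) and conservative relative to the 1-df chi-square tail;
  # the two must agree on the significance decision, and the enumerated
  # values are frozen as regression anchors
  cases <- list(
    list(a = g2, b = ctl, perm = 6 / 20),
    list(a = g1, b = g2, perm = 1 / 56),
    list(a = list(time = c(3, 5, 7), event = c(1, 1, 1)),
         b = list(time = c(4, 6, 9, 9), event = c(1, 1, 1, 0)),
         perm = 12 / 35))
  for (cs in cases) {
    chi2P <- logrankTest(cs$a$time, cs$a$event, cs$b$time, cs$b$event)@p
    permP <- permutationLogrankP(cs$a$time, cs$a$event,
                                 cs$b$time, cs$b$event)
    expect_equal(permP, cs$perm, tolerance = 1e-12)
    expect_equal(chi2P < 0.05, permP < 0.05)
    expect_gte(permP, chi2P)  # conservative at these sizes
    nAll <- length(cs$a$time) + length(cs$b$time)
    expect_gte(permP, 1 / choose(nAll, length(cs$a$time)) - 1e-12)
  }
})

test_that("the test is symmetric and degenerate cases behave", {
  r1 <- logrankTest(g2$time, g2$event, ctl$time, ctl$event)
  r2 <- logrankTest(ctl$time, ctl$event, g2$time, g2$event)
  expect_equal(r1@statistic, r2@statistic)
  expect_equal(r1@p, r2@p)
  same <- logrankTest(g2$time, g2$event, g2$time, g2$event)
  expect_equal(same@statistic, 0)
  expect_equal(same@p, 1)
  expect_error(logrankTest(rep(66, 3), rep(0, 3), rep(66, 2), rep(0, 2)),
               "at least one event")
  expect_error(logrankTest(numeric(0), numeric(0), ctl$time, ctl$event),
               "non-empty")
})

test_that("pairwise comparisons and summaries cover a 3-group cohort", {
  cohort <- data.frame(
    animal_id = sprintf("pig%02d", 1:11),
    group = rep(c("treated", "sham", "control"), c(5, 3, 3)),
    time_days = c(g1$time, g2$time, ctl$time),
    event = c(g1$event, g2$event, ctl$event))
  res <- logrankPairwise(cohort, pooledAgainst = "treated")
  expect_length(res, 4)
  expect_lt(res[["treated vs sham"]]@p, 0.01)
  expect_lt(res[["treated vs control"]]@p, 0.01)
  expect_equal(res[["sham vs control"]]@p, 0.096, tolerance = 1e-3)
  expect_lt(res[["treated vs rest"]]@p, 0.01)
  s <- survivalSummary(cohort)
  expect_equal(s$mean_truncated[s$group == "sham"], 8.6)
  expect_equal(s$mean_truncated[s$group == "control"], 7.3)
  expect_equal(s$median[s$group == "sham"], 9)
  expect_equal(s$events[s$group == "treated"], 0)
})
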