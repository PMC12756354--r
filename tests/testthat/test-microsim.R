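test_that("identical seeds give bit-identical cohorts", {
  k <- korea_unrounded_params()
  a <- simulate_cohort(k, n = 20000, seed = 7, keep_records = TRUE)
  b <- simulate_cohort(k, n = 20000, seed = 7, keep_records = TRUE)
  expect_identical(a, b)
  c <- simulate_cohort(k, n = 20000, seed = 8)
  expect_false(identical(a$net_benefit, c$net_benefit))
})

test_that("every record maps to one of the 24 types with the right arm split", {
  k <- korea_params()
  sim <- simulate_cohort(k, n = 50000, seed = 13, keep_records = TRUE)
  rec <- sim$records
  expect_true(all(rec$patient_type %in% 1:24))
  expect_identical(rec$patient_type <= 12, rec$ai_used)
  # conventional-arm patients accrue nothing
  acc <- rowSums(abs(rec[, grep("^accrual_", names(rec))]))
  expect_true(all(acc[!rec$ai_used] == 0))
  # aggregate net equals the sum of per-record accruals (scaled)
  expect_equal(sim$net_benefit,
               sum(acc_signed <- rowSums(rec[, grep("^accrual_",
                                                    names(rec))])) *
                 sim$n_total / sim$n)
})

test_that("per-term Monte-Carlo means are unbiased for the closed forms", {
  k <- korea_unrounded_params()
  n <- 400000L
  sim <- simulate_cohort(k, n = n, seed = 17)
  closed <- coef(pd_cba(k))
  dc <- derived_counts(k)
  tf <- k$persons_per_visit * k$wage_65plus * k$employment_65plus *
    k$hours_pet
  trf <- k$persons_per_visit * k$transport_roundtrip
  unit <- c(MB1 = k$cost_pet, MB2 = k$cost_pet, MC1 = k$cost_pet,
            MC2 = k$cost_pet, MC3 = k$cost_ai, MC4 = k$cost_ai,
            MC5 = k$cost_ai, MB3 = k$cost_early, MC6 = k$cost_early,
            MB4 = k$cost_delayed, MC7 = k$cost_delayed,
            MB5 = tf, MB6 = tf, MC8 = tf, MC9 = tf,
            MB7 = trf, MC10 = trf, MC11 = trf)
  nt <- dc[["n_total"]]
  for (id in names(closed)) {
    got <- sim$term_totals[[id]]
    want <- closed[[id]]
    # each term total is (trigger count / n) * unit * n_total, so its
    # sampling error is binomial in the trigger probability p
    p_trig <- want / (unit[[id]] * nt)
    se <- unit[[id]] * nt * sqrt(p_trig * (1 - p_trig) / n)
    expect_lt(abs(got - want), 4 * se, label = id)
  }
})

test_that("the aggregate net converges to the closed form within 3 SE", {
  k <- korea_unrounded_params()
  sim <- simulate_cohort(k, n = 400000L, seed = 19)
  closed <- pd_cba(k)$net_benefit
  expect_lt(abs(sim$net_benefit - closed), 3 * sim$se)
})

test_that("empirical subgroup frequencies match the expected partition", {
  k <- korea_params()
  n <- 200000L
  sim <- simulate_cohort(k, n = n, seed = 23, keep_records = TRUE)
  rec <- sim$records
  correct <- ifelse(rec$pd_status, rec$ai_positive, !rec$ai_positive)
  key <- paste0(ifelse(rec$pd_status, "PD", "nonPD"),
                ifelse(rec$economic_burden, "yes", "no"),
                ifelse(correct, 1, 2))
  emp <- table(key) / n
  sg <- subgroup_counts(k)
  prop <- unclass(sg) / attr(sg, "n_total")
  names(prop) <- c("PDno1", "PDno2", "nonPDno1", "nonPDno2",
                   "PDyes1", "PDyes2", "nonPDyes1", "nonPDyes2")
  for (nm in names(prop)) {
    se <- sqrt(prop[[nm]] * (1 - prop[[nm]]) / n)
    expect_lt(abs(emp[[nm]] - prop[[nm]]), 4 * se, label = nm)
  }
})

test_that("replicate estimator behaves like a mean of independent cohorts", {
  k <- korea_unrounded_params()
  est <- estimate_net_benefit_mc(k, n = 5000, replicates = 8, seed = 29)
  expect_length(est$nets, 8L)
  expect_equal(est$mean, mean(est$nets))
  expect_equal(est$se, stats::sd(est$nets) / sqrt(8))

  # degenerate economy: all unit costs zero
  z <- modify_params(k, cost_pet = 0, cost_ai = 0, cost_early = 0,
                     cost_delayed = 0, wage_65plus = 0,
                     transport_roundtrip = 0)
  ez <- estimate_net_benefit_mc(z, n = 2000, replicates = 4, seed = 31)
  expect_identical(ez$mean, 0)
  expect_identical(ez$se, 0)

  # 1/n variance scaling: halving n roughly doubles replicate variance
  v_small <- stats::var(estimate_net_benefit_mc(k, n = 1000,
                                                replicates = 150,
                                                seed = 37)$nets)
  v_large <- stats::var(estimate_net_benefit_mc(k, n = 2000,
                                                replicates = 150,
                                                seed = 41)$nets)
  expect_gt(v_small / v_large, 1.4)
  expect_lt(v_small / v_large, 2.9)
})

test_that("a perfect test with no burden leaves only triage savings and AI fees", {
  k <- modify_params(korea_unrounded_params(), sens_ai = 1, spec_ai = 1,
                     pet_unaffordable = 0)
  sim <- simulate_cohort(k, n = 50000, seed = 43)
  nz <- names(sim$term_totals)[sim$term_totals > 0]
  expect_true(all(nz %in% c("MB2", "MB6", "MB7", "MC3")))
  expect_true(all(c("MB2", "MC3") %in% nz))
})
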