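test_that("adoption sweep scales scenarios linearly", {
  k <- korea_unrounded_params()
  sw <- adoption_sweep(k, c(0.3, 0.65, 1))
  nets <- vapply(sw, `[[`, numeric(1), "net_benefit")
  expect_length(sw, 3L)
  expect_equal(unname(nets[2] / nets[1]), 65 / 30, tolerance = 1e-12)
  expect_equal(unname(nets[3] / nets[1]), 100 / 30, tolerance = 1e-12)
  expect_equal(adoption_sweep(k, 0)[[1]]$net_benefit, 0)
  expect_error(adoption_sweep(k, numeric(0)), "non-empty")
})

test_that("one-way sensitivity recovers the published unaffordability range", {
  k <- korea_unrounded_params()
  s <- one_way_sensitivity(k, "pet_unaffordable", c(0, 0.5, 1))
  expect_equal(s$net_benefit[1] / 1e6, 10.90, tolerance = 5e-4)
  expect_equal(s$net_benefit[3] / 1e6, 5.53, tolerance = 1e-3)
  expect_equal(s$ratio_pct[1], 117.3, tolerance = 1e-3)
  expect_equal(s$ratio_pct[3], 59.5, tolerance = 1e-3)
  # affinity: the mid-point lies on the chord
  expect_equal(s$net_benefit[2],
               (s$net_benefit[1] + s$net_benefit[3]) / 2,
               tolerance = 1e-9)
  # an affine function changes sign at most once over the grid
  signs <- sign(one_way_sensitivity(k, "pet_unaffordable",
                                    seq(0, 1, 0.1))$net_benefit)
  expect_lte(sum(diff(signs) != 0), 1L)
})

test_that("sweeping the AI price strictly decreases the net", {
  k <- korea_unrounded_params()
  s <- one_way_sensitivity(k, "cost_ai", seq(1, 400, length.out = 9))
  expect_true(all(diff(s$net_benefit) < 0))
  expect_error(one_way_sensitivity(k, "label", 1:3), "sweepable")
  expect_error(one_way_sensitivity(k, "cost_ai", c(2, 1)),
               "increasing")
})

test_that("break-even price zeroes the net and matches bisection", {
  u <- usa_params()
  c_star <- break_even_ai_cost(u)
  expect_equal(as.numeric(c_star), 1506.62, tolerance = 1e-5)
  expect_lt(abs(attr(c_star, "net_at_breakeven")), 1e-9 * 7.6e7)

  # independent root-finding oracle on net(cost_ai)
  f <- function(cai)
    pd_cba(modify_params(u, cost_ai = cai))$net_benefit
  root <- stats::uniroot(f, c(0, 10 * as.numeric(c_star)),
                         tol = 1e-10)$root
  expect_equal(root, as.numeric(c_star), tolerance = 1e-6)

  # already at break-even: the solver is a fixed point
  u_star <- modify_params(u, cost_ai = as.numeric(c_star))
  expect_equal(as.numeric(break_even_ai_cost(u_star)),
               as.numeric(c_star), tolerance = 1e-9)

  # no AI usage: undefined
  expect_true(is.na(break_even_ai_cost(u, adoption = 0)))
})

test_that("break-even holds for random parameter sets", {
  set.seed(51)
  for (i in 1:10) {
    p <- random_parameters()
    c_star <- break_even_ai_cost(p, adoption = runif(1, 0.05, 1))
    expect_false(is.na(c_star))  # adoption > 0 so volume > 0
  }
})

test_that("stationary projections are constant and cumulative sums prefix", {
  k <- korea_unrounded_params()
  flat <- project_long_term(k, 2025, 2050,
                            adoption_ramp = function(kk) 0.3,
                            cohort_growth = 0)
  expect_equal(flat$annual_net, rep(flat$annual_net[1], 26))
  expect_equal(flat$cumulative_net[26], 26 * flat$annual_net[1])

  proj <- project_long_term(k, 2025, 2050, cohort_growth = 0)
  # prefix-sum oracle: recompute each year independently
  indep <- vapply(seq_len(26), function(i)
    pd_cba(k, adoption = proj$adoption[i])$net_benefit, numeric(1))
  expect_equal(proj$annual_net, indep)
  expect_equal(proj$cumulative_net, cumsum(indep))
  # default linear ramp reaches 80% at year 10 and stays
  expect_equal(proj$adoption[1], 0.3)
  expect_equal(proj$adoption[11], 0.8)
  expect_equal(proj$adoption[26], 0.8)
})

test_that("projection is homogeneous in cohort size and discounts correctly", {
  k <- korea_unrounded_params()
  p1 <- project_long_term(k, 2025, 2034, cohort_growth = 0.02)
  k2 <- modify_params(k, n_pd = 2 * k$n_pd)
  p2 <- project_long_term(k2, 2025, 2034, cohort_growth = 0.02)
  expect_equal(p2$annual_net, 2 * p1$annual_net)

  d <- project_long_term(k, 2025, 2034, cohort_growth = 0,
                         discount_rate = 0.03)
  und <- project_long_term(k, 2025, 2034, cohort_growth = 0)
  expect_equal(d$annual_net, und$annual_net / 1.03^(0:9))

  lg <- project_long_term(k, 2025, 2050, adoption_ramp = "logistic")
  expect_true(all(lg$adoption >= 0 & lg$adoption <= 1))
  expect_true(all(diff(lg$adoption) >= 0))

  expect_error(project_long_term(k, 2030, 2025))
  expect_error(project_long_term(k, 2025, 2030,
                                 adoption_ramp = function(kk) 1.5),
               "\\[0, 1\\]")
  expect_error(project_long_term(k, 2025, 2030, cohort_growth = -1),
               "non-positive")
})
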