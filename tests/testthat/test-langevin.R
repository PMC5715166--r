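test_that("negative-production accumulator conserves and clamps", {
  expect_equal(apply_negative_accumulator(-5, 0),
               list(applied = 0, deficit = -5))
  expect_equal(apply_negative_accumulator(8, -5),
               list(applied = 3, deficit = 0))
  expect_equal(apply_negative_accumulator(0, 0),
               list(applied = 0, deficit = 0))
  expect_error(apply_negative_accumulator(1, 2), "deficit")
  # conservation and sign invariants over random sequences
  set.seed(1)
  for (rep in 1:20) {
    raws <- sample(-10:15, 50, replace = TRUE)
    def <- 0
    applied <- numeric(50)
    for (i in seq_along(raws)) {
      r <- apply_negative_accumulator(raws[i], def)
      applied[i] <- r$applied
      def <- r$deficit
      expect_gte(r$applied, 0)
      expect_lte(r$deficit, 0)
    }
    expect_equal(sum(applied) + def, sum(raws))
  }
})

test_that("select_tau reproduces the hand-evaluated step bounds", {
  gp <- ref_gene()  # k_g b_m b_p = 100, gamma_p = 1
  cfg <- step_config(epsilon = 0.03)

  # protein degradation binds: tau = max(eps*p,1)/(gamma_p p) = 3/100
  st <- system_state(g = 1, m = 1, p = 100)
  out <- select_tau(st, gp, "BOTH_BURSTS", cfg)
  expect_equal(out$tau, 0.03)
  expect_null(out$critical)

  # negligible degradation, large p: the burst bound eps*p / (k_g b_m b_p)
  gp2 <- gene_params(5, 95, 200, 10, 100, 1e-9)
  st2 <- system_state(g = 1, m = 1, p = 1000)
  expect_equal(select_tau(st2, gp2, "BOTH_BURSTS", cfg)$tau,
               0.03 * 1000 / 100)

  # eps*p <= 1 with b_p > 1: a whole burst fits, tau = b_p/(k_g b_m b_p)
  st3 <- system_state(g = 1, m = 1, p = 10)
  set.seed(1)
  out3 <- select_tau(st3, gp2, "BOTH_BURSTS", cfg)
  # p = 10 is at the critical threshold boundary (p < 10 is critical), so
  # no critical channel exists and the burst bound 1/(k_g b_m) holds
  expect_equal(out3$tau, min(1 / 10, out3$tau))
  expect_equal(out3$tau, 0.1)

  # extra channels enter the non-burst bounds
  out4 <- select_tau(st2, gp2, "BOTH_BURSTS", cfg,
                     extra_channels = list(list(a = 1000, nu = -1)))
  expect_equal(out4$tau, min(0.03 * 1000 / 100,
                             max(0.03 * 1000, 1) / 1000,
                             max(0.03 * 1000, 1)^2 / 1000))
})

test_that("langevin_step: trivial cases and the production moments", {
  cfg <- step_config()
  # no upstream production and empty state: only time advances
  silent <- gene_params(5, 95, 0, 10, 0, 1)
  st <- system_state(g = 1, m = 0, p = 0)
  out <- langevin_step(st, 0.05, "BOTH_BURSTS", silent, cfg)
  expect_equal(out$p, 0)
  expect_equal(out$t, 0.05)

  # applied production over many accumulator-chained steps matches the
  # closed-form mean (negative-burst removal preserves the mean)
  gp <- ref_gene()
  pm <- production_moments("BOTH_BURSTS", gp, tau = 0.03)
  set.seed(99)
  n <- 2e4
  applied <- numeric(n)
  def <- 0
  for (i in seq_len(n)) {
    raw <- burstsim:::round_half_away(rnorm(1, pm$delta, pm$sd))
    r <- apply_negative_accumulator(raw, def)
    applied[i] <- r$applied
    def <- r$deficit
  }
  se <- sd(applied) / sqrt(n)
  expect_lt(abs(mean(applied) + def / n - pm$delta), 3 * se)

  # a step too large for the Bernoulli gene switch errors out
  expect_error(langevin_step(system_state(g = 1, m = 0, p = 50), 0.5,
                             "PROTEIN_BURST", gp, cfg), "tau")
})

test_that("burst Langevin trajectories are reproducible and non-negative", {
  gp <- ref_gene()
  a <- bl_simulate(gp, t_end = 30, regime = "BOTH_BURSTS", seed = 11)
  b <- bl_simulate(gp, t_end = 30, regime = "BOTH_BURSTS", seed = 11)
  expect_identical(a$states, b$states)
  expect_true(all(a$states[, "p"] >= 0))
  expect_true(all(a$states[, "p"] == floor(a$states[, "p"])))
  expect_true(all(is.na(a$states[, c("g", "m")])))

  # accumulator conservation over the whole run
  d <- a$diagnostics
  expect_equal(d$applied_production + d$deficit, d$raw_production)
  expect_true(all(d$deficit <= 0))
})

test_that("negative-burst removal preserves the production mean in runs", {
  gp <- ref_gene()
  tr <- bl_simulate(gp, t_end = 2000, regime = "BOTH_BURSTS", seed = 21,
                    sample_grid = c(0, 2000))
  d <- tr$diagnostics
  rate <- d$applied_production[2] / 2000
  # production rate k_g b_m b_p = 100; variance rate of the draws ~ 6100
  expect_lt(abs(rate - 100), 4 * sqrt(6100 / 2000))
})

test_that("each regime's Langevin reproduces its steady-state statistics", {
  cfg <- step_config()
  cases <- list(
    list(par = gene_params(2, 50, 100, 5, 10, 1), reg = "BOTH_BURSTS"),
    list(par = gene_params(2, 40, 60, 4, 4, 1), reg = "MRNA_BURST"),
    list(par = gene_params(1, 1, 30, 10, 20, 1), reg = "PROTEIN_BURST"))
  for (cs in cases) {
    apx <- steady_state_moments(cs$par, "burst", cs$reg)
    ta <- burstsim:::run_timeavg("BL", cs$par, cs$reg, t_burn = 20,
                                 t_avg = 3000, cfg = cfg, seed = 31)
    # mean must match the exact value; SD the regime approximation
    expect_lt(abs(ta$mean[2] - apx$p_bar),
              4 * ta$se_mean[2] + 0.02 * apx$p_bar)
    expect_lt(abs(ta$sd[2] - sqrt(apx$var_p)),
              4 * ta$se_sd[2] + 0.1 * sqrt(apx$var_p))
  }
})

test_that("reference gene: burst Langevin ensemble mean is ~100", {
  es <- ensemble_steady_state("BL", ref_gene(), regime = "BOTH_BURSTS",
                              n_points = 400, seed_base = 51)
  expect_equal(es$n_points, 400)
  expect_equal(sum(es$histogram), 400)
  expect_lt(abs(es$mean - 100), 3 * es$stderr_mean + 2)
})

test_that("NO_BURST mode runs as plain CLE with a notice", {
  par <- small_gene()
  expect_message(tr <- bl_simulate(par, t_end = 10, seed = 3), "NO_BURST")
  expect_true(all(tr$states >= 0))
})
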