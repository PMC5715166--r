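test_that("Hill fraction identities", {
  expect_equal(hill_fraction(200, 200, 3), 0.5)
  expect_equal(hill_fraction(200, 200, -4), 0.5)
  expect_equal(hill_fraction(0, 200, 3), 1)
  expect_equal(hill_fraction(400, 200, 3), 1 / 9)  # 200^3/(200^3+400^3)
  expect_equal(hill_fraction(0, 200, -2), 0)       # activation limit
  expect_equal(hill_fraction(123, 200, 0), 0.5)    # n_H = 0 identity
  # repression is monotone decreasing
  f <- hill_fraction(c(0, 50, 200, 800), 200, 3)
  expect_true(all(diff(f) < 0))
  expect_error(hill_fraction(-1, 200, 3), "p1")
})

test_that("downstream transcription rate follows the leak convention", {
  net <- preset("fig6")$network
  # fully activated: k_m2 * 1 + k_l = 260; off gene contributes nothing
  expect_equal(downstream_transcription_rate(1, 0, net), 260)
  expect_equal(downstream_transcription_rate(0, 0, net), 0)
  # fully repressed: only the leak remains
  expect_equal(downstream_transcription_rate(1, 1e9, net), 60,
               tolerance = 1e-6)
  # effective burst size at p1 = 0 gives the activated steady state
  b_m2_eff <- 260 / 105
  p2_act <- 5 / 105 * 260 / 10 * 100 / 1
  expect_equal(5 * b_m2_eff * 10, p2_act)
  expect_equal(p2_act, 123.8095, tolerance = 1e-4)
})

test_that("upstream fixed point matches k_g1 b_m1 b_p1 / gamma_p1", {
  net <- preset("fig6")$network
  u <- net$upstream  # b_m1 = 1, b_p1 = 1
  bs <- burst_statistics(u)
  expect_equal(bs$b_m_bar, 1)
  expect_equal(bs$b_p_bar, 1)
  expect_equal(steady_state_moments(u)$p_bar,
               u$k_g * bs$b_m_bar * bs$b_p_bar / u$gamma_p)
})

test_that("silent upstream leaves the downstream gene isolated", {
  net0 <- preset("fig6")$network
  up_silent <- gene_params(5, 100, 0, 10, 10, 1)
  net <- regulated_network(up_silent, net0$downstream, net0$K, net0$n_H,
                           net0$k_l)
  # p1 stays 0, so the downstream runs at k_m2 + k_l = 260
  iso <- gene_params(5, 100, 260, 10, 100, 1)
  p2_iso <- steady_state_moments(iso)$p_bar
  for (sim in c("SSA", "BL")) {
    ta <- burstsim:::run_timeavg(sim, net, NULL, t_burn = 20, t_avg = 1500,
                                 cfg = step_config(), seed = 4)
    expect_equal(ta$mean[1], 0)
    expect_lt(abs(ta$mean[2] - p2_iso), 4 * ta$se_mean[2] + 0.02 * p2_iso)
  }
})

test_that("network Langevin tracks the SSA and mean p2 is monotone", {
  net0 <- preset("fig6")$network
  p2_bl <- numeric(3)
  for (i in seq_along(c(1, 10, 100))) {
    b_p1 <- c(1, 10, 100)[i]
    up <- gene_params(5, 100, 105, 10, b_p1 * 10, 1)  # b_m1 = 1
    net <- regulated_network(up, net0$downstream, net0$K, net0$n_H, net0$k_l)
    ta_bl <- burstsim:::run_timeavg("BL", net, NULL, t_burn = 20,
                                    t_avg = 2000, cfg = step_config(),
                                    seed = 40 + i)
    ta_ssa <- burstsim:::run_timeavg("SSA", net, NULL, t_burn = 20,
                                     t_avg = 2000, cfg = step_config(),
                                     seed = 50 + i)
    p2_bl[i] <- ta_bl$mean[2]
    se <- sqrt(ta_bl$se_mean[2]^2 + ta_ssa$se_mean[2]^2)
    expect_lt(abs(ta_bl$mean[2] - ta_ssa$mean[2]),
              4 * se + 0.05 * ta_ssa$mean[2])
  }
  # more repressor -> less downstream protein (within Monte-Carlo error)
  expect_true(all(diff(p2_bl) < 5))
  expect_lt(p2_bl[3], p2_bl[1])
})

test_that("network trajectories are reproducible and integer-valued", {
  net <- preset("fig6")$network
  a <- network_bl_simulate(net, t_end = 20, seed = 8)
  b <- network_bl_simulate(net, t_end = 20, seed = 8)
  expect_identical(a$states, b$states)
  expect_true(all(a$states >= 0))
  s <- ssa_simulate_network(net, t_end = 10, seed = 8)
  expect_identical(s$states,
                   ssa_simulate_network(net, t_end = 10, seed = 8)$states)
})
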