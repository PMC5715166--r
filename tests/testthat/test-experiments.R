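test_that("minimal ensembles complete and count their points", {
  es <- ensemble_steady_state("SSA", small_gene(), n_points = 2,
                              t_relax = 5, seed_base = 1)
  expect_equal(es$n_points, 2)
  expect_equal(sum(es$histogram), 2)
  expect_equal(nrow(es$samples), 2)
})

test_that("ensembles are reproducible from (params, seed_base)", {
  a <- ensemble_steady_state("BL", ref_gene(), regime = "BOTH_BURSTS",
                             n_points = 50, seed_base = 7)
  b <- ensemble_steady_state("BL", ref_gene(), regime = "BOTH_BURSTS",
                             n_points = 50, seed_base = 7)
  expect_identical(a$samples, b$samples)
})

test_that("a degenerate one-cell grid equals a single ensemble comparison", {
  par <- gene_params(2, 50, 100, 5, 10, 1)
  g <- mean_error_grid(par, regime = "BOTH_BURSTS", seed_base = 5,
                       r_target = 0.01)
  expect_equal(nrow(g), 1)
  # the % error is consistent with its own reported components
  expect_equal(g$err_mean_pct,
               100 * (g$mean_bl - g$mean_ssa) / g$mean_ssa)
  expect_lt(abs(g$err_mean_pct), 4 * g$se_err_mean_pct + 3)
})

test_that("distribution overlay: distance, modes and error handling", {
  es1 <- ensemble_steady_state("SSA", small_gene(), n_points = 200,
                               t_relax = 10, seed_base = 1)
  ov_same <- distribution_overlay(es1, es1)
  expect_equal(ov_same$tv_distance, 0)

  es2 <- ensemble_steady_state("SSA", small_gene(), n_points = 200,
                               t_relax = 10, seed_base = 300)
  ov <- distribution_overlay(es1, es2)
  expect_lt(ov$tv_distance, 0.5)

  es_other <- ensemble_steady_state("SSA", ref_gene(), n_points = 50,
                                    t_relax = 5, seed_base = 1)
  expect_error(distribution_overlay(es1, es_other), "parameterizations")

  ta <- ensemble_steady_state("SSA", small_gene(), mode = "timeavg",
                              t_avg = 100, seed_base = 1)
  expect_error(distribution_overlay(ta, ta), "replicas")
})

test_that("bimodal regime: both simulators show two protein modes", {
  par <- bimodal_gene()  # slow switching, fast mRNA: protein bursts
  es_ssa <- ensemble_steady_state("SSA", par, n_points = 800, t_relax = 60,
                                  seed_base = 100)
  es_bl <- ensemble_steady_state("BL", par, regime = "PROTEIN_BURST",
                                 n_points = 800, t_relax = 60,
                                 seed_base = 100)
  ov <- distribution_overlay(es_bl, es_ssa)
  expect_equal(length(ov$modes_a), 2)
  expect_equal(length(ov$modes_b), 2)
  # matching mode locations (low mode near 0, high mode near k_m/gamma_m *
  # k_p/gamma_p = 100), within a couple of bins
  expect_equal(sort(ov$modes_a), sort(ov$modes_b),
               tolerance = 0.4)
  # and the distributions agree about as well as two SSA runs do
  es_ssa2 <- ensemble_steady_state("SSA", par, n_points = 800, t_relax = 60,
                                   seed_base = 5000)
  null_tv <- distribution_overlay(es_ssa, es_ssa2)$tv_distance
  expect_lt(ov$tv_distance, 2 * null_tv + 0.1)
})

test_that("switching dynamics: plateau levels and BL/SSA agreement", {
  par <- preset("fig7")$params
  sched <- preset("fig7")$kg_schedule
  dyn <- switching_dynamics(par, sched, t_end = 21, n_trajectories = 400,
                            sample_grid = seq(0, 21, by = 1), seed_base = 60,
                            regime = "BOTH_BURSTS")
  # pre-switch plateau: closed-form mean at k_g = 3
  p_lo <- steady_state_moments(gene_params(3, 100, 200, 10, 100, 1))$p_bar
  p_hi <- steady_state_moments(gene_params(30, 100, 200, 10, 100, 1))$p_bar
  pre <- dyn[dyn$time == 6, ]
  expect_lt(abs(pre$mean_ssa - p_lo), 4 * pre$sd_ssa / sqrt(400))
  # activated phase climbs towards the k_g = 30 level
  peak <- dyn[dyn$time == 14, ]
  expect_gt(peak$mean_ssa, 0.85 * p_hi)
  # Langevin mean stays within 3 combined stderr + 2% at every sample time
  se <- sqrt(dyn$sd_ssa^2 + dyn$sd_bl^2) / sqrt(400)
  expect_true(all(abs(dyn$mean_bl - dyn$mean_ssa) <=
                    3 * se + 0.02 * pmax(dyn$mean_ssa, 5)))
})
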