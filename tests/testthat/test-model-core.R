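test_that("burst statistics follow the kinetic definitions", {
  bs <- burst_statistics(ref_gene())
  expect_equal(bs$b_m_bar, 2)          # 200 / (5 + 95)
  expect_equal(bs$b_p_bar, 10)         # 100 / 10
  expect_equal(bs$b_p0_bar, 100 / 11)
  expect_equal(bs$q, 1 / 3)
  expect_equal(bs$var_bm, bs$b_m_bar^2 + bs$b_m_bar)
  expect_equal(bs$var_bp, bs$b_p_bar^2 + bs$b_p_bar)
  expect_equal(bs$freq_m, 5)

  # no transcription: burst size and variance collapse to zero
  silent <- gene_params(5, 95, 0, 10, 100, 1)
  expect_equal(burst_statistics(silent)$b_m_bar, 0)
  expect_equal(burst_statistics(silent)$var_bm, 0)

  # inverting the definition: k_m = b_m * (k_g + gamma_g)
  par <- gene_params(5, 100, 8 * 105, 10, 100, 1)
  expect_equal(burst_statistics(par)$b_m_bar, 8)

  # the legacy small-k_g form k_m / gamma_g is exposed separately
  expect_equal(mrna_burst_size_legacy(ref_gene()), 200 / 95)

  expect_error(gene_params(5, -1, 200, 10, 100, 1), "positive")
  expect_error(gene_params(5, 95, 200, 10, 100, 1, n_copies = 0), "n_copies")
})

test_that("regime classification splits on the timescale ratios", {
  lab <- function(gg, gm, gp, kg = 5)
    classify_regime(gene_params(kg, gg, 100, gm, 10, gp))$label
  expect_equal(lab(100, 10, 1), "BOTH_BURSTS")   # boundary equality is burst
  expect_equal(lab(1, 1, 1), "NO_BURST")
  expect_equal(lab(0.1, 10, 1, kg = 0.1), "PROTEIN_BURST")
  expect_equal(lab(10, 1, 1), "MRNA_BURST")
  expect_equal(lab(99.9, 10, 1), "PROTEIN_BURST") # just inside the boundary
  expect_error(classify_regime(ref_gene(), threshold = 1), "threshold")
})

test_that("production moments match the regime closed forms", {
  gp <- ref_gene()
  pm <- production_moments("BOTH_BURSTS", gp, tau = 0.03)
  expect_equal(pm$delta, 3)               # k_g * b_m * b_p * tau
  expect_equal(pm$var, 183)               # 0.3 * 10 * (2*2*10 + 2*10 + 1)
  expect_equal(pm$sd, sqrt(183), tolerance = 1e-12)

  # linear in tau near zero
  pm1 <- production_moments("BOTH_BURSTS", gp, tau = 1e-6)
  expect_equal(pm1$delta / 1e-6, 100, tolerance = 1e-9)
  expect_equal(pm1$var / 1e-6, 6100, tolerance = 1e-9)

  # mRNA-burst row and its event moments
  pm2 <- production_moments("MRNA_BURST", gp, tau = 0.2)
  expect_equal(pm2$e_bar, 1)                       # k_g * tau
  expect_equal(pm2$delta, 2)
  expect_equal(pm2$var, 1 * 2 * (2 * 2 + 1))       # k_g tau b_m (2 b_m + 1)

  # inactive gene produces nothing in the protein-burst regime
  pm3 <- production_moments("PROTEIN_BURST", gp, tau = 0.1, g = 0)
  expect_equal(pm3$delta, 0)
  expect_equal(pm3$var, 0)
  pm4 <- production_moments("PROTEIN_BURST", gp, tau = 0.1, g = 1)
  expect_equal(pm4$delta, 200 * 0.1 * 10)
  expect_equal(pm4$var, 200 * 0.1 * 10 * 21)
  expect_error(production_moments("PROTEIN_BURST", gp, tau = 0.1), "g")

  # NO_BURST falls back to plain chemical-Langevin moments
  pm5 <- production_moments("NO_BURST", gp, tau = 0.5, rate = 7)
  expect_equal(pm5$delta, 3.5)
  expect_equal(pm5$var, 3.5)
  expect_error(production_moments("NO_BURST", gp, tau = 0.5), "rate")
})

test_that("compound burst variance composes events and sizes", {
  # Poisson events + geometric sizes reproduce the mRNA production variance
  kg_tau <- 0.73
  b <- 2
  expect_equal(compose_burst_variance(kg_tau, kg_tau, b, b^2 + b),
               kg_tau * b * (2 * b + 1))
  expect_equal(compose_burst_variance(3, 0, 5, 0), 0)
  expect_error(compose_burst_variance(-1, 1, 1, 1), "non-negative")
})

test_that("compound-sum simulation reproduces the composed variance", {
  # brute-force oracle: E ~ Poisson(4) events, geometric sizes of mean 3
  set.seed(42)
  n <- 1e6
  e_mean <- 4
  b_mean <- 3
  q <- 1 / (1 + b_mean)
  ev <- rpois(n, e_mean)
  sizes <- rgeom(sum(ev), q)
  tot <- numeric(n)
  idx <- rep.int(seq_len(n), ev)
  rs <- rowsum(sizes, idx)
  tot[as.integer(rownames(rs))] <- rs[, 1L]
  v_emp <- var(tot)
  v_th <- compose_burst_variance(e_mean, e_mean, b_mean, b_mean^2 + b_mean)
  m4 <- mean((tot - mean(tot))^4)
  se_var <- sqrt((m4 - v_emp^2) / n)
  expect_lt(abs(v_emp - v_th), 3 * se_var)
  expect_equal(mean(tot), e_mean * b_mean, tolerance = 0.01)
})

test_that("steady-state moments: means, variances and fractions", {
  gp <- ref_gene()
  lna <- steady_state_moments(gp)
  expect_equal(lna$m_bar, 1)
  expect_equal(lna$p_bar, 100)
  # exact protein variance: p_bar (F0 b_m b_p0 + b_p0 + 1)
  F0 <- 95 * (95 + 10 + 1 + 5) / ((95 + 10 + 5) * (95 + 1 + 5))
  expect_equal(lna$F0, F0)
  expect_equal(lna$var_p, 100 * (F0 * 2 * 100 / 11 + 100 / 11 + 1))
  expect_true(all(c(lna$F0, lna$F1, lna$F2) > 0 &
                    c(lna$F0, lna$F1, lna$F2) <= 1))

  # no translation: protein mean and variance vanish
  kp0 <- gene_params(5, 95, 200, 10, 0, 1)
  expect_equal(steady_state_moments(kp0)$p_bar, 0)
  expect_equal(steady_state_moments(kp0)$var_p, 0)

  # switching-schedule baseline: k_g = 3 with the fig7 rates
  g7 <- gene_params(3, 100, 200, 10, 100, 1)
  expect_equal(steady_state_moments(g7)$p_bar, 3 / 103 * 20 * 100)

  # regime-matched burst approximations
  b_both <- steady_state_moments(gp, "burst", "BOTH_BURSTS")
  expect_equal(b_both$var_p, 100 * (2 * 10 + 10 + 1))
  b_m <- steady_state_moments(gp, "burst", "MRNA_BURST")
  expect_equal(b_m$var_p, 100 * (2 * 100 / 11 + 100 / 11 + 1))
  expect_equal(b_m$var_m, 1 * (2 + 1))
  b_p <- steady_state_moments(gp, "burst", "PROTEIN_BURST")
  expect_equal(b_p$var_p, 100 * (lna$F2 * 2 * 10 + 10 + 1))
  expect_error(steady_state_moments(gp, "burst", "NO_BURST"), "NO_BURST")
  expect_error(steady_state_moments(gp, "burst"), "regime")
})

test_that("burst approximations converge to the LNA as gamma_g grows", {
  # b_m held at 2 by back-solving k_m; gamma_m >> gamma_p so that the
  # finite-lifetime burst size correction also vanishes
  gg <- 1e8
  par <- gene_params(5, gg, 2 * (5 + gg), 1e4, 1e5, 1)
  lna <- steady_state_moments(par)
  expect_equal(lna$F0, 1, tolerance = 1e-3)
  expect_equal(lna$F1, 1, tolerance = 1e-3)
  expect_equal(lna$F2, 1, tolerance = 1e-3)
  for (reg in c("MRNA_BURST", "BOTH_BURSTS", "PROTEIN_BURST")) {
    apx <- steady_state_moments(par, "burst", reg)
    expect_equal(apx$var_p / lna$var_p, 1, tolerance = 1e-3)
  }
  apx_m <- steady_state_moments(par, "burst", "MRNA_BURST")
  expect_equal(apx_m$var_m / lna$var_m, 1, tolerance = 1e-3)
})

test_that("negative-production probability is the rounded Gaussian tail", {
  pm <- production_moments("BOTH_BURSTS", ref_gene(), tau = 0.03)
  expect_equal(negative_production_fraction(pm$delta, pm$sd), 0.40,
               tolerance = 0.01)
  expect_lt(negative_production_fraction(100, 1), 1e-12)
  expect_equal(negative_production_fraction(0, 10), pnorm(-0.05))
  expect_error(negative_production_fraction(3, 0), "sigma")
})

test_that("variance error map: corner values, regimes and invariance", {
  # exact evaluation at the mRNA-burst corner (gamma_g = 10, gamma_m = 1)
  map <- variance_error_map(gamma_g = c(5, 10), gamma_m = c(1, 2))
  corner <- map[map$gamma_g == 10 & map$gamma_m == 1, ]
  expect_equal(corner$regime, "MRNA_BURST")
  expect_equal(corner$error_percent, 12.5, tolerance = 0.01)
  no_burst <- map[map$gamma_g == 5 & map$gamma_m == 1, ]
  expect_equal(no_burst$regime, "NO_BURST")
  expect_equal(no_burst$error_percent, 0)

  # time-unit invariance: scaling every rate by a common factor
  m1 <- variance_error_map(gamma_g = c(10, 100), gamma_m = c(1, 10),
                           k_g = 5, gamma_p = 1)
  m2 <- variance_error_map(gamma_g = 7 * c(10, 100), gamma_m = 7 * c(1, 10),
                           k_g = 7 * 5, gamma_p = 7)
  expect_equal(m1$error_percent, m2$error_percent, tolerance = 1e-10)
  expect_equal(m1$regime, m2$regime)

  path <- tempfile(fileext = ".tsv")
  write_error_map(map, path)
  back <- read.delim(path)
  expect_equal(back$error_percent, map$error_percent, tolerance = 1e-6)
})
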