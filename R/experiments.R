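default_t_relax <- function(params) {
  gp <- if (inherits(params, "regulated_network"))
    min(params$upstream$gamma_p, params$downstream$gamma_p)
  else params$gamma_p
  20 / gp
}

regime_code <- function(regime) {
  match(as_regime(regime)$label,
        c("MRNA_BURST", "BOTH_BURSTS", "PROTEIN_BURST", "NO_BURST"))
}

# one replica read out at t_relax; returns the tracked species
run_final <- function(simulator, params, regime, t_relax, cfg, seed) {
  set.seed(seed)
  empty <- numeric(0)
  if (inherits(params, "regulated_network")) {
    init <- network_fixed_point(params)
    if (simulator == "SSA") {
      r <- ssa_net_run_cpp(rates_vec(params$upstream),
                           rates_vec(params$downstream),
                           params$K, params$n_H, params$k_l,
                           params$upstream$n_copies,
                           params$downstream$n_copies,
                           as.numeric(init), t_relax, empty, -1, 0L)
      r$final[c(3L, 6L)]
    } else {
      r <- bl_net_run_cpp(rates_vec(params$upstream),
                          rates_vec(params$downstream),
                          params$K, params$n_H, params$k_l,
                          params$upstream$n_copies,
                          params$downstream$n_copies,
                          as.numeric(init[c("p1", "p2")]), t_relax,
                          cfg$epsilon, cfg$n_critical, cfg$max_halvings,
                          empty, -1, 0L)
      r$final
    }
  } else {
    init <- deterministic_fixed_point(params)
    if (simulator == "SSA") {
      r <- ssa_run_cpp(rates_vec(params), params$n_copies, as.numeric(init),
                       t_relax, empty, empty, empty, -1, 0L)
    } else {
      r <- bl_run_cpp(regime_code(regime), rates_vec(params),
                      params$n_copies, as.numeric(init), t_relax,
                      cfg$epsilon, cfg$n_critical, cfg$max_halvings,
                      empty, empty, empty, -1, 0L)
    }
    r$final[c(2L, 3L)]
  }
}

# one long run; exact time-averaged moments with batch-mean standard errors
run_timeavg <- function(simulator, params, regime, t_burn, t_avg, cfg, seed,
                        n_batch = 50L) {
  set.seed(seed)
  empty <- numeric(0)
  t_end <- t_burn + t_avg
  if (inherits(params, "regulated_network")) {
    init <- network_fixed_point(params)
    r <- if (simulator == "SSA")
      ssa_net_run_cpp(rates_vec(params$upstream), rates_vec(params$downstream),
                      params$K, params$n_H, params$k_l,
                      params$upstream$n_copies, params$downstream$n_copies,
                      as.numeric(init), t_end, empty, t_burn, n_batch)
    else
      bl_net_run_cpp(rates_vec(params$upstream), rates_vec(params$downstream),
                     params$K, params$n_H, params$k_l,
                     params$upstream$n_copies, params$downstream$n_copies,
                     as.numeric(init[c("p1", "p2")]), t_end, cfg$epsilon,
                     cfg$n_critical, cfg$max_halvings, empty, t_burn, n_batch)
  } else {
    init <- deterministic_fixed_point(params)
    r <- if (simulator == "SSA")
      ssa_run_cpp(rates_vec(params), params$n_copies, as.numeric(init),
                  t_end, empty, empty, empty, t_burn, n_batch)
    else
      bl_run_cpp(regime_code(regime), rates_vec(params), params$n_copies,
                 as.numeric(init), t_end, cfg$epsilon, cfg$n_critical,
                 cfg$max_halvings, empty, empty, empty, t_burn, n_batch)
  }
  blen <- t_avg / n_batch
  bm1 <- r$ta_s1 / blen        # per-batch means, one column per species
  bm2 <- r$ta_s2 / blen        # per-batch second moments
  mean_ <- colSums(r$ta_s1) / t_avg
  m2 <- colSums(r$ta_s2) / t_avg
  var_ <- pmax(0, m2 - mean_^2)
  se_mean <- apply(bm1, 2, stats::sd) / sqrt(n_batch)
  # linearized per-batch variance statistic (keeps the mean/second-moment
  # covariance): v_b = m2_b - 2*mean*m1_b + mean^2 averages to var exactly
  vb <- bm2 - 2 * sweep(bm1, 2, mean_, `*`) +
    matrix(mean_^2, n_batch, length(mean_), byrow = TRUE)
  se_var <- apply(vb, 2, stats::sd) / sqrt(n_batch)
  sd_ <- sqrt(var_)
  se_sd <- ifelse(sd_ > 0, se_var / (2 * sd_), NA_real_)
  list(mean = mean_, sd = sd_, se_mean = se_mean, se_sd = se_sd,
       t_avg = t_avg)
}

#' Steady-state ensemble of a stochastic simulator
#'
#' Summarizes the stationary distribution of a gene (or of the two-gene
#' network) under either simulator. Two sampling protocols:
#' \describe{
#'   \item{`"replicas"` (default)}{`n_points` independent trajectories from
#'     seeds `seed_base .. seed_base + n_points - 1`, each started at the
#'     rounded deterministic fixed point and read out at `t_relax`
#'     (default 20 protein lifetimes). Gives genuinely independent points
#'     and a per-molecule histogram.}
#'   \item{`"timeavg"`}{one long run, burn-in `t_relax`, then exact
#'     time-weighted first and second moments over a window `t_avg`, with
#'     batch-mean standard errors (`n_batch` batches). Far more efficient
#'     per unit of computer time for mean/SD comparisons; no histogram.}
#' }
#'
#' @param simulator `"SSA"` (exact Gillespie) or `"BL"` (burst Langevin).
#' @param params a [gene_params()] or [regulated_network()] object.
#' @param regime regime for the burst Langevin run (`NULL` = classify
#'   automatically; ignored for SSA and for networks, which run both-bursts).
#' @param n_points number of replicas (replicas mode).
#' @param t_relax relaxation/burn-in time (default `20/gamma_p`).
#' @param cfg a [step_config()].
#' @param seed_base integer; replica `i` uses seed `seed_base + i - 1`.
#' @param mode `"replicas"` or `"timeavg"`.
#' @param t_avg averaging window for `"timeavg"` (time units; default 4000).
#' @param n_batch batches for the batch-mean standard errors.
#' @return An object of class `ensemble_summary`: `n_points`, `mean`, `sd`,
#'   `stderr_mean`, `stderr_sd`, `histogram` (replicas mode; integer table
#'   of the protein of interest), `samples` (replicas mode; matrix with one
#'   column per tracked species), `species`, `params`, `regime`,
#'   `seed_base`, `mode`. For networks the protein of interest is `p2`
#'   (upstream `p1` summaries are in `mean_all`/`sd_all`).
#' @export
ensemble_steady_state <- function(simulator = c("SSA", "BL"), params,
                                  regime = NULL, n_points = 2000,
                                  t_relax = NULL, cfg = step_config(),
                                  seed_base = 1,
                                  mode = c("replicas", "timeavg"),
                                  t_avg = 4000, n_batch = 50L) {
  simulator <- match.arg(simulator)
  mode <- match.arg(mode)
  is_net <- inherits(params, "regulated_network")
  if (!is_net) {
    stopifnot_gene_params(params)
    if (is.null(regime)) regime <- classify_regime(params)
  }
  if (is.null(t_relax)) t_relax <- default_t_relax(params)
  species <- if (is_net) c("p1", "p2") else c("m", "p")
  poi <- 2L # protein of interest: p (single gene) or p2 (network)
  if (mode == "replicas") {
    if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
    samples <- matrix(0, nrow = n_points, ncol = 2L,
                      dimnames = list(NULL, species))
    for (i in seq_len(n_points))
      samples[i, ] <- run_final(simulator, params, regime, t_relax, cfg,
                                seed_base + i - 1L)
    x <- samples[, poi]
    out <- list(n_points = n_points, mean = mean(x), sd = stats::sd(x),
                stderr_mean = stats::sd(x) / sqrt(n_points),
                stderr_sd = stats::sd(x) / sqrt(2 * (n_points - 1)),
                histogram = table(x), samples = samples,
                mean_all = colMeans(samples),
                sd_all = apply(samples, 2, stats::sd))
  } else {
    ta <- run_timeavg(simulator, params, regime, t_relax, t_avg, cfg,
                      seed_base, n_batch)
    out <- list(n_points = n_points, mean = ta$mean[poi], sd = ta$sd[poi],
                stderr_mean = ta$se_mean[poi], stderr_sd = ta$se_sd[poi],
                histogram = NULL, samples = NULL,
                mean_all = stats::setNames(ta$mean, species),
                sd_all = stats::setNames(ta$sd, species),
                t_avg = t_avg)
  }
  out$species <- species
  out$simulator <- simulator
  out$params <- params
  out$regime <- if (is_net) "BOTH_BURSTS" else as_regime(regime)$label
  out$seed_base <- seed_base
  out$mode <- mode
  class(out) <- "ensemble_summary"
  out
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %s, %s mode\n", x$simulator, x$mode))
  cat(sprintf("  %s: mean %.4g (se %.2g), sd %.4g (se %.2g)\n",
              x$species[2L], x$mean, x$stderr_mean, x$sd, x$stderr_sd))
  invisible(x)
}

# averaging window long enough that the Monte-Carlo stderr of the
# time-averaged mean is ~ r_target relative: T = 2.5 * relvar / r_target^2
# (correlation time ~ one protein lifetime; 2.5 includes a safety margin)
timeavg_window <- function(relvar, r_target, t_min = 2000) {
  max(t_min, ceiling(2.5 * relvar / r_target^2))
}

# precision tier: tighter where the protein count (hence the cost per time
# unit) is low and the Langevin bias is largest
r_target_for <- function(p_bar) {
  if (p_bar <= 1000) 0.002 else if (p_bar <= 5000) 0.003 else 0.004
}

#' Grid comparison of burst Langevin vs Gillespie steady states
#'
#' For each parameter set, runs both simulators to the steady state and
#' reports the normalized errors of the protein mean and standard deviation,
#' `100 * (BL - SSA)/SSA`, together with propagated Monte-Carlo standard
#' errors. The default protocol is the time-average mode with a per-cell
#' averaging window sized from the closed-form variance so that every cell
#' carries at least 2000 effective independent samples and the stderr of
#' the mean is a small fraction of the error bounds being tested.
#'
#' @param cells a list of [gene_params()] (one per grid cell), or a single
#'   `gene_params`.
#' @param labels optional data.frame of axis values (one row per cell),
#'   prepended to the result.
#' @param regime burst Langevin regime (`NULL` = classify per cell).
#' @param mode `"timeavg"` (default) or `"replicas"`.
#' @param n_points replicas per cell (replicas mode).
#' @param t_relax burn-in (default `20/gamma_p`).
#' @param cfg a [step_config()].
#' @param seed_base integer; cell `i` uses seeds derived from
#'   `seed_base + 2*(i-1)` (SSA) and `+ 2*i - 1` (BL).
#' @param r_target relative stderr target of the time-averaged mean
#'   (`NULL` = per-cell tier based on the protein level).
#' @return A data.frame with one row per cell: the label columns, `p_bar`
#'   (closed form), `mean_ssa`, `mean_bl`, `sd_ssa`, `sd_bl`,
#'   `err_mean_pct`, `err_sd_pct`, `se_err_mean_pct`, `se_err_sd_pct`.
#' @export
mean_error_grid <- function(cells, labels = NULL, regime = NULL,
                            mode = c("timeavg", "replicas"), n_points = 2000,
                            t_relax = NULL, cfg = step_config(),
                            seed_base = 1, r_target = NULL) {
  mode <- match.arg(mode)
  if (inherits(cells, "gene_params")) cells <- list(cells)
  rows <- lapply(seq_along(cells), function(i) {
    par <- cells[[i]]
    reg <- if (is.null(regime)) classify_regime(par) else as_regime(regime)
    ss <- steady_state_moments(par, "burst", reg)
    relvar <- ss$var_p / ss$p_bar^2
    rt <- if (is.null(r_target)) r_target_for(ss$p_bar) else r_target
    tav <- timeavg_window(relvar, rt)
    seeds <- seed_base + c(2L * (i - 1L), 2L * i - 1L)
    run1 <- function(sim, seed) {
      if (mode == "timeavg")
        ensemble_steady_state(sim, par, reg, t_relax = t_relax, cfg = cfg,
                              seed_base = seed, mode = "timeavg", t_avg = tav)
      else
        ensemble_steady_state(sim, par, reg, n_points = n_points,
                              t_relax = t_relax, cfg = cfg,
                              seed_base = seed, mode = "replicas")
    }
    es_ssa <- run1("SSA", seeds[1L])
    es_bl <- run1("BL", seeds[2L])
    err_mean <- 100 * (es_bl$mean - es_ssa$mean) / es_ssa$mean
    err_sd <- 100 * (es_bl$sd - es_ssa$sd) / es_ssa$sd
    se_em <- 100 * sqrt(es_bl$stderr_mean^2 + es_ssa$stderr_mean^2) /
      es_ssa$mean
    se_es <- 100 * sqrt(es_bl$stderr_sd^2 + es_ssa$stderr_sd^2) / es_ssa$sd
    data.frame(p_bar = ss$p_bar, mean_ssa = es_ssa$mean, mean_bl = es_bl$mean,
               sd_ssa = es_ssa$sd, sd_bl = es_bl$sd,
               err_mean_pct = err_mean, err_sd_pct = err_sd,
               se_err_mean_pct = se_em, se_err_sd_pct = se_es)
  })
  out <- do.call(rbind, rows)
  if (!is.null(labels)) out <- cbind(labels, out)
  rownames(out) <- NULL
  out
}

#' Parameter cells of the burst-frequency x protein-burst-size scan
#'
#' Gene activation rate `k_g` crossed with protein burst size `b_p`
#' (translation rate back-solved as `k_p = b_p * gamma_m`), at fixed
#' `k_m = 100`, `gamma_g = 100`, `gamma_m = 10`, `gamma_p = 1`.
#'
#' @param k_g,b_p axis values.
#' @return list with `cells` (list of [gene_params()]) and `labels`.
#' @export
frequency_size_cells <- function(k_g = c(3, 10, 100), b_p = c(1, 10, 100)) {
  grid <- expand.grid(k_g = k_g, b_p = b_p, KEEP.OUT.ATTRS = FALSE)
  cells <- lapply(seq_len(nrow(grid)), function(i)
    gene_params(k_g = grid$k_g[i], gamma_g = 100, k_m = 100, gamma_m = 10,
                k_p = grid$b_p[i] * 10, gamma_p = 1))
  list(cells = cells, labels = grid)
}

#' Parameter cells of the mRNA x protein burst-size scan
#'
#' mRNA burst size `b_m` crossed with protein burst size `b_p`
#' (`k_m = b_m*(k_g+gamma_g)`, `k_p = b_p*gamma_m` back-solved), at fixed
#' `k_g = 5`, `gamma_g = 100`, `gamma_m = 10`, `gamma_p = 1`.
#'
#' @param b_m,b_p axis values.
#' @return list with `cells` and `labels`.
#' @export
burst_size_cells <- function(b_m = c(1, 8, 30), b_p = c(1, 10, 100)) {
  grid <- expand.grid(b_m = b_m, b_p = b_p, KEEP.OUT.ATTRS = FALSE)
  cells <- lapply(seq_len(nrow(grid)), function(i)
    gene_params(k_g = 5, gamma_g = 100, k_m = grid$b_m[i] * 105,
                gamma_m = 10, k_p = grid$b_p[i] * 10, gamma_p = 1))
  list(cells = cells, labels = grid)
}

# closed-form sizing of the network averaging window: intrinsic p2 variance
# plus the upstream fluctuation transmitted through the Hill slope
network_relvar_p2 <- function(net) {
  u <- net$upstream; d <- net$downstream
  bs1 <- burst_statistics(u)
  p1 <- u$n_copies * u$k_g * bs1$b_m_bar * bs1$b_p_bar / u$gamma_p
  var1 <- p1 * (bs1$b_m_bar * bs1$b_p_bar + bs1$b_p_bar + 1)
  h <- hill_fraction(p1, net$K, net$n_H)
  bm2 <- (d$k_m * h + net$k_l) / (d$k_g + d$gamma_g)
  bp2 <- d$k_p / d$gamma_m
  p2 <- d$n_copies * d$k_g * bm2 * bp2 / d$gamma_p
  var2 <- p2 * (bm2 * bp2 + bp2 + 1)
  dh <- if (p1 > 0 && net$n_H != 0) {
    r <- (p1 / net$K)^net$n_H
    -net$n_H * r / (p1 * (1 + r)^2)
  } else 0
  dp2dp1 <- d$n_copies * d$k_g * bp2 / d$gamma_p * d$k_m / (d$k_g + d$gamma_g) * dh
  list(p2_bar = p2, relvar = (var2 + 0.5 * (dp2dp1^2) * var1) / p2^2)
}

#' Grid comparison for the repression network
#'
#' Scans upstream burst parameters `(b_m1, b_p1)` (transcription and
#' translation rates back-solved), holding the downstream gene fixed, and
#' compares the steady-state mean of the downstream protein `p2` between
#' the burst Langevin and Gillespie simulators.
#'
#' @param net_base a [regulated_network()]; its upstream `k_m`/`k_p` are
#'   overwritten per cell.
#' @param b_m1,b_p1 upstream axis values.
#' @inheritParams mean_error_grid
#' @return A data.frame: `b_m1`, `b_p1`, `p1_bar`, `p2_ssa`, `p2_bl`,
#'   `err_mean_pct`, `se_err_mean_pct` (plus SD columns as in
#'   [mean_error_grid()]).
#' @export
network_error_grid <- function(net_base, b_m1 = c(1, 8, 30),
                               b_p1 = c(1, 10, 100),
                               mode = c("timeavg", "replicas"),
                               n_points = 2000, t_relax = NULL,
                               cfg = step_config(), seed_base = 1,
                               r_target = 0.006) {
  mode <- match.arg(mode)
  stopifnot(inherits(net_base, "regulated_network"))
  grid <- expand.grid(b_m1 = b_m1, b_p1 = b_p1, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    u <- net_base$upstream
    up <- gene_params(u$k_g, u$gamma_g,
                      k_m = grid$b_m1[i] * (u$k_g + u$gamma_g),
                      gamma_m = u$gamma_m,
                      k_p = grid$b_p1[i] * u$gamma_m,
                      gamma_p = u$gamma_p, n_copies = u$n_copies)
    net <- regulated_network(up, net_base$downstream, net_base$K,
                             net_base$n_H, net_base$k_l)
    est <- network_relvar_p2(net)
    tav <- timeavg_window(est$relvar, r_target)
    seeds <- seed_base + c(2L * (i - 1L), 2L * i - 1L)
    run1 <- function(sim, seed) {
      if (mode == "timeavg")
        ensemble_steady_state(sim, net, t_relax = t_relax, cfg = cfg,
                              seed_base = seed, mode = "timeavg", t_avg = tav)
      else
        ensemble_steady_state(sim, net, n_points = n_points,
                              t_relax = t_relax, cfg = cfg, seed_base = seed)
    }
    es_ssa <- run1("SSA", seeds[1L])
    es_bl <- run1("BL", seeds[2L])
    data.frame(
      b_m1 = grid$b_m1[i], b_p1 = grid$b_p1[i],
      p1_bar = es_ssa$mean_all[["p1"]], p2_ssa = es_ssa$mean,
      p2_bl = es_bl$mean, sd_ssa = es_ssa$sd, sd_bl = es_bl$sd,
      err_mean_pct = 100 * (es_bl$mean - es_ssa$mean) / es_ssa$mean,
      err_sd_pct = 100 * (es_bl$sd - es_ssa$sd) / es_ssa$sd,
      se_err_mean_pct = 100 * sqrt(es_bl$stderr_mean^2 +
                                     es_ssa$stderr_mean^2) / es_ssa$mean)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ensemble dynamics under a gene-activation schedule
#'
#' Runs `n_trajectories` independent trajectories per simulator under a
#' piecewise-constant `k_g(t)` schedule and returns the per-time ensemble
#' mean and SD of the protein number for both simulators.
#'
#' @param params a [gene_params()] object (its `k_g` is overridden by the
#'   schedule).
#' @param kg_schedule `list(times =, values =)`; see [ssa_simulate()].
#' @param t_end end time.
#' @param n_trajectories trajectories per simulator.
#' @param sample_grid times at which to record (default step 0.25).
#' @param cfg a [step_config()].
#' @param seed_base integer seed base (trajectory `i` of the SSA uses
#'   `seed_base + i`, of the Langevin `seed_base + 100000 + i`).
#' @param regime burst Langevin regime (`NULL` = classify).
#' @return A data.frame: `time`, `mean_ssa`, `sd_ssa`, `mean_bl`, `sd_bl`.
#' @export
switching_dynamics <- function(params, kg_schedule, t_end,
                               n_trajectories = 2000, sample_grid = NULL,
                               cfg = step_config(), seed_base = 1,
                               regime = NULL) {
  stopifnot_gene_params(params)
  if (is.null(sample_grid)) sample_grid <- seq(0, t_end, by = 0.25)
  grid <- resolve_grid(sample_grid, t_end)
  sch <- check_schedule(kg_schedule, t_end)
  if (is.null(regime)) regime <- classify_regime(params)
  init <- deterministic_fixed_point(
    gene_params(sch$values[1L], params$gamma_g, params$k_m, params$gamma_m,
                params$k_p, params$gamma_p, params$n_copies))
  acc <- function(sim, offset) {
    s1 <- s2 <- numeric(length(grid))
    for (i in seq_len(n_trajectories)) {
      set.seed(seed_base + offset + i)
      p <- if (sim == "SSA")
        ssa_run_cpp(rates_vec(params), params$n_copies, as.numeric(init),
                    t_end, grid, sch$times, sch$values, -1, 0L)$states[, 3L]
      else
        bl_run_cpp(regime_code(regime), rates_vec(params), params$n_copies,
                   as.numeric(init), t_end, cfg$epsilon, cfg$n_critical,
                   cfg$max_halvings, grid, sch$times, sch$values,
                   -1, 0L)$states[, 3L]
      s1 <- s1 + p
      s2 <- s2 + p^2
    }
    m <- s1 / n_trajectories
    list(mean = m, sd = sqrt(pmax(0, s2 / n_trajectories - m^2) *
                               n_trajectories / (n_trajectories - 1)))
  }
  ssa <- acc("SSA", 0L)
  bl <- acc("BL", 100000L)
  data.frame(time = grid, mean_ssa = ssa$mean, sd_ssa = ssa$sd,
             mean_bl = bl$mean, sd_bl = bl$sd)
}

#' Compare two steady-state distributions
#'
#' Aligns the replica histograms of two [ensemble_steady_state()] summaries
#' on a common binning and reports the total-variation distance together
#' with the detected mode locations of each (local maxima of the lightly
#' smoothed binned frequencies, at least 5% of the peak).
#'
#' @param summary_a,summary_b `ensemble_summary` objects in replicas mode
#'   with identical parameterizations.
#' @param binwidth histogram bin width (default: combined SD / 5, at
#'   least 1).
#' @return A list: `tv_distance`, `modes_a`, `modes_b` (bin centers),
#'   `breaks`, `freq_a`, `freq_b`.
#' @export
distribution_overlay <- function(summary_a, summary_b, binwidth = NULL) {
  stopifnot(inherits(summary_a, "ensemble_summary"),
            inherits(summary_b, "ensemble_summary"))
  if (is.null(summary_a$samples) || is.null(summary_b$samples))
    stop("distribution_overlay needs replicas-mode summaries", call. = FALSE)
  if (!identical(unclass(summary_a$params), unclass(summary_b$params)))
    stop("summaries have different parameterizations", call. = FALSE)
  xa <- summary_a$samples[, 2L]
  xb <- summary_b$samples[, 2L]
  if (is.null(binwidth))
    binwidth <- max(1, round(stats::sd(c(xa, xb)) / 5))
  hi <- max(xa, xb) + binwidth
  breaks <- seq(-0.5, hi + binwidth, by = binwidth)
  fa <- graphics::hist(xa, breaks = breaks, plot = FALSE)$counts / length(xa)
  fb <- graphics::hist(xb, breaks = breaks, plot = FALSE)$counts / length(xb)
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  list(tv_distance = 0.5 * sum(abs(fa - fb)),
       modes_a = find_modes(fa, centers), modes_b = find_modes(fb, centers),
       breaks = breaks, freq_a = fa, freq_b = fb)
}

# local maxima of a lightly smoothed frequency vector (>= 5% of the peak)
find_modes <- function(freq, centers, min_frac = 0.05) {
  k <- c(1, 2, 3, 2, 1) / 9
  n <- length(freq)
  if (n < 5) return(centers[which.max(freq)])
  sm <- as.numeric(stats::filter(c(freq[1], freq[1], freq, freq[n], freq[n]),
                                 k, sides = 2))[3:(n + 2)]
  is_max <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    sm[i] >= max(sm[lo:hi]) && sm[i] >= min_frac * max(sm)
  }, logical(1))
  # merge adjacent plateau bins into one mode
  runs <- rle(is_max)
  pos <- cumsum(runs$lengths)
  starts <- pos - runs$lengths + 1L
  centers[round((starts[runs$values] + pos[runs$values]) / 2)]
}
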