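#' Step-size controller settings for the burst Langevin integrator
#'
#' @param epsilon relative-change tolerance of the tau-leaping bound
#'   (0 < epsilon < 1; default 0.03).
#' @param n_critical copy-number threshold below which a degradation channel
#'   is treated as a critical reaction (default 10).
#' @param max_halvings retry limit of the half-tau scheme (default 20).
#' @return An object of class `step_config`.
#' @export
step_config <- function(epsilon = 0.03, n_critical = 10, max_halvings = 20) {
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 1)
    stop("epsilon must lie in (0, 1)", call. = FALSE)
  if (n_critical < 1) stop("n_critical must be >= 1", call. = FALSE)
  if (max_halvings < 1) stop("max_halvings must be >= 1", call. = FALSE)
  structure(list(epsilon = epsilon, n_critical = as.integer(n_critical),
                 max_halvings = as.integer(max_halvings)),
            class = "step_config")
}

#' Apply the negative-production accumulator
#'
#' A Gaussian production draw rounded to a negative integer is not applied;
#' it is stored as a deficit and offset against subsequent draws, so that
#' applied production stays non-negative while the long-run mean is
#' preserved. Conservation: `applied + new_deficit == raw + deficit`.
#'
#' @param raw rounded production draw (integer, may be negative).
#' @param deficit pending deficit from earlier steps (integer <= 0).
#' @return A list with `applied` (integer >= 0) and `deficit` (<= 0).
#' @examples
#' apply_negative_accumulator(-5, 0)   # applied 0, deficit -5
#' apply_negative_accumulator(8, -5)   # applied 3, deficit 0
#' @export
apply_negative_accumulator <- function(raw, deficit) {
  if (deficit > 0) stop("deficit must be <= 0", call. = FALSE)
  total <- raw + deficit
  if (total > 0) list(applied = total, deficit = 0)
  else list(applied = 0, deficit = total)
}

# tau-leaping bound helpers (mirror of the C++ driver)
tau_burst_bound_r <- function(eps, y, b_bar, rate) {
  if (rate <= 0) return(Inf)
  max(eps * y, max(b_bar, 1)) / rate
}
tau_cle_bound_r <- function(eps, y, mean_rate, var_rate) {
  num <- max(eps * y, 1)
  b1 <- if (abs(mean_rate) > 0) num / abs(mean_rate) else Inf
  b2 <- if (var_rate > 0) num^2 / var_rate else Inf
  min(b1, b2)
}

#' Adaptive step-size selection for the burst Langevin scheme
#'
#' Computes the leap size tau as the minimum over all tracked species of (a)
#' the burst-production bound `max(eps*y, b_bar) / production_rate` (at least
#' one whole burst fits in the step when `eps*y` is small) and (b) the
#' standard tau-leaping mean/variance bounds `max(eps*y,1)/|sum nu_j a_j|`
#' and `max(eps*y,1)^2 / sum nu_j^2 a_j` over the non-burst channels. If any
#' critical channels are present (gene switching; degradation of a species
#' below `cfg$n_critical` copies), a candidate time `tau_c` is drawn from an
#' exponential with rate equal to the summed critical propensities; when
#' `tau_c < tau` the step is `tau_c` and the sampled critical channel fires.
#'
#' @param state a [system_state()].
#' @param params a [gene_params()] object.
#' @param regime a `regime` object or label.
#' @param cfg a [step_config()].
#' @param extra_channels optional list of additional protein channels, each
#'   `list(a = propensity, nu = change)`, entering the non-burst bounds.
#' @param t_remaining upper bound on the step (default `Inf`).
#' @return A list with `tau`, `critical` (channel name or `NULL`) and
#'   `tau_c` (`NA` if no critical channel exists). The critical channel is
#'   one of `"gene_on"`, `"gene_off"`, `"m_deg"`, `"p_deg"`.
#' @export
select_tau <- function(state, params, regime, cfg = step_config(),
                       extra_channels = NULL, t_remaining = Inf) {
  stopifnot(inherits(state, "system_state"))
  stopifnot_gene_params(params)
  regime <- as_regime(regime)
  eps <- cfg$epsilon
  bs <- burst_statistics(params)
  n <- params$n_copies
  g <- state$g; m <- state$m; p <- state$p
  extra_mean <- extra_var <- 0
  for (ch in extra_channels) {
    extra_mean <- extra_mean + ch$nu * ch$a
    extra_var <- extra_var + ch$nu^2 * ch$a
  }
  m_crit <- regime$label %in% c("MRNA_BURST", "NO_BURST") &&
    m > 0 && m < cfg$n_critical
  p_crit <- p > 0 && p < cfg$n_critical
  gene_tracked <- regime$label %in% c("PROTEIN_BURST", "NO_BURST")

  tau <- t_remaining
  pd <- if (p_crit) 0 else params$gamma_p * p
  if (regime$label == "MRNA_BURST") {
    tau <- min(tau, tau_burst_bound_r(eps, m, bs$b_m_bar, n * params$k_g * bs$b_m_bar))
    md <- if (m_crit) 0 else params$gamma_m * m
    if (md > 0) tau <- min(tau, tau_cle_bound_r(eps, m, md, md))
    pp <- params$k_p * m
    tau <- min(tau, tau_cle_bound_r(eps, p, pp - pd + extra_mean,
                                    pp + pd + extra_var))
  } else if (regime$label == "BOTH_BURSTS") {
    tau <- min(tau, tau_burst_bound_r(eps, p, bs$b_p_bar,
                                      n * params$k_g * bs$b_m_bar * bs$b_p_bar))
    if (pd > 0 || extra_var > 0)
      tau <- min(tau, tau_cle_bound_r(eps, p, -pd + extra_mean, pd + extra_var))
  } else if (regime$label == "PROTEIN_BURST") {
    tau <- min(tau, tau_burst_bound_r(eps, p, bs$b_p_bar,
                                      g * params$k_m * bs$b_p_bar))
    if (pd > 0 || extra_var > 0)
      tau <- min(tau, tau_cle_bound_r(eps, p, -pd + extra_mean, pd + extra_var))
    tau <- min(tau, 0.1 / max(params$k_g, params$gamma_g))
  } else { # NO_BURST: plain CLE on m and p
    mp <- params$k_m * g
    md <- if (m_crit) 0 else params$gamma_m * m
    if (mp > 0 || md > 0)
      tau <- min(tau, tau_cle_bound_r(eps, m, mp - md, mp + md))
    pp <- params$k_p * m
    if (pp > 0 || pd > 0 || extra_var > 0)
      tau <- min(tau, tau_cle_bound_r(eps, p, pp - pd + extra_mean,
                                      pp + pd + extra_var))
    tau <- min(tau, 0.1 / max(params$k_g, params$gamma_g))
  }

  crit <- c(gene_on = if (gene_tracked) params$k_g * (n - g) else 0,
            gene_off = if (gene_tracked) params$gamma_g * g else 0,
            m_deg = if (m_crit) params$gamma_m * m else 0,
            p_deg = if (p_crit) params$gamma_p * p else 0)
  a_crit <- sum(crit)
  if (a_crit <= 0) return(list(tau = tau, critical = NULL, tau_c = NA_real_))
  tau_c <- stats::rexp(1, rate = a_crit)
  if (tau_c < tau) {
    ch <- sample(names(crit), 1L, prob = crit)
    list(tau = tau_c, critical = ch, tau_c = tau_c)
  } else {
    list(tau = tau, critical = NULL, tau_c = tau_c)
  }
}

#' One Euler-Maruyama step of the burst Langevin equation
#'
#' Propagates the regime-specific update over a step `tau`: a Gaussian
#' production draw per produced species with the regime's burst moments
#' (see [production_moments()]), rounded to the nearest integer and passed
#' through the negative-production accumulator, and a Gaussian degradation
#' draw with mean and variance `gamma*y*tau`, also rounded. In the
#' `PROTEIN_BURST` regime the gene state first switches with Bernoulli
#' probability `k_g*tau` (off to on) or `gamma_g*tau` (on to off); the
#' production moments use the pre-switch gene state, which is treated as
#' constant within the step. If any provisional count is negative the draws
#' are discarded, tau is halved and the step redrawn, up to
#' `cfg$max_halvings` times.
#'
#' @param state a [system_state()].
#' @param tau step size, normally from [select_tau()].
#' @param regime a `regime` object or label (fixed for a run).
#' @param params a [gene_params()] object.
#' @param cfg a [step_config()].
#' @return The new [system_state()] at `state$t + tau` (the committed tau
#'   after any halvings is recorded in attribute `"tau_used"`).
#' @export
langevin_step <- function(state, tau, regime, params, cfg = step_config()) {
  stopifnot(inherits(state, "system_state"))
  stopifnot_gene_params(params)
  regime <- as_regime(regime)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  bs <- burst_statistics(params)
  n <- params$n_copies

  g <- state$g
  if (regime$label == "PROTEIN_BURST") {
    pr <- if (g < n) params$k_g * tau else params$gamma_g * tau
    if (pr > 1) stop("tau too large for Bernoulli gene switching; ",
                     "cap tau below 1/max(k_g, gamma_g)", call. = FALSE)
    if (stats::runif(1) < pr) g <- if (g < n) g + 1 else g - 1
  }

  draw_prod <- function(delta, var, deficit) {
    raw <- round_half_away(delta + sqrt(var) * stats::rnorm(1))
    c(apply_negative_accumulator(raw, deficit), list(raw = raw))
  }
  draw_deg <- function(mu) {
    if (mu <= 0) return(0)
    round_half_away(mu + sqrt(mu) * stats::rnorm(1))
  }

  for (halv in 0:cfg$max_halvings) {
    m_new <- state$m; p_new <- state$p
    def_m <- state$deficit_m; def_p <- state$deficit_p
    if (regime$label == "MRNA_BURST") {
      pm <- production_moments(regime, params, tau)
      dr <- draw_prod(pm$delta, pm$var, def_m)
      m_new <- state$m + dr$applied - draw_deg(params$gamma_m * state$m * tau)
      def_m <- dr$deficit
      pp_rate <- params$k_p * state$m
      if (pp_rate > 0) {
        dr <- draw_prod(pp_rate * tau, pp_rate * tau, def_p)
        p_new <- state$p + dr$applied
        def_p <- dr$deficit
      }
      p_new <- p_new - draw_deg(params$gamma_p * state$p * tau)
    } else if (regime$label == "BOTH_BURSTS") {
      pm <- production_moments(regime, params, tau)
      dr <- draw_prod(pm$delta, pm$var, def_p)
      p_new <- state$p + dr$applied - draw_deg(params$gamma_p * state$p * tau)
      def_p <- dr$deficit
    } else if (regime$label == "PROTEIN_BURST") {
      if (state$g > 0) {
        pm <- production_moments(regime, params, tau, g = state$g)
        dr <- draw_prod(pm$delta, pm$var, def_p)
        p_new <- state$p + dr$applied
        def_p <- dr$deficit
      }
      p_new <- p_new - draw_deg(params$gamma_p * state$p * tau)
    } else { # NO_BURST: plain CLE on every channel
      mp_rate <- params$k_m * state$g
      if (mp_rate > 0) {
        dr <- draw_prod(mp_rate * tau, mp_rate * tau, def_m)
        m_new <- state$m + dr$applied
        def_m <- dr$deficit
      }
      m_new <- m_new - draw_deg(params$gamma_m * state$m * tau)
      pp_rate <- params$k_p * state$m
      if (pp_rate > 0) {
        dr <- draw_prod(pp_rate * tau, pp_rate * tau, def_p)
        p_new <- state$p + dr$applied
        def_p <- dr$deficit
      }
      p_new <- p_new - draw_deg(params$gamma_p * state$p * tau)
    }
    if (m_new >= 0 && p_new >= 0) {
      out <- system_state(g = g, m = m_new, p = p_new, t = state$t + tau,
                          deficit_m = def_m, deficit_p = def_p)
      attr(out, "tau_used") <- tau
      return(out)
    }
    tau <- tau / 2
  }
  stop("count still negative after ", cfg$max_halvings, " halvings",
       call. = FALSE)
}

round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Burst Langevin simulation of a single gene
#'
#' Adaptive-step Euler-Maruyama propagation of the regime-specific burst
#' Langevin equation: repeated [select_tau()]-style step selection, Gaussian
#' production/degradation draws rounded to integers, the
#' negative-production accumulator, critical-reaction interleaving (gene
#' switching always; degradations below `cfg$n_critical` copies) and
#' half-tau retries. Tracked species depend on the regime: `MRNA_BURST`
#' tracks (m, p), `BOTH_BURSTS` only p, `PROTEIN_BURST` (g, p), `NO_BURST`
#' all three (as plain chemical Langevin; exact simulation via
#' [ssa_simulate()] is the better tool there). Untracked species are `NA`
#' in the trajectory. The integration loop runs in compiled code; the same
#' scheme is exposed step by step through [select_tau()] and
#' [langevin_step()].
#'
#' @inheritParams ssa_simulate
#' @param regime a `regime` object or label; `NULL` classifies
#'   automatically via [classify_regime()].
#' @param cfg a [step_config()].
#' @return A `trajectory`; diagnostics include step, halving and
#'   critical-event counts plus the production accumulator totals
#'   (`raw_production`, `applied_production`, `deficit`, each for (m, p)).
#' @examples
#' gp <- gene_params(5, 95, 200, 10, 100, 1)
#' tr <- bl_simulate(gp, t_end = 10, seed = 1)
#' tr$diagnostics$n_steps
#' @export
bl_simulate <- function(params, t_end, regime = NULL, initial = NULL,
                        cfg = step_config(), seed = NULL, sample_grid = NULL,
                        kg_schedule = NULL) {
  stopifnot_gene_params(params)
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (is.null(regime)) regime <- classify_regime(params)
  regime <- as_regime(regime)
  if (regime$label == "NO_BURST")
    message("NO_BURST regime: plain chemical Langevin on all species; ",
            "ssa_simulate() is the recommended simulator here")
  init <- resolve_initial(initial, params)
  grid <- resolve_grid(sample_grid, t_end)
  sch <- check_schedule(kg_schedule, t_end)
  if (!is.null(seed)) set.seed(seed)
  code <- match(regime$label,
                c("MRNA_BURST", "BOTH_BURSTS", "PROTEIN_BURST", "NO_BURST"))
  res <- bl_run_cpp(code, rates_vec(params), params$n_copies,
                    as.numeric(init), t_end, cfg$epsilon, cfg$n_critical,
                    cfg$max_halvings, grid, sch$times, sch$values, -1, 0L)
  states <- res$states
  colnames(states) <- c("g", "m", "p")
  tracked <- switch(regime$label,
                    MRNA_BURST = c(FALSE, TRUE, TRUE),
                    BOTH_BURSTS = c(FALSE, FALSE, TRUE),
                    PROTEIN_BURST = c(TRUE, FALSE, TRUE),
                    NO_BURST = c(TRUE, TRUE, TRUE))
  states[, !tracked] <- NA_real_
  new_trajectory(grid, states, params, seed, "BL", regime = regime$label,
                 diagnostics = list(
                   n_steps = res$n_steps, n_halvings = res$n_halvings,
                   n_critical_events = res$n_critical_events,
                   raw_production = res$raw_production,
                   applied_production = res$applied_production,
                   deficit = res$deficit, final = res$final))
}
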