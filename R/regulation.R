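#' Two-gene network with Hill repression and leak
#'
#' Couples two genes: the upstream protein `p1` represses (or, with negative
#' `n_H`, activates) the downstream gene's transcription through a Hill
#' function with threshold `K`, plus a leak transcription rate `k_l` that
#' keeps a repressed gene at a low basal level. The effective downstream
#' transcription rate while the gene is active is
#' `k_m2 * K^n/(K^n + p1^n) + k_l`.
#'
#' @param upstream,downstream [gene_params()] objects for the two genes.
#' @param K regulation threshold (molecules, > 0).
#' @param n_H Hill coefficient; positive = repression, negative =
#'   activation, 0 = constant factor 1/2.
#' @param k_l leak transcription rate (1/time, >= 0), added to the
#'   Hill-modulated transcription rate.
#' @return An object of class `regulated_network`.
#' @export
regulated_network <- function(upstream, downstream, K, n_H, k_l = 0) {
  stopifnot_gene_params(upstream)
  stopifnot_gene_params(downstream)
  if (!is.numeric(K) || K <= 0) stop("K must be > 0", call. = FALSE)
  if (!is.numeric(k_l) || k_l < 0) stop("k_l must be >= 0", call. = FALSE)
  structure(list(upstream = upstream, downstream = downstream,
                 K = K, n_H = n_H, k_l = k_l),
            class = "regulated_network")
}

#' @export
print.regulated_network <- function(x, ...) {
  cat("<regulated_network>  p1 --| p2 (Hill)\n")
  cat(sprintf("  K = %g, n_H = %g, k_l = %g\n", x$K, x$n_H, x$k_l))
  cat("  upstream: "); print(x$upstream)
  cat("  downstream: "); print(x$downstream)
  invisible(x)
}

#' Hill regulation fraction
#'
#' `K^n / (K^n + p1^n)`, the fraction of full transcription under Hill
#' regulation. For repression (`n_H > 0`) it decreases from 1 at `p1 = 0`
#' to 0; negative `n_H` encodes activation (0 at `p1 = 0`, continuous
#' limit); `n_H = 0` gives the constant 1/2.
#'
#' @param p1 upstream protein count (>= 0).
#' @param K threshold (> 0).
#' @param n_H Hill coefficient.
#' @return The regulation fraction in `[0, 1]`.
#' @examples
#' hill_fraction(200, K = 200, n_H = 3)  # 0.5 at the threshold
#' @export
hill_fraction <- function(p1, K, n_H) {
  if (any(p1 < 0)) stop("p1 must be >= 0", call. = FALSE)
  if (K <= 0) stop("K must be > 0", call. = FALSE)
  if (n_H == 0) return(rep(0.5, length(p1)))
  out <- ifelse(p1 <= 0, if (n_H > 0) 1 else 0,
                1 / (1 + (p1 / K)^n_H))
  as.numeric(out)
}

#' Effective downstream transcription rate
#'
#' The transcription propensity of the downstream gene while active:
#' `k_m2 * hill_fraction(p1) + k_l`. Multiplied by the gene state `g2` it is
#' the SSA transcription propensity; divided by `(k_g2 + gamma_g2)` it is
#' the effective downstream mRNA burst size used by the burst Langevin
#' production moments. Both simulators use this one convention, so it
#' cancels in every error comparison.
#'
#' @param g2 downstream gene state (0..n_copies).
#' @param p1 upstream protein count.
#' @param net a [regulated_network()].
#' @return Rate (1/time).
#' @export
downstream_transcription_rate <- function(g2, p1, net) {
  stopifnot(inherits(net, "regulated_network"))
  g2 * (net$downstream$k_m * hill_fraction(p1, net$K, net$n_H) + net$k_l)
}

# deterministic fixed point of the coupled rate equations (for initials):
# p1 from the upstream gene, p2 from the Hill-regulated balance at p1
network_fixed_point <- function(net) {
  u <- deterministic_fixed_point(net$upstream)
  dn <- net$downstream
  g2_bar <- dn$n_copies * dn$k_g / (dn$k_g + dn$gamma_g)
  km_eff <- dn$k_m * hill_fraction(u[["p"]], net$K, net$n_H) + net$k_l
  m2_bar <- g2_bar * km_eff / dn$gamma_m
  p2_bar <- m2_bar * dn$k_p / dn$gamma_p
  c(g1 = u[["g"]], m1 = u[["m"]], p1 = u[["p"]],
    g2 = min(dn$n_copies, floor(g2_bar + 0.5)),
    m2 = floor(m2_bar + 0.5), p2 = floor(p2_bar + 0.5))
}

#' Burst Langevin simulation of the repression network
#'
#' Joint propagation of the two proteins, both genes in both-bursts mode:
#' only `p1` and `p2` are tracked. Each step uses a shared tau (the minimum
#' of the two species' step bounds); the downstream production moments are
#' recomputed every step from the current `p1` (treated as constant within
#' the step) through the effective mRNA burst size
#' `(k_m2 * Hill(p1) + k_l)/(k_g2 + gamma_g2)`. Negative-production
#' accumulators, critical degradation channels and half-tau retries work as
#' in [bl_simulate()].
#'
#' @param net a [regulated_network()].
#' @param t_end end time.
#' @param initial `NULL` (deterministic fixed point) or numeric
#'   `c(p1, p2)`.
#' @inheritParams bl_simulate
#' @return A `trajectory` with species columns `p1`, `p2`.
#' @export
network_bl_simulate <- function(net, t_end, initial = NULL,
                                cfg = step_config(), seed = NULL,
                                sample_grid = NULL) {
  stopifnot(inherits(net, "regulated_network"))
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  init <- if (is.null(initial)) {
    fp <- network_fixed_point(net)
    c(fp[["p1"]], fp[["p2"]])
  } else {
    if (!is.numeric(initial) || length(initial) != 2L)
      stop("initial must be NULL or numeric c(p1, p2)", call. = FALSE)
    initial
  }
  grid <- resolve_grid(sample_grid, t_end)
  if (!is.null(seed)) set.seed(seed)
  res <- bl_net_run_cpp(rates_vec(net$upstream), rates_vec(net$downstream),
                        net$K, net$n_H, net$k_l,
                        net$upstream$n_copies, net$downstream$n_copies,
                        as.numeric(init), t_end, cfg$epsilon,
                        cfg$n_critical, cfg$max_halvings, grid, -1, 0L)
  states <- res$states
  colnames(states) <- c("p1", "p2")
  new_trajectory(grid, states, net, seed, "BL", regime = "BOTH_BURSTS",
                 diagnostics = list(
                   n_steps = res$n_steps, n_halvings = res$n_halvings,
                   n_critical_events = res$n_critical_events,
                   raw_production = res$raw_production,
                   applied_production = res$applied_production,
                   deficit = res$deficit, final = res$final))
}
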