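rates_vec <- function(params) {
  c(params$k_g, params$gamma_g, params$k_m, params$gamma_m,
    params$k_p, params$gamma_p)
}

check_schedule <- function(kg_schedule, t_end) {
  if (is.null(kg_schedule)) return(list(times = numeric(0), values = numeric(0)))
  if (!is.list(kg_schedule) || is.null(kg_schedule$times) ||
      is.null(kg_schedule$values) ||
      length(kg_schedule$values) != length(kg_schedule$times) + 1L)
    stop("kg_schedule must be list(times = <breakpoints>, values = ",
         "<length(times)+1 rates>)", call. = FALSE)
  if (is.unsorted(kg_schedule$times, strictly = TRUE))
    stop("kg_schedule$times must be strictly increasing", call. = FALSE)
  lapply(kg_schedule, as.numeric)
}

resolve_initial <- function(initial, params) {
  if (is.null(initial)) return(deterministic_fixed_point(params))
  if (inherits(initial, "system_state"))
    return(c(g = initial$g, m = initial$m, p = initial$p))
  if (is.numeric(initial) && length(initial) == 3L) {
    v <- initial
    names(v) <- c("g", "m", "p")
    return(v)
  }
  stop("initial must be NULL, a system_state, or a numeric c(g, m, p)",
       call. = FALSE)
}

resolve_grid <- function(sample_grid, t_end) {
  if (is.null(sample_grid)) sample_grid <- seq(0, t_end, length.out = 201L)
  sample_grid <- as.numeric(sample_grid)
  if (is.unsorted(sample_grid) || any(sample_grid < 0) ||
      any(sample_grid > t_end))
    stop("sample_grid must be ascending within [0, t_end]", call. = FALSE)
  sample_grid
}

#' Exact Gillespie simulation of a single gene
#'
#' Direct-method stochastic simulation of the six-channel gene expression
#' model (gene activation/deactivation, transcription, mRNA degradation,
#' translation, protein degradation). Exact: every reaction event is
#' simulated; the state is recorded on `sample_grid` by last-event hold.
#'
#' @param params a [gene_params()] object.
#' @param t_end end time (> 0).
#' @param initial initial state: `NULL` (rounded deterministic fixed point),
#'   a [system_state()], or a numeric `c(g, m, p)`.
#' @param seed integer RNG seed; the same seed reproduces the trajectory
#'   bit for bit. `NULL` continues the current RNG stream.
#' @param sample_grid ascending times at which to record the state
#'   (default: 201 points over `[0, t_end]`).
#' @param kg_schedule optional piecewise-constant activation-rate schedule,
#'   `list(times = breakpoints, values = rates)` with one more value than
#'   breakpoints; overrides `params$k_g`.
#' @return A `trajectory` object (see [write_trajectory()]).
#' @examples
#' gp <- gene_params(5, 95, 200, 10, 100, 1)
#' tr <- ssa_simulate(gp, t_end = 10, seed = 1)
#' mean(tr$states[, "p"])
#' @export
ssa_simulate <- function(params, t_end, initial = NULL, seed = NULL,
                         sample_grid = NULL, kg_schedule = NULL) {
  stopifnot_gene_params(params)
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  init <- resolve_initial(initial, params)
  if (init["g"] > params$n_copies)
    stop("initial g exceeds n_copies", call. = FALSE)
  grid <- resolve_grid(sample_grid, t_end)
  sch <- check_schedule(kg_schedule, t_end)
  if (!is.null(seed)) set.seed(seed)
  res <- ssa_run_cpp(rates_vec(params), params$n_copies, as.numeric(init),
                     t_end, grid, sch$times, sch$values, -1, 0L)
  states <- res$states
  colnames(states) <- c("g", "m", "p")
  new_trajectory(grid, states, params, seed, "SSA",
                 diagnostics = list(n_events = res$n_events,
                                    final = res$final))
}

#' Exact Gillespie simulation of the two-gene repression network
#'
#' Direct-method SSA over the twelve reaction channels of two genes, where
#' the downstream transcription propensity while active is
#' `k_m2 * Hill(p1) + k_l` (see [downstream_transcription_rate()]).
#'
#' @param net a [regulated_network()] object.
#' @param t_end end time.
#' @param initial `NULL` (deterministic fixed point of both genes) or a
#'   numeric `c(g1, m1, p1, g2, m2, p2)`.
#' @inheritParams ssa_simulate
#' @return A `trajectory` with species columns `g1, m1, p1, g2, m2, p2`.
#' @export
ssa_simulate_network <- function(net, t_end, initial = NULL, seed = NULL,
                                 sample_grid = NULL) {
  stopifnot(inherits(net, "regulated_network"))
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  init <- if (is.null(initial)) network_fixed_point(net) else {
    if (!is.numeric(initial) || length(initial) != 6L)
      stop("initial must be NULL or numeric c(g1, m1, p1, g2, m2, p2)",
           call. = FALSE)
    initial
  }
  grid <- resolve_grid(sample_grid, t_end)
  if (!is.null(seed)) set.seed(seed)
  res <- ssa_net_run_cpp(rates_vec(net$upstream), rates_vec(net$downstream),
                         net$K, net$n_H, net$k_l,
                         net$upstream$n_copies, net$downstream$n_copies,
                         as.numeric(init), t_end, grid, -1, 0L)
  states <- res$states
  colnames(states) <- c("g1", "m1", "p1", "g2", "m2", "p2")
  new_trajectory(grid, states, net, seed, "SSA",
                 diagnostics = list(n_events = res$n_events,
                                    final = res$final))
}
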