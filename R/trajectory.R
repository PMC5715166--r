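#' Instantaneous system state
#'
#' Holds the time, the copy numbers of each tracked species and the pending
#' negative-production deficits (the accumulator of the burst Langevin
#' scheme; always <= 0 between steps).
#'
#' @param g active gene copies (0..n_copies).
#' @param m mRNA count (integer >= 0).
#' @param p protein count (integer >= 0).
#' @param t time (default 0).
#' @param deficit_m,deficit_p pending negative production per species
#'   (integers <= 0).
#' @return An object of class `system_state`.
#' @export
system_state <- function(g = 0, m = 0, p = 0, t = 0,
                         deficit_m = 0, deficit_p = 0) {
  if (m < 0 || p < 0 || g < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (deficit_m > 0 || deficit_p > 0)
    stop("deficits must be <= 0", call. = FALSE)
  structure(list(t = t, g = g, m = m, p = p,
                 deficit_m = deficit_m, deficit_p = deficit_p),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> t = %g: g = %g, m = %g, p = %g", x$t, x$g,
              x$m, x$p))
  if (x$deficit_m < 0 || x$deficit_p < 0)
    cat(sprintf("  (deficit m %g, p %g)", x$deficit_m, x$deficit_p))
  cat("\n")
  invisible(x)
}

# deterministic fixed point of the rate equations, rounded to integers;
# the default initial condition for steady-state runs
deterministic_fixed_point <- function(params) {
  g_bar <- params$n_copies * params$k_g / (params$k_g + params$gamma_g)
  m_bar <- g_bar * params$k_m / params$gamma_m
  p_bar <- m_bar * params$k_p / params$gamma_p
  c(g = min(params$n_copies, floor(g_bar + 0.5)),
    m = floor(m_bar + 0.5), p = floor(p_bar + 0.5))
}

new_trajectory <- function(times, states, params, seed, simulator,
                           regime = NULL, diagnostics = list()) {
  structure(list(times = times, states = states, params = params,
                 seed = seed, simulator = simulator, regime = regime,
                 diagnostics = diagnostics),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s, %d sample times over [%g, %g]\n",
              x$simulator, length(x$times), min(x$times), max(x$times)))
  if (!is.null(x$regime)) cat(sprintf("  regime: %s\n", x$regime))
  cat("  species:", paste(colnames(x$states), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Write a trajectory as TSV with a JSON metadata sidecar
#'
#' The TSV holds one row per sample time (columns `time` plus the species;
#' untracked species are `NA`). A `<path>.json` sidecar stores the
#' parameters, seed, simulator and diagnostics needed to reproduce the run.
#'
#' @param traj a trajectory from [ssa_simulate()], [bl_simulate()] or the
#'   network equivalents.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(simulator = traj$simulator, seed = traj$seed,
               regime = traj$regime,
               params = unclass(traj$params),
               diagnostics = traj$diagnostics)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
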