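gene_keys <- c("k_g", "gamma_g", "k_m", "gamma_m", "k_p", "gamma_p",
               "n_copies")

gene_params_from_list <- function(x, where = "gene") {
  unknown <- setdiff(names(x), gene_keys)
  if (length(unknown))
    stop("unknown keys in ", where, ": ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(setdiff(gene_keys, "n_copies"), names(x))
  if (length(missing))
    stop("missing required rates in ", where, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  gene_params(x$k_g, x$gamma_g, x$k_m, x$gamma_m, x$k_p, x$gamma_p,
              n_copies = if (is.null(x$n_copies)) 1L else x$n_copies)
}

network_from_list <- function(x) {
  unknown <- setdiff(names(x), c("upstream", "downstream", "K", "n_H", "k_l"))
  if (length(unknown))
    stop("unknown keys in network: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(x$upstream) || is.null(x$downstream) || is.null(x$K) ||
      is.null(x$n_H))
    stop("network needs upstream, downstream, K and n_H", call. = FALSE)
  regulated_network(gene_params_from_list(x$upstream, "upstream"),
                    gene_params_from_list(x$downstream, "downstream"),
                    K = x$K, n_H = x$n_H,
                    k_l = if (is.null(x$k_l)) 0 else x$k_l)
}

run_config_keys <- c("gene", "network", "regime", "simulator", "step",
                     "t_end", "sample_dt", "kg_schedule", "seed", "out_dir")

#' Load a run configuration from JSON
#'
#' A configuration describes one simulation: a single gene (`gene`) or a
#' two-gene network (`network`), the simulator (`"SSA"` or `"BL"`), an
#' optional regime override, step-controller settings, the end time and
#' sampling interval, a seed and an output directory. Keys mirror the rate
#' symbols (`k_g`, `gamma_g`, `k_m`, `gamma_m`, `k_p`, `gamma_p`).
#' Unknown keys are rejected by name.
#'
#' @param path path to a JSON file.
#' @return An object of class `run_config`.
#' @seealso [write_config()] for the round-trip dump, [preset()] for the
#'   bundled parameter sets.
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_run_config(x)
}

as_run_config <- function(x) {
  if (!is.list(x) || length(x) == 0)
    stop("empty configuration; required: one of gene/network, plus ",
         "simulator settings", call. = FALSE)
  unknown <- setdiff(names(x), run_config_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(x$gene) && is.null(x$network))
    stop("configuration must contain a gene or a network block",
         call. = FALSE)
  if (!is.null(x$gene) && !is.null(x$network))
    stop("configuration cannot contain both gene and network", call. = FALSE)
  params <- if (!is.null(x$gene)) gene_params_from_list(x$gene)
  else network_from_list(x$network)
  regime <- if (is.null(x$regime) || identical(x$regime, "auto")) NULL
  else as_regime(x$regime)$label
  simulator <- if (is.null(x$simulator)) "BL"
  else match.arg(x$simulator, c("SSA", "BL"))
  step <- if (is.null(x$step)) step_config()
  else do.call(step_config, x$step)
  sched <- if (is.null(x$kg_schedule)) NULL
  else check_schedule(x$kg_schedule, Inf)
  structure(list(params = params, regime = regime, simulator = simulator,
                 step = step, t_end = x$t_end, sample_dt = x$sample_dt,
                 kg_schedule = sched, seed = x$seed, out_dir = x$out_dir),
            class = "run_config")
}

#' Write a run configuration as JSON
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list()
  if (inherits(config$params, "regulated_network")) {
    x$network <- list(upstream = unclass(config$params$upstream),
                      downstream = unclass(config$params$downstream),
                      K = config$params$K, n_H = config$params$n_H,
                      k_l = config$params$k_l)
  } else {
    x$gene <- unclass(config$params)
  }
  x$regime <- if (is.null(config$regime)) "auto" else config$regime
  x$simulator <- config$simulator
  x$step <- unclass(config$step)
  x$t_end <- config$t_end
  x$sample_dt <- config$sample_dt
  if (!is.null(config$kg_schedule) && length(config$kg_schedule$times))
    x$kg_schedule <- config$kg_schedule
  x$seed <- config$seed
  x$out_dir <- config$out_dir
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

preset_env <- new.env(parent = emptyenv())

read_presets <- function() {
  if (is.null(preset_env$presets)) {
    path <- system.file("extdata", "presets.json", package = "burstsim",
                        mustWork = TRUE)
    preset_env$presets <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  preset_env$presets
}

#' Bundled parameter presets
#'
#' Named parameter sets used throughout the package's validation
#' experiments, keyed by the figure of the source study they reproduce:
#' \describe{
#'   \item{`"fig1"`, `"fig8"`}{the reference single gene (`k_g = 5`,
#'     `gamma_g = 95`, `k_m = 200`, `gamma_m = 10`, `k_p = 100`,
#'     `gamma_p = 1`; mean protein 100, burst sizes 2 and 10); `fig8` adds
#'     the step size `tau = 0.03` of the production-distribution example.}
#'   \item{`"fig2"`}{the analytic error-map parameterization (fixed burst
#'     sizes 2 and 10, `k_g = 5`, `gamma_p = 1`).}
#'   \item{`"fig3"`, `"fig5"`}{the simulator-comparison grids (activation
#'     rate x protein burst size; mRNA x protein burst size).}
#'   \item{`"fig6"`}{the repression network (downstream `k_m2 = 200`,
#'     `k_l = 60`, `K = 200`, `n_H = 3`) with the upstream burst scan.}
#'   \item{`"fig7"`}{the gene-switching schedule (`k_g`: 3, then 30 on
#'     t = 7..14, then 3 again).}
#' }
#'
#' @param name preset name.
#' @return A list whose elements depend on the preset: `params`
#'   ([gene_params()]), `network` ([regulated_network()]), `map`, grid axis
#'   values, `kg_schedule`, `tau`, `t_end`.
#' @examples
#' preset("fig1")$params
#' preset("fig6")$network$K
#' @export
preset <- function(name) {
  presets <- read_presets()
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  raw <- presets[[name]]
  out <- list(name = name)
  if (!is.null(raw$gene)) out$params <- gene_params_from_list(raw$gene)
  if (!is.null(raw$network)) out$network <- network_from_list(raw$network)
  if (!is.null(raw$kg_schedule))
    out$kg_schedule <- list(times = as.numeric(raw$kg_schedule$times),
                            values = as.numeric(raw$kg_schedule$values))
  for (k in c("map", "fixed", "k_g_values", "b_p_values", "b_m_values",
              "b_m1_values", "b_p1_values", "tau", "t_end"))
    if (!is.null(raw[[k]])) out[[k]] <- raw[[k]]
  out
}
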