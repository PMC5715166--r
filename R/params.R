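#' Kinetic parameters of a single gene
#'
#' Bundles the six rate constants of the three-stage gene expression model
#' (telegraph gene activation, transcription, translation) plus the gene copy
#' number. The deterministic model is
#' \deqn{dg/dt = k_g (n - g) - \gamma_g g}
#' \deqn{dm/dt = k_m g - \gamma_m m}
#' \deqn{dp/dt = k_p m - \gamma_p p}
#' where \eqn{g} is the number of active gene copies and \eqn{m}, \eqn{p} the
#' mRNA and protein counts.
#'
#' @param k_g gene activation rate (1/time).
#' @param gamma_g gene deactivation rate (1/time).
#' @param k_m transcription rate per active gene copy (1/time).
#' @param gamma_m mRNA degradation rate (1/time).
#' @param k_p translation rate per mRNA (1/time).
#' @param gamma_p protein degradation rate (1/time).
#' @param n_copies gene copy number (integer, >= 1).
#'
#' @return An object of class `gene_params`.
#' @examples
#' gp <- gene_params(k_g = 5, gamma_g = 95, k_m = 200,
#'                   gamma_m = 10, k_p = 100, gamma_p = 1)
#' burst_statistics(gp)
#' @export
gene_params <- function(k_g, gamma_g, k_m, gamma_m, k_p, gamma_p,
                        n_copies = 1L) {
  rates <- c(k_g = k_g, gamma_g = gamma_g, k_m = k_m,
             gamma_m = gamma_m, k_p = k_p, gamma_p = gamma_p)
  if (!all(is.finite(rates)))
    stop("all six rate constants must be finite numbers", call. = FALSE)
  # zero production (k_m or k_p) is permitted; switching and degradation
  # rates must be strictly positive
  if (k_m < 0 || k_p < 0)
    stop("production rates must be non-negative", call. = FALSE)
  pos <- rates[c("k_g", "gamma_g", "gamma_m", "gamma_p")]
  if (any(pos <= 0))
    stop("rates must be strictly positive: ",
         paste(names(pos)[pos <= 0], collapse = ", "), call. = FALSE)
  n_copies <- as.integer(n_copies)
  if (is.na(n_copies) || n_copies < 1L)
    stop("n_copies must be an integer >= 1", call. = FALSE)
  structure(list(k_g = k_g, gamma_g = gamma_g, k_m = k_m,
                 gamma_m = gamma_m, k_p = k_p, gamma_p = gamma_p,
                 n_copies = n_copies),
            class = "gene_params")
}

#' @export
print.gene_params <- function(x, ...) {
  cat("<gene_params>\n")
  cat(sprintf("  k_g = %g, gamma_g = %g  (gene switching)\n", x$k_g, x$gamma_g))
  cat(sprintf("  k_m = %g, gamma_m = %g  (mRNA)\n", x$k_m, x$gamma_m))
  cat(sprintf("  k_p = %g, gamma_p = %g  (protein)\n", x$k_p, x$gamma_p))
  if (x$n_copies != 1L) cat(sprintf("  n_copies = %d\n", x$n_copies))
  invisible(x)
}

stopifnot_gene_params <- function(params) {
  if (!inherits(params, "gene_params"))
    stop("`params` must be a gene_params object", call. = FALSE)
  invisible(params)
}

#' Derived burst statistics of a gene
#'
#' Computes the burst sizes, burst frequency and burst-size variances implied
#' by the kinetic constants. The mRNA burst size uses the kinetically accurate
#' definition \eqn{\bar b_m = k_m/(k_g+\gamma_g)} (the probability that an
#' activation period ends without producing an mRNA is
#' \eqn{q = 1/(1+\bar b_m)}, so the burst size is geometric with mean
#' \eqn{(1-q)/q}). The protein burst size is \eqn{\bar b_p = k_p/\gamma_m};
#' the finite-lifetime variant \eqn{\bar b_{p0} = k_p/(\gamma_m+\gamma_p)}
#' appears in the exact steady-state variance. Geometric burst sizes have
#' variance \eqn{\bar b^2 + \bar b}.
#'
#' @param params a [gene_params()] object.
#' @return An object of class `burst_statistics`: a list with elements
#'   `b_m_bar`, `b_p_bar`, `b_p0_bar`, `q`, `var_bm`, `var_bp`, `freq_m`
#'   (mRNA burst frequency, `n_copies * k_g`).
#' @seealso [mrna_burst_size_legacy()] for the small-\eqn{k_g} literature
#'   definition \eqn{k_m/\gamma_g}.
#' @export
burst_statistics <- function(params) {
  stopifnot_gene_params(params)
  b_m <- params$k_m / (params$k_g + params$gamma_g)
  b_p <- params$k_p / params$gamma_m
  structure(list(
    b_m_bar  = b_m,
    b_p_bar  = b_p,
    b_p0_bar = params$k_p / (params$gamma_m + params$gamma_p),
    q        = 1 / (1 + b_m),
    var_bm   = b_m^2 + b_m,
    var_bp   = b_p^2 + b_p,
    freq_m   = params$n_copies * params$k_g
  ), class = "burst_statistics")
}

#' @export
print.burst_statistics <- function(x, ...) {
  cat("<burst_statistics>\n")
  cat(sprintf("  mRNA:    mean size %.4g (var %.4g), frequency %.4g, q = %.4g\n",
              x$b_m_bar, x$var_bm, x$freq_m, x$q))
  cat(sprintf("  protein: mean size %.4g (var %.4g), finite-lifetime size %.4g\n",
              x$b_p_bar, x$var_bp, x$b_p0_bar))
  invisible(x)
}

#' Legacy mRNA burst size
#'
#' The historical definition \eqn{\bar b_m = k_m/\gamma_g}, valid only in the
#' limit of very small \eqn{k_g}. Exposed for comparison with the corrected
#' definition used everywhere else in this package
#' (\eqn{k_m/(k_g+\gamma_g)}, see [burst_statistics()]).
#'
#' @inheritParams burst_statistics
#' @return A single number.
#' @export
mrna_burst_size_legacy <- function(params) {
  stopifnot_gene_params(params)
  params$k_m / params$gamma_g
}

#' Classify the bursting regime of a gene
#'
#' A gene produces mRNA in bursts when gene deactivation is much faster than
#' mRNA turnover (\eqn{\gamma_g \ge} `threshold` \eqn{\cdot \gamma_m}), and
#' protein in bursts when mRNA turnover is much faster than protein turnover
#' (\eqn{\gamma_m \ge} `threshold` \eqn{\cdot \gamma_p}). The four
#' combinations give the regimes `BOTH_BURSTS`, `MRNA_BURST`,
#' `PROTEIN_BURST` and `NO_BURST`. Boundary equality counts as bursting.
#'
#' @inheritParams burst_statistics
#' @param threshold separation-of-timescales ratio (default 10).
#' @return An object of class `regime`: list with `label`, `ratio_gm`
#'   (\eqn{\gamma_g/\gamma_m}) and `ratio_mp` (\eqn{\gamma_m/\gamma_p}).
#' @examples
#' classify_regime(gene_params(5, 100, 200, 10, 100, 1))  # BOTH_BURSTS
#' @export
classify_regime <- function(params, threshold = 10) {
  stopifnot_gene_params(params)
  if (!is.numeric(threshold) || threshold <= 1)
    stop("threshold must be > 1", call. = FALSE)
  ratio_gm <- params$gamma_g / params$gamma_m
  ratio_mp <- params$gamma_m / params$gamma_p
  m_burst <- ratio_gm >= threshold
  p_burst <- ratio_mp >= threshold
  label <- if (m_burst && p_burst) "BOTH_BURSTS"
  else if (m_burst) "MRNA_BURST"
  else if (p_burst) "PROTEIN_BURST"
  else "NO_BURST"
  structure(list(label = label, ratio_gm = ratio_gm, ratio_mp = ratio_mp,
                 threshold = threshold),
            class = "regime")
}

#' @export
print.regime <- function(x, ...) {
  cat(sprintf("<regime> %s  (gamma_g/gamma_m = %.3g, gamma_m/gamma_p = %.3g, threshold %g)\n",
              x$label, x$ratio_gm, x$ratio_mp, x$threshold))
  invisible(x)
}

as_regime <- function(regime) {
  if (inherits(regime, "regime")) return(regime)
  if (is.character(regime) && length(regime) == 1L) {
    labels <- c("MRNA_BURST", "PROTEIN_BURST", "BOTH_BURSTS", "NO_BURST")
    lab <- tryCatch(match.arg(regime, labels),
                    error = function(e)
                      stop("unknown regime label '", regime, "'; must be ",
                           "one of ", paste(labels, collapse = ", "),
                           call. = FALSE))
    return(structure(list(label = lab, ratio_gm = NA_real_,
                          ratio_mp = NA_real_, threshold = NA_real_),
                     class = "regime"))
  }
  stop("`regime` must be a regime object or a regime label", call. = FALSE)
}
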