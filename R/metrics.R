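#' Paired diet overlap between two consumers
#'
#' The fraction of the narrower consumer's resources that are shared with
#' the wider consumer's diet: `|wide diet intersect narrow diet| / |narrow diet|`.
#'
#' @param diet_wide,diet_narrow vectors of resource indices; the wide diet
#'   must be at least as large as the narrow one.
#' @return a fraction in \[0, 1\], or `NA` if the narrow diet is empty.
#' @export
paired_overlap <- function(diet_wide, diet_narrow) {
  diet_wide <- unique(diet_wide); diet_narrow <- unique(diet_narrow)
  if (length(diet_narrow) == 0) return(NA_real_)
  if (length(diet_wide) < length(diet_narrow)) {
    stop("diet_wide must be at least as large as diet_narrow", call. = FALSE)
  }
  length(intersect(diet_wide, diet_narrow)) / length(diet_narrow)
}

#' Consumer nestedness (NODF over columns)
#'
#' Sorts the matrix in descending order of row and column marginal totals,
#' then scores every ordered pair of consumer columns (wider-diet consumer
#' first): the pair contributes `100 * paired_overlap` when the wider degree
#' strictly exceeds the narrower, and is excluded from the average ("NA")
#' when the two degrees are equal — so perfectly coincident feeding ranges
#' are neither rewarded nor penalized — or when the narrower consumer has no
#' links. The score is the mean of the recorded pair values; 100 indicates
#' perfect nestedness. `original = TRUE` restores the classic convention in
#' which equal-degree pairs score 0 instead of being excluded.
#'
#' @param net a `bipartite_network` with at least two consumers.
#' @param original logical; score equal-degree pairs 0 (classic NODF)
#'   instead of excluding them.
#' @return list with `score` (in \[0, 100\], or `NA` if every pair was
#'   excluded) and `n_pairs_used`.
#' @export
nodf_consumers <- function(net, original = FALSE) {
  validate_network(net, require_links = FALSE)
  if (n_consumers(net) < 2) {
    stop("consumer NODF requires at least two consumers", call. = FALSE)
  }
  a <- sort_by_marginals(net)$adjacency
  deg <- colSums(a)
  S_C <- ncol(a)
  scores <- c()
  for (i in seq_len(S_C - 1)) {
    for (j in seq.int(i + 1, S_C)) {
      if (deg[j] == 0) next
      if (deg[i] == deg[j]) {
        if (original) scores <- c(scores, 0)
        next
      }
      shared <- sum(a[, i] == 1L & a[, j] == 1L)
      scores <- c(scores, 100 * shared / deg[j])
    }
  }
  if (length(scores) == 0) {
    return(list(score = NA_real_, n_pairs_used = 0L))
  }
  list(score = mean(scores), n_pairs_used = length(scores))
}

#' Niche interval of a consumer
#'
#' The consumer's dietary range on the niche axis, `[c - r/2, c + r/2]`
#' (width exactly `r`), not clipped to the unit interval. With
#' `convention = "quantile"` the cutoffs are placed where the niche kernel
#' falls to 2.5% of its peak, an alternative matching the habit of drawing
#' 97.5% dietary ranges.
#'
#' @param c_i consumer niche center.
#' @param r_i consumer niche width (> 0).
#' @param g kernel exponent (used by the quantile convention).
#' @param convention `"halfwidth"` (default) or `"quantile"`.
#' @return numeric vector `c(lower, upper)`.
#' @export
r_interval <- function(c_i, r_i, g = 2, convention = c("halfwidth", "quantile")) {
  convention <- match.arg(convention)
  if (r_i <= 0) stop("niche width must be positive", call. = FALSE)
  half <- if (convention == "halfwidth") r_i / 2
          else (r_i / 2) * (-log(0.025))^(1 / g)
  c(c_i - half, c_i + half)
}

#' Continuous niche overlap of a consumer community
#'
#' The continuous analogue of consumer NODF, computed directly from fitted
#' niche intervals instead of simulated binary matrices. Consumers are
#' sorted by decreasing niche width; each ordered pair (wider `i`, narrower
#' `j`) with `r_i > r_j` contributes
#' `100 * |interval_i intersect interval_j| / r_j`, and equal-width pairs
#' are excluded from the average. A score of 100 means every narrower range
#' lies inside every wider one.
#'
#' @param params a `bpnm_params` with at least two consumers.
#' @param convention interval convention passed to [r_interval()].
#' @return list with `score` (in \[0, 100\] or `NA`) and `n_pairs_used`.
#' @export
continuous_overlap <- function(params, convention = "halfwidth") {
  stopifnot(inherits(params, "bpnm_params"))
  S_C <- length(params$c)
  if (S_C < 2) stop("need at least two consumers", call. = FALSE)
  ord <- order(-params$r)
  cc <- params$c[ord]; rr <- params$r[ord]
  iv <- vapply(seq_len(S_C),
               function(k) r_interval(cc[k], rr[k], params$g, convention),
               numeric(2))
  widths <- iv[2, ] - iv[1, ]
  scores <- c()
  for (i in seq_len(S_C - 1)) {
    for (j in seq.int(i + 1, S_C)) {
      if (rr[i] == rr[j]) next
      ov <- max(0, min(iv[2, i], iv[2, j]) - max(iv[1, i], iv[1, j]))
      scores <- c(scores, 100 * ov / widths[j])
    }
  }
  if (length(scores) == 0) {
    return(list(score = NA_real_, n_pairs_used = 0L))
  }
  list(score = mean(scores), n_pairs_used = length(scores))
}

#' Expected fraction of observed links predicted by a model
#'
#' `f_L = (1/L) * sum of p_ij over cells where A_ij = 1`: the expected
#' fraction of the observed links that a draw from the model realizes. The
#' measure is only meaningful when the model's expected link count
#' (`sum(P)`) is close to the observed count; a warning is emitted when the
#' relative discrepancy exceeds 5%.
#'
#' @param net a `bipartite_network` with `L >= 1`.
#' @param P a `probability_matrix` of matching dimensions.
#' @param threshold optional; when non-`NULL`, use the count variant instead:
#'   the fraction of observed links with `p_ij >= threshold`.
#' @return a fraction.
#' @export
fraction_links_predicted <- function(net, P, threshold = NULL) {
  validate_network(net)
  a <- net$adjacency
  if (!all(dim(a) == dim(P))) {
    stop("probability matrix dimensions do not match the network", call. = FALSE)
  }
  L <- sum(a)
  if (abs(sum(P) - L) / L > 0.05) {
    warning("expected link count differs from observed by more than 5%; ",
            "f_L may be a misleading measure of performance", call. = FALSE)
  }
  if (is.null(threshold)) sum(P[a == 1L]) / L
  else sum(P[a == 1L] >= threshold) / L
}

#' Connectance implied by a probability matrix
#'
#' The expected connectance `sum(p_ij) / (S_C * S_R)`, which avoids
#' simulating realized networks.
#'
#' @param P a `probability_matrix`.
#' @return a fraction.
#' @export
connectance_from_probabilities <- function(P) {
  mean(P)
}

#' Rank agreement between empirical degree and fitted niche width
#'
#' Spearman rank correlation (average ranks for ties) between each
#' consumer's number of resources in the observed network and its fitted
#' niche width `r` — the specialist-to-generalist ordering check.
#'
#' @param net a `bipartite_network` with at least three consumers.
#' @param params the fitted `bpnm_params`.
#' @return Spearman's rho, or `NA` if either ranking has zero variance.
#' @export
degree_r_rank_correlation <- function(net, params) {
  validate_network(net, require_links = FALSE)
  stopifnot(inherits(params, "bpnm_params"))
  if (n_consumers(net) < 3) stop("need at least three consumers", call. = FALSE)
  deg <- colSums(net$adjacency)
  if (length(params$r) != length(deg)) {
    stop("parameter set does not match the network's consumers", call. = FALSE)
  }
  if (stats::sd(deg) == 0 || stats::sd(params$r) == 0) return(NA_real_)
  stats::cor(deg, params$r, method = "spearman")
}

#' Dispersion of consumer niche centers
#'
#' Sample standard deviation (n - 1 denominator) of the consumer niche
#' centers `c`; distinguishes clumped niche structure (small or very large
#' dispersion) from near-uniform structure (intermediate dispersion).
#'
#' @param params a `bpnm_params` with at least two consumers.
#' @return a nonnegative number.
#' @export
c_dispersion <- function(params) {
  stopifnot(inherits(params, "bpnm_params"))
  if (length(params$c) < 2) stop("need at least two consumers", call. = FALSE)
  stats::sd(params$c)
}

#' Structural metrics report for a network and an optional fit
#'
#' Convenience wrapper assembling the structural metrics into a single-row
#' data frame: empirical consumer NODF, empirical connectance, and — when a
#' BPNM fit is supplied — continuous niche overlap, probability-based
#' connectance, ensemble-mean NODF/connectance, expected fraction of links
#' predicted, degree-vs-width rank correlation and niche-center dispersion.
#'
#' @param net a `bipartite_network`.
#' @param fit optional `bpnm_fit` with `model_kind = "bpnm"`.
#' @param ensemble_size number of simulated networks used for the
#'   simulation-based model metrics (0 to skip).
#' @param seed seed for the simulated ensemble.
#' @return a one-row data frame (class `metrics_report`).
#' @export
metrics_report <- function(net, fit = NULL, ensemble_size = 100, seed = 1) {
  nodf <- nodf_consumers(net)
  out <- data.frame(
    nodf_c = nodf$score,
    n_pairs_used = nodf$n_pairs_used,
    connectance_emp = connectance_empirical(net),
    overlap_r = NA_real_,
    connectance_prob = NA_real_,
    nodf_sim_mean = NA_real_,
    connectance_sim_mean = NA_real_,
    f_L = NA_real_,
    degree_r_spearman = NA_real_,
    c_sd = NA_real_
  )
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "bpnm_fit"), fit$model_kind == "bpnm")
    P <- probability_matrix(fit$params)
    out$overlap_r <- continuous_overlap(fit$params)$score
    out$connectance_prob <- connectance_from_probabilities(P)
    out$f_L <- fraction_links_predicted(net, P)
    out$degree_r_spearman <- degree_r_rank_correlation(net, fit$params)
    out$c_sd <- c_dispersion(fit$params)
    if (ensemble_size > 0) {
      ens <- simulate_ensemble(P, n_networks = ensemble_size, seed = seed)
      out$nodf_sim_mean <- ens$mean_nodf
      out$connectance_sim_mean <- ens$mean_connectance
    }
  }
  class(out) <- c("metrics_report", class(out))
  out
}
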