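#' Draw one realized network from a probability matrix
#'
#' Each consumer-resource cell is realized independently as a Bernoulli draw
#' with its link probability. Deterministic given `seed`.
#'
#' @param P a `probability_matrix`.
#' @param seed integer seed.
#' @return a `bipartite_network` (possibly with zero-degree species).
#' @export
draw_realization <- function(P, seed = 1) {
  set.seed(seed)
  a <- matrix(as.integer(stats::runif(length(P)) < P), nrow(P), ncol(P))
  bipartite_network(a)
}

#' Simulate an ensemble of networks and summarize its structure
#'
#' Draws `n_networks` independent realizations (realization `t` uses
#' [sub_seed()] `t` of `seed`) and records consumer NODF and connectance for
#' each. Realizations where NODF is undefined — fewer than two consumers
#' with links, or every column pair excluded — are skipped for the NODF mean
#' but still counted for connectance.
#'
#' @param P a `probability_matrix`.
#' @param n_networks ensemble size (default 100).
#' @param seed master seed.
#' @return an `ensemble_summary` list: `n_networks`, `mean_nodf`,
#'   `mean_connectance`, `n_nodf_undefined`, and per-network vectors `nodf`
#'   and `connectance`.
#' @export
simulate_ensemble <- function(P, n_networks = 100, seed = 1) {
  stopifnot(n_networks >= 1)
  nodf <- connect <- numeric(n_networks)
  for (t in seq_len(n_networks)) {
    net <- draw_realization(P, sub_seed(seed, t))
    connect[t] <- connectance_empirical(net)
    nodf[t] <- if (n_consumers(net) >= 2 && n_links(net) >= 1) {
      nodf_consumers(net)$score
    } else NA_real_
  }
  structure(list(n_networks = n_networks,
                 mean_nodf = mean(nodf, na.rm = TRUE),
                 mean_connectance = mean(connect),
                 n_nodf_undefined = sum(is.na(nodf)),
                 nodf = nodf,
                 connectance = connect),
            class = "ensemble_summary")
}

#' Specification for the synthetic-network generator
#'
#' Describes how ground-truth niche parameters are sampled. Resource
#' positions are always uniform on the niche axis. Consumer centers are
#' either uniform ("mutualistic-like" niche structure) or clumped around
#' `k_peaks` Gaussian peaks ("antagonistic-like"). Widths are either fixed
#' or exponential with a given mean (truncated into the legal width range).
#'
#' @param S_C,S_R consumer and resource counts.
#' @param center_law `"uniform"` or `"clumped"`.
#' @param k_peaks,peak_sd clumped-law settings: number of peaks and the
#'   Gaussian spread of centers around each peak.
#' @param width_law `"fixed"` or `"exponential"`.
#' @param width width value (fixed law) or mean (exponential law).
#' @param g,p_max global kernel parameters of the generating model.
#' @param class_label label carried through to study records; defaults to
#'   `"mutualistic-like"` for uniform centers and `"antagonistic-like"` for
#'   clumped centers.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(S_C = 15, S_R = 15,
                           center_law = c("uniform", "clumped"),
                           k_peaks = 1, peak_sd = 0.05,
                           width_law = c("fixed", "exponential"),
                           width = 0.3, g = 2, p_max = 0.95,
                           class_label = NULL) {
  center_law <- match.arg(center_law)
  width_law <- match.arg(width_law)
  stopifnot(S_C >= 2, S_R >= 2, k_peaks >= 1, peak_sd > 0, width > 0)
  if (is.null(class_label)) {
    class_label <- if (center_law == "clumped") "antagonistic-like"
                   else "mutualistic-like"
  }
  structure(list(S_C = as.integer(S_C), S_R = as.integer(S_R),
                 center_law = center_law, k_peaks = as.integer(k_peaks),
                 peak_sd = peak_sd, width_law = width_law, width = width,
                 g = g, p_max = p_max, class_label = class_label),
            class = "synthetic_spec")
}

sample_truth <- function(spec) {
  n <- stats::runif(spec$S_R)
  centers <- if (spec$center_law == "uniform") {
    stats::runif(spec$S_C)
  } else {
    peaks <- stats::runif(spec$k_peaks, 0.15, 0.85)
    pmin(pmax(stats::rnorm(spec$S_C,
                           mean = sample(peaks, spec$S_C, replace = TRUE),
                           sd = spec$peak_sd), 0), 1)
  }
  widths <- if (spec$width_law == "fixed") {
    rep(spec$width, spec$S_C)
  } else {
    pmin(pmax(stats::rexp(spec$S_C, rate = 1 / spec$width), 0.02),
         .bpnm_bounds$r_cap)
  }
  bpnm_params(n, centers, widths, spec$g, spec$p_max)
}

#' Generate a synthetic network with known ground truth
#'
#' Samples ground-truth niche parameters according to the spec, builds the
#' implied probability matrix, and draws one realization. Zero-degree
#' species are kept (they are a normal feature of realized draws); only
#' realizations with an all-zero side (no links at all) are redrawn with
#' fresh sub-seeds, up to `max_retries` times.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; the full (network, truth) pair is reproducible.
#' @param max_retries redraw cap before giving up on a too-sparse spec.
#' @return list with `network` (a `bipartite_network`), `truth` (the
#'   generating `bpnm_params`), `class_label`, `seed`.
#' @export
generate_synthetic_network <- function(spec, seed = 1, max_retries = 50) {
  stopifnot(inherits(spec, "synthetic_spec"))
  for (attempt in seq_len(max_retries)) {
    s <- sub_seed(seed, attempt - 1)
    set.seed(s)
    truth <- sample_truth(spec)
    P <- probability_matrix(truth)
    net <- draw_realization(P, sub_seed(s, 1))
    if (n_links(net) >= 1) {
      return(list(network = net, truth = truth,
                  class_label = spec$class_label, seed = seed))
    }
  }
  stop("generation failed: spec too sparse to yield any links within the ",
       "retry cap", call. = FALSE)
}

#' Well-spaced niche community with known ground truth
#'
#' Deterministic-by-seed generator of a community designed for parameter
#' identifiability, used to study how well fitting recovers known niche
#' parameters from a single realized network. Consumer niche centers sit on
#' a regular grid across the axis; niche widths take five well-separated
#' levels (0.3 to 1.3, three consumers each, plus a small jitter that makes
#' all widths distinct), with the wider levels assigned to the more central
#' consumers so that every niche lies essentially on the axis — a width
#' whose interval extends far past the ends of the axis is not identifiable
#' from interaction data. Resource positions are a jittered regular grid.
#' One realization is drawn from the implied probability matrix; draws with
#' an isolated species are retried with fresh sub-seeds.
#'
#' @param S_C,S_R consumer and resource counts.
#' @param g,p_max global kernel parameters of the generating model.
#' @param seed integer seed.
#' @param max_retries redraw cap.
#' @return list with `network`, `truth` (`bpnm_params`), `seed`.
#' @export
well_spaced_community <- function(S_C = 15, S_R = 15, g = 2, p_max = 0.95,
                                  seed = 1, max_retries = 100) {
  ck <- (seq_len(S_C) - 0.5) / S_C
  width_levels <- rep(seq(1.3, 0.3, length.out = 5),
                      each = ceiling(S_C / 5))[seq_len(S_C)]
  w0 <- numeric(S_C)
  w0[order(abs(ck - 0.5))] <- width_levels  # widest niches mid-axis
  for (attempt in seq_len(max_retries)) {
    s <- sub_seed(seed, attempt - 1)
    set.seed(s)
    widths <- pmin(pmax(w0 + stats::runif(S_C, -0.02, 0.02), 0.05),
                   .bpnm_bounds$r_cap)
    n <- pmin(pmax((seq_len(S_R) - 0.5) / S_R + stats::runif(S_R, -0.03, 0.03),
                   0), 1)
    truth <- bpnm_params(n, ck, widths, g, p_max)
    net <- draw_realization(probability_matrix(truth), sub_seed(s, 1))
    if (all(rowSums(net$adjacency) > 0) && all(colSums(net$adjacency) > 0)) {
      return(list(network = net, truth = truth, seed = seed))
    }
  }
  stop("generation failed within the retry cap", call. = FALSE)
}

#' Perfectly nested triangular network
#'
#' The canonical maximally nested fixture: an S x S binary matrix in which
#' consumer k interacts with resources 1..k, so all column degrees are
#' distinct and every narrower diet is a subset of every wider one.
#'
#' @param S side length (>= 2).
#' @return a `bipartite_network` with `S * (S + 1) / 2` links.
#' @export
generate_nested_matrix <- function(S) {
  stopifnot(S >= 2)
  a <- outer(seq_len(S), seq_len(S), function(j, k) as.integer(j <= k))
  bipartite_network(a)
}
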