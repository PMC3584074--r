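#' Run the full per-network analysis over a collection of networks
#'
#' For each input network: fits the BPNM, cascade and random models, records
#' their AICc, and computes the structural metrics (empirical consumer NODF,
#' continuous niche overlap of the fitted parameters, connectance by all
#' three estimators, expected fraction of links predicted, degree-vs-width
#' rank correlation, niche-center dispersion). A failure on one network is
#' recorded and the run continues.
#'
#' @param networks list of inputs; each element is either a
#'   `bipartite_network` or a list with elements `network` and (optionally)
#'   `class_label`, as returned by [generate_synthetic_network()].
#' @param config an [anneal_config()]; each network gets its own sub-seed.
#' @param ensemble_size networks simulated per fit for the simulation-based
#'   model metrics (0 to skip them).
#' @return a data frame with one row per network (columns `network_id`,
#'   `class_label`, `size`, `aicc_bpnm`, `aicc_cascade`, `aicc_random`,
#'   `f_L`, `nodf_c`, `nodf_sim_mean`, `overlap_r`, `connectance_emp`,
#'   `connectance_prob`, `connectance_sim_mean`, `degree_r_spearman`,
#'   `c_sd`, `error`); fitted BPNM objects in `attr(, "bpnm_fits")`.
#' @export
run_study <- function(networks, config = anneal_config(), ensemble_size = 100) {
  if (length(networks) == 0) stop("no networks supplied", call. = FALSE)
  rows <- vector("list", length(networks))
  bpnm_fits <- vector("list", length(networks))
  for (idx in seq_along(networks)) {
    item <- networks[[idx]]
    if (inherits(item, "bipartite_network")) {
      net <- item; label <- NA_character_
    } else {
      net <- item$network
      label <- if (!is.null(item$class_label)) item$class_label else NA_character_
    }
    rec <- data.frame(network_id = idx, class_label = label,
                      size = n_consumers(net) * n_resources(net),
                      aicc_bpnm = NA_real_, aicc_cascade = NA_real_,
                      aicc_random = NA_real_, f_L = NA_real_,
                      nodf_c = NA_real_, nodf_sim_mean = NA_real_,
                      overlap_r = NA_real_, connectance_emp = NA_real_,
                      connectance_prob = NA_real_,
                      connectance_sim_mean = NA_real_,
                      degree_r_spearman = NA_real_, c_sd = NA_real_,
                      error = NA_character_)
    res <- tryCatch({
      cfg <- config
      cfg$seed <- sub_seed(config$seed, idx)
      cmp <- suppressWarnings(compare_models(net, config = cfg))
      fits <- attr(cmp, "fits")
      fit <- fits$bpnm
      rep <- suppressWarnings(
        metrics_report(net, fit, ensemble_size = ensemble_size,
                       seed = sub_seed(cfg$seed, 999))
      )
      rec$aicc_bpnm <- fits$bpnm$aicc
      rec$aicc_cascade <- fits$cascade$aicc
      rec$aicc_random <- fits$random$aicc
      rec$f_L <- rep$f_L
      rec$nodf_c <- rep$nodf_c
      rec$nodf_sim_mean <- rep$nodf_sim_mean
      rec$overlap_r <- rep$overlap_r
      rec$connectance_emp <- rep$connectance_emp
      rec$connectance_prob <- rep$connectance_prob
      rec$connectance_sim_mean <- rep$connectance_sim_mean
      rec$degree_r_spearman <- rep$degree_r_spearman
      rec$c_sd <- rep$c_sd
      bpnm_fits[[idx]] <- fit
      rec
    }, error = function(e) {
      rec$error <- conditionMessage(e)
      rec
    })
    rows[[idx]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bpnm_fits") <- bpnm_fits
  out
}

#' Regression of a model-derived metric on its empirical counterpart
#'
#' Ordinary least squares of the model-derived values on the empirical
#' values across networks, with residuals paired with network size for
#' scale diagnostics.
#'
#' @param records a study data frame from [run_study()].
#' @param model_col column holding the model-derived metric (default
#'   `"overlap_r"`; use `"nodf_sim_mean"`, `"connectance_prob"` or
#'   `"connectance_sim_mean"` for the other comparisons).
#' @param empirical_col column holding the empirical metric.
#' @return list with `slope`, `intercept`, `r_squared`, `n`, and a
#'   `residuals` data frame (`size`, `residual`), plus the underlying `lm`
#'   fit in `$model`.
#' @export
overlap_regression <- function(records, model_col = "overlap_r",
                               empirical_col = "nodf_c") {
  x <- records[[empirical_col]]; y <- records[[model_col]]
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3) stop("need at least three defined points", call. = FALSE)
  d <- data.frame(x = x[keep], y = y[keep], size = records$size[keep])
  fit <- stats::lm(y ~ x, data = d)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = nrow(d),
       residuals = data.frame(size = d$size,
                              residual = unname(stats::residuals(fit))),
       model = fit)
}

#' Compare niche-center dispersion between two network classes
#'
#' Two-sample Kolmogorov-Smirnov comparison of the per-network standard
#' deviations of fitted consumer niche centers between two classes (e.g.
#' mutualistic-like vs antagonistic-like), plus the point pairs of a Q-Q
#' plot. The p-value is the asymptotic Kolmogorov approximation.
#'
#' @param records a study data frame from [run_study()] with a
#'   `class_label` column (exactly two classes, each with at least two
#'   defined values).
#' @param value_col column to compare (default `"c_sd"`).
#' @return list with `statistic` (KS D), `p_value`, `classes`, sample sizes
#'   `n1`, `n2`, and `qq` (data frame of matched quantile pairs `q1`, `q2`).
#' @export
class_comparison <- function(records, value_col = "c_sd") {
  keep <- is.finite(records[[value_col]]) & !is.na(records$class_label)
  records <- records[keep, , drop = FALSE]
  classes <- sort(unique(records$class_label))
  if (length(classes) != 2) stop("need exactly two classes", call. = FALSE)
  x <- records[[value_col]][records$class_label == classes[1]]
  y <- records[[value_col]][records$class_label == classes[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop("each class needs at least two records", call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  # Q-Q pairs: sorted smaller sample vs interpolated quantiles of the larger
  sx <- sort(x); sy <- sort(y)
  if (length(sx) > length(sy)) {
    sx <- stats::approx(seq_along(sx), sx, n = length(sy))$y
  } else if (length(sy) > length(sx)) {
    sy <- stats::approx(seq_along(sy), sy, n = length(sx))$y
  }
  list(statistic = unname(ks$statistic),
       p_value = ks$p.value,
       classes = classes,
       n1 = length(x), n2 = length(y),
       qq = data.frame(q1 = sx, q2 = sy))
}
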