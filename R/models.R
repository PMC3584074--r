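## Probability clamp applied to every link probability so the Bernoulli
## log-likelihood stays finite (e.g. a "forbidden" cascade pair that is
## nonetheless observed).
.bpnm_eps <- 1e-10

## Domain bounds for model parameters. A width of 2 spans the whole unit
## niche axis; the cap on g avoids numerically flat plateau kernels.
.bpnm_bounds <- list(r_cap = 2, g_min = 1, g_cap = 20)

#' Parameter sets for the three link models
#'
#' `bpnm_params()` holds the niche-model parameters: resource niche positions
#' `n` on the unit axis, consumer niche centers `c` and widths `r`, a global
#' cutoff-shape exponent `g` (g = 2 is a Gaussian niche; larger values are
#' flatter in the center and cut off faster at the edges) and a global peak
#' probability `p_max` (the interaction probability when a resource sits
#' exactly at a consumer's niche optimum).
#'
#' `cascade_params()` holds the probabilistic bipartite cascade model's
#' order parameters: one `phi` per consumer and one `psi` per resource, both
#' on the unit interval. A consumer-resource pair is "allowed" iff
#' `psi_j < phi_i`.
#'
#' `random_params()` holds the single constant link probability of the
#' random model.
#'
#' @param n numeric vector of resource niche positions in \[0, 1\].
#' @param centers numeric vector of consumer niche centers in \[0, 1\].
#' @param widths numeric vector of positive consumer niche widths (at most 2).
#' @param g cutoff-shape exponent in \[1, 20\].
#' @param p_max peak interaction probability in (0, 1\].
#' @return an object of class `bpnm_params`, `cascade_params` or
#'   `random_params`.
#' @export
bpnm_params <- function(n, centers, widths, g = 2, p_max = 0.9) {
  n <- as.numeric(n); centers <- as.numeric(centers); widths <- as.numeric(widths)
  if (length(centers) != length(widths)) {
    stop("centers and widths must have one entry per consumer", call. = FALSE)
  }
  if (any(n < 0 | n > 1) || any(centers < 0 | centers > 1)) {
    stop("niche positions and centers must lie in [0, 1]", call. = FALSE)
  }
  if (any(widths <= 0) || any(widths > .bpnm_bounds$r_cap)) {
    stop("niche widths must lie in (0, ", .bpnm_bounds$r_cap, "]", call. = FALSE)
  }
  if (length(g) != 1 || g < .bpnm_bounds$g_min || g > .bpnm_bounds$g_cap) {
    stop("g must be a single value in [", .bpnm_bounds$g_min, ", ",
         .bpnm_bounds$g_cap, "]", call. = FALSE)
  }
  if (length(p_max) != 1 || p_max <= .bpnm_eps || p_max > 1) {
    stop("p_max must be a single probability in (0, 1]", call. = FALSE)
  }
  structure(list(n = n, c = centers, r = widths, g = g, p_max = p_max),
            class = "bpnm_params")
}

#' @rdname bpnm_params
#' @param phi numeric vector of consumer order parameters in \[0, 1\].
#' @param psi numeric vector of resource order parameters in \[0, 1\].
#' @export
cascade_params <- function(phi, psi) {
  phi <- as.numeric(phi); psi <- as.numeric(psi)
  if (any(phi < 0 | phi > 1) || any(psi < 0 | psi > 1)) {
    stop("cascade order parameters must lie in [0, 1]", call. = FALSE)
  }
  structure(list(phi = phi, psi = psi), class = "cascade_params")
}

#' @rdname bpnm_params
#' @param p constant link probability in (0, 1).
#' @export
random_params <- function(p) {
  if (length(p) != 1 || p <= 0 || p >= 1) {
    stop("p must be a single probability in (0, 1)", call. = FALSE)
  }
  structure(list(p = as.numeric(p)), class = "random_params")
}

clamp_prob <- function(p, eps = .bpnm_eps) pmin(pmax(p, eps), 1 - eps)

#' Niche-model interaction probability
#'
#' The probability that a consumer with niche center `c_i` and width `r_i`
#' interacts with a resource at niche position `n_j`:
#' `p_max * exp(-(|n_j - c_i| / (r_i / 2))^g)`, clamped away from 0 and 1 by
#' a tiny epsilon. The kernel peaks at `p_max` when the resource sits on the
#' consumer's optimum and decreases symmetrically with distance; `g = 2`
#' gives a Gaussian profile.
#'
#' @param n_j resource niche position(s).
#' @param c_i consumer niche center.
#' @param r_i consumer niche width (> 0).
#' @param g cutoff-shape exponent.
#' @param p_max peak probability.
#' @return interaction probability (vectorized over `n_j`).
#' @export
bpnm_probability <- function(n_j, c_i, r_i, g = 2, p_max = 0.9) {
  if (any(r_i <= 0)) stop("niche width r_i must be positive", call. = FALSE)
  clamp_prob(p_max * exp(-(abs(n_j - c_i) / (r_i / 2))^g))
}

new_probability_matrix <- function(p, model_kind) {
  structure(clamp_prob(p), model_kind = model_kind, epsilon = .bpnm_eps,
            class = c("probability_matrix", class(p)))
}

#' Per-pair probability matrix of a model
#'
#' Evaluates a parameter set into the full resource-by-consumer matrix of
#' link probabilities. For the cascade model, each allowed pair (where
#' `psi_j < phi_i`) gets probability `L_observed / L_p` with `L_p` the number
#' of allowed pairs — so that the expected number of links equals the
#' observed count — and forbidden pairs get the epsilon floor.
#'
#' @param params a `bpnm_params`, `cascade_params` or `random_params` object.
#' @param ... passed to methods.
#' @return a `probability_matrix`: numeric matrix with entries clamped to
#'   \[eps, 1 - eps\], with attributes `model_kind` and `epsilon`.
#' @export
probability_matrix <- function(params, ...) UseMethod("probability_matrix")

#' @rdname probability_matrix
#' @export
probability_matrix.bpnm_params <- function(params, ...) {
  # outer |n_j - c_i| scaled per consumer column
  d <- abs(outer(params$n, params$c, "-"))
  z <- sweep(d, 2, params$r / 2, "/")
  new_probability_matrix(params$p_max * exp(-z^params$g), "bpnm")
}

#' @rdname probability_matrix
#' @param L_observed observed link count the cascade model is calibrated to.
#' @export
probability_matrix.cascade_params <- function(params, L_observed, ...) {
  allowed <- outer(params$psi, params$phi, "<")
  L_p <- sum(allowed)
  if (L_p == 0) {
    stop("degenerate cascade parameters: no allowed pairs (L_p = 0)",
         call. = FALSE)
  }
  p <- matrix(0, nrow(allowed), ncol(allowed))
  p[allowed] <- L_observed / L_p
  new_probability_matrix(p, "cascade")
}

#' @rdname probability_matrix
#' @param S_C,S_R consumer and resource counts for the constant matrix.
#' @export
probability_matrix.random_params <- function(params, S_C, S_R, ...) {
  new_probability_matrix(matrix(params$p, S_R, S_C), "random")
}

#' Bernoulli log-likelihood of a network under a probability matrix
#'
#' Sums `A_ij * log(p_ij) + (1 - A_ij) * log(1 - p_ij)` over all
#' consumer-resource cells. Always finite (probabilities are clamped) and
#' non-positive.
#'
#' @param net a `bipartite_network`.
#' @param P a `probability_matrix` of matching dimensions.
#' @return the log-likelihood (a single non-positive number).
#' @export
log_likelihood <- function(net, P) {
  validate_network(net, require_links = FALSE)
  a <- net$adjacency
  if (!all(dim(a) == dim(P))) {
    stop("probability matrix dimensions do not match the network", call. = FALSE)
  }
  sum(ifelse(a == 1L, log(P), log1p(-P)))
}

#' Number of free parameters per model
#'
#' BPNM: one `n` per resource, `c` and `r` per consumer, plus the two global
#' parameters `g` and `p_max`, so `S_R + 2 * S_C + 2`. Cascade: one order
#' parameter per species, `S_C + S_R`. Random: 1.
#'
#' @param model_kind `"bpnm"`, `"cascade"` or `"random"`.
#' @param S_C,S_R consumer and resource counts.
#' @return integer parameter count.
#' @export
parameter_count <- function(model_kind, S_C, S_R) {
  switch(match.arg(model_kind, c("bpnm", "cascade", "random")),
         bpnm = S_R + 2L * S_C + 2L,
         cascade = S_C + S_R,
         random = 1L)
}

#' AICc: Akaike information criterion with small-sample correction
#'
#' `-2 logL + 2k + 2k(k + 1)/(n_obs - k - 1)`, where `n_obs` is the number
#' of binary observations (`S_C * S_R` cells for a bipartite network).
#' Undefined (returns `NA` with a warning) when `n_obs <= k + 1`.
#'
#' @param logL maximized log-likelihood.
#' @param k number of free parameters.
#' @param n_obs number of observations.
#' @return the AICc value, or `NA_real_` if the correction is undefined.
#' @export
aicc <- function(logL, k, n_obs) {
  if (n_obs <= k + 1) {
    warning("AICc undefined: n_obs <= k + 1; model excluded from comparison",
            call. = FALSE)
    return(NA_real_)
  }
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

model_kind_of <- function(params) {
  switch(class(params)[1],
         bpnm_params = "bpnm",
         cascade_params = "cascade",
         random_params = "random",
         stop("unknown parameter class", call. = FALSE))
}

#' Read and write model parameter sets
#'
#' Parameter sets serialize to JSON with a `model_kind` tag and full-precision
#' numeric vectors; the round trip is exact.
#'
#' @param params a parameter object.
#' @param path file path.
#' @return `read_params` returns the parameter object; `write_params` returns
#'   `path` invisibly.
#' @export
write_params <- function(params, path) {
  obj <- c(list(model_kind = model_kind_of(params)), unclass(params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$model_kind,
         bpnm = bpnm_params(obj$n, obj$c, obj$r, obj$g, obj$p_max),
         cascade = cascade_params(obj$phi, obj$psi),
         random = random_params(obj$p),
         stop("unknown model_kind in parameter file", call. = FALSE))
}
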