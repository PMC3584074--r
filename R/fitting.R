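#' Simulated-annealing configuration
#'
#' Settings for the annealer used by [fit_model()]. One sweep proposes one
#' move per free parameter; the temperature is multiplied by
#' `cooling_factor` after each sweep (geometric schedule). With
#' `initial_temperature = "auto"` the starting temperature is the standard
#' deviation of the log-likelihood over 50 random-parameter probes, which
#' scales the schedule to the roughness of the likelihood surface of the
#' network at hand.
#'
#' @param n_sweeps number of annealing sweeps.
#' @param initial_temperature positive number, or `"auto"`.
#' @param cooling_factor geometric cooling multiplier in (0, 1).
#' @param proposal_sd standard deviation of the Gaussian perturbation applied
#'   to a parameter (on the log scale for `g`, logit scale for `p_max`).
#' @param global_move_prob probability that a proposal redraws the parameter
#'   uniformly over its whole domain instead of taking a local Gaussian
#'   step. Niche positions sit in a multimodal likelihood (a resource can
#'   often be mirrored to the far side of a consumer's niche center at a
#'   local optimum), and the occasional domain-wide redraw — a symmetric
#'   proposal, so Metropolis acceptance still applies — lets the annealer
#'   jump between such modes.
#' @param n_restarts number of independent annealing restarts; the best is
#'   returned.
#' @param seed integer seed controlling all randomness of the fit.
#' @return an `anneal_config` list.
#' @export
anneal_config <- function(n_sweeps = 400, initial_temperature = "auto",
                          cooling_factor = 0.95, proposal_sd = 0.05,
                          global_move_prob = 0.15,
                          n_restarts = 3, seed = 1) {
  stopifnot(n_sweeps >= 1,
            identical(initial_temperature, "auto") ||
              (is.numeric(initial_temperature) && initial_temperature > 0),
            cooling_factor > 0, cooling_factor < 1,
            proposal_sd > 0, global_move_prob >= 0, global_move_prob < 1,
            n_restarts >= 1)
  structure(list(n_sweeps = as.integer(n_sweeps),
                 initial_temperature = initial_temperature,
                 cooling_factor = cooling_factor,
                 proposal_sd = proposal_sd,
                 global_move_prob = global_move_prob,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "anneal_config")
}

#' Derive a reproducible sub-seed
#'
#' Counter scheme used everywhere randomness is split across restarts or
#' ensemble members: sub-seed `k` of master seed `s` is
#' `(s * 48271 + k) mod (2^31 - 1)`. Deterministic and extendable (adding
#' members never changes earlier ones).
#'
#' @param seed master integer seed.
#' @param k counter (restart or realization index).
#' @return an integer seed.
#' @export
sub_seed <- function(seed, k) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + as.numeric(k)) %% 2147483647)
}

## cellwise Bernoulli log-likelihood terms; a is a 0/1 matrix/vector
ll_terms <- function(a, p) a * log(p) + (1 - a) * log1p(-p)

## reflect a proposal into [lo, hi]
reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

random_bpnm_params <- function(S_C, S_R) {
  bpnm_params(n = stats::runif(S_R), centers = stats::runif(S_C),
              widths = stats::runif(S_C, 0.05, .bpnm_bounds$r_cap),
              g = exp(stats::runif(1, 0, log(.bpnm_bounds$g_cap))),
              p_max = stats::runif(1, 0.05, 1))
}

random_cascade_params <- function(S_C, S_R) {
  repeat {
    par <- cascade_params(stats::runif(S_C), stats::runif(S_R))
    if (sum(outer(par$psi, par$phi, "<")) >= 1) return(par)
  }
}

## auto initial temperature: sd of logL over random-parameter probes
auto_temperature <- function(net, model_kind, n_probe = 50) {
  S_C <- n_consumers(net); S_R <- n_resources(net); L <- n_links(net)
  lls <- vapply(seq_len(n_probe), function(i) {
    par <- if (model_kind == "bpnm") random_bpnm_params(S_C, S_R)
           else random_cascade_params(S_C, S_R)
    P <- if (model_kind == "bpnm") probability_matrix(par)
         else probability_matrix(par, L_observed = L)
    log_likelihood(net, P)
  }, numeric(1))
  t0 <- stats::sd(lls)
  if (!is.finite(t0) || t0 <= 0) t0 <- 1
  t0
}

## Correspondence-analysis (reciprocal-averaging) scores of a binary matrix:
## the classical 1-D ordination that recovers a latent niche axis ordering.
## Returns row and column scores rescaled to [0, 1].
ca_axis_scores <- function(a) {
  rs <- rowSums(a); cs <- colSums(a); N <- sum(a)
  p <- a / N
  e <- outer(rs / N, cs / N)
  z <- (p - e) / sqrt(e + 1e-12)
  sv <- svd(z)
  # first non-trivial axis
  row_score <- sv$u[, 1] / sqrt(rs / N + 1e-12)
  col_score <- sv$v[, 1] / sqrt(cs / N + 1e-12)
  rescale01 <- function(x) {
    rg <- range(x)
    if (diff(rg) < 1e-12) rep(0.5, length(x)) else (x - rg[1]) / diff(rg)
  }
  list(rows = rescale01(row_score), cols = rescale01(col_score))
}

## degree-based initial niche widths: invert the expected-degree relation
## E[deg_i] ~ S_R * p_max * (r_i / 2) * sqrt(pi) of a Gaussian kernel on a
## unit axis densely tiled with resources
degree_width_init <- function(a, p_peak) {
  deg <- colSums(a)
  w <- 2 * deg / (nrow(a) * p_peak * sqrt(pi))
  pmin(base::pmax(w, 0.05), .bpnm_bounds$r_cap)
}

## ---- BPNM annealing restart -------------------------------------------
## Incremental likelihood bookkeeping: a move of n_j touches only row j of
## the probability matrix, a move of c_i or r_i only column i; g and p_max
## touch the whole matrix.
anneal_bpnm <- function(a, config, t0, fix_g = NULL, fix_p_max = NULL,
                        init = c("random", "ca", "ca_reflected")) {
  init <- match.arg(init)
  S_R <- nrow(a); S_C <- ncol(a)
  g <- if (is.null(fix_g)) 2 else fix_g
  pmax <- if (is.null(fix_p_max)) 0.9 else fix_p_max
  if (init == "random") {
    n <- stats::runif(S_R); cc <- stats::runif(S_C)
    r <- rep(0.3, S_C)
  } else {
    sc <- ca_axis_scores(a)
    n <- sc$rows; cc <- sc$cols
    if (init == "ca_reflected") { n <- 1 - n; cc <- 1 - cc }
    r <- degree_width_init(a, pmax)
  }
  sd0 <- config$proposal_sd
  r_cap <- .bpnm_bounds$r_cap
  lg_lo <- log(.bpnm_bounds$g_min); lg_hi <- log(.bpnm_bounds$g_cap)

  col_p <- function(i) clamp_prob(pmax * exp(-(abs(n - cc[i]) / (r[i] / 2))^g))
  row_p <- function(j) clamp_prob(pmax * exp(-(abs(n[j] - cc) / (r / 2))^g))
  full_p <- function(gv, pv) {
    z <- sweep(abs(outer(n, cc, "-")), 2, r / 2, "/")
    clamp_prob(pv * exp(-z^gv))
  }

  P <- full_p(g, pmax)
  LL <- ll_terms(a, P)
  ll <- sum(LL)
  best <- list(n = n, c = cc, r = r, g = g, p_max = pmax)
  best_ll <- ll

  # move table: type 1 = n_j, 2 = c_i, 3 = r_i, 4 = g, 5 = p_max
  types <- c(rep(1L, S_R), rep(2L, S_C), rep(3L, S_C),
             if (is.null(fix_g)) 4L, if (is.null(fix_p_max)) 5L)
  idxs  <- c(seq_len(S_R), seq_len(S_C), seq_len(S_C),
             if (is.null(fix_g)) 0L, if (is.null(fix_p_max)) 0L)
  n_par <- length(types)

  temp <- t0
  trace <- matrix(NA_real_, config$n_sweeps, 3,
                  dimnames = list(NULL, c("sweep", "temperature", "logL")))
  mark_sweep <- max(1L, floor(0.9 * config$n_sweeps))
  ll_at_mark <- NA_real_

  for (sweep in seq_len(config$n_sweeps)) {
    ord <- sample.int(n_par)
    steps <- stats::rnorm(n_par, 0, sd0)
    us <- stats::runif(n_par)
    gates <- stats::runif(n_par) < config$global_move_prob
    draws <- stats::runif(n_par)
    for (m in seq_len(n_par)) {
      k <- ord[m]; ty <- types[k]; id <- idxs[k]
      if (ty == 1L) {
        new_v <- if (gates[m]) draws[m] else reflect(n[id] + steps[m], 0, 1)
        old_v <- n[id]; n[id] <- new_v
        p_new <- row_p(id)
        l_new <- ll_terms(a[id, ], p_new)
        dll <- sum(l_new) - sum(LL[id, ])
        if (dll >= 0 || us[m] < exp(dll / temp)) {
          P[id, ] <- p_new; LL[id, ] <- l_new; ll <- ll + dll
        } else n[id] <- old_v
      } else if (ty == 2L || ty == 3L) {
        if (ty == 2L) {
          old_v <- cc[id]
          cc[id] <- if (gates[m]) draws[m] else reflect(cc[id] + steps[m], 0, 1)
        } else {
          old_v <- r[id]
          r[id] <- if (gates[m]) 1e-4 + draws[m] * (r_cap - 1e-4)
                   else reflect(r[id] + steps[m], 1e-4, r_cap)
        }
        p_new <- col_p(id)
        l_new <- ll_terms(a[, id], p_new)
        dll <- sum(l_new) - sum(LL[, id])
        if (dll >= 0 || us[m] < exp(dll / temp)) {
          P[, id] <- p_new; LL[, id] <- l_new; ll <- ll + dll
        } else if (ty == 2L) cc[id] <- old_v else r[id] <- old_v
      } else {
        if (ty == 4L) {
          old_v <- g
          g <- if (gates[m]) exp(lg_lo + draws[m] * (lg_hi - lg_lo))
               else exp(reflect(log(g) + steps[m], lg_lo, lg_hi))
        } else {
          old_v <- pmax
          pmax <- if (gates[m]) 1e-6 + draws[m] * (1 - 2e-6)
                  else stats::plogis(stats::qlogis(clamp_prob(pmax)) + steps[m])
        }
        p_new <- full_p(g, pmax)
        l_new <- ll_terms(a, p_new)
        dll <- sum(l_new) - ll
        if (dll >= 0 || us[m] < exp(dll / temp)) {
          P <- p_new; LL <- l_new; ll <- ll + dll
        } else if (ty == 4L) g <- old_v else pmax <- old_v
      }
      if (ll > best_ll) {
        best_ll <- ll
        best <- list(n = n, c = cc, r = r, g = g, p_max = pmax)
      }
    }
    # collective affine moves: rescale/shift the whole axis with widths
    # rescaled in step. Single-parameter moves cannot escape a solution in
    # which the axis is compressed or locally warped (an approximate gauge
    # freedom of niche models); a joint move can.
    for (aff in 1:2) {
      bsc <- exp(stats::rnorm(1, 0, 0.15))
      shift <- stats::rnorm(1, 0, 0.08)
      n2 <- shift + bsc * n
      c2 <- shift + bsc * cc
      # folding out-of-range values back would warp the axis non-monotonically;
      # skip proposals that leave the domain instead
      if (any(n2 < 0 | n2 > 1) || any(c2 < 0 | c2 > 1)) next
      r2 <- pmin(base::pmax(bsc * r, 1e-4), r_cap)
      z2 <- sweep(abs(outer(n2, c2, "-")), 2, r2 / 2, "/")
      P2 <- clamp_prob(pmax * exp(-z2^g))
      L2 <- ll_terms(a, P2)
      dll <- sum(L2) - ll
      if (dll >= 0 || stats::runif(1) < exp(dll / temp)) {
        n <- n2; cc <- c2; r <- r2; P <- P2; LL <- L2; ll <- ll + dll
        if (ll > best_ll) {
          best_ll <- ll
          best <- list(n = n, c = cc, r = r, g = g, p_max = pmax)
        }
      }
    }
    trace[sweep, ] <- c(sweep, temp, ll)
    if (sweep == mark_sweep) ll_at_mark <- best_ll
    temp <- temp * config$cooling_factor
  }
  converged <- is.finite(ll_at_mark) && (best_ll - ll_at_mark) < 1e-6
  params <- bpnm_params(best$n, best$c, pmin(base::pmax(best$r, 1e-4), r_cap),
                        best$g, min(max(best$p_max, 1e-6), 1))
  list(params = params, logL = best_ll, trace = as.data.frame(trace),
       converged = converged)
}

## ---- cascade annealing restart ----------------------------------------
## The calibrated link probability L/L_p is global, so every move is scored
## with a full (vectorized) matrix recomputation.
anneal_cascade <- function(a, config, t0) {
  S_R <- nrow(a); S_C <- ncol(a); L <- sum(a)
  eval_ll <- function(phi, psi) {
    allowed <- outer(psi, phi, "<")
    L_p <- sum(allowed)
    if (L_p == 0) return(-Inf)
    p <- matrix(.bpnm_eps, S_R, S_C)
    p[allowed] <- min(L / L_p, 1 - .bpnm_eps)
    sum(ll_terms(a, p))
  }
  repeat {
    phi <- stats::runif(S_C); psi <- stats::runif(S_R)
    ll <- eval_ll(phi, psi)
    if (is.finite(ll)) break
  }
  best <- list(phi = phi, psi = psi); best_ll <- ll
  n_par <- S_C + S_R
  types <- c(rep(1L, S_C), rep(2L, S_R))
  idxs  <- c(seq_len(S_C), seq_len(S_R))
  temp <- t0
  trace <- matrix(NA_real_, config$n_sweeps, 3,
                  dimnames = list(NULL, c("sweep", "temperature", "logL")))
  mark_sweep <- max(1L, floor(0.9 * config$n_sweeps))
  ll_at_mark <- NA_real_

  for (sweep in seq_len(config$n_sweeps)) {
    ord <- sample.int(n_par)
    steps <- stats::rnorm(n_par, 0, config$proposal_sd)
    us <- stats::runif(n_par)
    gates <- stats::runif(n_par) < config$global_move_prob
    draws <- stats::runif(n_par)
    for (m in seq_len(n_par)) {
      k <- ord[m]
      if (types[k] == 1L) {
        old_v <- phi[idxs[k]]
        phi[idxs[k]] <- if (gates[m]) draws[m]
                        else reflect(old_v + steps[m], 0, 1)
      } else {
        old_v <- psi[idxs[k]]
        psi[idxs[k]] <- if (gates[m]) draws[m]
                        else reflect(old_v + steps[m], 0, 1)
      }
      ll_new <- eval_ll(phi, psi)
      dll <- ll_new - ll
      if (dll >= 0 || us[m] < exp(dll / temp)) {
        ll <- ll_new
      } else if (types[k] == 1L) phi[idxs[k]] <- old_v else psi[idxs[k]] <- old_v
      if (ll > best_ll) { best_ll <- ll; best <- list(phi = phi, psi = psi) }
    }
    trace[sweep, ] <- c(sweep, temp, ll)
    if (sweep == mark_sweep) ll_at_mark <- best_ll
    temp <- temp * config$cooling_factor
  }
  converged <- is.finite(ll_at_mark) && (best_ll - ll_at_mark) < 1e-6
  list(params = cascade_params(best$phi, best$psi), logL = best_ll,
       trace = as.data.frame(trace), converged = converged)
}

## deterministic coordinate refinement: cyclic 1-D Brent maximization of
## each niche parameter with the others held fixed, until a pass yields no
## improvement. Quenches residual annealing noise near the optimum.
polish_bpnm <- function(net, params, passes = 4, fix_g = NULL,
                        fix_p_max = NULL) {
  ll_of <- function(p) log_likelihood(net, probability_matrix(p))
  cur <- ll_of(params)
  for (pass in seq_len(passes)) {
    before <- cur
    for (j in seq_along(params$n)) {
      o <- stats::optimize(function(v) {
        p <- params; p$n[j] <- v; ll_of(p)
      }, c(0, 1), maximum = TRUE, tol = 1e-6)
      if (o$objective > cur) { params$n[j] <- o$maximum; cur <- o$objective }
    }
    for (i in seq_along(params$c)) {
      o <- stats::optimize(function(v) {
        p <- params; p$c[i] <- v; ll_of(p)
      }, c(0, 1), maximum = TRUE, tol = 1e-6)
      if (o$objective > cur) { params$c[i] <- o$maximum; cur <- o$objective }
      o <- stats::optimize(function(v) {
        p <- params; p$r[i] <- v; ll_of(p)
      }, c(1e-4, .bpnm_bounds$r_cap), maximum = TRUE, tol = 1e-6)
      if (o$objective > cur) { params$r[i] <- o$maximum; cur <- o$objective }
    }
    if (is.null(fix_g)) {
      o <- stats::optimize(function(v) {
        p <- params; p$g <- v; ll_of(p)
      }, c(.bpnm_bounds$g_min, .bpnm_bounds$g_cap), maximum = TRUE, tol = 1e-6)
      if (o$objective > cur) { params$g <- o$maximum; cur <- o$objective }
    }
    if (is.null(fix_p_max)) {
      o <- stats::optimize(function(v) {
        p <- params; p$p_max <- v; ll_of(p)
      }, c(1e-6, 1), maximum = TRUE, tol = 1e-6)
      if (o$objective > cur) { params$p_max <- o$maximum; cur <- o$objective }
    }
    if (cur - before < 1e-8) break
  }
  params
}

params_to_matrix <- function(params, net) {
  switch(model_kind_of(params),
         bpnm = probability_matrix(params),
         cascade = probability_matrix(params, L_observed = n_links(net)),
         random = probability_matrix(params, S_C = n_consumers(net),
                                     S_R = n_resources(net)))
}

#' Fit a link model to a network by maximum likelihood
#'
#' The random model has a closed-form maximum-likelihood estimate,
#' `p = L / (S_C * S_R)`, and bypasses the annealer. BPNM and cascade
#' parameters are estimated by simulated annealing with Metropolis
#' acceptance, best-of-`n_restarts`; all randomness flows from
#' `config$seed`, so results are reproducible.
#'
#' @param net a `bipartite_network` with at least one link.
#' @param model_kind `"bpnm"`, `"cascade"` or `"random"`.
#' @param config an [anneal_config()].
#' @param fix_g,fix_p_max optionally hold the BPNM's global shape exponent
#'   and/or peak probability at a fixed value instead of estimating them
#'   (e.g. `fix_g = 2` for a strictly Gaussian niche). Each fixed global
#'   parameter reduces the parameter count `k` by one. On small networks
#'   a free `g` tends to run to its upper bound, turning niches into
#'   near-rectangular windows that can cover the observed links in many
#'   geometrically inconsistent ways; fixing `g` is the standard guard when
#'   fitted niche parameters are to be interpreted.
#' @param polish logical; after annealing, refine the best BPNM solution by
#'   deterministic cyclic one-dimensional maximization of every parameter
#'   (Brent's method) until no pass improves the likelihood. Removes
#'   residual stochastic-search noise near the optimum.
#' @return a `bpnm_fit` object: list with `model_kind`, `params`, `logL`,
#'   `k` (parameter count), `aicc`, `trace` (per-sweep data frame of the
#'   best restart), `restart_logL`, `seed`, `converged`.
#' @export
fit_model <- function(net, model_kind = c("bpnm", "cascade", "random"),
                      config = anneal_config(), fix_g = NULL, fix_p_max = NULL,
                      polish = FALSE) {
  model_kind <- match.arg(model_kind)
  validate_network(net)
  S_C <- n_consumers(net); S_R <- n_resources(net); L <- n_links(net)
  k <- parameter_count(model_kind, S_C, S_R)
  if (model_kind == "bpnm") {
    k <- k - (!is.null(fix_g)) - (!is.null(fix_p_max))
  }

  if (model_kind == "random") {
    params <- random_params(clamp_prob(L / (S_C * S_R)))
    P <- probability_matrix(params, S_C = S_C, S_R = S_R)
    ll <- log_likelihood(net, P)
    res <- list(params = params, logL = ll,
                trace = data.frame(sweep = integer(), temperature = numeric(),
                                   logL = numeric()),
                converged = TRUE)
    restart_ll <- ll
  } else {
    a <- net$adjacency
    t0 <- config$initial_temperature
    if (identical(t0, "auto")) {
      set.seed(sub_seed(config$seed, 0))
      t0 <- auto_temperature(net, model_kind)
    }
    runs <- lapply(seq_len(config$n_restarts), function(rs) {
      set.seed(sub_seed(config$seed, rs))
      if (model_kind == "bpnm") {
        # first two restarts start from the correspondence-analysis axis
        # (both orientations); the rest start from random geometry
        init <- if (rs == 1) "ca" else if (rs == 2) "ca_reflected" else "random"
        anneal_bpnm(a, config, t0, fix_g, fix_p_max, init = init)
      } else anneal_cascade(a, config, t0)
    })
    restart_ll <- vapply(runs, `[[`, numeric(1), "logL")
    res <- runs[[which.max(restart_ll)]]
    if (polish && model_kind == "bpnm") {
      res$params <- polish_bpnm(net, res$params, fix_g = fix_g,
                                fix_p_max = fix_p_max)
    }
    # recompute from the returned parameters so logL is exact bookkeeping
    res$logL <- log_likelihood(net, params_to_matrix(res$params, net))
  }
  structure(list(model_kind = model_kind,
                 params = res$params,
                 logL = res$logL,
                 k = k,
                 aicc = suppressWarnings(aicc(res$logL, k, S_C * S_R)),
                 aicc_defined = S_C * S_R > k + 1,
                 trace = res$trace,
                 restart_logL = restart_ll,
                 seed = config$seed,
                 converged = res$converged),
            class = "bpnm_fit")
}

#' @export
print.bpnm_fit <- function(x, ...) {
  cat(sprintf("%s fit: logL = %.4f, k = %d, AICc = %s (%d restart%s, seed %d)\n",
              x$model_kind, x$logL, x$k,
              if (is.na(x$aicc)) "undefined" else sprintf("%.4f", x$aicc),
              length(x$restart_logL),
              if (length(x$restart_logL) == 1) "" else "s", x$seed))
  invisible(x)
}

#' Fit several models and rank them by AICc
#'
#' Fits each requested model kind (each with its own sub-seed derived from
#' `config$seed`) and returns a table sorted by ascending AICc, including the
#' ratio `AICc(bpnm) / AICc(model)` used to display relative performance.
#' A model whose fit fails is reported with `NA` values rather than aborting
#' the comparison.
#'
#' @param net a `bipartite_network`.
#' @param kinds character vector of at least two model kinds.
#' @param config an [anneal_config()].
#' @param ... passed on to [fit_model()] (e.g. `polish = TRUE`).
#' @return a data frame with columns `model_kind`, `logL`, `k`, `aicc`,
#'   `aicc_ratio_vs_bpnm`, sorted by `aicc`; fitted objects in
#'   `attr(, "fits")`.
#' @export
compare_models <- function(net, kinds = c("bpnm", "cascade", "random"),
                           config = anneal_config(), ...) {
  kinds <- match.arg(kinds, c("bpnm", "cascade", "random"), several.ok = TRUE)
  if (length(kinds) < 2) stop("need at least two model kinds", call. = FALSE)
  kind_counter <- c(bpnm = 101L, cascade = 102L, random = 103L)
  fits <- lapply(kinds, function(kind) {
    cfg <- config
    cfg$seed <- sub_seed(config$seed, kind_counter[[kind]])
    tryCatch(fit_model(net, kind, cfg, ...), error = function(e) {
      warning(sprintf("fit of %s model failed: %s", kind, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  })
  names(fits) <- kinds
  ok <- !vapply(fits, is.null, logical(1))
  tab <- data.frame(
    model_kind = kinds[ok],
    logL = vapply(fits[ok], `[[`, numeric(1), "logL"),
    k = vapply(fits[ok], function(f) as.numeric(f$k), numeric(1)),
    aicc = vapply(fits[ok], `[[`, numeric(1), "aicc"),
    row.names = NULL
  )
  bpnm_aicc <- if ("bpnm" %in% tab$model_kind) {
    tab$aicc[tab$model_kind == "bpnm"]
  } else NA_real_
  tab$aicc_ratio_vs_bpnm <- bpnm_aicc / tab$aicc
  tab <- tab[order(tab$aicc), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Likelihood sensitivity profile around a fitted parameter
#'
#' Perturbs one fitted parameter across a symmetric grid of offsets while
#' holding all other parameters at their maximum-likelihood values, and
#' records the log-likelihood at each offset. Offsets that would push the
#' parameter outside its legal domain (positions and centers in \[0, 1\],
#' widths positive) are dropped, so profiles near a boundary are asymmetric.
#'
#' @param net the fitted `bipartite_network`.
#' @param fit a `bpnm_fit` with `model_kind = "bpnm"`.
#' @param species_side `"consumer"` (parameters `c`, `r`) or `"resource"`
#'   (parameter `n`).
#' @param species_index index of the species on that side.
#' @param param_name `"n"`, `"c"` or `"r"`.
#' @param half_range maximum |offset| explored (default 0.3).
#' @param step grid spacing.
#' @return data frame with columns `offset`, `value`, `logL`; the row at
#'   offset 0 equals the fit's log-likelihood.
#' @export
sensitivity_profile <- function(net, fit, species_side = c("consumer", "resource"),
                                species_index, param_name = c("c", "r", "n"),
                                half_range = 0.3, step = 0.01) {
  species_side <- match.arg(species_side)
  param_name <- match.arg(param_name)
  stopifnot(inherits(fit, "bpnm_fit"), fit$model_kind == "bpnm")
  params <- fit$params
  if (species_side == "consumer") {
    if (!param_name %in% c("c", "r")) {
      stop("consumer parameters are 'c' and 'r'", call. = FALSE)
    }
    if (species_index < 1 || species_index > length(params$c)) {
      stop("invalid consumer index", call. = FALSE)
    }
  } else {
    if (param_name != "n") stop("resource parameter is 'n'", call. = FALSE)
    if (species_index < 1 || species_index > length(params$n)) {
      stop("invalid resource index", call. = FALSE)
    }
  }
  base <- params[[param_name]][species_index]
  offsets <- seq(-half_range, half_range, by = step)
  # snap the grid so that offset 0 is always present
  if (!any(abs(offsets) < 1e-12)) offsets <- sort(c(offsets, 0))
  values <- base + offsets
  keep <- if (param_name == "r") {
    values > 0 & values <= .bpnm_bounds$r_cap
  } else {
    values >= 0 & values <= 1
  }
  offsets <- offsets[keep]; values <- values[keep]
  lls <- vapply(values, function(v) {
    p2 <- params
    p2[[param_name]][species_index] <- v
    log_likelihood(net, probability_matrix(p2))
  }, numeric(1))
  data.frame(offset = offsets, value = values, logL = lls)
}
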