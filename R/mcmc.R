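## ---- single-block Gibbs updates -------------------------------------------
## All four binary blocks live in one compiled sweep (fixed scan order
## R, Z, W, Lambda); the wrappers below expose each block's full conditional
## in isolation so the enumeration-oracle tests can exercise them directly.

sweep_state <- function(data, state, params, do_R, do_Z, do_W, do_L) {
  stopifnot(inherits(data, "baysub_data"), inherits(state, "baysub_state"),
            inherits(params, "baysub_params"))
  res <- gibbs_sweep_cpp(data$X, data$Y, state$R, state$Z, state$W,
                         state$labels - 1L,
                         params$gamma, params$delta, params$beta, params$p,
                         params$mu0, params$mu1, params$sigma0, params$sigma1,
                         params$alpha0, params$alpha1, params$eta0, params$eta1,
                         do_R, do_Z, do_W, do_L, FALSE)
  s <- nrow(state$W)
  lab <- res$labels + 1L
  Lambda <- matrix(0L, nrow(state$Z), s)
  Lambda[cbind(seq_along(lab), lab)] <- 1L
  latent_state(res$R, res$Z, res$W, Lambda)
}

#' Gibbs updates of the binary latent blocks
#'
#' Each function resamples one latent block from its full conditional given
#' everything else, using the current R random-number stream:
#' * `gibbs_update_R()`: each reference status `r_j` from the two-point
#'   conditional combining the `Bernoulli(gamma)` prior with the
#'   retain/flip channel evidence from column j of `Z`.
#' * `gibbs_update_Z()`: each `z_ij` from the two-point conditional
#'   combining the channel term versus `r_j`, the normal-tissue Gaussian
#'   term for `x_ij`, and the tumor Gaussian term for `y_ij` through
#'   `phi_ij = z_ij XOR w_k(i),j`.
#' * `gibbs_update_W()`: each path bit `w_kj` from the two-point
#'   conditional combining the `Bernoulli(beta)` prior with the tumor
#'   Gaussian terms of subtype k's members (an empty subtype reduces to
#'   the prior).
#' * `gibbs_update_Lambda()`: each membership categorically with
#'   probability proportional to `p_k` times the tumor likelihood of the
#'   sample under path k.
#' * `gibbs_sweep()`: all four blocks in the fixed scan order R, Z, W,
#'   Lambda.
#'
#' All conditionals are computed in log space.
#'
#' @param data A [paired_methylation()] object.
#' @param state A [latent_state()] object.
#' @param params A [model_parameters()] object.
#' @return An updated [latent_state()].
#' @name gibbs_updates
NULL

#' @rdname gibbs_updates
#' @export
gibbs_update_R <- function(data, state, params)
  sweep_state(data, state, params, TRUE, FALSE, FALSE, FALSE)

#' @rdname gibbs_updates
#' @export
gibbs_update_Z <- function(data, state, params)
  sweep_state(data, state, params, FALSE, TRUE, FALSE, FALSE)

#' @rdname gibbs_updates
#' @export
gibbs_update_W <- function(data, state, params)
  sweep_state(data, state, params, FALSE, FALSE, TRUE, FALSE)

#' @rdname gibbs_updates
#' @export
gibbs_update_Lambda <- function(data, state, params)
  sweep_state(data, state, params, FALSE, FALSE, FALSE, TRUE)

#' @rdname gibbs_updates
#' @export
gibbs_sweep <- function(data, state, params)
  sweep_state(data, state, params, TRUE, TRUE, TRUE, TRUE)

## ---- continuous-parameter conditionals ------------------------------------

## Beta(a, b) truncated to (lo, hi) by inverse-CDF; degenerate truncation
## collapses to the nearest interior boundary
rtrunc_beta <- function(a, b, lo, hi) {
  plo <- pbeta(lo, a, b); phi <- pbeta(hi, a, b)
  if (!is.finite(plo) || !is.finite(phi) || phi - plo < 1e-14) {
    mid <- a / (a + b)
    return(min(max(mid, lo + 1e-9), hi - 1e-9))
  }
  q <- qbeta(runif(1L, plo, phi), a, b)
  min(max(q, lo + 1e-12), hi - 1e-12)
}

rtrunc_norm <- function(mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  if (!is.finite(plo) || !is.finite(phi) || phi - plo < 1e-14)
    return(min(max(mean, lo + sd * 1e-6), hi - sd * 1e-6))
  qnorm(runif(1L, plo, phi), mean, sd)
}

## flat prior on the SD scale: density proportional to
## sigma^-c * exp(-SS / (2 sigma^2)), i.e. sigma^2 ~ InvGamma((c-1)/2, SS/2)
draw_sd <- function(c, SS, fallback) {
  if (c < 2L || SS <= 0) return(fallback)
  sqrt((SS / 2) / rgamma(1L, shape = (c - 1) / 2))
}

#' Gibbs update of the continuous parameters
#'
#' Draws every continuous parameter from its full conditional under flat
#' (truncated-flat) priors: `gamma`, `delta` and `beta` from Beta
#' conditionals (latent counts + 1), with `delta` truncated to `(0.5, 1]`
#' and `beta` to `[0, 0.5)` by inverse-CDF sampling; `p` from the
#' Dirichlet conditional (membership counts + 1); the emission means from
#' Gaussian conditionals given the current assignments, truncated to the
#' orderings `mu0 < mu1` and `alpha0 < alpha1`; and the emission standard
#' deviations from the flat-prior conditional on the SD scale via a
#' root-inverse-gamma draw. A component with no currently assigned
#' observations (or fewer than two, for an SD) retains its previous value.
#'
#' @inheritParams gibbs_updates
#' @return An updated [model_parameters()] object.
#' @export
update_continuous <- function(data, state, params) {
  stopifnot(inherits(data, "baysub_data"), inherits(state, "baysub_state"),
            inherits(params, "baysub_params"))
  n <- nrow(data$X); m <- ncol(data$X); s <- nrow(state$W)
  z1 <- state$Z == 1L
  f1 <- compose_phi(state$Z, state$W, state$Lambda) == 1L
  x0 <- data$X[!z1]; x1 <- data$X[z1]
  y0 <- data$Y[!f1]; y1 <- data$Y[f1]
  stats <- list(
    n = n, m = m, s = s,
    sumR = sum(state$R),
    agree = sum(sweep(state$Z, 2L, state$R, "==")),
    sumW = sum(state$W),
    label_counts = tabulate(state$labels, nbins = s),
    count = c(length(x0), length(x1), length(y0), length(y1)),
    sum = c(sum(x0), sum(x1), sum(y0), sum(y1)),
    sumsq = c(sum(x0^2), sum(x1^2), sum(y0^2), sum(y1^2)))
  draw_continuous(stats, params)
}

## the conditional draws themselves, from sufficient statistics; shared by
## update_continuous() and the compiled-statistics path inside run_chain()
draw_continuous <- function(stats, params) {
  n <- stats$n; m <- stats$m; s <- stats$s
  gamma <- rtrunc_beta(stats$sumR + 1, m - stats$sumR + 1, 0, 1)
  delta <- rtrunc_beta(stats$agree + 1, n * m - stats$agree + 1, 0.5, 1)
  beta <- rtrunc_beta(stats$sumW + 1, s * m - stats$sumW + 1, 0, 0.5)
  g <- rgamma(s, shape = stats$label_counts + 1)
  p <- g / sum(g)

  draw_mean <- function(idx, sd_now, prev, lo = -Inf, hi = Inf) {
    cnt <- stats$count[idx]
    if (cnt == 0) return(prev)
    rtrunc_norm(stats$sum[idx] / cnt, sd_now / sqrt(cnt), lo, hi)
  }
  draw_scale <- function(idx, mu, prev) {
    cnt <- stats$count[idx]
    SS <- stats$sumsq[idx] - 2 * mu * stats$sum[idx] + cnt * mu^2
    draw_sd(cnt, SS, prev)
  }
  mu0 <- draw_mean(1L, params$sigma0, params$mu0, hi = params$mu1)
  mu1 <- draw_mean(2L, params$sigma1, params$mu1, lo = mu0)
  sigma0 <- draw_scale(1L, mu0, params$sigma0)
  sigma1 <- draw_scale(2L, mu1, params$sigma1)
  alpha0 <- draw_mean(3L, params$eta0, params$alpha0, hi = params$alpha1)
  alpha1 <- draw_mean(4L, params$eta1, params$alpha1, lo = alpha0)
  eta0 <- draw_scale(3L, alpha0, params$eta0)
  eta1 <- draw_scale(4L, alpha1, params$eta1)

  model_parameters(gamma = gamma, delta = delta, beta = beta, p = p,
                   mu0 = mu0, mu1 = mu1, sigma0 = sigma0, sigma1 = sigma1,
                   alpha0 = alpha0, alpha1 = alpha1, eta0 = eta0, eta1 = eta1)
}

## ---- chain execution -------------------------------------------------------

#' MCMC run configuration
#'
#' @param s Number of subtypes to fit.
#' @param n_iterations Sweeps per chain (default 200).
#' @param n_chains Number of independent chains (default 10).
#' @param seed Master seed; per-chain seeds are spawned from it.
#' @param estimate_window Number of final iterations averaged for the
#'   estimates (default 30).
#' @param rhat_window Number of final iterations used by the split
#'   Gelman-Rubin diagnostic; must be even (default 60).
#' @return An object of class `baysub_config`.
#' @export
run_config <- function(s, n_iterations = 200L, n_chains = 10L, seed = 1L,
                       estimate_window = 30L, rhat_window = 60L) {
  stopifnot(s >= 1L, n_iterations >= 1L, n_chains >= 1L)
  if (estimate_window > n_iterations)
    stop("'estimate_window' cannot exceed 'n_iterations'")
  if (rhat_window %% 2L != 0L || rhat_window > n_iterations)
    stop("'rhat_window' must be even and at most 'n_iterations'")
  structure(list(s = as.integer(s), n_iterations = as.integer(n_iterations),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 estimate_window = as.integer(estimate_window),
                 rhat_window = as.integer(rhat_window)),
            class = "baysub_config")
}

## data-driven initialization: quartiles for the means, global SDs,
## X thresholded at the component midpoint for R and Z, W empty,
## memberships uniform at random
init_chain <- function(data, s) {
  q <- quantile(data$X, c(0.25, 0.75), names = FALSE)
  mu0 <- q[1L]; mu1 <- q[2L]
  if (mu1 <= mu0) mu1 <- mu0 + 1e-3
  qy <- quantile(data$Y, c(0.25, 0.75), names = FALSE)
  alpha0 <- qy[1L]; alpha1 <- qy[2L]
  if (alpha1 <= alpha0) alpha1 <- alpha0 + 1e-3
  sx <- max(sd(data$X), 1e-3); sy <- max(sd(data$Y), 1e-3)
  params <- model_parameters(gamma = 0.5, delta = 0.95, beta = 0.1,
                             p = rep(1 / s, s),
                             mu0 = mu0, mu1 = mu1, sigma0 = sx, sigma1 = sx,
                             alpha0 = alpha0, alpha1 = alpha1,
                             eta0 = sy, eta1 = sy)
  mid <- (mu0 + mu1) / 2
  Z <- (data$X > mid) * 1L
  R <- as.integer(colMeans(Z) > 0.5)
  W <- matrix(0L, s, ncol(data$X))
  lab <- sample.int(s, nrow(data$X), replace = TRUE)
  Lambda <- matrix(0L, nrow(data$X), s)
  Lambda[cbind(seq_along(lab), lab)] <- 1L
  list(params = params, state = latent_state(R, Z, W, Lambda))
}

#' Run one MCMC chain
#'
#' Executes systematic-scan sweeps (R, Z, W, Lambda, then the continuous
#' parameters) for `n_iterations`. Estimates are taken from the final
#' `estimate_window` iterations: posterior means for the continuous
#' parameters, posterior frequency thresholded at 0.5 for `W`, and the
#' modal subtype per sample (ties broken by the final iteration) for the
#' labels.
#'
#' @param data A [paired_methylation()] object.
#' @param config A [run_config()] object.
#' @param seed Optional seed overriding `config$seed` (used by
#'   [run_multichain()] to give each chain its own stream).
#' The log-likelihood trace records, per iteration, the complete-data
#' log-likelihood of the freshly swept latents under the parameters that
#' drove the sweep.
#'
#' @return An object of class `baysub_chain` with elements `draws` (one row
#'   per iteration of the continuous parameters), `log_likelihood_trace`,
#'   `estimate_params`, `estimate_W`, `estimate_labels`, and the retained
#'   window's latent draws.
#' @export
run_chain <- function(data, config, seed = config$seed) {
  stopifnot(inherits(data, "baysub_data"), inherits(config, "baysub_config"))
  set.seed(seed)
  s <- config$s
  n <- nrow(data$X); m <- ncol(data$X)
  cur <- init_chain(data, s)
  state <- cur$state; params <- cur$params
  n_it <- config$n_iterations
  keep_from <- n_it - config$estimate_window + 1L
  cont_names <- c("gamma", "delta", "beta", "mu0", "mu1", "sigma0", "sigma1",
                  "alpha0", "alpha1", "eta0", "eta1")
  draws <- matrix(NA_real_, n_it, length(cont_names) + s,
                  dimnames = list(NULL, c(cont_names, paste0("p", seq_len(s)))))
  ll <- numeric(n_it)
  W_freq <- matrix(0, s, m)
  label_counts <- matrix(0L, n, s)
  last_labels <- NULL
  R_cur <- state$R; Z_cur <- state$Z; W_cur <- state$W
  lab0 <- state$labels - 1L
  for (it in seq_len(n_it)) {
    res <- gibbs_sweep_cpp(data$X, data$Y, R_cur, Z_cur, W_cur, lab0,
                           params$gamma, params$delta, params$beta, params$p,
                           params$mu0, params$mu1, params$sigma0,
                           params$sigma1, params$alpha0, params$alpha1,
                           params$eta0, params$eta1,
                           TRUE, TRUE, TRUE, TRUE, TRUE)
    R_cur <- res$R; Z_cur <- res$Z; W_cur <- res$W; lab0 <- res$labels
    stats <- list(n = n, m = m, s = s, sumR = res$sumR, agree = res$agree,
                  sumW = res$sumW, label_counts = res$label_counts,
                  count = res$count, sum = res$sum, sumsq = res$sumsq)
    params <- draw_continuous(stats, params)
    draws[it, ] <- c(unlist(params[cont_names]), params$p)
    ll[it] <- res$loglik
    if (it >= keep_from) {
      W_freq <- W_freq + W_cur
      lab <- lab0 + 1L
      label_counts[cbind(seq_len(n), lab)] <-
        label_counts[cbind(seq_len(n), lab)] + 1L
      last_labels <- lab
    }
  }
  Lambda <- matrix(0L, n, s); Lambda[cbind(seq_len(n), lab0 + 1L)] <- 1L
  state <- latent_state(R_cur, Z_cur, W_cur, Lambda)
  win <- keep_from:n_it
  est <- colMeans(draws[win, , drop = FALSE])
  estimate_params <- model_parameters(
    gamma = est[["gamma"]], delta = est[["delta"]], beta = est[["beta"]],
    p = est[paste0("p", seq_len(s))] / sum(est[paste0("p", seq_len(s))]),
    mu0 = est[["mu0"]], mu1 = est[["mu1"]],
    sigma0 = est[["sigma0"]], sigma1 = est[["sigma1"]],
    alpha0 = est[["alpha0"]], alpha1 = est[["alpha1"]],
    eta0 = est[["eta0"]], eta1 = est[["eta1"]])
  estimate_W <- (W_freq / length(win) >= 0.5) * 1L
  ## modal subtype over the retained window; ties go to the final sweep
  estimate_labels <- vapply(seq_len(n), function(i) {
    cnt <- label_counts[i, ]
    top <- which(cnt == max(cnt))
    if (length(top) > 1L && last_labels[i] %in% top) last_labels[i]
    else top[1L]
  }, integer(1))
  structure(list(draws = as.data.frame(draws),
                 log_likelihood_trace = ll,
                 estimate_params = estimate_params,
                 estimate_W = estimate_W,
                 estimate_labels = estimate_labels,
                 final_state = state,
                 config = config, seed = seed),
            class = "baysub_chain")
}

#' Run multiple independent chains and select the best
#'
#' Runs `config$n_chains` chains with distinct sub-seeds spawned from the
#' master seed, and reports the chain with the highest mean retained
#' log-likelihood. Latent estimates are never averaged across chains
#' (subtype labels are only identified within a chain), so the selected
#' chain's estimates are the fit.
#'
#' @inheritParams run_chain
#' @return An object of class `baysub_fit`: the selected chain's estimates
#'   plus `chains` (all [run_chain()] results), `best_index`, and the split
#'   Gelman-Rubin statistics of the selected chain's key parameters.
#' @export
run_multichain <- function(data, config) {
  stopifnot(inherits(config, "baysub_config"))
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  chains <- lapply(chain_seeds, function(sd) run_chain(data, config, seed = sd))
  win <- (config$n_iterations - config$estimate_window + 1L):config$n_iterations
  scores <- vapply(chains, function(ch) mean(ch$log_likelihood_trace[win]),
                   numeric(1))
  best <- which.max(scores)
  bc <- chains[[best]]
  rhat <- vapply(c("mu0", "mu1", "gamma"), function(v)
    gelman_rubin(bc$draws[[v]], config$rhat_window), numeric(1))
  structure(list(estimate_params = bc$estimate_params,
                 estimate_W = bc$estimate_W,
                 estimate_labels = bc$estimate_labels,
                 best_chain = bc, best_index = best,
                 chain_scores = scores, chains = chains,
                 rhat = rhat, config = config),
            class = "baysub_fit")
}

#' @export
print.baysub_fit <- function(x, ...) {
  cat(sprintf("Paired-methylation subtype fit: s = %d, %d chains (best: #%d)\n",
              x$config$s, x$config$n_chains, x$best_index))
  cat("  subtype sizes:", paste(tabulate(x$estimate_labels, x$config$s),
                                collapse = " "), "\n")
  cat("  R-hat (mu0, mu1, gamma):",
      paste(signif(x$rhat, 4), collapse = " "), "\n")
  print(x$estimate_params)
  invisible(x)
}

#' Split Gelman-Rubin statistic of a single trace
#'
#' Splits the final `window` values of the trace into two halves of length
#' `w = window / 2`, and returns
#' `sqrt(((w - 1) / w * Wv + Bv / w) / Wv)` where `Wv` is the mean of the
#' two within-half variances and `Bv = w * var(half means)`. Values near 1
#' indicate the two halves agree in mean and spread.
#'
#' @param trace Numeric vector of per-iteration values.
#' @param window Even number of final iterations to use.
#' @return The split R-hat, or `NaN` when the within-half variance is zero
#'   (constant halves; documented degenerate case).
#' @export
gelman_rubin <- function(trace, window = 60L) {
  stopifnot(is.numeric(trace), window %% 2L == 0L, window >= 4L)
  if (window > length(trace)) stop("'window' exceeds the trace length")
  x <- trace[(length(trace) - window + 1L):length(trace)]
  w <- window %/% 2L
  h1 <- x[seq_len(w)]; h2 <- x[(w + 1L):window]
  Wv <- (var(h1) + var(h2)) / 2
  if (Wv == 0) return(NaN)
  Bv <- w * var(c(mean(h1), mean(h2)))
  sqrt(((w - 1) / w * Wv + Bv / w) / Wv)
}
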