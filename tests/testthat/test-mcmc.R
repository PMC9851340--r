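## Frequencies of a two-point conditional over repeated single-block
## updates are compared against exact enumeration of that conditional
## (the block conditionals do not depend on the block's current value, so
## repeated updates from a fixed state draw i.i.d. from the conditional).

test_that("reference-bit conditional matches enumeration and the prior-only limit", {
  pp <- model_parameters(gamma = 0.3, delta = 0.8, beta = 0.1, p = 1,
                         mu0 = -2, mu1 = 2, sigma0 = 1, sigma1 = 1,
                         alpha0 = -2, alpha1 = 2, eta0 = 1, eta1 = 1)
  inst <- tiny_instance(2, 1, 1, pp = pp, seed = 301)
  ## exact conditional from the naive joint
  p_exact <- cond_prob_bit(inst$data$X, inst$data$Y, inst$R, inst$Z, inst$W,
                           inst$lab, pp, "R", j = 1)
  set.seed(1)
  nrep <- 4000
  f <- freq_of(gibbs_update_R, function(st) st$R[1],
               inst$data, inst$state, pp, nrep)
  expect_lt(abs(f - p_exact), 4 * mc_se(p_exact, nrep))
  ## delta = 0.5 + eps makes Z uninformative: conditional collapses to gamma
  pp2 <- model_parameters(gamma = 0.3, delta = 0.5 + 1e-12, beta = 0.1, p = 1,
                          mu0 = -2, mu1 = 2, alpha0 = -2, alpha1 = 2)
  p_prior <- cond_prob_bit(inst$data$X, inst$data$Y, inst$R, inst$Z, inst$W,
                           inst$lab, pp2, "R", j = 1)
  expect_equal(p_prior, 0.3, tolerance = 1e-9)
  set.seed(2)
  f2 <- freq_of(gibbs_update_R, function(st) st$R[1],
                inst$data, inst$state, pp2, nrep)
  expect_lt(abs(f2 - 0.3), 4 * mc_se(0.3, nrep))
})

test_that("reference-bit conditional reproduces the two-term closed form", {
  ## z = (1, 1), gamma = 0.5, delta = 0.99:
  ## P(r = 1 | z) = 0.99^2 / (0.99^2 + 0.01^2)
  pp <- model_parameters(gamma = 0.5, delta = 0.99, beta = 0.1, p = 1)
  Z <- matrix(c(1L, 1L), 2, 1)
  X <- matrix(0, 2, 1); Y <- matrix(0, 2, 1)
  p_exact <- cond_prob_bit(X, Y, 0L, Z, matrix(0L, 1, 1), c(1L, 1L), pp,
                           "R", j = 1)
  expect_equal(p_exact, 0.99^2 / (0.99^2 + 0.01^2), tolerance = 1e-12)
})

test_that("normal-profile conditional matches enumeration; balanced case is 1/2", {
  pp <- model_parameters(gamma = 0.4, delta = 0.85, beta = 0.2, p = 1,
                         mu0 = -1, mu1 = 1, sigma0 = 1.2, sigma1 = 0.8,
                         alpha0 = -1.5, alpha1 = 1.5, eta0 = 1, eta1 = 1.3)
  inst <- tiny_instance(1, 1, 1, pp = pp, seed = 303)
  p_exact <- cond_prob_bit(inst$data$X, inst$data$Y, inst$R, inst$Z, inst$W,
                           inst$lab, pp, "Z", i = 1, j = 1)
  set.seed(3)
  nrep <- 4000
  f <- freq_of(gibbs_update_Z, function(st) st$Z[1, 1],
               inst$data, inst$state, pp, nrep)
  expect_lt(abs(f - p_exact), 4 * mc_se(p_exact, nrep))
  ## delta -> 1/2 with symmetric emissions puts no information on z
  ppb <- model_parameters(gamma = 0.5, delta = 0.5 + 1e-12, beta = 0, p = 1,
                          mu0 = -1, mu1 = 1, sigma0 = 1, sigma1 = 1,
                          alpha0 = -1, alpha1 = 1, eta0 = 1, eta1 = 1)
  db <- paired_methylation(matrix(0), matrix(0))  # equidistant from both means
  stb <- latent_state(1L, matrix(0L), matrix(0L), matrix(1L))
  expect_equal(cond_prob_bit(db$X, db$Y, 1L, matrix(0L), matrix(0L), 1L,
                             ppb, "Z", i = 1, j = 1), 0.5, tolerance = 1e-9)
  set.seed(4)
  fb <- freq_of(gibbs_update_Z, function(st) st$Z[1, 1], db, stb, ppb, nrep)
  expect_lt(abs(fb - 0.5), 4 * mc_se(0.5, nrep))
})

test_that("path-bit conditional: member evidence and empty-subtype prior", {
  pp <- model_parameters(gamma = 0.5, delta = 0.9, beta = 0.25,
                         p = c(0.5, 0.5),
                         mu0 = -2, mu1 = 2, sigma0 = 1, sigma1 = 1,
                         alpha0 = -2, alpha1 = 2, eta0 = 1.1, eta1 = 0.9)
  inst <- tiny_instance(1, 1, 2, pp = pp, seed = 305)
  inst$lab <- 1L                       # subtype 2 has no members
  Lambda <- matrix(c(1L, 0L), 1, 2)
  st <- latent_state(inst$R, inst$Z, inst$W, Lambda)
  p_member <- cond_prob_bit(inst$data$X, inst$data$Y, inst$R, inst$Z, inst$W,
                            1L, pp, "W", k = 1, j = 1)
  set.seed(5)
  nrep <- 4000
  f1 <- freq_of(gibbs_update_W, function(s2) s2$W[1, 1],
                inst$data, st, pp, nrep)
  expect_lt(abs(f1 - p_member), 4 * mc_se(p_member, nrep))
  ## empty subtype: conditional reduces to Bernoulli(beta)
  f2 <- freq_of(gibbs_update_W, function(s2) s2$W[2, 1],
                inst$data, st, pp, nrep)
  expect_lt(abs(f2 - pp$beta), 4 * mc_se(pp$beta, nrep))
})

test_that("membership conditional: degenerate cases and 2-subtype enumeration", {
  ## s = 1: always subtype 1
  pp1 <- model_parameters(p = 1)
  inst1 <- tiny_instance(3, 2, 1, pp = pp1, seed = 307)
  st <- gibbs_update_Lambda(inst1$data, inst1$state, pp1)
  expect_true(all(st$labels == 1L))
  ## identical W rows: posterior proportional to p
  pp <- model_parameters(gamma = 0.5, delta = 0.9, beta = 0.2,
                         p = c(0.7, 0.3))
  inst <- tiny_instance(1, 2, 2, pp = pp, seed = 309)
  inst$W[2, ] <- inst$W[1, ]
  stW <- latent_state(inst$R, inst$Z, inst$W, inst$state$Lambda)
  set.seed(6)
  nrep <- 4000
  f <- freq_of(gibbs_update_Lambda, function(s2) as.integer(s2$labels[1] == 1),
               inst$data, stW, pp, nrep)
  expect_lt(abs(f - 0.7), 4 * mc_se(0.7, nrep))
  ## m = 2 instance against the enumerated categorical conditional
  inst2 <- tiny_instance(2, 2, 2, seed = 311)
  p_exact <- cond_prob_label(inst2$data$X, inst2$data$Y, inst2$R, inst2$Z,
                             inst2$W, inst2$lab, inst2$params, i = 1)
  set.seed(7)
  f2 <- freq_of(gibbs_update_Lambda,
                function(s2) as.integer(s2$labels[1] == 1),
                inst2$data, inst2$state, inst2$params, nrep)
  expect_lt(abs(f2 - p_exact[1]), 4 * mc_se(p_exact[1], nrep))
})

test_that("continuous conditionals are conjugate with flat priors", {
  ## gamma: sum(R) = 20 of m = 40 -> Beta(21, 21), mean 1/2
  set.seed(8)
  m <- 40; n <- 4
  R <- rep(c(0L, 1L), each = 20)
  Z <- matrix(rep(R, each = n), n, m)
  W <- matrix(0L, 1, m)
  Lambda <- matrix(1L, n, 1)
  pp <- model_parameters(p = 1)
  X <- matrix(rnorm(n * m, ifelse(Z == 1, pp$mu1, pp$mu0), 0.5), n, m)
  Y <- matrix(rnorm(n * m, ifelse(Z == 1, pp$alpha1, pp$alpha0), 0.5), n, m)
  d <- paired_methylation(X, Y)
  st <- latent_state(R, Z, W, Lambda)
  draws <- replicate(3000, update_continuous(d, st, pp)$gamma)
  bmean <- 21 / 42; bsd <- sqrt(21 * 21 / (42^2 * 43))
  expect_lt(abs(mean(draws) - bmean), 4 * bsd / sqrt(3000))
  expect_lt(abs(sd(draws) - bsd), 0.2 * bsd)
  ## mu0 conditional is centered at the mean of component-0 x values
  draws_mu0 <- replicate(2000, update_continuous(d, st, pp)$mu0)
  xbar0 <- mean(X[Z == 0L])
  n0 <- sum(Z == 0L)
  expect_lt(abs(mean(draws_mu0) - xbar0),
            4 * pp$sigma0 / sqrt(n0) / sqrt(2000) + 1e-3)
  ## truncations always respected
  many <- replicate(500, {
    u <- update_continuous(d, st, pp)
    c(u$delta, u$beta, u$mu1 - u$mu0, u$alpha1 - u$alpha0)
  })
  expect_true(all(many[1, ] > 0.5))
  expect_true(all(many[2, ] < 0.5))
  expect_true(all(many[3, ] > 0) && all(many[4, ] > 0))
})

test_that("long-run latent marginals match exhaustive enumeration (fixed params)", {
  ## n = 2, m = 2, s = 2: all 4096 latent configurations enumerated by the
  ## naive oracle give exact marginals; the systematic-scan sampler's
  ## long-run frequencies must agree
  inst <- tiny_instance(2, 2, 2, seed = 313)
  enum <- enumerate_joint(inst$data$X, inst$data$Y, 2, inst$params)
  marg <- function(f) sum(enum$weights * vapply(enum$configs, f, numeric(1)))
  exact <- c(R1 = marg(function(cf) cf$R[1]),
             Z11 = marg(function(cf) cf$Z[1, 1]),
             W12 = marg(function(cf) cf$W[1, 2]),
             L1 = marg(function(cf) as.integer(cf$lab[1] == 1)))
  set.seed(9)
  nrep <- 12000
  st <- inst$state
  acc <- c(R1 = 0, Z11 = 0, W12 = 0, L1 = 0)
  for (t in seq_len(nrep)) {
    st <- gibbs_sweep(inst$data, st, inst$params)
    acc <- acc + c(st$R[1], st$Z[1, 1], st$W[1, 2],
                   as.integer(st$labels[1] == 1))
  }
  freq <- acc / nrep
  ## allow for autocorrelation with a conservative effective sample size
  for (nm in names(exact))
    expect_lt(abs(freq[[nm]] - exact[[nm]]),
              4 * mc_se(exact[[nm]], nrep / 10) + 0.005)
})

test_that("joint sampler recovers the analytic posterior mean of gamma", {
  ## tiny instance, all parameters but gamma held at truth; the exact
  ## posterior mean of gamma marginalizes the latents by enumeration and
  ## gamma analytically (flat prior => E[gamma | R] = (sumR+1)/(m+2))
  inst <- tiny_instance(2, 2, 2, seed = 315)
  pp <- inst$params
  enum_ll <- c(); enum_mean <- c()
  bits <- function(len) as.matrix(expand.grid(rep(list(0:1), len)))
  Rs <- bits(2); Zs <- bits(4); Ws <- bits(4)
  labs <- as.matrix(expand.grid(1:2, 1:2))
  idx <- 1L
  for (a in seq_len(nrow(Rs))) for (b in seq_len(nrow(Zs)))
    for (cc in seq_len(nrow(Ws))) for (dd in seq_len(nrow(labs))) {
      R <- Rs[a, ]; Z <- matrix(Zs[b, ], 2, 2); W <- matrix(Ws[cc, ], 2, 2)
      lab <- labs[dd, ]
      ll <- naive_joint(inst$data$X, inst$data$Y, R, Z, W, lab, pp)
      ## remove the gamma factor, replace with its flat-prior integral
      lgam <- sum(log(ifelse(R == 1, pp$gamma, 1 - pp$gamma)))
      ll <- ll - lgam + lbeta(sum(R) + 1, 2 - sum(R) + 1)
      enum_ll[idx] <- ll
      enum_mean[idx] <- (sum(R) + 1) / (2 + 2)
      idx <- idx + 1L
    }
  wts <- exp(enum_ll - max(enum_ll)); wts <- wts / sum(wts)
  exact_mean <- sum(wts * enum_mean)
  set.seed(10)
  nrep <- 8000
  st <- inst$state
  gam <- pp$gamma
  tot <- 0
  for (t in seq_len(nrep)) {
    pcur <- model_parameters(gamma = gam, delta = pp$delta, beta = pp$beta,
                             p = pp$p, mu0 = pp$mu0, mu1 = pp$mu1,
                             sigma0 = pp$sigma0, sigma1 = pp$sigma1,
                             alpha0 = pp$alpha0, alpha1 = pp$alpha1,
                             eta0 = pp$eta0, eta1 = pp$eta1)
    st <- gibbs_sweep(inst$data, st, pcur)
    gam <- rbeta(1, sum(st$R) + 1, 2 - sum(st$R) + 1)
    tot <- tot + gam
  }
  expect_lt(abs(tot / nrep - exact_mean), 0.02)
})

test_that("split Gelman-Rubin statistic behaves at its anchors", {
  expect_true(is.nan(gelman_rubin(rep(1, 60), 60)))
  expect_true(is.nan(gelman_rubin(c(rep(0, 30), rep(1, 30)), 60)))
  ## same-distribution halves sit near 1
  set.seed(11)
  vals <- replicate(50, gelman_rubin(rnorm(60), 60))
  expect_lt(median(vals), 1.1)
  expect_lt(mean(vals > 1.2), 0.2)
  ## hand-computed small case
  tr <- c(1, 2, 3, 4, 10, 11, 12, 13)
  w <- 4
  Wv <- (var(tr[1:4]) + var(tr[5:8])) / 2
  Bv <- w * var(c(mean(tr[1:4]), mean(tr[5:8])))
  expect_equal(gelman_rubin(tr, 8), sqrt(((w - 1) / w * Wv + Bv / w) / Wv),
               tolerance = 1e-12)
  expect_error(gelman_rubin(rnorm(10), 12), "exceeds")
  expect_error(run_config(s = 2, rhat_window = 55, n_iterations = 100),
               "even")
})

test_that("a single chain fits a small instance and reports full traces", {
  sim <- simulate_pure(30, 500, 2, seed = 401)
  cfg <- run_config(s = 2, n_iterations = 80, n_chains = 1, seed = 402,
                    estimate_window = 20, rhat_window = 40)
  ch <- run_chain(sim$data, cfg)
  expect_length(ch$log_likelihood_trace, 80)
  expect_equal(nrow(ch$draws), 80)
  expect_true(all(ch$estimate_W %in% c(0L, 1L)))
  expect_length(ch$estimate_labels, 30)
  ## the trace rises from its dispersed start and stabilizes
  expect_gt(mean(ch$log_likelihood_trace[61:80]),
            mean(ch$log_likelihood_trace[1:3]))
  sd_late <- sd(ch$log_likelihood_trace[61:80])
  rng_early <- diff(range(ch$log_likelihood_trace[1:10]))
  expect_lt(sd_late, rng_early)
  ## perfect clustering on this easy instance
  expect_equal(adjusted_rand_index(ch$estimate_labels, sim$true_labels), 1)
})

test_that("multichain selection picks the highest mean retained log-likelihood", {
  sim <- simulate_pure(20, 300, 2, seed = 405)
  cfg <- run_config(s = 2, n_iterations = 60, n_chains = 3, seed = 406,
                    estimate_window = 15, rhat_window = 30)
  fit <- run_multichain(sim$data, cfg)
  win <- 46:60
  scores <- vapply(fit$chains, function(ch)
    mean(ch$log_likelihood_trace[win]), numeric(1))
  expect_equal(fit$best_index, which.max(scores))
  expect_equal(fit$chain_scores, scores)
  expect_identical(fit$estimate_labels,
                   fit$chains[[fit$best_index]]$estimate_labels)
  ## distinct chain seeds give distinct draws
  expect_false(identical(fit$chains[[1]]$draws$gamma,
                         fit$chains[[2]]$draws$gamma))
})

test_that("relabeling the truth leaves ARI, NMI, AE and AS unchanged", {
  sim <- simulate_pure(20, 300, 2, seed = 407)
  cfg <- run_config(s = 2, n_iterations = 60, n_chains = 1, seed = 408,
                    estimate_window = 15, rhat_window = 30)
  fit <- run_multichain(sim$data, cfg)
  ev1 <- evaluate_fit(fit, sim$true_labels, sim$state$W)
  perm <- c(2L, 1L)
  ev2 <- evaluate_fit(fit, perm[sim$true_labels],
                      sim$state$W[order(perm), , drop = FALSE])
  expect_equal(ev1$ari, ev2$ari)
  expect_equal(ev1$nmi, ev2$nmi)
  expect_equal(ev1$ae, ev2$ae)
  expect_equal(ev1$as, ev2$as)
})
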