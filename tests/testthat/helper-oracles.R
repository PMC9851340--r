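## Independent oracles used across the suite.  Everything here is written
## naively (scalar loops, direct probability products) on purpose: these
## functions must not share code paths with the package implementation
## they check.

## Table of generating values used throughout the simulation experiments
true_params <- function(s = 2) {
  model_parameters(gamma = 0.5, delta = 0.99, beta = 0.2, p = rep(1 / s, s),
                   mu0 = -2.6, mu1 = 1.5, sigma0 = 1.3, sigma1 = 1.4,
                   alpha0 = -2.9, alpha1 = 1.1, eta0 = 1.1, eta1 = 1.7)
}

## joint log density by scalar loops: log P(X, Y, R, Z, W, lab | params)
naive_joint <- function(X, Y, R, Z, W, lab, pp) {
  n <- nrow(X); m <- ncol(X); s <- nrow(W)
  lp <- function(v) log(max(v, 1e-300))
  ll <- 0
  for (j in seq_len(m)) ll <- ll + lp(if (R[j] == 1) pp$gamma else 1 - pp$gamma)
  for (k in seq_len(s)) for (j in seq_len(m))
    ll <- ll + lp(if (W[k, j] == 1) pp$beta else 1 - pp$beta)
  for (i in seq_len(n)) ll <- ll + lp(pp$p[lab[i]])
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ll <- ll + lp(if (Z[i, j] == R[j]) pp$delta else 1 - pp$delta)
    ll <- ll + if (Z[i, j] == 1)
      dnorm(X[i, j], pp$mu1, pp$sigma1, log = TRUE) else
      dnorm(X[i, j], pp$mu0, pp$sigma0, log = TRUE)
    phi <- xor(Z[i, j] == 1, W[lab[i], j] == 1)
    ll <- ll + if (phi)
      dnorm(Y[i, j], pp$alpha1, pp$eta1, log = TRUE) else
      dnorm(Y[i, j], pp$alpha0, pp$eta0, log = TRUE)
  }
  ll
}

## every binary latent configuration of a tiny instance:
## list of (R, Z, W, lab) with their naive joint log densities
enumerate_joint <- function(X, Y, s, pp) {
  n <- nrow(X); m <- ncol(X)
  bits <- function(len) as.matrix(expand.grid(rep(list(0:1), len)))
  Rs <- bits(m); Zs <- bits(n * m); Ws <- bits(s * m)
  labs <- as.matrix(expand.grid(rep(list(seq_len(s)), n)))
  out <- list(); ll <- c()
  idx <- 1L
  for (a in seq_len(nrow(Rs))) for (b in seq_len(nrow(Zs)))
    for (cc in seq_len(nrow(Ws))) for (d in seq_len(nrow(labs))) {
      R <- Rs[a, ]; Z <- matrix(Zs[b, ], n, m); W <- matrix(Ws[cc, ], s, m)
      lab <- labs[d, ]
      out[[idx]] <- list(R = R, Z = Z, W = W, lab = lab)
      ll[idx] <- naive_joint(X, Y, R, Z, W, lab, pp)
      idx <- idx + 1L
    }
  w <- exp(ll - max(ll)); w <- w / sum(w)
  list(configs = out, weights = w, logliks = ll)
}

## exact conditional P(target bit = 1 | everything else) via two-point
## evaluation of the naive joint
cond_prob_bit <- function(X, Y, R, Z, W, lab, pp, what, i = NULL, j = NULL,
                          k = NULL) {
  set_val <- function(v) {
    if (what == "R") R[j] <- v
    else if (what == "Z") Z[i, j] <- v
    else if (what == "W") W[k, j] <- v
    naive_joint(X, Y, R, Z, W, lab, pp)
  }
  l1 <- set_val(1L); l0 <- set_val(0L)
  1 / (1 + exp(l0 - l1))
}

## exact conditional membership distribution for sample i
cond_prob_label <- function(X, Y, R, Z, W, lab, pp, i) {
  s <- nrow(W)
  ll <- vapply(seq_len(s), function(k) {
    lab[i] <- k
    naive_joint(X, Y, R, Z, W, lab, pp)
  }, numeric(1))
  w <- exp(ll - max(ll)); w / sum(w)
}

## tiny paired dataset with known latents, drawn outside the package
tiny_instance <- function(n, m, s, pp = true_params(s), seed = 42) {
  set.seed(seed)
  R <- rbinom(m, 1, pp$gamma)
  Z <- matrix(rbinom(n * m, 1, 0.5), n, m)
  W <- matrix(rbinom(s * m, 1, pp$beta), s, m)
  lab <- sample.int(s, n, replace = TRUE)
  X <- matrix(rnorm(n * m, ifelse(Z == 1, pp$mu1, pp$mu0),
                    ifelse(Z == 1, pp$sigma1, pp$sigma0)), n, m)
  phi <- matrix(0L, n, m)
  for (i in seq_len(n)) phi[i, ] <- as.integer(xor(Z[i, ] == 1, W[lab[i], ] == 1))
  Y <- matrix(rnorm(n * m, ifelse(phi == 1, pp$alpha1, pp$alpha0),
                    ifelse(phi == 1, pp$eta1, pp$eta0)), n, m)
  Lambda <- matrix(0L, n, s); Lambda[cbind(seq_len(n), lab)] <- 1L
  list(data = paired_methylation(X, Y),
       state = latent_state(R, Z, W, Lambda),
       R = R, Z = Z, W = W, lab = lab, params = pp)
}

## Monte-Carlo standard error of a Bernoulli frequency estimate
mc_se <- function(p, nrep) sqrt(max(p * (1 - p), 1e-12) / nrep)

## frequency of a latent bit over repeated single-block updates from a
## fixed state (the block conditional does not depend on its own value,
## so the draws are i.i.d. from the conditional)
freq_of <- function(update, extract, data, state, params, nrep) {
  hits <- 0
  for (t in seq_len(nrep)) hits <- hits + extract(update(data, state, params))
  hits / nrep
}
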