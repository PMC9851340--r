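#' Model parameters for the paired-methylation subtype mixture
#'
#' Bundles and validates the continuous parameters of the generative model:
#' the reference-cell methylation rate `gamma`, the probability `delta` that
#' a normal-tissue site retains the reference status, the per-site flip
#' probability `beta` of a subtype modification path, the subtype proportions
#' `p`, and the Gaussian emission parameters for normal (`mu0`/`mu1`,
#' `sigma0`/`sigma1`) and tumor (`alpha0`/`alpha1`, `eta0`/`eta1`) M-values,
#' indexed by methylation status (0 = unmethylated, 1 = methylated).
#'
#' Identifiability constraints are enforced at construction: `mu0 < mu1` and
#' `alpha0 < alpha1` pin down which emission component is "methylated";
#' `delta > 0.5` breaks the complement symmetry in which flipping every
#' reference status and replacing `gamma` by `1 - gamma` leaves the law of
#' the normal profiles unchanged; `beta < 0.5` keeps modification paths
#' sparse rather than their complements.
#'
#' @param gamma Reference-cell methylation probability, in `[0, 1]`.
#' @param delta Probability a normal-tissue site retains the reference
#'   status, in `(0.5, 1]`.
#' @param beta Per-site flip probability of a subtype path, in `[0, 0.5)`.
#' @param p Numeric vector of subtype proportions, summing to 1.
#' @param mu0,mu1 Normal-tissue M-value means (unmethylated/methylated),
#'   `mu0 < mu1`.
#' @param sigma0,sigma1 Normal-tissue M-value standard deviations, positive.
#' @param alpha0,alpha1 Tumor M-value means, `alpha0 < alpha1`.
#' @param eta0,eta1 Tumor M-value standard deviations, positive.
#' @return An object of class `baysub_params` (a validated named list).
#' @examples
#' model_parameters(p = c(0.5, 0.5))
#' @export
model_parameters <- function(gamma = 0.5, delta = 0.99, beta = 0.2,
                             p = c(0.5, 0.5),
                             mu0 = -2.6, mu1 = 1.5, sigma0 = 1.3, sigma1 = 1.4,
                             alpha0 = -2.9, alpha1 = 1.1, eta0 = 1.1, eta1 = 1.7) {
  stopifnot(is.numeric(p), length(p) >= 1L)
  for (nm in c("gamma", "delta", "beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", nm))
  }
  if (delta <= 0.5) stop("'delta' must exceed 0.5 (identifiability)")
  if (beta >= 0.5) stop("'beta' must be below 0.5 (identifiability)")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop("'p' must be nonnegative and sum to 1 (within 1e-12)")
  if (!(mu0 < mu1)) stop("'mu0' must be < 'mu1' (identifiability)")
  if (!(alpha0 < alpha1)) stop("'alpha0' must be < 'alpha1' (identifiability)")
  for (nm in c("sigma0", "sigma1", "eta0", "eta1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("'%s' must be a positive standard deviation", nm))
  }
  structure(list(gamma = gamma, delta = delta, beta = beta, p = as.numeric(p),
                 mu0 = mu0, mu1 = mu1, sigma0 = sigma0, sigma1 = sigma1,
                 alpha0 = alpha0, alpha1 = alpha1, eta0 = eta0, eta1 = eta1),
            class = "baysub_params")
}

#' @export
print.baysub_params <- function(x, ...) {
  cat("Paired-methylation mixture parameters (", length(x$p), " subtypes)\n",
      sep = "")
  cat(sprintf("  gamma=%.4g delta=%.4g beta=%.4g\n", x$gamma, x$delta, x$beta))
  cat("  p =", paste(signif(x$p, 4), collapse = " "), "\n")
  cat(sprintf("  normal: mu=(%.4g, %.4g) sigma=(%.4g, %.4g)\n",
              x$mu0, x$mu1, x$sigma0, x$sigma1))
  cat(sprintf("  tumor:  alpha=(%.4g, %.4g) eta=(%.4g, %.4g)\n",
              x$alpha0, x$alpha1, x$eta0, x$eta1))
  invisible(x)
}

#' Latent state of the subtype mixture
#'
#' Collects the binary latent variables: the reference-cell methylation
#' vector `R` (length m), the normal-tissue profiles `Z` (n x m), the
#' subtype modification paths `W` (s x m) and the one-hot subtype
#' memberships `Lambda` (n x s).
#'
#' @param R Binary vector of length m.
#' @param Z Binary n x m matrix.
#' @param W Binary s x m matrix.
#' @param Lambda Binary n x s matrix with exactly one 1 per row.
#' @return An object of class `baysub_state`, with an element `labels`
#'   (integer subtype index per sample) derived from `Lambda`.
#' @export
latent_state <- function(R, Z, W, Lambda) {
  R <- as.integer(R); Z <- binmat(Z, "Z"); W <- binmat(W, "W")
  Lambda <- binmat(Lambda, "Lambda")
  if (any(R != 0L & R != 1L)) stop("'R' must be binary")
  m <- length(R)
  if (ncol(Z) != m || ncol(W) != m)
    stop("'Z' and 'W' must have one column per entry of 'R'")
  if (nrow(Lambda) != nrow(Z) || ncol(Lambda) != nrow(W))
    stop("'Lambda' must be n x s with n = nrow(Z), s = nrow(W)")
  if (any(rowSums(Lambda) != 1L))
    stop("each row of 'Lambda' must contain exactly one 1")
  structure(list(R = R, Z = Z, W = W, Lambda = Lambda,
                 labels = max.col(Lambda)),
            class = "baysub_state")
}

binmat <- function(M, name) {
  M <- as.matrix(M)
  storage.mode(M) <- "integer"
  if (any(is.na(M)) || any(M != 0L & M != 1L))
    stop(sprintf("'%s' must be a binary matrix", name))
  M
}

#' Paired tumor/normal M-value data
#'
#' @param X Numeric n x m matrix of normal-tissue M-values (samples in rows,
#'   CpG sites in columns).
#' @param Y Numeric n x m matrix of matched tumor M-values; row i of `Y` is
#'   the tumor paired with row i of `X`.
#' @param site_ids Character vector of m CpG site identifiers.
#' @param sample_ids Character vector of n sample identifiers.
#' @return An object of class `baysub_data`.
#' @export
paired_methylation <- function(X, Y, site_ids = NULL, sample_ids = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)))
    stop("'X' and 'Y' must share dimensions (matched pairs)")
  if (anyNA(X) || anyNA(Y)) stop("missing M-values are not allowed")
  if (is.null(site_ids)) site_ids <- sprintf("cg%08d", seq_len(ncol(X)))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%03d", seq_len(nrow(X)))
  if (length(site_ids) != ncol(X) || anyDuplicated(site_ids))
    stop("'site_ids' must be unique and match ncol(X)")
  if (length(sample_ids) != nrow(X) || anyDuplicated(sample_ids))
    stop("'sample_ids' must be unique and match nrow(X)")
  dimnames(X) <- dimnames(Y) <- list(sample_ids, site_ids)
  structure(list(X = X, Y = Y, site_ids = as.character(site_ids),
                 sample_ids = as.character(sample_ids)),
            class = "baysub_data")
}

#' @export
print.baysub_data <- function(x, ...) {
  cat(sprintf("Paired methylation data: %d sample pairs x %d CpG sites\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Tumor methylation profile from normal profile, paths and memberships
#'
#' The binary tumor profile of sample i at site j is its normal profile
#' XOR-ed with its subtype's modification path:
#' `Phi[i, j] = Z[i, j] XOR W[k(i), j]` where `k(i)` is the subtype of
#' sample i encoded by the one-hot row `Lambda[i, ]`.
#'
#' @param Z Binary n x m matrix of normal-tissue profiles.
#' @param W Binary s x m matrix of modification paths.
#' @param Lambda Binary n x s one-hot membership matrix.
#' @return Binary n x m matrix `Phi`.
#' @examples
#' compose_phi(Z = rbind(c(0, 1)), W = rbind(c(1, 1)), Lambda = rbind(1))
#' @export
compose_phi <- function(Z, W, Lambda) {
  Z <- binmat(Z, "Z"); W <- binmat(W, "W"); Lambda <- binmat(Lambda, "Lambda")
  if (nrow(Lambda) != nrow(Z) || ncol(Lambda) != nrow(W) ||
      ncol(Z) != ncol(W))
    stop("dimension mismatch among Z (n x m), W (s x m), Lambda (n x s)")
  if (any(rowSums(Lambda) != 1L))
    stop("each row of 'Lambda' must contain exactly one 1")
  k <- max.col(Lambda)
  Phi <- xor(Z == 1L, W[k, , drop = FALSE] == 1L)
  storage.mode(Phi) <- "integer"
  dimnames(Phi) <- dimnames(Z)
  Phi
}

## log of a probability: exact zeros (a degenerate parameter contradicted
## by the latents) map to -Inf, while merely tiny values are floored at
## 1e-300 so products cannot underflow to NaN arithmetic
logp <- function(p) ifelse(p <= 0, -Inf, log(pmax(p, 1e-300)))

#' Complete-data log-likelihood
#'
#' The joint log density of the observed M-values and all latent binaries,
#' `log P(X, Y, R, Z, W, Lambda | params)`: Bernoulli terms for `R` (rate
#' `gamma`), for the retain/flip channel linking `Z` to `R` (retain
#' probability `delta`), for `W` (rate `beta`), multinomial terms for the
#' memberships, and Gaussian terms for `X` given `Z` and `Y` given
#' `Phi = Z XOR` path.
#'
#' Degenerate probabilities (`gamma`, `delta`, `beta` or an entry of `p`
#' exactly 0 or 1) contradicted by the latents yield `-Inf` rather than an
#' error.
#'
#' @param data A [paired_methylation()] object.
#' @param state A [latent_state()] object of matching dimensions.
#' @param params A [model_parameters()] object with `length(p) == nrow(W)`.
#' @return A finite scalar (or `-Inf` in the degenerate cases above).
#' @export
complete_log_likelihood <- function(data, state, params) {
  stopifnot(inherits(data, "baysub_data"), inherits(state, "baysub_state"),
            inherits(params, "baysub_params"))
  n <- nrow(data$X); m <- ncol(data$X); s <- nrow(state$W)
  if (length(state$R) != m || nrow(state$Z) != n || length(params$p) != s)
    stop("dimension mismatch between data, state and params")
  R <- state$R; Z <- state$Z; W <- state$W
  k <- state$labels
  Phi <- compose_phi(Z, W, state$Lambda)
  agree <- sweep(Z, 2L, R, "==")          # z_ij == r_j: status retained
  ll <- sum(ifelse(R == 1L, logp(params$gamma), logp(1 - params$gamma))) +
    sum(ifelse(agree, logp(params$delta), logp(1 - params$delta))) +
    sum(ifelse(W == 1L, logp(params$beta), logp(1 - params$beta))) +
    sum(logp(params$p[k])) +
    sum(dnorm(data$X, ifelse(Z == 1L, params$mu1, params$mu0),
              ifelse(Z == 1L, params$sigma1, params$sigma0), log = TRUE)) +
    sum(dnorm(data$Y, ifelse(Phi == 1L, params$alpha1, params$alpha0),
              ifelse(Phi == 1L, params$eta1, params$eta0), log = TRUE))
  ll
}

## Per-site observed likelihood given fixed W and labels, marginalizing
## (r_j, z_ij) exactly.  Returns length-m vector of per-site log terms.
plugin_site_loglik <- function(data, params, W, labels) {
  n <- nrow(data$X); m <- ncol(data$X)
  lx <- list(dnorm(data$X, params$mu0, params$sigma0, log = TRUE),
             dnorm(data$X, params$mu1, params$sigma1, log = TRUE))
  ly <- list(dnorm(data$Y, params$alpha0, params$eta0, log = TRUE),
             dnorm(data$Y, params$alpha1, params$eta1, log = TRUE))
  Wlab <- W[labels, , drop = FALSE]       # n x m: each sample's path bit
  out <- numeric(m)
  ## per site: sum_r P(r) prod_i sum_z P(z | r) N(x | z) N(y | z xor w)
  for (r in 0:1) {
    pr <- if (r == 1L) params$gamma else 1 - params$gamma
    ## z = r (retain) vs z = 1 - r (flip)
    l_keep <- lx[[r + 1L]] +
      ifelse(Wlab == 1L, ly[[2L - r]], ly[[r + 1L]])
    l_flip <- lx[[2L - r]] +
      ifelse(Wlab == 1L, ly[[r + 1L]], ly[[2L - r]])
    hi <- pmax(l_keep, l_flip)
    per_ij <- hi + log(params$delta * exp(l_keep - hi) +
                       (1 - params$delta) * exp(l_flip - hi))
    site_r <- colSums(per_ij) + logp(pr)
    out <- if (r == 0L) site_r else {
      hi2 <- pmax(out, site_r)
      hi2 + log(exp(out - hi2) + exp(site_r - hi2))
    }
  }
  out
}

#' Observed-data log-likelihood
#'
#' Marginalizes the binary latents out of the model likelihood. Two modes:
#'
#' * **Plug-in** (default when `W` and `labels` are supplied): conditional on
#'   a fixed modification matrix and membership labels, sites factorize and
#'   `(r_j, z_ij)` are summed out exactly per site. This is the likelihood
#'   used for AIC/BIC.
#' * **Full** (when `W` and `labels` are both `NULL`): additionally sums over
#'   all membership assignments and, per site, over `(r_j, w_1j..w_sj, z_.j)`
#'   by exact enumeration. Exponential in `n`; guarded to small instances.
#'
#' @param data A [paired_methylation()] object.
#' @param params A [model_parameters()] object.
#' @param W Optional binary s x m matrix of modification paths (plug-in mode).
#' @param labels Optional integer vector of subtype labels (plug-in mode).
#' @param max_configs Guard on `s^n` membership configurations in full mode.
#' @return Scalar log-likelihood.
#' @export
observed_log_likelihood <- function(data, params, W = NULL, labels = NULL,
                                    max_configs = 1e5) {
  stopifnot(inherits(data, "baysub_data"), inherits(params, "baysub_params"))
  if (xor(is.null(W), is.null(labels)))
    stop("supply both 'W' and 'labels' (plug-in) or neither (full)")
  if (!is.null(W)) {
    W <- binmat(W, "W")
    labels <- as.integer(labels)
    stopifnot(length(labels) == nrow(data$X), all(labels >= 1L),
              all(labels <= nrow(W)), ncol(W) == ncol(data$X))
    return(sum(plugin_site_loglik(data, params, W, labels)))
  }
  n <- nrow(data$X); m <- ncol(data$X); s <- length(params$p)
  if (s^n > max_configs)
    stop("full marginalization is exponential in n; instance too large")
  ## enumerate membership assignments; per assignment sites factorize and
  ## (r_j, w_.j) are summed per site with z_ij summed analytically inside
  lx <- list(dnorm(data$X, params$mu0, params$sigma0, log = TRUE),
             dnorm(data$X, params$mu1, params$sigma1, log = TRUE))
  ly <- list(dnorm(data$Y, params$alpha0, params$eta0, log = TRUE),
             dnorm(data$Y, params$alpha1, params$eta1, log = TRUE))
  wgrid <- as.matrix(expand.grid(rep(list(0:1), s)))  # 2^s path columns
  configs <- as.matrix(expand.grid(rep(list(seq_len(s)), n)))
  total <- -Inf
  for (ci in seq_len(nrow(configs))) {
    lab <- configs[ci, ]
    lcfg <- sum(logp(params$p[lab]))
    for (j in seq_len(m)) {
      site <- -Inf
      for (r in 0:1) {
        pr <- logp(if (r == 1) params$gamma else 1 - params$gamma)
        for (wi in seq_len(nrow(wgrid))) {
          w <- wgrid[wi, ]
          pw <- sum(logp(ifelse(w == 1, params$beta, 1 - params$beta)))
          li <- 0
          for (i in seq_len(n)) {
            acc <- 0
            for (z in 0:1) {
              pz <- if (z == r) params$delta else 1 - params$delta
              phi <- xor(z == 1, w[lab[i]] == 1)
              acc <- acc + pz * exp(lx[[z + 1]][i, j] + ly[[phi + 1]][i, j])
            }
            li <- li + logp(acc)
          }
          site <- logsumexp2(site, pr + pw + li)
        }
      }
      lcfg <- lcfg + site
    }
    total <- logsumexp2(total, lcfg)
  }
  total
}

logsumexp2 <- function(a, b) {
  if (a == -Inf && b == -Inf) return(-Inf)
  hi <- max(a, b)
  hi + log(exp(a - hi) + exp(b - hi))
}
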