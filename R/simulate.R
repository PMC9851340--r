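#' Simulate paired methylation data from the generative model
#'
#' Draws the latent binaries and observed M-values exactly per the model
#' hierarchy: reference statuses `r_j ~ Bernoulli(gamma)`; normal profiles
#' `z_ij = r_j XOR Bernoulli(1 - delta)`; modification paths
#' `w_kj ~ Bernoulli(beta)`; memberships `lambda_i ~ Multinomial(1; p)`;
#' then `x_ij ~ N(mu_z, sigma_z^2)` and `y_ij ~ N(alpha_phi, eta_phi^2)`
#' with `phi = z XOR w_k`.
#'
#' @param n Number of matched sample pairs.
#' @param m Number of CpG sites.
#' @param s Number of subtypes; must equal `length(params$p)`.
#' @param params A [model_parameters()] object.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `baysub_sim`: a list with `params`, `state`
#'   ([latent_state()]), `data` ([paired_methylation()]) and `true_labels`.
#' @examples
#' sim <- simulate_pure(n = 10, m = 50, s = 2, seed = 1)
#' table(sim$true_labels)
#' @export
simulate_pure <- function(n, m, s = length(params$p),
                          params = model_parameters(p = rep(1 / s, s)),
                          seed = 1L) {
  check_sim_args(n, m, s, params)
  set.seed(seed)
  draw_pure(n, m, s, params)
}

check_sim_args <- function(n, m, s, params) {
  stopifnot(inherits(params, "baysub_params"))
  if (!is.numeric(n) || n < 1 || !is.numeric(m) || m < 1 || s < 1)
    stop("'n', 'm' and 's' must be positive counts")
  if (length(params$p) != s)
    stop("'s' must equal length(params$p)")
  invisible(TRUE)
}

## one draw from the model hierarchy using the current RNG stream;
## fixed draw order (R, Z, W, Lambda, X, Y) so seeded runs are reproducible
draw_pure <- function(n, m, s, params, labels = NULL) {
  R <- rbinom(m, 1L, params$gamma)
  flip <- matrix(rbinom(n * m, 1L, 1 - params$delta), n, m)
  Z <- xor(matrix(R == 1L, n, m, byrow = TRUE), flip == 1L)
  storage.mode(Z) <- "integer"
  W <- matrix(rbinom(s * m, 1L, params$beta), s, m)
  if (is.null(labels))
    labels <- sample.int(s, n, replace = TRUE, prob = params$p)
  Lambda <- matrix(0L, n, s); Lambda[cbind(seq_len(n), labels)] <- 1L
  state <- latent_state(R, Z, W, Lambda)
  Phi <- compose_phi(Z, W, Lambda)
  X <- matrix(rnorm(n * m, ifelse(Z == 1L, params$mu1, params$mu0),
                    ifelse(Z == 1L, params$sigma1, params$sigma0)), n, m)
  Y <- matrix(rnorm(n * m, ifelse(Phi == 1L, params$alpha1, params$alpha0),
                    ifelse(Phi == 1L, params$eta1, params$eta0)), n, m)
  structure(list(params = params, state = state,
                 data = paired_methylation(X, Y),
                 true_labels = as.integer(labels)),
            class = "baysub_sim")
}

#' Mixture proportions for contaminated tumor samples
#'
#' @param P_A Proportion of the major subtype's signal.
#' @param P_B Proportion of the minor subtype's signal; `P_A > P_B`.
#' @param P_N Proportion of admixed normal-cell signal.
#' @return An object of class `baysub_mix`.
#' @export
mixture_spec <- function(P_A, P_B, P_N) {
  stopifnot(is.numeric(P_A), is.numeric(P_B), is.numeric(P_N))
  if (P_A < 0 || P_B < 0 || P_N < 0 || abs(P_A + P_B + P_N - 1) > 1e-12)
    stop("proportions must be nonnegative and sum to 1")
  if (P_A == P_B)
    stop("'P_A' must exceed 'P_B' so the major subtype is defined")
  if (P_A < P_B) stop("'P_A' must be the largest (major) proportion")
  structure(list(P_A = P_A, P_B = P_B, P_N = P_N), class = "baysub_mix")
}

#' Simulate contaminated (impure) tumor samples
#'
#' Emulates tumor heterogeneity and dissection contamination: each observed
#' pair is a linear combination of two tumor subtypes and normal tissue.
#' For every patient i one latent normal profile `z_i` is drawn (shared by
#' all components), then component pairs are generated — one per subtype
#' (tumor side modified by that subtype's path) plus a normal component
#' (tumor side unmodified, `phi = z`) — and two distinct subtypes `A_i`,
#' `B_i` are selected at random. The observed pair is
#' `P_A * {x_A, y_A} + P_B * {x_B, y_B} + P_N * {x_0, y_0}`, and the truth
#' label is the major subtype `A_i`.
#'
#' @inheritParams simulate_pure
#' @param mix A [mixture_spec()] object.
#' @return A `baysub_sim` whose `true_labels` are the major subtypes, with
#'   an extra element `components` holding, per patient, the component
#'   matrices and the selected `(A_i, B_i)`.
#' @export
simulate_contaminated <- function(n, m, s = length(params$p),
                                  params = model_parameters(p = rep(1 / s, s)),
                                  mix = mixture_spec(0.8, 0.1, 0.1),
                                  seed = 1L) {
  check_sim_args(n, m, s, params)
  stopifnot(inherits(mix, "baysub_mix"))
  if (s < 2) stop("contamination requires s >= 2 subtypes")
  set.seed(seed)
  R <- rbinom(m, 1L, params$gamma)
  W <- matrix(rbinom(s * m, 1L, params$beta), s, m)
  X <- matrix(0, n, m); Y <- matrix(0, n, m)
  A <- integer(n); B <- integer(n)
  Z <- matrix(0L, n, m)
  comp_x <- vector("list", n); comp_y <- vector("list", n)
  for (i in seq_len(n)) {
    flip <- rbinom(m, 1L, 1 - params$delta)
    z <- as.integer(xor(R == 1L, flip == 1L))
    Z[i, ] <- z
    ab <- sample.int(s, 2L)               # distinct subtypes, A major
    A[i] <- ab[1L]; B[i] <- ab[2L]
    ## component emissions: rows 1..s are subtypes, row s+1 is normal tissue
    cx <- matrix(0, s + 1L, m); cy <- matrix(0, s + 1L, m)
    for (k in seq_len(s)) {
      phi <- as.integer(xor(z == 1L, W[k, ] == 1L))
      cx[k, ] <- rnorm(m, ifelse(z == 1L, params$mu1, params$mu0),
                       ifelse(z == 1L, params$sigma1, params$sigma0))
      cy[k, ] <- rnorm(m, ifelse(phi == 1L, params$alpha1, params$alpha0),
                       ifelse(phi == 1L, params$eta1, params$eta0))
    }
    cx[s + 1L, ] <- rnorm(m, ifelse(z == 1L, params$mu1, params$mu0),
                          ifelse(z == 1L, params$sigma1, params$sigma0))
    cy[s + 1L, ] <- rnorm(m, ifelse(z == 1L, params$alpha1, params$alpha0),
                          ifelse(z == 1L, params$eta1, params$eta0))
    X[i, ] <- mix$P_A * cx[A[i], ] + mix$P_B * cx[B[i], ] + mix$P_N * cx[s + 1L, ]
    Y[i, ] <- mix$P_A * cy[A[i], ] + mix$P_B * cy[B[i], ] + mix$P_N * cy[s + 1L, ]
    comp_x[[i]] <- cx; comp_y[[i]] <- cy
  }
  Lambda <- matrix(0L, n, s); Lambda[cbind(seq_len(n), A)] <- 1L
  structure(list(params = params,
                 state = latent_state(R, Z, W, Lambda),
                 data = paired_methylation(X, Y),
                 true_labels = A,
                 components = list(x = comp_x, y = comp_y,
                                   major = A, minor = B, mix = mix)),
            class = "baysub_sim")
}

## partition m sites into k contiguous regions with random cut points
## (k - 1 distinct gaps chosen uniformly without replacement)
random_regions <- function(m, k) {
  if (k > m) stop("'n_regions' cannot exceed the number of sites")
  if (k == 1L) return(rep(1L, m))
  cuts <- sort(sample.int(m - 1L, k - 1L))
  rep(seq_len(k), times = diff(c(0L, cuts, m)))
}

#' Simulate region-correlated, heavy-tailed paired methylation data
#'
#' Departs from the model's i.i.d. Gaussian assumptions in two ways. The
#' reference vector `R` is split into `n_regions` contiguous random-length
#' regions whose Bernoulli rates alternate between `p_high` and `p_low`
#' (adjacent regions always differ; the first region's rate is chosen at
#' random). Each row of `W` is split independently into `n_regions` regions
#' that are constant within a region, the region value being
#' `Bernoulli(p_w)`. Emissions come from a location-scale t distribution
#' with `df` degrees of freedom, using the model's means as locations and
#' its standard deviations as scale parameters.
#'
#' @inheritParams simulate_pure
#' @param n_regions Number of contiguous regions (default 100).
#' @param p_high,p_low Alternating region rates for `R` (defaults 0.7, 0.3).
#' @param p_w Probability a `W` region takes the value 1 (default 0.2).
#' @param df Degrees of freedom of the t emissions (default 3).
#' @return A `baysub_sim` object.
#' @export
simulate_correlated <- function(n, m, s = length(params$p),
                                params = model_parameters(p = rep(1 / s, s)),
                                n_regions = 100L, p_high = 0.7, p_low = 0.3,
                                p_w = 0.2, df = 3, seed = 1L) {
  check_sim_args(n, m, s, params)
  if (n_regions > m) stop("'n_regions' cannot exceed 'm'")
  if (p_high == p_low)
    warning("'p_high' == 'p_low': R has no region structure")
  set.seed(seed)
  reg_r <- random_regions(m, n_regions)
  first_high <- runif(1) < 0.5
  rates <- ifelse((reg_r %% 2L == 1L) == first_high, p_high, p_low)
  R <- rbinom(m, 1L, rates)
  flip <- matrix(rbinom(n * m, 1L, 1 - params$delta), n, m)
  Z <- xor(matrix(R == 1L, n, m, byrow = TRUE), flip == 1L)
  storage.mode(Z) <- "integer"
  W <- matrix(0L, s, m)
  for (k in seq_len(s)) {
    reg_w <- random_regions(m, n_regions)
    vals <- rbinom(n_regions, 1L, p_w)
    W[k, ] <- vals[reg_w]
  }
  labels <- sample.int(s, n, replace = TRUE, prob = params$p)
  Lambda <- matrix(0L, n, s); Lambda[cbind(seq_len(n), labels)] <- 1L
  Phi <- compose_phi(Z, W, Lambda)
  X <- matrix(ifelse(Z == 1L, params$mu1, params$mu0) +
                ifelse(Z == 1L, params$sigma1, params$sigma0) *
                  rt(n * m, df), n, m)
  Y <- matrix(ifelse(Phi == 1L, params$alpha1, params$alpha0) +
                ifelse(Phi == 1L, params$eta1, params$eta0) *
                  rt(n * m, df), n, m)
  structure(list(params = params,
                 state = latent_state(R, Z, W, Lambda),
                 data = paired_methylation(X, Y),
                 true_labels = as.integer(labels)),
            class = "baysub_sim")
}

#' Write a simulated dataset and its ground truth to disk
#'
#' The data go out as the two TSV matrices of [write_paired_matrices()];
#' the truth (labels, W, R and the generating parameters) goes into a
#' plain-text sidecar.
#'
#' @param sim A `baysub_sim` object.
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "baysub_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  px <- file.path(dir, paste0(prefix, "_normal.tsv"))
  py <- file.path(dir, paste0(prefix, "_tumor.tsv"))
  write_paired_matrices(sim$data, px, py)
  pt <- file.path(dir, paste0(prefix, "_truth.tsv"))
  truth <- data.frame(sample_id = sim$data$sample_ids,
                      subtype = sim$true_labels)
  write.table(truth, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  pw <- file.path(dir, paste0(prefix, "_W.tsv"))
  Wdf <- data.frame(site_id = sim$data$site_ids, t(sim$state$W),
                    check.names = FALSE)
  names(Wdf)[-1L] <- paste0("subtype", seq_len(nrow(sim$state$W)))
  write.table(Wdf, pw, sep = "\t", quote = FALSE, row.names = FALSE)
  pp <- file.path(dir, paste0(prefix, "_params.tsv"))
  pars <- sim$params
  pdf <- data.frame(parameter = c(names(pars)[names(pars) != "p"],
                                  paste0("p", seq_along(pars$p))),
                    value = c(unlist(pars[names(pars) != "p"]), pars$p))
  write.table(pdf, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(px, py, pt, pw, pp))
}
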