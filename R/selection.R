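#' AIC and BIC of a fitted subtype model
#'
#' Uses the plug-in observed-data likelihood `L`: the posterior-mean
#' continuous parameters with the modification matrix and memberships at
#' their estimates, marginalizing the reference and normal-profile bits
#' per site (see [observed_log_likelihood()]). The parameter count is
#' `k = 11 + (s - 1) + s * m` — the 11 continuous parameters, the free
#' subtype proportions, and the `s * m` modification-path bits whose growth
#' with `s` is what the penalty must control — and the sample size is
#' `N = 2 n m`, every observed M-value.
#'
#' `AIC = 2 k - 2 L`, `BIC = k log(N) - 2 L`.
#'
#' @param fit A [run_multichain()] or [run_chain()] result fitted with `s`
#'   subtypes on `data`.
#' @param data The [paired_methylation()] object the fit used.
#' @param s Number of subtypes of the fit.
#' @return Named list with `aic`, `bic`, `loglik`, `k`, `N`.
#' @export
information_criteria <- function(fit, data, s = fit$config$s) {
  stopifnot(inherits(data, "baysub_data"))
  if (nrow(fit$estimate_W) != s)
    stop("'s' does not match the fitted modification matrix")
  n <- nrow(data$X); m <- ncol(data$X)
  L <- observed_log_likelihood(data, fit$estimate_params,
                               W = fit$estimate_W,
                               labels = fit$estimate_labels)
  if (!is.finite(L)) stop("non-finite plug-in log-likelihood")
  k <- 11 + (s - 1) + s * m
  N <- 2 * n * m
  list(aic = 2 * k - 2 * L, bic = k * log(N) - 2 * L, loglik = L,
       k = k, N = N)
}

#' Select the number of subtypes by AIC/BIC
#'
#' Fits the model for every candidate `s` via [run_multichain()] and
#' tabulates both criteria; the minima are the selected subtype counts.
#'
#' @param data A [paired_methylation()] object.
#' @param s_range Integer vector of candidate subtype counts.
#' @param n_iterations,n_chains,seed,estimate_window,rhat_window Passed to
#'   [run_config()] for every candidate fit.
#' @return An object of class `baysub_selection`: a list with `s_values`,
#'   `aic`, `bic`, `best_aic_s`, `best_bic_s` and the per-candidate `fits`.
#' @export
select_s <- function(data, s_range, n_iterations = 200L, n_chains = 10L,
                     seed = 1L, estimate_window = 30L, rhat_window = 60L) {
  s_range <- sort(unique(as.integer(s_range)))
  stopifnot(length(s_range) >= 1L, all(s_range >= 1L))
  fits <- vector("list", length(s_range))
  aic <- bic <- numeric(length(s_range))
  for (i in seq_along(s_range)) {
    cfg <- run_config(s = s_range[i], n_iterations = n_iterations,
                      n_chains = n_chains, seed = seed + i - 1L,
                      estimate_window = estimate_window,
                      rhat_window = rhat_window)
    fits[[i]] <- run_multichain(data, cfg)
    ic <- information_criteria(fits[[i]], data, s_range[i])
    aic[i] <- ic$aic; bic[i] <- ic$bic
  }
  structure(list(s_values = s_range, aic = aic, bic = bic,
                 best_aic_s = s_range[which.min(aic)],
                 best_bic_s = s_range[which.min(bic)],
                 fits = fits),
            class = "baysub_selection")
}

#' @export
print.baysub_selection <- function(x, ...) {
  cat("Subtype-number selection\n")
  print(data.frame(s = x$s_values, AIC = x$aic, BIC = x$bic))
  cat(sprintf("  argmin AIC: s = %d; argmin BIC: s = %d\n",
              x$best_aic_s, x$best_bic_s))
  invisible(x)
}
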