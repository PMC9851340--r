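contingency <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  if (length(a) != length(b) || length(a) < 2L)
    stop("labelings must have equal length >= 2")
  table(factor(a), factor(b))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement from the contingency table:
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent labelings.
#'
#' @param labels_a,labels_b Vectors of cluster labels, equal length.
#' @return A scalar, at most 1.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  tab <- contingency(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)    # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies (one of several conventions in use; fixed here so values are
#' comparable across runs). In `[0, 1]`, with 1 for identical partitions.
#'
#' @inheritParams adjusted_rand_index
#' @return A scalar in `[0, 1]`.
#' @export
normalized_mutual_information <- function(labels_a, labels_b) {
  tab <- contingency(labels_a, labels_b)
  n <- sum(tab)
  pij <- tab / n
  pa <- rowSums(pij); pb <- colSums(pij)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- ent(pa); hb <- ent(pb)
  if (ha == 0 && hb == 0) return(1)       # both partitions trivial
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pa, pb)[nz]))
  mi / ((ha + hb) / 2)
}

#' Match fitted subtypes to reference subtypes
#'
#' Subtype indices are arbitrary, so before comparing a fitted modification
#' matrix to a reference one the rows must be aligned. Finds the
#' permutation `perm` minimizing the total Hamming distance between
#' `W_fit[perm[k], ]` and `W_true[k, ]` by exhaustive search over
#' permutations (s up to 8).
#'
#' @param W_fit Binary s x m fitted modification matrix.
#' @param W_true Binary s x m reference modification matrix.
#' @return Integer permutation `perm` such that `W_fit[perm, ]` aligns with
#'   `W_true`; apply the inverse map to fitted labels via
#'   `match(labels, perm)`.
#' @export
match_subtypes <- function(W_fit, W_true) {
  W_fit <- binmat(W_fit, "W_fit"); W_true <- binmat(W_true, "W_true")
  if (!all(dim(W_fit) == dim(W_true)))
    stop("'W_fit' and 'W_true' must share dimensions")
  s <- nrow(W_fit)
  if (s == 1L) return(1L)
  if (s > 8L) stop("exhaustive matching supports at most 8 subtypes")
  ## cost[a, b] = Hamming distance between fitted row a and true row b
  cost <- matrix(0L, s, s)
  for (a in seq_len(s)) for (b in seq_len(s))
    cost[a, b] <- sum(W_fit[a, ] != W_true[b, ])
  perms <- all_permutations(s)
  totals <- vapply(seq_len(nrow(perms)), function(i)
    sum(cost[cbind(perms[i, ], seq_len(s))]), integer(1))
  unname(perms[which.min(totals), ])
}

all_permutations <- function(s) {
  if (s == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(s - 1L)
  do.call(rbind, lapply(seq_len(s), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Apply a subtype matching to a fit
#'
#' Convenience wrapper: reorders the rows of the fitted `W` and remaps the
#' fitted labels so both are expressed in the reference subtype indexing.
#'
#' @param W_fit Binary s x m fitted modification matrix.
#' @param labels_fit Integer fitted labels.
#' @param W_true Binary s x m reference matrix.
#' @return List with `W` (matched fitted matrix), `labels` (remapped
#'   labels) and `perm`.
#' @export
apply_matching <- function(W_fit, labels_fit, W_true) {
  perm <- match_subtypes(W_fit, W_true)
  list(W = W_fit[perm, , drop = FALSE],
       labels = match(labels_fit, perm),
       perm = perm)
}

#' Element-wise signature accuracy (AE)
#'
#' Percentage of entries of the (matched) fitted modification matrix that
#' agree with the reference: `100 / (s m) * sum I(w_kj == w~_kj)`.
#'
#' @param W_fit_matched Binary s x m fitted matrix, already aligned to the
#'   reference subtype order (see [match_subtypes()]).
#' @param W_true Binary s x m reference matrix.
#' @return A percentage in `[0, 100]`.
#' @export
accuracy_elements <- function(W_fit_matched, W_true) {
  W_fit_matched <- binmat(W_fit_matched, "W_fit_matched")
  W_true <- binmat(W_true, "W_true")
  if (!all(dim(W_fit_matched) == dim(W_true))) stop("dimension mismatch")
  100 * mean(W_fit_matched == W_true)
}

#' Site-wise signature accuracy (AS)
#'
#' Percentage of CpG sites whose status is correct in every subtype:
#' `100 / m * sum_j prod_k I(w_kj == w~_kj)`. Always at most
#' [accuracy_elements()].
#'
#' @inheritParams accuracy_elements
#' @return A percentage in `[0, 100]`.
#' @export
accuracy_sites <- function(W_fit_matched, W_true) {
  W_fit_matched <- binmat(W_fit_matched, "W_fit_matched")
  W_true <- binmat(W_true, "W_true")
  if (!all(dim(W_fit_matched) == dim(W_true))) stop("dimension mismatch")
  100 * mean(colSums(W_fit_matched != W_true) == 0L)
}

#' Empirical modification signature from mean M-values
#'
#' Reference signature used to score fits on real data, where the true
#' modification matrix is unknown. Per subtype k the mean M-value vectors
#' over its samples are computed for normal and tumor tissue; a site is
#' called methylated when its mean M-value exceeds 0 (the natural M-value
#' midpoint), and the signature bit is the XOR of the two calls:
#' `w~_kj = I(xbar_kj > 0) XOR I(ybar_kj > 0)`.
#'
#' @param data A [paired_methylation()] object.
#' @param labels Integer subtype label per sample; every subtype in
#'   `1..max(labels)` must be non-empty.
#' @return Binary s x m matrix.
#' @export
empirical_signature <- function(data, labels) {
  stopifnot(inherits(data, "baysub_data"))
  labels <- as.integer(labels)
  if (length(labels) != nrow(data$X)) stop("one label per sample required")
  s <- max(labels)
  if (any(tabulate(labels, s) == 0L))
    stop("every subtype must contain at least one sample")
  W <- matrix(0L, s, ncol(data$X))
  for (k in seq_len(s)) {
    idx <- labels == k
    cx <- colMeans(data$X[idx, , drop = FALSE]) > 0
    cy <- colMeans(data$Y[idx, , drop = FALSE]) > 0
    W[k, ] <- as.integer(xor(cx, cy))
  }
  W
}

#' Score a fit against a reference
#'
#' Bundles the four accuracy measures: ARI and NMI of the labels, and AE
#' and AS of the modification matrix after optimal subtype matching.
#'
#' @param fit A [run_multichain()] (or [run_chain()]) result.
#' @param true_labels Reference labels.
#' @param W_true Optional reference modification matrix; when `NULL`, AE
#'   and AS are omitted.
#' @return Named list with `ari`, `nmi` and (when `W_true` is given) `ae`,
#'   `as`.
#' @export
evaluate_fit <- function(fit, true_labels, W_true = NULL) {
  labels <- fit$estimate_labels
  out <- list(ari = adjusted_rand_index(labels, true_labels),
              nmi = normalized_mutual_information(labels, true_labels))
  if (!is.null(W_true)) {
    matched <- apply_matching(fit$estimate_W, labels, W_true)
    out$ae <- accuracy_elements(matched$W, W_true)
    out$as <- accuracy_sites(matched$W, W_true)
  }
  out
}
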