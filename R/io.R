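#' Convert methylation beta-values to M-values
#'
#' `M = log2(beta / (1 - beta))`. Beta-values are clamped to
#' `[1e-6, 1 - 1e-6]` before conversion so that boundary probes map to
#' finite M-values.
#'
#' @param beta Numeric vector/matrix of beta-values in `[0, 1]`.
#' @return Object of the same shape with M-values.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))   # -2, 0, 2
#' @export
beta_to_m <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta-values must lie in [0, 1]")
  b <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  out <- log2(b / (1 - b))
  attributes(out) <- attributes(beta)
  out
}

#' Convert M-values back to beta-values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`.
#'
#' @param m Numeric vector/matrix of M-values.
#' @return Beta-values in `(0, 1)`.
#' @export
m_to_beta <- function(m) {
  out <- 1 / (1 + 2^(-m))
  attributes(out) <- attributes(m)
  out
}

## matrices travel as sites x samples TSV: first column `site_id`,
## header row of sample IDs
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "site_id")
    stop(sprintf("'%s': first column must be 'site_id'", path))
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop(sprintf("'%s': duplicated site IDs", path))
  M <- as.matrix(df[-1L])
  if (!is.numeric(M)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
    stop(sprintf("'%s': non-numeric values in column '%s'",
                 path, names(df[-1L])[bad]))
  }
  if (anyDuplicated(colnames(M))) stop(sprintf("'%s': duplicated sample IDs", path))
  rownames(M) <- ids
  M
}

write_matrix_tsv <- function(M, path) {
  df <- data.frame(site_id = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read paired normal/tumor M-value matrices
#'
#' Each file is a tab-separated sites x samples matrix with a `site_id`
#' first column and sample IDs in the header. The tumor matrix is reordered
#' to the normal matrix's site and sample order by ID; samples or sites
#' present in only one file are an error.
#'
#' @param path_x Path to the normal-tissue matrix.
#' @param path_y Path to the matched tumor matrix.
#' @return A [paired_methylation()] object (samples x sites internally).
#' @export
read_paired_matrices <- function(path_x, path_y) {
  MX <- read_matrix_tsv(path_x)
  MY <- read_matrix_tsv(path_y)
  if (!setequal(colnames(MX), colnames(MY)))
    stop("sample IDs differ between normal and tumor matrices")
  if (!setequal(rownames(MX), rownames(MY)))
    stop("site IDs differ between normal and tumor matrices")
  MY <- MY[rownames(MX), colnames(MX), drop = FALSE]
  paired_methylation(X = t(MX), Y = t(MY),
                     site_ids = rownames(MX), sample_ids = colnames(MX))
}

#' Write a paired dataset as two TSV matrices
#'
#' @param data A [paired_methylation()] object.
#' @param path_x,path_y Output paths for the normal and tumor matrices
#'   (sites x samples).
#' @return Invisibly, `c(path_x, path_y)`.
#' @export
write_paired_matrices <- function(data, path_x, path_y) {
  stopifnot(inherits(data, "baysub_data"))
  write_matrix_tsv(t(data$X), path_x)
  write_matrix_tsv(t(data$Y), path_y)
  invisible(c(path_x, path_y))
}

#' Restrict paired datasets to their common CpG sites
#'
#' Intersects site IDs across all supplied datasets and restricts each to
#' the shared sites, ordered by their appearance in the first dataset.
#'
#' @param datasets A list of [paired_methylation()] objects.
#' @return A list of [paired_methylation()] objects on the common sites.
#' @export
intersect_common_sites <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "baysub_data")))
  common <- Reduce(intersect, lapply(datasets, `[[`, "site_ids"))
  if (length(common) == 0L) stop("no CpG sites shared by all datasets")
  common <- datasets[[1L]]$site_ids[datasets[[1L]]$site_ids %in% common]
  lapply(datasets, function(d) {
    idx <- match(common, d$site_ids)
    paired_methylation(d$X[, idx, drop = FALSE], d$Y[, idx, drop = FALSE],
                       site_ids = common, sample_ids = d$sample_ids)
  })
}
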