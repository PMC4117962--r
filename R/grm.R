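#' Genomic relationship matrix (VanRaden method 1)
#'
#' Builds `G = Z Z' / (2 * sum_j p_j (1 - p_j))` from autosomal markers,
#' where `Z_ij = g_ij - 2 p_j` and `p_j` is the in-sample frequency of the
#' counted (alternate) allele at marker `j`. Centering makes each marker
#' column sum to zero, so `G` has (numerically) zero row sums and is
#' positive semi-definite; under Hardy-Weinberg its diagonal averages ~1.
#'
#' Non-autosomal markers (X, Y, MT, unplaced) never contribute. Missing
#' genotypes are mean-imputed (replaced by `2 p_j`, i.e. a zero entry of
#' `Z`) by default, matching the contribution of an average animal.
#'
#' @param gm a [genotype_matrix()]
#' @param impute `"mean"` (default) replaces missing calls with `2 p_j`;
#'   `"none"` errors on missing data.
#' @param ridge optional non-negative value added to the diagonal for
#'   downstream eigen-stability (default 0).
#' @return an object of class `grm`: list with the `n x n` matrix `G`,
#'   `n_markers_used` and the per-marker `allele_freqs`
#' @export
compute_grm <- function(gm, impute = c("mean", "none"), ridge = 0) {
  impute <- match.arg(impute)
  auto <- chromosome_class(gm$markers) == "autosome"
  if (!any(auto)) stop("no autosomal markers available for the GRM")
  geno <- gm$geno[, auto, drop = FALSE]
  storage.mode(geno) <- "double"
  p <- colMeans(geno, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  if (anyNA(geno)) {
    if (impute == "none") stop("missing genotypes present; use impute = \"mean\"")
    idx <- which(is.na(geno))
    geno[idx] <- (2 * p)[(idx - 1L) %/% nrow(geno) + 1L]
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all autosomal markers are monomorphic; GRM denominator is zero")
  Z <- sweep(geno, 2L, 2 * p)
  G <- tcrossprod(Z) / denom
  if (ridge > 0) G <- G + diag(ridge, nrow(G))
  dimnames(G) <- list(gm$samples, gm$samples)
  structure(list(G = G, n_markers_used = sum(auto), allele_freqs = p),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d x %d from %d autosomal markers; mean diag %.3f\n",
              nrow(x$G), ncol(x$G), x$n_markers_used, mean(diag(x$G))))
  invisible(x)
}
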