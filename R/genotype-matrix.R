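#' Genotype matrix container
#'
#' Holds biallelic genotype calls for a set of samples at a set of markers,
#' coded as the number of copies of the counted (alternate) allele:
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' `NA` = missing call. Marker metadata travels with the calls.
#'
#' @param geno integer matrix, samples in rows, markers in columns; values
#'   must be 0, 1, 2 or `NA`.
#' @param markers data.frame with one row per marker and columns `id`
#'   (unique character), `chrom` (character label: autosome number, `"X"`,
#'   `"Y"`, `"MT"` or `"unknown"`), `pos` (1-based bp, `NA` allowed only for
#'   unplaced markers) and `class` (`"snp"` or `"indel"`).
#' @param samples character vector of sample ids (defaults to the row names
#'   of `geno`).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `geno`, `markers` and `samples`.
#' @export
genotype_matrix <- function(geno, markers, samples = rownames(geno)) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(samples)) samples <- sprintf("S%04d", seq_len(nrow(geno)))
  stopifnot(is.data.frame(markers), nrow(markers) == ncol(geno),
            length(samples) == nrow(geno))
  if (!all(c("id", "chrom", "pos") %in% names(markers)))
    stop("markers must have columns id, chrom, pos")
  if (anyDuplicated(markers$id))
    stop("marker ids must be unique")
  if (is.null(markers$class)) markers$class <- "snp"
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype calls must be 0, 1, 2 or NA")
  markers$chrom <- as.character(markers$chrom)
  rownames(markers) <- NULL
  dimnames(geno) <- list(samples, markers$id)
  structure(list(geno = geno, markers = markers,
                 samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%s)\n",
              length(x$samples), nrow(x$markers),
              paste(utils::head(unique(x$markers$chrom), 8), collapse = ", ")))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing call rate: %.4f\n", miss))
  invisible(x)
}

#' Number of samples / markers in a genotype matrix
#' @param gm a [genotype_matrix()]
#' @return integer count
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_markers <- function(gm) nrow(gm$markers)

#' Subset a genotype matrix by marker
#'
#' @param gm a [genotype_matrix()]
#' @param keep logical or integer index over markers
#' @return a new `genotype_matrix`
#' @export
gm_subset_markers <- function(gm, keep) {
  genotype_matrix(gm$geno[, keep, drop = FALSE],
                  gm$markers[keep, , drop = FALSE], gm$samples)
}

#' Per-marker missing-call fraction
#' @param gm a [genotype_matrix()]
#' @return numeric vector, one value per marker
#' @export
marker_missing_rate <- function(gm) colMeans(is.na(gm$geno))

#' Per-marker minor allele frequency
#'
#' Missing calls are excluded from the allele-count denominator. A marker
#' with no non-missing call gets MAF 0 (it is unusable either way).
#'
#' @param gm a [genotype_matrix()]
#' @return numeric vector of minor allele frequencies in \[0, 0.5\]
#' @export
marker_maf <- function(gm) {
  p <- colMeans(gm$geno, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  pmin(p, 1 - p)
}

#' Chromosome class of each marker
#'
#' Classifies markers into `"autosome"`, `"X"`, `"Y"`, `"MT"` or
#' `"unknown"` (unplaced: chromosome label missing/0/unknown or position
#' missing). The mitochondrial, Y-chromosomal and unplaced classes are the
#' ones dropped before association analysis.
#'
#' @param markers marker metadata data.frame (see [genotype_matrix()])
#' @return character vector of class labels
#' @export
chromosome_class <- function(markers) {
  chrom <- toupper(as.character(markers$chrom))
  cls <- rep("autosome", nrow(markers))
  cls[chrom %in% c("MT", "M", "MITO")] <- "MT"
  cls[chrom == "Y"] <- "Y"
  cls[chrom == "X"] <- "X"
  unknown <- is.na(chrom) | chrom %in% c("", "0", "UN", "UNKNOWN", "NA") |
    is.na(markers$pos)
  cls[unknown] <- "unknown"
  cls
}
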