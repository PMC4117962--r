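#' Marker quality control
#'
#' SNP-array marker filters applied before association analysis:
#' chromosome-class removal (mitochondrial, Y-chromosomal and unplaced
#' markers), per-marker call-rate and minor-allele-frequency thresholds.
#' Thresholds are strict inequalities: a marker fails the call-rate filter
#' iff its missing fraction is *greater than* `max_missing` and fails the
#' MAF filter iff its MAF is *strictly below* `min_maf`.
#'
#' Each filter returns the filtered matrix together with a `qc_report`
#' itemizing removal counts. [apply_qc()] flags all three criteria
#' independently on the input and removes the union of failures, so the
#' surviving set does not depend on filter order.
#'
#' @name qc
NULL

new_qc_report <- function(n_input, removed, fail) {
  structure(list(n_input = n_input,
                 n_removed_by_class = removed,
                 n_output = n_input - sum(fail),
                 fail = fail),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d markers in, %d out (%d removed)\n",
              x$n_input, x$n_output, x$n_input - x$n_output))
  for (nm in names(x$n_removed_by_class))
    cat(sprintf("  %-14s %d\n", nm, x$n_removed_by_class[[nm]]))
  invisible(x)
}

#' Remove mitochondrial, Y-chromosomal and unplaced markers
#'
#' @param gm a [genotype_matrix()]
#' @return list with elements `gm` (filtered matrix) and `report`
#'   (a `qc_report` itemizing MT, Y and unknown-position removals)
#' @export
filter_chromosome_class <- function(gm) {
  cls <- chromosome_class(gm$markers)
  fail <- cls %in% c("MT", "Y", "unknown")
  removed <- c(MT = sum(cls == "MT"), Y = sum(cls == "Y"),
               unknown = sum(cls == "unknown"))
  list(gm = gm_subset_markers(gm, !fail),
       report = new_qc_report(n_markers(gm), as.list(removed), fail))
}

#' Remove markers with too many missing calls
#'
#' @param gm a [genotype_matrix()]
#' @param max_missing maximum tolerated missing-call fraction (default 0.05);
#'   markers are removed iff their missing fraction exceeds it strictly.
#' @return list with elements `gm` and `report`
#' @export
filter_call_rate <- function(gm, max_missing = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  fail <- marker_missing_rate(gm) > max_missing
  list(gm = gm_subset_markers(gm, !fail),
       report = new_qc_report(n_markers(gm), list(call_rate = sum(fail)),
                              fail))
}

#' Remove low-frequency markers
#'
#' MAF is computed from non-missing calls only; a monomorphic marker has
#' MAF 0 and is removed (not an error).
#'
#' @param gm a [genotype_matrix()]
#' @param min_maf minimum minor allele frequency (default 0.005); markers
#'   with MAF strictly below it are removed.
#' @return list with elements `gm` and `report`
#' @export
filter_maf <- function(gm, min_maf = 0.005) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  fail <- marker_maf(gm) < min_maf
  list(gm = gm_subset_markers(gm, !fail),
       report = new_qc_report(n_markers(gm), list(maf = sum(fail)), fail))
}

#' Apply all marker filters as a union of independent fail flags
#'
#' The three criteria are evaluated independently on the *input* matrix and
#' the union of failing markers is removed, so per-filter counts can
#' overlap; the report carries both the per-filter and the union counts.
#'
#' @param gm a [genotype_matrix()]
#' @param max_missing call-rate threshold, see [filter_call_rate()]
#' @param min_maf MAF threshold, see [filter_maf()]
#' @return list with elements `gm` and `report`
#' @export
apply_qc <- function(gm, max_missing = 0.05, min_maf = 0.005) {
  cls <- chromosome_class(gm$markers)
  f_cls <- cls %in% c("MT", "Y", "unknown")
  f_cr <- marker_missing_rate(gm) > max_missing
  f_maf <- marker_maf(gm) < min_maf
  fail <- f_cls | f_cr | f_maf
  removed <- list(MT = sum(cls == "MT"), Y = sum(cls == "Y"),
                  unknown = sum(cls == "unknown"),
                  call_rate = sum(f_cr), maf = sum(f_maf),
                  union = sum(fail))
  list(gm = gm_subset_markers(gm, !fail),
       report = new_qc_report(n_markers(gm), removed, fail))
}

#' Sliding-window mean of log R ratios
#'
#' Means of `window` consecutive values (stride 1) along markers ordered by
#' position, used to screen an interval for copy-number changes: a
#' deletion depresses the windowed log R ratio.
#'
#' @param values numeric per-marker log R ratios, ordered by position
#' @param pos optional marker positions (bp); when given, each window is
#'   reported at the midpoint of its first and last marker, otherwise at
#'   the midpoint index.
#' @param window window size in markers (default 3)
#' @return data.frame with columns `mid` (window midpoint) and `mean`
#' @export
logr_sliding_window <- function(values, pos = NULL, window = 3L) {
  m <- length(values)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window > m) stop("window (", window, ") exceeds number of markers (",
                       m, ")")
  cs <- c(0, cumsum(values))
  k <- m - window + 1L
  means <- (cs[(window + 1L):(m + 1L)] - cs[seq_len(k)]) / window
  if (is.null(pos)) {
    mid <- (seq_len(k) + (seq_len(k) + window - 1L)) / 2
  } else {
    if (length(pos) != m) stop("pos must match values in length")
    if (is.unsorted(pos)) stop("pos must be sorted")
    mid <- (pos[seq_len(k)] + pos[seq_len(k) + window - 1L]) / 2
  }
  data.frame(mid = mid, mean = means)
}
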