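#' Run-of-homozygosity detection
#'
#' Scans each sample's genotypes along each chromosome for maximal runs of
#' consecutive non-heterozygous calls. A run may contain at most `max_het`
#' heterozygous and `max_missing` missing calls, cannot start or end on a
#' heterozygous or missing call, and must span at least `min_markers`
#' markers and `min_length_bp` base pairs (coordinates are the positions of
#' the first and last marker of the run, 1-based inclusive). With
#' `max_het > 0` maximal runs may overlap; all of them are reported.
#'
#' The defaults (20 markers, 0 heterozygotes, 2 missing, 500 kb) are
#' conservative for a high-density array; there is no canonical parameter
#' set for autozygosity scans, so every threshold is exposed.
#'
#' @param gm a [genotype_matrix()] with markers sorted by (chrom, pos)
#' @param samples sample ids to scan (default: all)
#' @param min_markers minimum markers per run
#' @param max_het maximum heterozygous calls tolerated inside a run
#' @param max_missing maximum missing calls tolerated inside a run
#' @param min_length_bp minimum run length in bp
#' @return data.frame of segments: `sample`, `chrom`, `start`, `end`,
#'   `n_markers`, `n_het`, `n_missing`
#' @export
detect_roh <- function(gm, samples = NULL, min_markers = 20L, max_het = 0L,
                       max_missing = 2L, min_length_bp = 5e5) {
  if (is.null(samples)) samples <- gm$samples
  miss <- setdiff(samples, gm$samples)
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (chr in unique(gm$markers$chrom)) {
    idx <- which(gm$markers$chrom == chr)
    pos <- gm$markers$pos[idx]
    if (is.unsorted(pos)) stop("markers on chromosome ", chr,
                               " are not sorted by position")
    for (s in samples) {
      g <- gm$geno[match(s, gm$samples), idx]
      runs <- .roh_runs(g, min_markers, max_het, max_missing)
      if (!nrow(runs)) next
      keep <- (pos[runs$end_idx] - pos[runs$start_idx] + 1) >= min_length_bp
      runs <- runs[keep, , drop = FALSE]
      if (!nrow(runs)) next
      out[[length(out) + 1L]] <- data.frame(
        sample = s, chrom = chr,
        start = pos[runs$start_idx], end = pos[runs$end_idx],
        n_markers = runs$n_markers, n_het = runs$n_het,
        n_missing = runs$n_missing, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_markers = integer(), n_het = integer(),
                      n_missing = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# maximal runs in one genotype vector; two-pointer over feasibility
# windows, then trimming to homozygous boundaries and containment pruning
.roh_runs <- function(g, min_markers, max_het, max_missing) {
  m <- length(g)
  empty <- data.frame(start_idx = integer(), end_idx = integer(),
                      n_markers = integer(), n_het = integer(),
                      n_missing = integer())
  if (!m) return(empty)
  is_mis <- is.na(g)
  is_het <- !is_mis & g == 1L
  is_hom <- !is_mis & !is_het
  e <- integer(m)
  j <- 0L; nh <- 0L; nm <- 0L
  for (i in seq_len(m)) {
    if (j < i - 1L) { j <- i - 1L; nh <- 0L; nm <- 0L }
    while (j < m) {
      nh2 <- nh + is_het[j + 1L]
      nm2 <- nm + is_mis[j + 1L]
      if (nh2 > max_het || nm2 > max_missing) break
      j <- j + 1L; nh <- nh2; nm <- nm2
    }
    e[i] <- j
    if (j >= i) { nh <- nh - is_het[i]; nm <- nm - is_mis[i] }
  }
  starts <- which(e >= seq_len(m) & c(TRUE, e[-m] < e[-1L]))
  segs <- matrix(integer(), 0, 2)
  for (i in starts) {
    homs <- which(is_hom[i:e[i]])
    if (!length(homs)) next
    s2 <- i + homs[1L] - 1L
    t2 <- i + homs[length(homs)] - 1L
    if (t2 - s2 + 1L < min_markers) next
    segs <- rbind(segs, c(s2, t2))
  }
  if (!nrow(segs)) return(empty)
  segs <- unique(segs)
  # drop segments contained in another (possible after trimming)
  keep <- rep(TRUE, nrow(segs))
  for (i in seq_len(nrow(segs)))
    for (k in seq_len(nrow(segs)))
      if (i != k && keep[i] &&
          segs[k, 1] <= segs[i, 1] && segs[k, 2] >= segs[i, 2] &&
          (segs[k, 1] < segs[i, 1] || segs[k, 2] > segs[i, 2]))
        keep[i] <- FALSE
  segs <- segs[keep, , drop = FALSE]
  data.frame(
    start_idx = segs[, 1], end_idx = segs[, 2],
    n_markers = segs[, 2] - segs[, 1] + 1L,
    n_het = vapply(seq_len(nrow(segs)),
                   function(r) sum(is_het[segs[r, 1]:segs[r, 2]]), 0L),
    n_missing = vapply(seq_len(nrow(segs)),
                       function(r) sum(is_mis[segs[r, 1]:segs[r, 2]]), 0L))
}

#' Intersect per-case homozygosity segments into the shared disease segment
#'
#' Returns the longest interval contained in at least one segment of every
#' case. Candidate left endpoints are segment starts; for each, the right
#' endpoint is the minimum over cases of the furthest covering segment end.
#' An empty intersection is allowed and flagged.
#'
#' @param segments data.frame from [detect_roh()] (columns `sample`,
#'   `chrom`, `start`, `end`)
#' @param case_ids the full case list; a case contributing no segment
#'   forces an empty result (default: the samples present in `segments`)
#' @param region_hint optional list `(chrom, start, end)` restricting the
#'   search
#' @return object of class `shared_segment`: list with `chrom`, `start`,
#'   `end`, `length_bp` (= end - start + 1), `cases` and `empty`
#' @export
intersect_case_segments <- function(segments, case_ids = NULL,
                                    region_hint = NULL) {
  if (is.null(case_ids)) case_ids <- unique(segments$sample)
  empty_res <- structure(list(chrom = NA_character_, start = NA_real_,
                              end = NA_real_, length_bp = 0,
                              cases = case_ids, empty = TRUE),
                         class = "shared_segment")
  if (!length(case_ids) || !nrow(segments)) return(empty_res)
  if (!is.null(region_hint)) {
    segments <- segments[segments$chrom == region_hint$chrom, , drop = FALSE]
    segments$start <- pmax(segments$start, region_hint$start)
    segments$end <- pmin(segments$end, region_hint$end)
    segments <- segments[segments$start <= segments$end, , drop = FALSE]
  }
  segments <- segments[segments$sample %in% case_ids, , drop = FALSE]
  if (!nrow(segments)) return(empty_res)
  best <- NULL
  for (chr in unique(segments$chrom)) {
    sc <- segments[segments$chrom == chr, , drop = FALSE]
    if (length(unique(sc$sample)) < length(case_ids)) next
    for (s in unique(sc$start)) {
      ends <- vapply(case_ids, function(cs) {
        cover <- sc$sample == cs & sc$start <= s & sc$end >= s
        if (!any(cover)) return(-Inf)
        max(sc$end[cover])
      }, 0)
      e <- min(ends)
      if (!is.finite(e) || e < s) next
      if (is.null(best) || (e - s) > (best$end - best$start)) {
        best <- list(chrom = chr, start = s, end = e)
      }
    }
  }
  if (is.null(best)) return(empty_res)
  structure(list(chrom = best$chrom, start = best$start, end = best$end,
                 length_bp = best$end - best$start + 1,
                 cases = case_ids, empty = FALSE),
            class = "shared_segment")
}

#' @export
print.shared_segment <- function(x, ...) {
  if (x$empty) cat("shared_segment: empty (no interval common to all cases)\n")
  else cat(sprintf("shared_segment: %s:%s-%s (%.0f kb) across %d cases\n",
                   x$chrom, format(x$start, big.mark = ","),
                   format(x$end, big.mark = ","), x$length_bp / 1000,
                   length(x$cases)))
  invisible(x)
}

#' Find samples homozygous across the shared segment
#'
#' Screens samples for homozygosity over every marker inside a shared
#' segment, with the same heterozygote/missing tolerances as
#' [detect_roh()]. Used to spot unaffected animals homozygous for the
#' disease-associated region.
#'
#' @param gm a [genotype_matrix()]
#' @param shared a `shared_segment` from [intersect_case_segments()]
#' @param samples sample ids to screen (default: all)
#' @param max_het,max_missing tolerances as in [detect_roh()]
#' @return character vector of homozygous sample ids
#' @export
find_homozygous_controls <- function(gm, shared, samples = NULL,
                                     max_het = 0L, max_missing = 2L) {
  if (shared$empty) stop("shared segment is empty")
  if (is.null(samples)) samples <- gm$samples
  idx <- which(gm$markers$chrom == shared$chrom &
                 gm$markers$pos >= shared$start &
                 gm$markers$pos <= shared$end)
  if (!length(idx)) return(character())
  sub <- gm$geno[match(samples, gm$samples), idx, drop = FALSE]
  n_het <- rowSums(sub == 1L, na.rm = TRUE)
  n_mis <- rowSums(is.na(sub))
  samples[n_het <= max_het & n_mis <= max_missing]
}

#' Write homozygosity segments as BED-like text
#'
#' The native table is 1-based inclusive; `bed = TRUE` converts to
#' standard 0-based half-open BED.
#'
#' @param segments data.frame from [detect_roh()]
#' @param path output file
#' @param bed write true BED coordinates instead of 1-based inclusive
#' @return the path, invisibly
#' @export
write_roh_segments <- function(segments, path, bed = FALSE) {
  out <- segments
  if (bed) {
    out <- data.frame(chrom = segments$chrom, start = segments$start - 1,
                      end = segments$end, name = segments$sample,
                      stringsAsFactors = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
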