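#' Variant table container
#'
#' Sequencing variants with per-sample genotype dosages (0 = hom ref,
#' 1 = het, 2 = hom alt, `NA` = missing). `class` is `"indel"` iff ref and
#' alt allele strings differ in length.
#'
#' @param meta data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`
#'   and optionally `class` (derived from allele lengths when absent)
#' @param geno integer matrix, variants in rows, samples in columns
#' @param samples character vector of sample ids
#' @param gt optional character matrix of raw GT strings (same shape as
#'   `geno`), kept to preserve phase separators on round-trip
#' @return an object of class `variant_table`
#' @export
variant_table <- function(meta, geno, samples, gt = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(meta), nrow(meta) == nrow(geno),
            length(samples) == ncol(geno))
  if (is.null(meta$class))
    meta$class <- ifelse(nchar(meta$ref) != nchar(meta$alt), "indel", "snp")
  if (any(!is.na(meta$pos) & meta$pos < 1)) stop("positions must be >= 1")
  rownames(meta) <- NULL
  structure(list(meta = meta, geno = geno,
                 samples = as.character(samples), gt = gt),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d variants (%d SNP, %d indel) x %d samples\n",
              nrow(x$meta), sum(x$meta$class == "snp"),
              sum(x$meta$class == "indel"), length(x$samples)))
  invisible(x)
}

vt_subset <- function(vt, keep) {
  variant_table(vt$meta[keep, , drop = FALSE],
                vt$geno[keep, , drop = FALSE], vt$samples,
                if (!is.null(vt$gt)) vt$gt[keep, , drop = FALSE])
}

#' Subset variants to a genomic interval
#'
#' Retains records with `start <= pos <= end` (1-based inclusive on both
#' sides) on the given chromosome. Records with a missing chromosome or
#' position are skipped with a warning and counted.
#'
#' @param vt a [variant_table()]
#' @param chrom chromosome label
#' @param start,end interval bounds, 1-based inclusive
#' @return list with `variants` (the subset), `counts` (named: `snp`,
#'   `indel`) and `n_skipped`
#' @export
subset_region <- function(vt, chrom, start, end) {
  stopifnot(start <= end)
  bad <- is.na(vt$meta$chrom) | is.na(vt$meta$pos)
  if (any(bad))
    warning(sum(bad), " malformed record(s) skipped (missing chrom/pos)")
  keep <- !bad & vt$meta$chrom == chrom & vt$meta$pos >= start &
    vt$meta$pos <= end
  sub <- vt_subset(vt, keep)
  list(variants = sub,
       counts = c(snp = sum(sub$meta$class == "snp"),
                  indel = sum(sub$meta$class == "indel")),
       n_skipped = sum(bad))
}

#' Filter variants compatible with recessive inheritance
#'
#' A variant is retained iff every affected sample is homozygous for the
#' alternate allele (`case_mode = "hom_alt"`, the pattern a fully penetrant
#' recessive must show) or merely segregating -- heterozygous or
#' homozygous-alternate -- (`case_mode = "segregating"`, tolerant of
#' genotyping error at low coverage), AND every haplotype-homozygous
#' control (an unaffected animal homozygous for the disease-associated
#' haplotype, which must carry the ancestral, mutation-free version) is
#' heterozygous or homozygous-reference, AND every remaining control is
#' homozygous-reference.
#'
#' @param vt a [variant_table()]
#' @param case_ids affected sample ids
#' @param haplo_hom_control_ids unaffected haplotype-homozygous sample ids
#' @param control_ids remaining control sample ids
#' @param case_mode `"hom_alt"` (default) or `"segregating"`
#' @param missing_policy `"strict"` (default: a missing genotype in any
#'   constrained sample makes the variant incompatible) or `"permissive"`
#'   (missing genotypes are ignored)
#' @return the retained [variant_table()]
#' @export
recessive_filter <- function(vt, case_ids, haplo_hom_control_ids = character(),
                             control_ids,
                             case_mode = c("hom_alt", "segregating"),
                             missing_policy = c("strict", "permissive")) {
  case_mode <- match.arg(case_mode)
  missing_policy <- match.arg(missing_policy)
  ids <- c(case_ids, haplo_hom_control_ids, control_ids)
  if (anyDuplicated(ids))
    stop("case, haplotype-homozygous and control id sets must be disjoint")
  unknown <- setdiff(ids, vt$samples)
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  g_case <- vt$geno[, match(case_ids, vt$samples), drop = FALSE]
  g_hh <- vt$geno[, match(haplo_hom_control_ids, vt$samples), drop = FALSE]
  g_ctl <- vt$geno[, match(control_ids, vt$samples), drop = FALSE]

  all_match <- function(g, pred) {
    ok <- pred(g)
    if (missing_policy == "strict") ok[is.na(ok)] <- FALSE
    else ok[is.na(ok)] <- TRUE
    rowSums(!ok) == 0
  }
  keep <- if (case_mode == "hom_alt") all_match(g_case, function(g) g == 2L)
  else all_match(g_case, function(g) g >= 1L)
  keep <- keep & all_match(g_hh, function(g) g <= 1L)
  keep <- keep & all_match(g_ctl, function(g) g == 0L)
  vt_subset(vt, keep)
}

#' Coding-sequence model
#'
#' A validated coding sequence (5'->3', coding strand): length divisible by
#' three, starting with ATG, ending with a stop codon and containing no
#' internal stop.
#'
#' @param seq character scalar (or `Biostrings::DNAString`) of the CDS
#' @return an object of class `cds_model` with elements `seq` and
#'   `protein_length` (residues, excluding the stop)
#' @export
cds_model <- function(seq) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) %% 3 != 0) stop("CDS length must be divisible by 3")
  if (grepl("[^ACGT]", seq)) stop("CDS must contain only A/C/G/T")
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (codons[1] != "ATG") stop("CDS must begin with ATG")
  if (aa[length(aa)] != "*") stop("CDS must end with a stop codon")
  if (any(aa[-length(aa)] == "*")) stop("CDS contains an internal stop codon")
  structure(list(seq = seq, protein_length = length(codons) - 1L),
            class = "cds_model")
}

#' Annotate the consequence of a single-base substitution in a CDS
#'
#' Locates the affected codon (`codon_index = ceiling(cds_pos / 3)`,
#' 1-based), substitutes the alternate base at the within-codon offset
#' `(cds_pos - 1) mod 3`, and classifies the change by the standard codon
#' table. For a stop-gain the truncated protein length is
#' `codon_index - 1` and `residues_lost` is the wild-type protein length
#' minus the truncated length.
#'
#' @param cds a [cds_model()]
#' @param cds_pos 1-based position in the CDS (coding strand)
#' @param alt_base alternate base (A/C/G/T); must differ from the
#'   reference base at `cds_pos`
#' @return an object of class `consequence`: list with `cds_pos`,
#'   `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `effect` (`"synonymous"`, `"missense"`, `"stop_gain"` or
#'   `"stop_lost"`), `truncated_protein_length` and `residues_lost`
#'   (the last two are `NA` unless the effect is a stop-gain)
#' @export
annotate_consequence <- function(cds, cds_pos, alt_base) {
  stopifnot(inherits(cds, "cds_model"))
  alt_base <- toupper(alt_base)
  if (!alt_base %in% c("A", "C", "G", "T")) stop("alt_base must be A/C/G/T")
  if (cds_pos < 1 || cds_pos > nchar(cds$seq))
    stop("cds_pos out of range [1, ", nchar(cds$seq), "]")
  ref_base <- substr(cds$seq, cds_pos, cds_pos)
  if (ref_base == alt_base)
    stop("alt_base equals the reference base at cds_pos ", cds_pos)
  codon_index <- ceiling(cds_pos / 3)
  offset <- (cds_pos - 1) %% 3
  cstart <- (codon_index - 1) * 3 + 1
  ref_codon <- substr(cds$seq, cstart, cstart + 2)
  alt_codon <- ref_codon
  substr(alt_codon, offset + 1, offset + 1) <- alt_base
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  effect <- if (alt_aa == "*" && ref_aa != "*") "stop_gain"
  else if (ref_aa == "*" && alt_aa != "*") "stop_lost"
  else if (ref_aa == alt_aa) "synonymous"
  else "missense"
  trunc_len <- if (effect == "stop_gain") codon_index - 1L else NA_integer_
  structure(list(cds_pos = cds_pos, codon_index = codon_index,
                 ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_aa = ref_aa, alt_aa = alt_aa, effect = effect,
                 truncated_protein_length = trunc_len,
                 residues_lost = if (effect == "stop_gain")
                   cds$protein_length - trunc_len else NA_integer_),
            class = "consequence")
}

#' @export
print.consequence <- function(x, ...) {
  cat(sprintf("consequence: c.%d %s>%s codon %d (%s -> %s) %s\n",
              x$cds_pos, substr(x$ref_codon, (x$cds_pos - 1) %% 3 + 1,
                                (x$cds_pos - 1) %% 3 + 1),
              substr(x$alt_codon, (x$cds_pos - 1) %% 3 + 1,
                     (x$cds_pos - 1) %% 3 + 1),
              x$codon_index, x$ref_aa, x$alt_aa, x$effect))
  if (identical(x$effect, "stop_gain"))
    cat(sprintf("  truncated protein: %d aa (%d residues lost)\n",
                x$truncated_protein_length, x$residues_lost))
  invisible(x)
}

#' Synthetic stand-in coding sequence for the PLD4 stop-gain example
#'
#' The true bovine PLD4 CDS is not bundled; this builds a *synthetic* CDS
#' constrained to the published facts only: an ATG start, tryptophan codon
#' TGG at codon 215 (so c.643-645 = TGG and the c.G645A substitution turns
#' it into the TGA stop), a 487-residue wild-type protein (214 retained +
#' 273 lost) and a single terminal stop. All other codons are neutral
#' filler and carry no biological meaning.
#'
#' @return a [cds_model()] of length 1,464 nt encoding 487 residues
#' @export
synthetic_pld4_cds <- function() {
  codons <- c("ATG", rep("GGC", 213), "TGG", rep("GCT", 272), "TAA")
  cds_model(paste(codons, collapse = ""))
}
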