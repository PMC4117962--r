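#' Haplotype allele frequency from carrier counts
#'
#' Allele frequency of a haplotype from per-animal carrier counts:
#' `(n_het + 2 n_hom) / (2 n_total)`.
#'
#' @param n_total animals screened
#' @param n_het heterozygous carriers
#' @param n_hom homozygous carriers
#' @return the haplotype allele frequency (proportion)
#' @export
haplotype_frequency <- function(n_total, n_het, n_hom) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_het < 0 || n_hom < 0 || n_het + n_hom > n_total)
    stop("carrier counts inconsistent: need n_het + n_hom <= n_total")
  (n_het + 2 * n_hom) / (2 * n_total)
}

#' Hardy-Weinberg exact test from carrier counts
#'
#' Exact conditional test: given the sample size and the minor-allele
#' count, the probability of each admissible heterozygote count is summed
#' over all outcomes no more probable than the observed one (standard, not
#' mid-p). With no minor allele the p-value is 1 by convention.
#'
#' @inheritParams haplotype_frequency
#' @return the exact p-value in (0, 1\]
#' @export
hwe_exact_test <- function(n_total, n_het, n_hom) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_het < 0 || n_hom < 0 || n_het + n_hom > n_total)
    stop("carrier counts inconsistent")
  rare <- n_het + 2 * n_hom
  # condition on the *minor* allele count; the heterozygote count is
  # symmetric under swapping the allele labels
  rare <- min(rare, 2 * n_total - rare)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, min(rare, 2 * n_total - rare), by = 2)
  lp <- .hwe_log_prob(n_total, rare, hets)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  if (is.na(obs)) stop("observed heterozygote count infeasible")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Hardy-Weinberg chi-square test from carrier counts
#'
#' One-degree-of-freedom goodness-of-fit test of the three genotype counts
#' against Hardy-Weinberg expectations at the sample allele frequency.
#' Included because published haplotype-distribution p-values are often
#' chi-square based; prefer [hwe_exact_test()] for rare alleles.
#'
#' @inheritParams haplotype_frequency
#' @return the chi-square p-value
#' @export
hwe_chisq_test <- function(n_total, n_het, n_hom) {
  if (n_total <= 0) stop("n_total must be positive")
  p <- (n_het + 2 * n_hom) / (2 * n_total)
  if (p == 0 || p == 1) return(1)
  expd <- c((1 - p)^2, 2 * p * (1 - p), p^2) * n_total
  obs <- c(n_total - n_het - n_hom, n_het, n_hom)
  stats::pchisq(sum((obs - expd)^2 / expd), df = 1, lower.tail = FALSE)
}

# log conditional probability of each heterozygote count given n genotypes
# and a minor-allele count
.hwe_log_prob <- function(n, rare, hets) {
  hom_r <- (rare - hets) / 2
  hom_c <- n - hets - hom_r
  lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(hets + 1) - lgamma(hom_c + 1) +
    hets * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
    lgamma(2 * n + 1)
}

#' Concordance between haplotype carriers and mutation carriers
#'
#' Fraction of disease-haplotype carriers that also carry the candidate
#' mutation, at the animal level (heterozygous haplotype carriers that
#' carry the mutation, over heterozygous haplotype carriers) or the copy
#' level (mutation-bearing haplotype copies over all carrier copies).
#'
#' @param n_het_carriers haplotype-heterozygous animals genotyped for the
#'   mutation
#' @param n_mut_among_het of those, animals carrying the mutation
#' @param n_hom_carriers haplotype-homozygous animals genotyped (copy level
#'   only)
#' @param n_mut_copies_among_hom mutation-allele copies observed in the
#'   haplotype homozygotes (copy level only)
#' @param level `"animal"` (default) or `"copy"`
#' @return the concordance (proportion)
#' @export
carrier_concordance <- function(n_het_carriers, n_mut_among_het,
                                n_hom_carriers = 0,
                                n_mut_copies_among_hom = 0,
                                level = c("animal", "copy")) {
  level <- match.arg(level)
  if (n_het_carriers <= 0 && (level == "animal" || n_hom_carriers <= 0))
    stop("no genotyped haplotype carriers")
  if (n_mut_among_het > n_het_carriers)
    stop("mutation carriers cannot exceed genotyped carriers")
  if (level == "animal") {
    n_mut_among_het / n_het_carriers
  } else {
    (n_mut_among_het + n_mut_copies_among_hom) /
      (n_het_carriers + 2 * n_hom_carriers)
  }
}

#' Defect-allele frequency from haplotype frequency and concordance
#'
#' The array-derived haplotype cannot distinguish the mutation-bearing from
#' the ancestral version, so the defect-allele frequency is the haplotype
#' frequency discounted by the concordance.
#'
#' @param haplotype_freq haplotype allele frequency
#' @param concordance fraction of haplotype copies/carriers bearing the
#'   mutation
#' @return their product
#' @export
defect_allele_frequency <- function(haplotype_freq, concordance) {
  stopifnot(haplotype_freq >= 0, haplotype_freq <= 1,
            concordance >= 0, concordance <= 1)
  haplotype_freq * concordance
}

#' Probability that a calf from a given mating is mutant-homozygous
#'
#' Exact transmission probability. A (heterozygous) carrier sire transmits
#' the defect allele with probability 1/2, a verified non-carrier never
#' does. The dam is untested: her paternal allele comes from the maternal
#' grandsire (defect with probability 1/2 if he is a carrier), her maternal
#' allele from the granddam side at the population frequency `pop_freq`;
#' she passes one of her two alleles at random. The calf is homozygous iff
#' both parents transmit.
#'
#' @param sire_carrier is the sire a heterozygous carrier?
#' @param mgs_carrier is the maternal grandsire a heterozygous carrier?
#' @param pop_freq defect-allele frequency on the granddam side
#'   (default 0)
#' @return the homozygosity probability
#' @export
risk_mating_homozygote_prob <- function(sire_carrier, mgs_carrier,
                                        pop_freq = 0) {
  stopifnot(is.logical(sire_carrier), is.logical(mgs_carrier),
            pop_freq >= 0, pop_freq < 1)
  p_sire <- if (sire_carrier) 0.5 else 0
  p_from_mgs <- if (mgs_carrier) 0.5 else 0
  p_dam <- (p_from_mgs + pop_freq) / 2
  p_sire * p_dam
}

#' Expected affected calves per year under random mating
#'
#' Hardy-Weinberg expectation `q^2 * births` for a recessive lethal at
#' allele frequency `q`.
#'
#' @param q defect-allele frequency
#' @param births annual births
#' @return expected affected calves per year
#' @export
expected_affected_per_year <- function(q, births) {
  stopifnot(q >= 0, q <= 1, births >= 0)
  q^2 * births
}

#' Call haplotype carriers from phased data
#'
#' A haplotype copy is a carrier copy iff its allele vector matches the
#' reference haplotype exactly across every segment marker. Samples with
#' missing phased data over the segment are excluded and reported.
#'
#' @param panel a `phased_panel` (see [simulate_cohort()]) or any list
#'   with `hap1`, `hap2`, `markers`, `samples`
#' @param segment optional `shared_segment` or list `(chrom, start, end)`;
#'   default: the panel's own founder segment
#' @param reference_haplotype allele vector over the segment markers;
#'   default: the panel's founder haplotype
#' @return list with `counts` (named: `n_total`, `n_het`, `n_hom`),
#'   `status` (data.frame of sample id and carrier copy count) and
#'   `excluded` (ids dropped for missing phase)
#' @export
call_haplotype_carriers <- function(panel, segment = NULL,
                                    reference_haplotype = NULL) {
  if (is.null(segment)) segment <- panel$segment
  idx <- which(panel$markers$chrom == segment$chrom &
                 panel$markers$pos >= segment$start &
                 panel$markers$pos <= segment$end)
  if (!length(idx)) stop("no phased markers inside the segment")
  if (is.null(reference_haplotype)) {
    if (is.null(panel$founder_haplotype))
      stop("reference_haplotype required (panel carries none)")
    if (identical(idx, panel$core_idx)) {
      reference_haplotype <- panel$founder_haplotype
    } else {
      common <- intersect(idx, panel$core_idx)
      if (!length(common)) stop("segment does not overlap the panel's founder segment")
      idx <- common
      reference_haplotype <- panel$founder_haplotype[match(common, panel$core_idx)]
    }
  }
  if (length(reference_haplotype) != length(idx))
    stop("reference_haplotype length must match segment marker count")
  h1 <- panel$hap1[, idx, drop = FALSE]
  h2 <- panel$hap2[, idx, drop = FALSE]
  bad <- rowSums(is.na(h1)) > 0 | rowSums(is.na(h2)) > 0
  ref <- matrix(reference_haplotype, nrow(h1), length(idx), byrow = TRUE)
  c1 <- rowSums(h1 != ref) == 0
  c2 <- rowSums(h2 != ref) == 0
  copies <- as.integer(c1) + as.integer(c2)
  copies[bad] <- NA_integer_
  ok <- !bad
  list(counts = c(n_total = sum(ok),
                  n_het = sum(copies[ok] == 1L),
                  n_hom = sum(copies[ok] == 2L)),
       status = data.frame(id = panel$samples, carrier_copies = copies,
                           stringsAsFactors = FALSE),
       excluded = panel$samples[bad])
}
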