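#' Configuration for the synthetic recessive-defect cohort
#'
#' Bundles every parameter of the forward simulation and validates it. The
#' defaults describe the study system the pipeline targets: a cohort of
#' 1,347 genotyped animals of which 8 affected calves are homozygous for a
#' founder haplotype segment on chromosome 21 (70,550,045-71,573,501 bp),
#' the haplotype segregating at 1.86% in the population, the nonsense
#' allele riding on 59.5% of haplotype copies, 7,086 SNPs and 574 InDels
#' called inside the segment, and calf survival calibrated to the observed
#' 300-day survival of 0.903 (non-risk matings) and 0.834 (risk matings).
#' The simulated genome is scaled down to `n_chroms` chromosomes of
#' `n_markers_per_chrom` markers each; the last chromosome carries the
#' founder segment.
#'
#' @param n_samples number of genotyped animals
#' @param n_cases number of affected (mutant-homozygous) animals planted
#' @param n_chroms number of simulated chromosomes
#' @param n_markers_per_chrom array markers per chromosome
#' @param segment_chrom chromosome label carrying the founder segment
#' @param segment_start,segment_end founder segment bounds, 1-based
#'   inclusive bp
#' @param haplotype_freq population frequency of the founder haplotype
#'   among non-planted haplotype copies
#' @param mutation_on_haplotype fraction of founder-haplotype copies that
#'   carry the nonsense allele (the mutation arose on an already
#'   segregating haplotype, so a mutant copy is always a founder copy)
#' @param array_missing_rate per-call missing rate injected into the array
#'   genotypes
#' @param maf_floor,maf_range per-marker minor allele frequencies are drawn
#'   uniformly from `[maf_floor, maf_floor + maf_range]`
#' @param seq_region_n_snps,seq_region_n_indels sequence variants emitted
#'   inside the segment (the planted causal SNP counts towards
#'   `seq_region_n_snps`)
#' @param seq_n_outside sequence variants emitted outside the segment
#' @param causal_pos bp position of the planted causal variant (must lie
#'   inside the segment)
#' @param erosion_mean_markers mean of the geometric erosion (in markers)
#'   trimming each edge of a founder-haplotype copy, emulating historical
#'   recombination at the segment flanks
#' @param erosion_flank_markers number of flanking markers beyond the core
#'   segment over which a founder copy may extend; erosion eats into this
#'   flank but never into the core, so every copy carries the full core
#'   segment
#' @param hazard_base baseline death hazard per day for non-homozygous
#'   calves; default solved from a 300-day survival of 0.903
#' @param hazard_hom_multiplier hazard multiplier for mutant homozygotes;
#'   default solved so a 12.5%-homozygote risk group has 300-day survival
#'   0.834 when the remainder survives at 0.903
#' @param censor_day administrative right-censoring age in days
#' @param n_risk_matings,n_nonrisk_matings calves simulated from
#'   carrier-sire x carrier-MGS and non-carrier-sire x carrier-MGS matings
#' @param seed integer seed; a fixed seed gives bit-identical output
#'
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(n_samples = 1347L, n_cases = 8L, n_chroms = 3L,
                       n_markers_per_chrom = 150L,
                       segment_chrom = "21",
                       segment_start = 70550045, segment_end = 71573501,
                       haplotype_freq = 0.0186,
                       mutation_on_haplotype = 0.595,
                       array_missing_rate = 0.01,
                       maf_floor = 0.05, maf_range = 0.40,
                       seq_region_n_snps = 7086L,
                       seq_region_n_indels = 574L,
                       seq_n_outside = 500L,
                       causal_pos = 71001232,
                       erosion_mean_markers = 5,
                       erosion_flank_markers = 15L,
                       hazard_base = -log(0.903) / 300,
                       hazard_hom_multiplier =
                         log((0.834 - (1 - 0.125) * 0.903) / 0.125) /
                         log(0.903),
                       censor_day = 300,
                       n_risk_matings = 1213L, n_nonrisk_matings = 2552L,
                       seed = 1L) {
  cfg <- structure(mget(names(formals(sim_config))), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks ranges and feasibility; an infeasible case count raises an error
#' naming the violated constraint. Called by [sim_config()] and again by
#' [run_pipeline()] before any stage runs.
#'
#' @param cfg a `sim_config`
#' @return `cfg`, invisibly
#' @export
validate_sim_config <- function(cfg) {
  chk_prop <- function(x, nm) {
    if (!is.numeric(cfg[[x]]) || cfg[[x]] < 0 || cfg[[x]] > 1)
      stop(nm, " must be a proportion in [0, 1]", call. = FALSE)
  }
  chk_prop("haplotype_freq", "haplotype_freq")
  chk_prop("mutation_on_haplotype", "mutation_on_haplotype")
  chk_prop("array_missing_rate", "array_missing_rate")
  chk_prop("maf_floor", "maf_floor")
  if (cfg$maf_floor + cfg$maf_range > 0.5 + 1e-12)
    stop("maf_floor + maf_range must not exceed 0.5", call. = FALSE)
  if (cfg$segment_start >= cfg$segment_end)
    stop("segment_start must be < segment_end", call. = FALSE)
  if (cfg$n_cases > cfg$n_samples)
    stop("infeasible config: n_cases (", cfg$n_cases,
         ") exceeds n_samples (", cfg$n_samples, ")", call. = FALSE)
  if (cfg$n_cases > 0 &&
      (cfg$haplotype_freq <= 0 || cfg$mutation_on_haplotype <= 0))
    stop("infeasible config: n_cases > 0 requires haplotype_freq > 0 and ",
         "mutation_on_haplotype > 0 (no mutant homozygote is achievable ",
         "otherwise)", call. = FALSE)
  if (cfg$hazard_base <= 0 || cfg$hazard_hom_multiplier <= 0)
    stop("hazard rates must be positive", call. = FALSE)
  if (cfg$causal_pos < cfg$segment_start || cfg$causal_pos > cfg$segment_end)
    stop("causal_pos must lie inside the segment", call. = FALSE)
  if (cfg$n_chroms < 1 || cfg$n_markers_per_chrom < 2)
    stop("need at least 1 chromosome with 2 markers", call. = FALSE)
  invisible(cfg)
}

# marker map for the scaled-down genome: the segment chromosome spans the
# core segment plus ~0.5 Mb on each side; other chromosomes are generic.
sim_marker_map <- function(cfg) {
  labs <- c(as.character(seq_len(cfg$n_chroms - 1L)), cfg$segment_chrom)
  pieces <- lapply(seq_along(labs), function(i) {
    m <- cfg$n_markers_per_chrom
    if (labs[i] == cfg$segment_chrom && i == length(labs)) {
      pad <- 525000
      pos <- round(seq(cfg$segment_start - pad, cfg$segment_end + pad,
                       length.out = m))
    } else {
      pos <- seq(1e6, by = 5e4, length.out = m)
    }
    data.frame(id = sprintf("snp_%s_%04d", labs[i], seq_len(m)),
               chrom = labs[i], pos = as.numeric(pos), class = "snp",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Simulate a genotyped cohort with a planted founder haplotype
#'
#' Forward-simulates `2 * n_samples` phased haplotypes: marker alleles are
#' drawn independently per haplotype (no background LD), then
#' founder-haplotype copies are dropped onto non-case samples i.i.d. at
#' `haplotype_freq`, each carrying the nonsense allele with probability
#' `mutation_on_haplotype`. Exactly `n_cases` samples are made homozygous
#' for the mutant founder copy and flagged affected; a non-case sample that
#' becomes mutant-homozygous by chance has one copy demoted to the
#' wild-type haplotype version (the two versions are identical over the
#' segment, so the array genotypes are untouched). Founder copies share
#' identical alleles across all core-segment markers and extend into the
#' flank by a geometrically eroded amount, emulating recombination at the
#' segment edges. Missing calls are injected uniformly at random.
#'
#' Sire and maternal-grandsire carrier labels are assigned consistently
#' with transmission: a mutant paternal copy implies a carrier sire; a
#' mutant maternal copy implies a carrier dam whose mutant allele came from
#' the MGS with probability 1/2; otherwise carrier status is drawn at the
#' background carrier rate.
#'
#' @param config a [sim_config()]
#' @return list with elements `panel` (a `phased_panel`: haplotype allele
#'   matrices `hap1`/`hap2`, per-copy `founder`/`mutant` flags, the founder
#'   allele vector and segment marker indices), `gm` (a
#'   [genotype_matrix()] with missing calls injected) and `cohort`
#'   (data.frame of per-animal id, affection status, copy counts and
#'   sire/MGS carrier flags).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  mk <- sim_marker_map(config)
  n <- config$n_samples
  m <- nrow(mk)
  maf <- stats::runif(m, config$maf_floor, config$maf_floor + config$maf_range)
  hap1 <- matrix(stats::rbinom(n * m, 1L, rep(maf, each = n)), n, m)
  hap2 <- matrix(stats::rbinom(n * m, 1L, rep(maf, each = n)), n, m)

  seg_idx <- which(mk$chrom == config$segment_chrom &
                     mk$pos >= config$segment_start &
                     mk$pos <= config$segment_end)
  if (!length(seg_idx))
    stop("no markers fall inside the founder segment")
  a <- min(seg_idx); b <- max(seg_idx)
  on_chrom <- range(which(mk$chrom == config$segment_chrom))
  flank <- min(config$erosion_flank_markers, a - on_chrom[1],
               on_chrom[2] - b)
  ext <- (a - flank):(b + flank)
  founder_hap <- stats::rbinom(length(ext), 1L, maf[ext])

  cases <- if (config$n_cases > 0) sample.int(n, config$n_cases) else integer(0)
  noncase <- setdiff(seq_len(n), cases)
  founder1 <- founder2 <- logical(n)
  founder1[noncase] <- stats::runif(length(noncase)) < config$haplotype_freq
  founder2[noncase] <- stats::runif(length(noncase)) < config$haplotype_freq
  mutant1 <- founder1 & stats::runif(n) < config$mutation_on_haplotype
  mutant2 <- founder2 & stats::runif(n) < config$mutation_on_haplotype
  founder1[cases] <- founder2[cases] <- TRUE
  mutant1[cases] <- mutant2[cases] <- TRUE
  # demote chance mutant homozygotes so exactly n_cases samples are affected
  chance_hom <- intersect(noncase, which(mutant1 & mutant2))
  mutant2[chance_hom] <- FALSE

  p_geom <- 1 / (1 + config$erosion_mean_markers)
  paint <- function(hap, flag) {
    idx <- which(flag)
    if (!length(idx)) return(hap)
    e1 <- pmin(stats::rgeom(length(idx), p_geom), flank)
    e2 <- pmin(stats::rgeom(length(idx), p_geom), flank)
    for (k in seq_along(idx)) {
      cov <- (a - flank + e1[k]):(b + flank - e2[k])
      hap[idx[k], cov] <- founder_hap[cov - (a - flank) + 1L]
    }
    hap
  }
  hap1 <- paint(hap1, founder1)
  hap2 <- paint(hap2, founder2)

  geno <- hap1 + hap2
  if (config$array_missing_rate > 0) {
    geno[stats::runif(n * m) < config$array_missing_rate] <- NA_integer_
  }
  samples <- sprintf("FV%05d", seq_len(n))

  q <- config$haplotype_freq * config$mutation_on_haplotype
  sire_carrier <- mutant1 | stats::runif(n) < q
  mgs_carrier <- (mutant2 & stats::runif(n) < 0.5) | stats::runif(n) < q

  affected <- mutant1 & mutant2
  cohort <- data.frame(
    id = samples,
    affected = affected,
    n_founder_copies = as.integer(founder1) + as.integer(founder2),
    n_mutant_copies = as.integer(mutant1) + as.integer(mutant2),
    sire_carrier = sire_carrier,
    mgs_carrier = mgs_carrier,
    stringsAsFactors = FALSE)

  panel <- structure(list(
    hap1 = hap1, hap2 = hap2,
    founder1 = founder1, founder2 = founder2,
    mutant1 = mutant1, mutant2 = mutant2,
    markers = mk, samples = samples,
    founder_haplotype = founder_hap[seg_idx - (a - flank) + 1L],
    core_idx = seg_idx, ext_idx = ext,
    segment = list(chrom = config$segment_chrom,
                   start = config$segment_start,
                   end = config$segment_end),
    config = config), class = "phased_panel")

  list(panel = panel,
       gm = genotype_matrix(geno, mk, samples),
       cohort = cohort)
}

#' @export
print.phased_panel <- function(x, ...) {
  cat(sprintf("phased_panel: %d samples x %d markers; %d founder copies (%d mutant)\n",
              length(x$samples), ncol(x$hap1),
              sum(x$founder1) + sum(x$founder2),
              sum(x$mutant1) + sum(x$mutant2)))
  invisible(x)
}

#' Simulate sequence variants in and around the founder segment
#'
#' Emits `seq_region_n_snps` SNP and `seq_region_n_indels` InDel records at
#' distinct positions inside the segment plus `n_outside` records outside
#' it, with genotypes for every panel sample. Background genotypes are
#' drawn under Hardy-Weinberg at a per-variant frequency; exactly one
#' record -- the planted causal SNP at `config$causal_pos` -- carries the
#' causal pattern: homozygous-alternate in mutant homozygotes, heterozygous
#' in mutant-heterozygotes, homozygous-reference otherwise. Any background
#' record that would be compatible with recessive inheritance by chance has
#' one case genotype perturbed to heterozygous, so the causal pattern is
#' unique (or, with `decoys = TRUE`, shared only by three planted decoy
#' records mirroring the classical compatible-variant table: an intergenic
#' InDel that is also heterozygous in haplotype-homozygous controls, and
#' two SNPs).
#'
#' @param config a [sim_config()]
#' @param panel a `phased_panel` from [simulate_cohort()]
#' @param n_outside records emitted outside the segment
#' @param decoys also plant the three decoy records
#' @return a `variant_table`: list with `meta` (chrom, pos, id, ref, alt,
#'   class), `geno` (variants x samples dosage matrix) and `samples`
#' @export
simulate_region_variants <- function(config, panel,
                                     n_outside = config$seq_n_outside,
                                     decoys = FALSE) {
  validate_sim_config(config)
  set.seed(config$seed + 1000L)
  n <- length(panel$samples)
  ns <- as.integer(config$seq_region_n_snps)
  ni <- as.integer(config$seq_region_n_indels)
  span <- config$segment_end - config$segment_start + 1
  if (ns + ni > span)
    stop("more in-segment variants requested (", ns + ni,
         ") than available integer positions (", span, ")")
  n_in <- ns + ni
  if (n_in < 1L && n_outside < 1L)
    return(variant_table(
      data.frame(chrom = character(), pos = numeric(), id = character(),
                 ref = character(), alt = character(), class = character(),
                 stringsAsFactors = FALSE),
      matrix(integer(), 0, n), panel$samples))

  decoy_pos <- c(70679787, 70842696, 71315111)
  decoy_id <- c("rs381259516", "rs384306864", "rs385301007")
  decoy_class <- c("indel", "snp", "snp")
  reserved <- config$causal_pos
  if (decoys) reserved <- c(reserved, decoy_pos)

  meta <- NULL
  geno <- NULL
  if (n_in >= 1L) {
    # background in-segment positions, avoiding reserved ones
    pool <- sample.int(span, min(span, n_in + length(reserved))) +
      config$segment_start - 1
    pool <- setdiff(pool, reserved)
    n_bg <- n_in - 1L - if (decoys) 3L else 0L
    if (n_bg < 0L) stop("seq_region counts too small to hold planted records")
    if (n_bg > 0L) {
      pos_bg <- pool[seq_len(n_bg)]
      cls_bg <- rep("snp", n_bg)
      # causal SNP and decoy classes count against the requested totals
      ni_bg <- ni - if (decoys) 1L else 0L
      if (ni_bg > 0)
        cls_bg[sample.int(n_bg, min(ni_bg, n_bg))] <- "indel"
      meta <- data.frame(chrom = config$segment_chrom, pos = pos_bg,
                         id = ".", ref = NA_character_, alt = NA_character_,
                         class = cls_bg, stringsAsFactors = FALSE)
    }
  }

  if (n_outside >= 1L) {
    lo <- max(1, config$segment_start - 2e6)
    off_pool <- c(seq(lo, config$segment_start - 1),
                  seq(config$segment_end + 1, config$segment_end + 2e6))
    pos_out <- sample(off_pool, n_outside)
    meta_out <- data.frame(chrom = config$segment_chrom, pos = pos_out,
                           id = ".", ref = NA_character_,
                           alt = NA_character_,
                           class = ifelse(stats::runif(n_outside) < 0.075,
                                          "indel", "snp"),
                           stringsAsFactors = FALSE)
    meta <- rbind(meta, meta_out)
  }

  v_bg <- nrow(meta)
  if (v_bg > 0) {
    f <- stats::runif(v_bg, 0.02, 0.5)
    geno <- matrix(stats::rbinom(v_bg * n, 2L, rep(f, times = n)), v_bg, n)
  } else {
    geno <- matrix(integer(), 0, n)
  }

  # planted causal record
  mutcopies <- as.integer(panel$mutant1) + as.integer(panel$mutant2)
  if (n_in >= 1L) {
    meta <- rbind(meta,
                  data.frame(chrom = config$segment_chrom,
                             pos = config$causal_pos, id = "rs378824791",
                             ref = "G", alt = "A", class = "snp",
                             stringsAsFactors = FALSE))
    geno <- rbind(geno, mutcopies)
  }

  affected <- panel$mutant1 & panel$mutant2
  haplo_hom <- panel$founder1 & panel$founder2 & !affected
  if (decoys && n_in >= 1L) {
    for (k in 1:3) {
      g <- mutcopies
      if (k == 1L) g[haplo_hom] <- pmax(g[haplo_hom], 1L)
      meta <- rbind(meta,
                    data.frame(chrom = config$segment_chrom,
                               pos = decoy_pos[k], id = decoy_id[k],
                               ref = if (decoy_class[k] == "indel") "GA" else "C",
                               alt = if (decoy_class[k] == "indel") "G" else "T",
                               class = decoy_class[k],
                               stringsAsFactors = FALSE))
      geno <- rbind(geno, g)
    }
  }

  # make the causal pattern unique among background records
  planted <- meta$id != "."
  if (any(affected) && any(!planted)) {
    bg <- which(!planted)
    ok_cases <- rowSums(geno[bg, affected, drop = FALSE] == 2L) == sum(affected)
    ok_hh <- rowSums(geno[bg, haplo_hom, drop = FALSE] <= 1L) == sum(haplo_hom)
    rest <- !affected & !haplo_hom
    ok_rest <- rowSums(geno[bg, rest, drop = FALSE] == 0L) == sum(rest)
    clash <- bg[ok_cases & ok_hh & ok_rest]
    if (length(clash)) geno[clash, which(affected)[1]] <- 1L
  }

  # ref/alt alleles for background records
  bases <- c("A", "C", "G", "T")
  todo <- which(is.na(meta$ref))
  if (length(todo)) {
    ref <- sample(bases, length(todo), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    ind <- meta$class[todo] == "indel"
    ins <- stats::runif(sum(ind)) < 0.5
    ext_len <- sample.int(3, sum(ind), replace = TRUE)
    extra <- vapply(ext_len, function(l)
      paste(sample(bases, l, replace = TRUE), collapse = ""), "")
    alt[ind][ins] <- paste0(ref[ind][ins], extra[ins])
    ref[ind][!ins] <- paste0(ref[ind][!ins], extra[!ins])
    meta$ref[todo] <- ref
    meta$alt[todo] <- alt
  }

  ord <- order(meta$pos)
  variant_table(meta[ord, , drop = FALSE],
                geno[ord, , drop = FALSE], panel$samples)
}

#' Simulate calves from risk and non-risk matings
#'
#' Risk matings (carrier sire x carrier MGS) produce a mutant-homozygous
#' calf with the exact transmission probability 1/8 (=
#' [risk_mating_homozygote_prob()] with a carrier sire and carrier MGS and
#' no population term); non-risk matings (non-carrier sire x carrier MGS)
#' cannot produce one.
#'
#' @param config a [sim_config()]
#' @return data.frame of calves: id, group (`"risk"`/`"nonrisk"`),
#'   sire/MGS carrier flags and the latent `is_hom` status
#' @export
simulate_matings <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 2000L)
  nr <- as.integer(config$n_risk_matings)
  nn <- as.integer(config$n_nonrisk_matings)
  p_hom <- risk_mating_homozygote_prob(TRUE, TRUE, 0)
  data.frame(
    id = sprintf("calf%05d", seq_len(nr + nn)),
    group = rep(c("risk", "nonrisk"), c(nr, nn)),
    sire_carrier = rep(c(TRUE, FALSE), c(nr, nn)),
    mgs_carrier = TRUE,
    is_hom = c(stats::runif(nr) < p_hom, rep(FALSE, nn)),
    stringsAsFactors = FALSE)
}

#' Simulate survival records for a set of calves
#'
#' Ages at death are exponential with per-day hazard `hazard_base`,
#' multiplied by `hazard_hom_multiplier` for mutant homozygotes; animals
#' alive at `censor_day` are administratively censored there.
#'
#' @param cohort data.frame with at least `id`, `is_hom` and `group`
#'   columns (e.g. from [simulate_matings()])
#' @param config a [sim_config()]
#' @return data.frame of records: id, time (days), event (1 = died,
#'   0 = censored), group
#' @export
simulate_survival <- function(cohort, config) {
  validate_sim_config(config)
  set.seed(config$seed + 3000L)
  rate <- config$hazard_base *
    ifelse(cohort$is_hom, config$hazard_hom_multiplier, 1)
  t_death <- stats::rexp(nrow(cohort), rate)
  event <- as.integer(t_death <= config$censor_day)
  data.frame(id = cohort$id,
             time = pmin(t_death, config$censor_day),
             event = event,
             group = cohort$group,
             stringsAsFactors = FALSE)
}
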