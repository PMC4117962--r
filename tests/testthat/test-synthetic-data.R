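test_that("frequency-zero config yields no founder copies or affecteds", {
  cfg <- sim_config(n_samples = 60, n_cases = 0, haplotype_freq = 0,
                    mutation_on_haplotype = 0, n_markers_per_chrom = 40,
                    seed = 2)
  sim <- simulate_cohort(cfg)
  expect_equal(sum(sim$cohort$n_founder_copies), 0)
  expect_equal(sum(sim$cohort$affected), 0)
})

test_that("identical seeds give bit-identical output", {
  cfg <- sim_config(n_samples = 80, n_markers_per_chrom = 50, seed = 7)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  s1 <- simulate_cohort(cfg)
  v1 <- simulate_region_variants(cfg, s1$panel)
  v2 <- simulate_region_variants(cfg, s1$panel)
  expect_identical(v1, v2)
  expect_false(identical(s1, simulate_cohort(sim_config(
    n_samples = 80, n_markers_per_chrom = 50, seed = 8))))
})

test_that("infeasible configurations raise errors naming the constraint", {
  expect_error(sim_config(n_samples = 5, n_cases = 6), "n_cases")
  expect_error(sim_config(n_cases = 2, haplotype_freq = 0), "infeasible")
  expect_error(sim_config(haplotype_freq = 1.2), "proportion")
  expect_error(sim_config(segment_start = 10, segment_end = 5),
               "segment_start")
  expect_error(sim_config(seq_region_n_snps = 3e6, seq_region_n_indels = 0)
               |> simulate_region_variants(
                 simulate_cohort(sim_config(n_samples = 10,
                                            n_markers_per_chrom = 40,
                                            seed = 1))$panel),
               "positions")
})

test_that("realized founder-haplotype frequency matches the binomial target", {
  cfg <- sim_config(n_samples = 50000, n_cases = 8, n_markers_per_chrom = 12,
                    haplotype_freq = 0.0186, mutation_on_haplotype = 0.595,
                    array_missing_rate = 0, seed = 13)
  sim <- simulate_cohort(cfg)
  freq <- sum(sim$cohort$n_founder_copies) / (2 * cfg$n_samples)
  sd3 <- 3 * sqrt(0.0186 * (1 - 0.0186) / (2 * cfg$n_samples))
  expect_lt(abs(freq - 0.0186), sd3 + 16 / (2 * cfg$n_samples))
  # mutation concordance among founder copies
  copies <- sum(sim$cohort$n_founder_copies)
  mut <- sum(sim$cohort$n_mutant_copies)
  expect_lt(abs(mut / copies - 0.595),
            3 * sqrt(0.595 * 0.405 / copies) + 0.01)
})

test_that("genotypes derive from haplotypes and cases are founder-homozygous", {
  cfg <- sim_config(n_samples = 100, n_cases = 5, n_markers_per_chrom = 60,
                    array_missing_rate = 0.02, seed = 4)
  sim <- simulate_cohort(cfg)
  p <- sim$panel
  derived <- p$hap1 + p$hap2
  obs <- sim$gm$geno
  ok <- !is.na(obs)
  expect_true(all(obs[ok] == derived[ok]))
  expect_true(all(obs[ok] %in% 0:2))
  # every case carries two founder copies identical over the full core
  cases <- which(sim$cohort$affected)
  expect_length(cases, 5)
  ref <- p$founder_haplotype
  for (i in cases) {
    expect_equal(unname(p$hap1[i, p$core_idx]), ref)
    expect_equal(unname(p$hap2[i, p$core_idx]), ref)
  }
})

test_that("region variants: counts, planted causal pattern, decoys", {
  cfg <- sim_config(n_samples = 40, n_cases = 2, n_markers_per_chrom = 40,
                    seq_region_n_snps = 7086, seq_region_n_indels = 574,
                    seq_n_outside = 500, seed = 9)
  sim <- simulate_cohort(cfg)
  vt <- simulate_region_variants(cfg, sim$panel)
  reg <- subset_region(vt, cfg$segment_chrom, cfg$segment_start,
                       cfg$segment_end)
  expect_equal(unname(reg$counts["snp"]), 7086)
  expect_equal(unname(reg$counts["indel"]), 574)
  expect_equal(sum(reg$counts), 7660)
  expect_equal(nrow(vt$meta), 7660 + 500)
  # the planted causal record tracks the panel's mutant-copy flags exactly
  causal <- which(vt$meta$id == "rs378824791")
  expect_length(causal, 1)
  truth <- as.integer(sim$panel$mutant1) + as.integer(sim$panel$mutant2)
  expect_equal(unname(vt$geno[causal, ]), truth)
  # empty in-segment request
  cfg0 <- sim_config(n_samples = 40, n_cases = 2, n_markers_per_chrom = 40,
                     seq_region_n_snps = 0, seq_region_n_indels = 0,
                     seq_n_outside = 10, seed = 9)
  vt0 <- simulate_region_variants(cfg0, sim$panel)
  reg0 <- subset_region(vt0, cfg0$segment_chrom, cfg0$segment_start,
                        cfg0$segment_end)
  expect_equal(nrow(reg0$variants$meta), 0)
  # decoys reproduce the four-record compatible table
  vtd <- simulate_region_variants(cfg, sim$panel, decoys = TRUE)
  expect_setequal(
    vtd$meta$id[vtd$meta$id != "."],
    c("rs381259516", "rs384306864", "rs378824791", "rs385301007"))
  regd <- subset_region(vtd, cfg$segment_chrom, cfg$segment_start,
                        cfg$segment_end)
  expect_equal(sum(regd$counts), 7660)
})

test_that("survival simulator matches its closed-form survival function", {
  cfg <- sim_config(n_risk_matings = 0, n_nonrisk_matings = 100000, seed = 21)
  mat <- simulate_matings(cfg)
  rec <- simulate_survival(mat, cfg)
  s300 <- mean(rec$event == 0) # survivors are exactly the censored
  expected <- exp(-300 * cfg$hazard_base)
  se <- sqrt(expected * (1 - expected) / nrow(rec))
  expect_lt(abs(s300 - expected), 3 * se)
  # homozygote hazard scales by the multiplier
  cfg2 <- sim_config(n_risk_matings = 0, n_nonrisk_matings = 50000, seed = 22)
  mat2 <- simulate_matings(cfg2)
  mat2$is_hom <- TRUE
  rec2 <- simulate_survival(mat2, cfg2)
  s300h <- mean(rec2$event == 0)
  exp_h <- exp(-300 * cfg2$hazard_base * cfg2$hazard_hom_multiplier)
  expect_lt(abs(s300h - exp_h), 3 * sqrt(exp_h * (1 - exp_h) / nrow(rec2)))
})

test_that("null hazard multiplier leaves the two mating groups exchangeable", {
  cfg <- sim_config(hazard_hom_multiplier = 1, n_risk_matings = 2000,
                    n_nonrisk_matings = 2000, seed = 31)
  rec <- simulate_survival(simulate_matings(cfg), cfg)
  parts <- split(rec, rec$group)
  lr <- logrank_test(parts$risk, parts$nonrisk)
  expect_gt(lr$p, 0.001)
})
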