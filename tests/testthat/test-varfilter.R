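make_vt <- function(geno, pos = NULL, chrom = "21", ref = "A", alt = "C") {
  geno <- as.matrix(geno)
  v <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(v) * 100
  meta <- data.frame(chrom = chrom, pos = pos,
                     id = sprintf("v%04d", seq_len(v)),
                     ref = rep_len(ref, v), alt = rep_len(alt, v),
                     stringsAsFactors = FALSE)
  variant_table(meta, geno, sprintf("s%03d", seq_len(ncol(geno))))
}

test_that("region subsetting is 1-based inclusive on both bounds", {
  vt <- make_vt(matrix(0L, 5, 2), pos = c(99, 100, 150, 200, 201))
  res <- subset_region(vt, "21", 100, 200)
  expect_equal(res$variants$meta$pos, c(100, 150, 200))
  expect_equal(sum(res$counts), 3)
  # no overlap
  expect_equal(nrow(subset_region(vt, "21", 500, 600)$variants$meta), 0)
  expect_equal(nrow(subset_region(vt, "7", 1, 1e9)$variants$meta), 0)
  # malformed records are skipped with a warning and counted
  vt$meta$pos[2] <- NA
  expect_warning(res2 <- subset_region(vt, "21", 1, 1e9), "malformed")
  expect_equal(res2$n_skipped, 1)
})

test_that("recessive filter matches the triple-loop oracle", {
  set.seed(53)
  for (case_mode in c("hom_alt", "segregating")) {
    geno <- matrix(sample(c(0:2, NA), 100 * 20, replace = TRUE,
                          prob = c(0.5, 0.25, 0.2, 0.05)), 100, 20)
    vt <- make_vt(geno)
    ids <- vt$samples
    keep_want <- recessive_oracle(vt, ids[1:2], ids[3:4], ids[5:15],
                                  case_mode)
    got <- recessive_filter(vt, ids[1:2], ids[3:4], ids[5:15],
                            case_mode = case_mode)
    expect_equal(got$meta$id, vt$meta$id[keep_want])
  }
})

test_that("recessive filter honours modes, missing policy and guards", {
  # variant hom_ref in everyone is excluded
  vt <- make_vt(matrix(0L, 3, 6))
  expect_equal(nrow(recessive_filter(vt, "s001", character(),
                                     sprintf("s%03d", 2:6))$meta), 0)
  # segregating mode admits het cases that hom_alt mode rejects
  g <- rbind(c(1L, 0L, 0L), c(2L, 0L, 0L))
  vt2 <- make_vt(g)
  expect_equal(nrow(recessive_filter(vt2, "s001", character(),
                                     c("s002", "s003"))$meta), 1)
  expect_equal(nrow(recessive_filter(vt2, "s001", character(),
                                     c("s002", "s003"),
                                     case_mode = "segregating")$meta), 2)
  # strict vs permissive missing handling
  g3 <- rbind(c(2L, NA, 0L))
  vt3 <- make_vt(g3)
  expect_equal(nrow(recessive_filter(vt3, "s001", character(),
                                     c("s002", "s003"))$meta), 0)
  expect_equal(nrow(recessive_filter(vt3, "s001", character(),
                                     c("s002", "s003"),
                                     missing_policy = "permissive")$meta), 1)
  expect_error(recessive_filter(vt3, "s001", character(), c("s001", "s002")),
               "disjoint")
  expect_error(recessive_filter(vt3, "s001", character(), "nope"), "unknown")
})

test_that("enlarging the control set never enlarges the retained set", {
  set.seed(59)
  geno <- matrix(sample(0:2, 60 * 30, replace = TRUE,
                        prob = c(0.6, 0.25, 0.15)), 60, 30)
  geno[, 1:5] <- 2L # cases hom-alt everywhere so something passes
  vt <- make_vt(geno)
  ids <- vt$samples
  prev <- Inf
  for (k in c(5, 10, 20, 25)) {
    got <- recessive_filter(vt, ids[1:5], character(), ids[6:(5 + k)])
    expect_lte(nrow(got$meta), prev)
    prev <- nrow(got$meta)
  }
})

test_that("the four-record compatible table is recovered from 43 animals", {
  # 1 affected calf, 1 haplotype-homozygous healthy animal, 41 controls
  set.seed(61)
  n <- 43
  v <- 300
  geno <- matrix(sample(0:2, v * n, replace = TRUE,
                        prob = c(0.7, 0.2, 0.1)), v, n)
  # four planted compatible rows mirroring the published genotype patterns:
  # calf aa; 58952 del/G or AA; 41 controls AA
  planted <- c(5, 60, 150, 288)
  geno[planted, ] <- 0L
  geno[planted, 1] <- 2L
  geno[planted[1], 2] <- 1L # the InDel is het in the haplotype homozygote
  # every unplanted row must violate the pattern somewhere; perturb clashes
  clash <- setdiff(which(geno[, 1] == 2L &
                           geno[, 2] <= 1L &
                           rowSums(geno[, 3:43, drop = FALSE]) == 0L),
                   planted)
  geno[clash, 1] <- 1L
  meta <- data.frame(chrom = "21",
                     pos = seq(70550045, 71573501, length.out = v),
                     id = sprintf("v%04d", seq_len(v)),
                     ref = "C", alt = "T", class = "snp",
                     stringsAsFactors = FALSE)
  meta$ref[planted[1]] <- "GA"; meta$alt[planted[1]] <- "G"
  meta$class[planted[1]] <- "indel"
  vt <- variant_table(meta, geno, c("calf", "hh58952",
                                    sprintf("ctl%02d", 1:41)))
  hits <- recessive_filter(vt, "calf", "hh58952",
                           sprintf("ctl%02d", 1:41))
  expect_equal(hits$meta$id, sprintf("v%04d", planted))
  expect_equal(sum(hits$meta$class == "indel"), 1)
  expect_equal(sum(hits$meta$class == "snp"), 3)
})

test_that("CDS validation catches malformed sequences", {
  expect_error(cds_model("ATGAA"), "divisible")
  expect_error(cds_model("TTGAAATAA"), "begin with ATG")
  expect_error(cds_model("ATGAAAAAA"), "end with a stop")
  expect_error(cds_model("ATGTAAAAATAA"), "internal stop")
  cds <- cds_model("ATGTGGTAA")
  expect_equal(cds$protein_length, 2)
})

test_that("stop-gain annotation reproduces the published codon arithmetic", {
  cds <- synthetic_pld4_cds()
  expect_equal(cds$protein_length, 487)
  cons <- annotate_consequence(cds, 645, "A")
  expect_equal(cons$codon_index, 215)
  expect_equal(cons$ref_codon, "TGG")
  expect_equal(cons$alt_codon, "TGA")
  expect_equal(cons$ref_aa, "W")
  expect_equal(cons$effect, "stop_gain")
  expect_equal(cons$truncated_protein_length, 214)
  expect_equal(cons$residues_lost, 273)
})

test_that("consequence classification and round-trip translation", {
  cds <- cds_model("ATGGGGTGGCATTAA") # M G W H *
  # third-position GGG->GGA is synonymous
  syn <- annotate_consequence(cds, 6, "A")
  expect_equal(syn$effect, "synonymous")
  # missense
  mis <- annotate_consequence(cds, 10, "G")
  expect_equal(mis$effect, "missense")
  # stop gain at codon 3 truncates to 2 residues
  sg <- annotate_consequence(cds, 9, "A")
  expect_equal(sg$effect, "stop_gain")
  expect_equal(sg$truncated_protein_length, 2)
  expect_equal(sg$codon_index, ceiling(9 / 3))
  # round-trip: translate the mutated CDS up to the first stop
  mutated <- cds$seq
  substr(mutated, 9, 9) <- "A"
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(mutated)))
  expect_equal(regexpr("\\*", aa) - 1L, sg$truncated_protein_length,
               ignore_attr = TRUE)
  # guards
  expect_error(annotate_consequence(cds, 99, "A"), "range")
  expect_error(annotate_consequence(cds, 4, "G"), "equals the reference")
})
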