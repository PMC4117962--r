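#' Demo pipeline configuration
#'
#' A scaled-down end-to-end configuration that runs in well under a minute:
#' 200 animals (8 affected), 3 chromosomes of 120 markers, 430 in-segment
#' sequence variants. Population parameters (haplotype frequency, mutation
#' concordance, hazards) keep their full-scale defaults.
#'
#' @param seed integer seed driving every stage
#' @return a `pipeline_config` list
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(
    sim = sim_config(n_samples = 200L, n_cases = 8L, n_chroms = 3L,
                     n_markers_per_chrom = 120L,
                     seq_region_n_snps = 400L, seq_region_n_indels = 30L,
                     seq_n_outside = 50L,
                     n_risk_matings = 600L, n_nonrisk_matings = 1200L,
                     seed = seed))
}

#' Assemble a pipeline configuration
#'
#' @param sim a [sim_config()]
#' @param max_missing,min_maf marker QC thresholds, see [apply_qc()]
#' @param roh ROH parameters passed to [detect_roh()]
#' @param case_mode,missing_policy recessive-filter modes, see
#'   [recessive_filter()]
#' @param n_seq_controls plain controls in the sequencing panel
#' @param decoys plant decoy compatible records, see
#'   [simulate_region_variants()]
#' @param births annual births for the expected-case projection
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(sim = sim_config(), max_missing = 0.05,
                            min_maf = 0.005,
                            roh = list(min_markers = 20L, max_het = 0L,
                                       max_missing = 2L,
                                       min_length_bp = 5e5),
                            case_mode = "hom_alt",
                            missing_policy = "strict",
                            n_seq_controls = 41L, decoys = FALSE,
                            births = 1e6) {
  structure(list(sim = sim, max_missing = max_missing, min_maf = min_maf,
                 roh = roh, case_mode = case_mode,
                 missing_policy = missing_policy,
                 n_seq_controls = n_seq_controls, decoys = decoys,
                 births = births),
            class = "pipeline_config")
}

#' Run the full mapping pipeline on a simulated cohort
#'
#' Executes simulate -> qc -> grm -> gwas -> roh -> haplotype statistics ->
#' region subsetting and recessive filter -> consequence annotation ->
#' survival contrast, writing checkpointed intermediates (PLINK text,
#' TSV, VCF) and a machine-readable `summary.json` to `out_dir`. All
#' randomness flows from `config$sim$seed`; a rerun with the same seed
#' reproduces the summary byte for byte. A stage failure aborts with the
#' stage name; outputs of completed stages are retained.
#'
#' @param config a [pipeline_config()] (default: [demo_config()])
#' @param out_dir output directory (created if absent)
#' @return the summary list, invisibly
#' @export
run_pipeline <- function(config = demo_config(), out_dir = tempfile("recmap_")) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_sim_config(config$sim)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- run_stage("simulate", {
    s <- simulate_cohort(config$sim)
    write_plink_text(s$gm, file.path(out_dir, "array"),
                     pheno = ifelse(s$cohort$affected, 1, 2))
    utils::write.table(s$cohort, file.path(out_dir, "cohort.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("simulate", "%d samples, %d markers, %d cases",
              n_samples(s$gm), n_markers(s$gm), sum(s$cohort$affected))
    s
  })

  qc <- run_stage("qc", {
    q <- apply_qc(sim$gm, config$max_missing, config$min_maf)
    utils::write.table(
      data.frame(filter = names(q$report$n_removed_by_class),
                 removed = unlist(q$report$n_removed_by_class)),
      file.path(out_dir, "qc_report.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    log_stage("qc", "%d -> %d markers", q$report$n_input, q$report$n_output)
    q
  })

  grm <- run_stage("grm", compute_grm(qc$gm))

  gwas <- run_stage("gwas", {
    y <- ifelse(sim$cohort$affected, 1, 2)
    fit <- fit_lmm_gwas(y, qc$gm, grm)
    utils::write.table(fit, file.path(out_dir, "gwas.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("gwas", "%d SNPs tested; min p = %.3g", nrow(fit), min(fit$p))
    fit
  })
  thr <- significance_threshold(sum(!gwas$degenerate))

  roh <- run_stage("roh", {
    cases <- sim$cohort$id[sim$cohort$affected]
    segs <- do.call(detect_roh,
                    c(list(gm = qc$gm, samples = cases), config$roh))
    shared <- intersect_case_segments(segs, case_ids = cases)
    write_roh_segments(segs, file.path(out_dir, "roh_segments.tsv"))
    hom_controls <- if (!shared$empty)
      setdiff(find_homozygous_controls(qc$gm, shared,
                                       max_het = config$roh$max_het,
                                       max_missing = config$roh$max_missing),
              cases)
    else character()
    if (!shared$empty)
      log_stage("roh", "shared segment %s:%.0f-%.0f (%d homozygous controls)",
                shared$chrom, shared$start, shared$end, length(hom_controls))
    list(segments = segs, shared = shared, hom_controls = hom_controls)
  })

  cc <- run_stage("haplo", call_haplotype_carriers(sim$panel))
  haplo <- run_stage("haplo", {
    unaff <- !sim$cohort$affected
    copies <- cc$status$carrier_copies
    counts <- c(n_total = sum(unaff), n_het = sum(copies[unaff] == 1L),
                n_hom = sum(copies[unaff] == 2L))
    hf <- haplotype_frequency(counts["n_total"], counts["n_het"],
                              counts["n_hom"])
    hwe <- hwe_exact_test(counts["n_total"], counts["n_het"],
                          counts["n_hom"])
    # concordance from the validated truth: mutation carriers among
    # haplotype-heterozygous animals
    het_ids <- which(copies == 1L & unaff)
    n_mut <- sum((sim$panel$mutant1 | sim$panel$mutant2)[het_ids])
    conc <- if (length(het_ids)) carrier_concordance(length(het_ids), n_mut)
    else NA_real_
    q <- if (is.na(conc)) NA_real_ else
      unname(defect_allele_frequency(hf, conc))
    list(counts = as.list(counts), haplotype_freq = unname(hf),
         hwe_p = unname(hwe),
         concordance = unname(conc),
         defect_allele_freq = q,
         risk_prob = risk_mating_homozygote_prob(TRUE, TRUE, 0),
         expected_cases = if (is.na(q)) NA_real_ else
           expected_affected_per_year(q, config$births))
  })

  varf <- run_stage("filter", {
    vt <- simulate_region_variants(config$sim, sim$panel,
                                   decoys = config$decoys)
    write_vcf(vt, file.path(out_dir, "region_variants.vcf"))
    reg <- subset_region(vt, config$sim$segment_chrom,
                         config$sim$segment_start, config$sim$segment_end)
    cases <- sim$cohort$id[sim$cohort$affected]
    seq_case <- cases[1]
    hh <- roh$hom_controls
    # plain controls must carry no copy of the disease haplotype (the
    # re-sequenced reference panel was haplotype-free)
    noncarrier <- sim$cohort$id[!is.na(cc$status$carrier_copies) &
                                  cc$status$carrier_copies == 0L]
    ctl <- utils::head(setdiff(noncarrier, c(cases, hh)),
                       config$n_seq_controls)
    hits <- recessive_filter(reg$variants, seq_case, hh, ctl,
                             case_mode = config$case_mode,
                             missing_policy = config$missing_policy)
    log_stage("filter", "%d in-segment variants -> %d compatible",
              nrow(reg$variants$meta), nrow(hits$meta))
    list(region_counts = reg$counts, hits = hits,
         panel = list(case = seq_case, haplo_hom = hh, controls = ctl))
  })

  anno <- run_stage("annotate", {
    cds <- synthetic_pld4_cds()
    annotate_consequence(cds, 645, "A")
  })

  surv <- run_stage("survival", {
    mat <- simulate_matings(config$sim)
    rec <- simulate_survival(mat, config$sim)
    utils::write.table(rec, file.path(out_dir, "survival_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    survival_contrast(rec)
  })

  summary <- list(
    seed = config$sim$seed,
    n_samples = n_samples(sim$gm),
    n_cases = sum(sim$cohort$affected),
    qc = list(n_input = qc$report$n_input, n_output = qc$report$n_output),
    gwas = list(n_tests = sum(!gwas$degenerate), threshold = thr,
                top_snp = gwas$id[which.min(gwas$p)],
                top_chrom = gwas$chrom[which.min(gwas$p)],
                top_pos = gwas$pos[which.min(gwas$p)],
                top_p = min(gwas$p)),
    shared_segment = roh$shared[c("chrom", "start", "end", "length_bp",
                                  "empty")],
    n_homozygous_controls = length(roh$hom_controls),
    haplotype = haplo,
    region_counts = as.list(varf$region_counts),
    compatible_variants = varf$hits$meta[, c("chrom", "pos", "id", "ref",
                                             "alt", "class")],
    consequence = anno[c("cds_pos", "codon_index", "effect",
                         "truncated_protein_length", "residues_lost")],
    survival = list(
      logrank_p = surv$logrank$p,
      tables = lapply(surv$tables, function(t)
        list(day = t$day, surv = t$surv)))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(summary)
}

#' Command-line entry point
#'
#' Thin dispatcher over the pipeline stages; invoked by the bundled
#' `recmap` script (`inst/exec/recmap`). Subcommands: `run` (full
#' pipeline), `simulate`, `annotate`.
#'
#' @param args character vector of command-line arguments
#' @return exit status, invisibly
#' @export
recmap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: recmap <run|simulate|annotate> [--seed N] [--out DIR]",
    "       recmap annotate --pos P --alt B", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  get_opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  seed <- as.integer(get_opt("--seed", "1"))
  out <- get_opt("--out", "recmap_out")
  switch(args[1],
         run = {
           run_pipeline(demo_config(seed), out)
           message("pipeline outputs written to ", out)
         },
         simulate = {
           sim <- simulate_cohort(sim_config(seed = seed))
           dir.create(out, showWarnings = FALSE, recursive = TRUE)
           write_plink_text(sim$gm, file.path(out, "array"),
                            pheno = ifelse(sim$cohort$affected, 1, 2))
           utils::write.table(sim$cohort, file.path(out, "cohort.tsv"),
                              sep = "\t", quote = FALSE, row.names = FALSE)
           message("cohort written to ", out)
         },
         annotate = {
           pos <- as.integer(get_opt("--pos", "645"))
           alt <- get_opt("--alt", "A")
           print(annotate_consequence(synthetic_pld4_cds(), pos, alt))
         },
         { message(usage); return(invisible(1L)) })
  invisible(0L)
}
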