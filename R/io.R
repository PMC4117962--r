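#' Read PLINK-text genotypes (.ped / .map)
#'
#' Parses a white-space delimited .ped (FID IID PAT MAT SEX PHENO followed
#' by two allele columns per marker) and a 4-column .map (chrom, id, cM,
#' pos). Genotypes are coded as the count of the lexicographically greater
#' allele observed at each marker; `0 0` is a missing call. Ragged rows
#' and half-missing calls raise an error naming the offending line.
#'
#' @param ped path to the .ped file
#' @param map path to the .map file
#' @return list with `gm` (a [genotype_matrix()]) and `fam` (data.frame of
#'   the six leading .ped columns)
#' @export
read_plink_text <- function(ped, map) {
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) != 4) stop(".map must have 4 columns (chrom id cM pos)")
  names(mp) <- c("chrom", "id", "cm", "pos")
  lines <- readLines(ped)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(".ped file is empty")
  m <- nrow(mp)
  rows <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  n <- length(rows)
  fam <- matrix("", n, 6L)
  a1s <- matrix("0", n, m)
  a2s <- matrix("0", n, m)
  for (i in seq_len(n)) {
    r <- rows[[i]]
    if (length(r) != want)
      stop(".ped line ", i, " has ", length(r), " fields; expected ", want)
    fam[i, ] <- r[1:6]
    a1 <- r[seq(7L, want, by = 2L)]
    a2 <- r[seq(8L, want, by = 2L)]
    half <- xor(a1 == "0", a2 == "0")
    if (any(half))
      stop(".ped line ", i, ": half-missing call at marker ",
           which(half)[1])
    a1s[i, ] <- a1
    a2s[i, ] <- a2
  }
  geno <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    als <- unique(setdiff(c(a1s[, j], a2s[, j]), "0"))
    if (length(als) > 2)
      stop("marker ", mp$id[j], " has more than two alleles: ",
           paste(als, collapse = "/"))
    if (!length(als)) next # all missing
    counted <- max(als) # lexicographically greater allele is counted
    cnt <- (a1s[, j] == counted) + (a2s[, j] == counted)
    cnt[a1s[, j] == "0"] <- NA_integer_
    geno[, j] <- as.integer(cnt)
  }
  fam <- data.frame(fid = fam[, 1], iid = fam[, 2], pat = fam[, 3],
                    mat = fam[, 4], sex = fam[, 5], pheno = fam[, 6],
                    stringsAsFactors = FALSE)
  markers <- data.frame(id = mp$id, chrom = as.character(mp$chrom),
                        pos = as.numeric(mp$pos), class = "snp",
                        stringsAsFactors = FALSE)
  list(gm = genotype_matrix(geno, markers, fam$iid), fam = fam)
}

#' Write PLINK-text genotypes (.ped / .map)
#'
#' Dosages are written with allele letters `A` (reference) and `B`
#' (counted); since `B` sorts after `A`, [read_plink_text()] recovers the
#' identical dosage matrix.
#'
#' @param gm a [genotype_matrix()]
#' @param prefix output path prefix (writes `<prefix>.ped` and
#'   `<prefix>.map`)
#' @param pheno optional numeric phenotype column (default 0 = missing)
#' @return the prefix, invisibly
#' @export
write_plink_text <- function(gm, prefix, pheno = NULL) {
  mp <- data.frame(chrom = gm$markers$chrom, id = gm$markers$id, cm = 0,
                   pos = ifelse(is.na(gm$markers$pos), 0, gm$markers$pos))
  utils::write.table(mp, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  code <- c("A A", "A B", "B B")
  n <- n_samples(gm)
  if (is.null(pheno)) pheno <- rep(0, n)
  lines <- vapply(seq_len(n), function(i) {
    g <- gm$geno[i, ]
    al <- ifelse(is.na(g), "0 0", code[g + 1L])
    paste(gm$samples[i], gm$samples[i], 0, 0, 0, pheno[i],
          paste(al, collapse = " "))
  }, "")
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read a VCF into a variant table
#'
#' Wraps `VariantAnnotation::readVcf`. Both phased (`|`) and unphased
#' (`/`) GT separators are accepted; the raw GT strings are kept so phase
#' survives a round-trip. Multi-allelic records are dropped with a warning
#' (`multiallelic = "drop"`, default) or rejected (`"reject"`). A VCF
#' without a GT FORMAT field is an error.
#'
#' @param path VCF file (plain text or bgzipped)
#' @param region optional `"chrom:start-end"` string or list
#'   `(chrom, start, end)`; records are filtered after reading
#' @param multiallelic `"drop"` or `"reject"`
#' @return a [variant_table()]
#' @export
read_vcf <- function(path, region = NULL, multiallelic = c("drop", "reject")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (!"GT" %in% names(VariantAnnotation::geno(vcf)))
    stop("VCF has no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  rrd <- as.data.frame(rr)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(alt_list)
  multi <- n_alt > 1L
  if (any(multi)) {
    if (multiallelic == "reject")
      stop(sum(multi), " multi-allelic record(s) present")
    warning(sum(multi), " multi-allelic record(s) dropped")
  }
  keep <- !multi & n_alt == 1L
  gt <- VariantAnnotation::geno(vcf)$GT
  meta <- data.frame(
    chrom = as.character(rrd$seqnames),
    pos = as.numeric(rrd$start),
    id = if (is.null(names(rr))) "." else names(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(seq_along(alt_list), function(i)
      if (n_alt[i] >= 1L) as.character(alt_list[[i]][1]) else NA_character_,
      ""),
    stringsAsFactors = FALSE)
  meta <- meta[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  geno[clean == "0/0"] <- 0L
  geno[clean %in% c("0/1", "1/0")] <- 1L
  geno[clean == "1/1"] <- 2L
  vt <- variant_table(meta, geno, colnames(gt), gt)
  if (!is.null(region)) {
    if (is.character(region)) {
      parts <- regmatches(region,
                          regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
      if (length(parts) != 4) stop("region must be \"chrom:start-end\"")
      region <- list(chrom = parts[2], start = as.numeric(parts[3]),
                     end = as.numeric(parts[4]))
    }
    vt <- subset_region(vt, region$chrom, region$start, region$end)$variants
  }
  vt
}

#' Write a variant table as VCF v4.2 text
#'
#' Emits GT-only records. When the table carries raw GT strings (from
#' [read_vcf()]) they are written verbatim, preserving phase separators;
#' otherwise dosages are encoded unphased.
#'
#' @param vt a [variant_table()]
#' @param path output file
#' @return the path, invisibly
#' @export
write_vcf <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=recmapr",
               sprintf("##contig=<ID=%s>", unique(vt$meta$chrom)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", vt$samples),
                     collapse = "\t")), con)
  if (nrow(vt$meta)) {
    if (!is.null(vt$gt)) {
      gtxt <- vt$gt
    } else {
      code <- c("0/0", "0/1", "1/1")
      gtxt <- matrix("./.", nrow(vt$geno), ncol(vt$geno))
      ok <- !is.na(vt$geno)
      gtxt[ok] <- code[vt$geno[ok] + 1L]
    }
    lines <- vapply(seq_len(nrow(vt$meta)), function(i) {
      paste(c(vt$meta$chrom[i], format(vt$meta$pos[i], scientific = FALSE),
              vt$meta$id[i], vt$meta$ref[i], vt$meta$alt[i], ".", ".", ".",
              "GT", gtxt[i, ]), collapse = "\t")
    }, "")
    writeLines(lines, con)
  }
  invisible(path)
}
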