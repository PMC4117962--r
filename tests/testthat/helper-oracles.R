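# fixture builders and independent brute-force oracles used across tests

make_gm <- function(geno, chrom = "1", pos = NULL, class = "snp") {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (length(chrom) == 1) chrom <- rep(chrom, m)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  genotype_matrix(geno,
                  data.frame(id = sprintf("m%03d", seq_len(m)),
                             chrom = chrom, pos = pos, class = class,
                             stringsAsFactors = FALSE))
}

# naive double-loop VanRaden GRM
grm_oracle <- function(geno) {
  p <- colMeans(geno, na.rm = TRUE) / 2
  denom <- 2 * sum(p * (1 - p))
  n <- nrow(geno)
  G <- matrix(0, n, n)
  for (i in seq_len(n))
    for (k in seq_len(n)) {
      s <- 0
      for (j in seq_len(ncol(geno)))
        s <- s + (geno[i, j] - 2 * p[j]) * (geno[k, j] - 2 * p[j])
      G[i, k] <- s / denom
    }
  G
}

# dense GLS fit at fixed delta: V = G + delta * I, REML variance scale,
# Wald statistic for the genotype effect
gls_oracle <- function(y, x, G, delta) {
  n <- length(y)
  X <- cbind(1, x)
  V <- G + delta * diag(n)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  sigma_a2 <- drop(t(r) %*% Vi %*% r) / (n - 2)
  covb <- sigma_a2 * solve(XtVX)
  list(beta = beta[2], se = sqrt(covb[2, 2]),
       stat = beta[2]^2 / covb[2, 2])
}

# dense REML negative log-likelihood (up to the same additive constant as
# the rotated-space version): direct determinant evaluation
reml_nll_dense <- function(delta, G, y, X) {
  n <- length(y); p <- ncol(X)
  V <- G + delta * diag(n)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  0.5 * ((n - p) * log(rss / (n - p)) +
           as.numeric(determinant(V, logarithm = TRUE)$modulus) +
           as.numeric(determinant(XtVX, logarithm = TRUE)$modulus))
}

# brute-force maximal-run ROH scan over all windows
roh_oracle <- function(g, pos, min_markers, max_het, max_missing,
                       min_length_bp) {
  m <- length(g)
  is_mis <- is.na(g)
  is_het <- !is_mis & g == 1L
  is_hom <- !is_mis & !is_het
  feasible <- function(i, j) {
    is_hom[i] && is_hom[j] &&
      sum(is_het[i:j]) <= max_het && sum(is_mis[i:j]) <= max_missing
  }
  wins <- list()
  for (i in seq_len(m)) for (j in i:m)
    if (feasible(i, j)) wins[[length(wins) + 1L]] <- c(i, j)
  if (!length(wins)) return(matrix(integer(), 0, 2))
  wmat <- do.call(rbind, wins)
  maximal <- vapply(seq_len(nrow(wmat)), function(r) {
    !any(wmat[, 1] <= wmat[r, 1] & wmat[, 2] >= wmat[r, 2] &
           (wmat[, 1] < wmat[r, 1] | wmat[, 2] > wmat[r, 2]))
  }, TRUE)
  wmat <- wmat[maximal, , drop = FALSE]
  keep <- (wmat[, 2] - wmat[, 1] + 1L) >= min_markers &
    (pos[wmat[, 2]] - pos[wmat[, 1]] + 1) >= min_length_bp
  wmat[keep, , drop = FALSE]
}

# brute-force longest interval contained in >= 1 segment of every case
shared_oracle <- function(segments, case_ids) {
  best <- NULL
  for (chr in unique(segments$chrom)) {
    sc <- segments[segments$chrom == chr, , drop = FALSE]
    for (s in sc$start) for (e in sc$end) {
      if (e < s) next
      ok <- all(vapply(case_ids, function(cs) {
        any(sc$sample == cs & sc$start <= s & sc$end >= e)
      }, TRUE))
      if (ok && (is.null(best) || (e - s) > (best[2] - best[1])))
        best <- c(s, e)
    }
  }
  best
}

# exact HWE enumeration over admissible heterozygote counts using choose()
hwe_enum_oracle <- function(n, n_het, n_hom) {
  rare <- n_het + 2 * n_hom
  rare <- min(rare, 2 * n - rare)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (rare - h) / 2
    bb <- n - h - aa
    choose(n, aa) * choose(n - aa, h) * 2^h
  }, 0)
  pr <- pr / sum(pr)
  obs <- pr[hets == n_het]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# micro-scale HWE oracle: enumerate every placement of the minor alleles
# into 2n allele slots and pair consecutive slots into genotypes
hwe_combn_oracle <- function(n, n_het, n_hom) {
  rare <- n_het + 2 * n_hom
  rare <- min(rare, 2 * n - rare)
  if (rare == 0) return(1)
  slots <- 2 * n
  combos <- utils::combn(slots, rare)
  hets <- apply(combos, 2, function(idx) {
    x <- integer(slots)
    x[idx] <- 1L
    g <- x[seq(1, slots, 2)] + x[seq(2, slots, 2)]
    sum(g == 1L)
  })
  tab <- table(hets) / ncol(combos)
  obs <- tab[as.character(n_het)]
  sum(tab[tab <= obs * (1 + 1e-12)])
}

# per-sample triple-loop recessive-compatibility oracle
recessive_oracle <- function(vt, case_ids, hh_ids, ctl_ids,
                             case_mode = "hom_alt") {
  keep <- logical(nrow(vt$meta))
  for (v in seq_len(nrow(vt$meta))) {
    ok <- TRUE
    for (s in case_ids) {
      g <- vt$geno[v, match(s, vt$samples)]
      if (is.na(g)) { ok <- FALSE; break }
      if (case_mode == "hom_alt" && g != 2L) { ok <- FALSE; break }
      if (case_mode == "segregating" && g < 1L) { ok <- FALSE; break }
    }
    if (ok) for (s in hh_ids) {
      g <- vt$geno[v, match(s, vt$samples)]
      if (is.na(g) || g > 1L) { ok <- FALSE; break }
    }
    if (ok) for (s in ctl_ids) {
      g <- vt$geno[v, match(s, vt$samples)]
      if (is.na(g) || g != 0L) { ok <- FALSE; break }
    }
    keep[v] <- ok
  }
  keep
}

# exhaustive transmission-tree oracle for the risk-mating probability:
# enumerate granddam genotype, dam alleles and transmissions
risk_mating_oracle <- function(sire_carrier, mgs_carrier, q) {
  p_total <- 0
  for (gd in 0:2) { # granddam defect-allele count
    p_gd <- stats::dbinom(gd, 2, q)
    for (gd_tx in 0:1) { # granddam transmits defect?
      p_tx <- if (gd_tx == 1) gd / 2 else 1 - gd / 2
      for (mgs_tx in 0:1) { # MGS transmits defect?
        p_m <- if (mgs_carrier) 0.5 else if (mgs_tx == 1) 0 else 1
        if (p_m == 0) next
        dam <- gd_tx + mgs_tx
        for (dam_tx in 0:1) {
          p_d <- if (dam_tx == 1) dam / 2 else 1 - dam / 2
          for (sire_tx in 0:1) {
            p_s <- if (sire_carrier) 0.5 else if (sire_tx == 1) 0 else 1
            if (p_s == 0) next
            if (dam_tx == 1 && sire_tx == 1)
              p_total <- p_total + p_gd * p_tx * p_m * p_d * p_s
          }
        }
      }
    }
  }
  p_total
}
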