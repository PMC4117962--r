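test_that("all-het samples yield no runs; planted runs are recovered", {
  gm <- make_gm(matrix(1L, 1, 50), pos = seq_len(50) * 1e5)
  expect_equal(nrow(detect_roh(gm, min_markers = 5, min_length_bp = 0)), 0)

  # 200-marker homozygous run flanked by hets
  g <- c(1L, 1L, rep(0L, 200), 1L, 1L)
  gm2 <- make_gm(matrix(g, 1), pos = seq_along(g) * 1e4)
  segs <- detect_roh(gm2, min_markers = 20, min_length_bp = 5e5)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 3e4)
  expect_equal(segs$end, 202e4)
  expect_equal(segs$n_markers, 200)
})

test_that("an interior het splits a run iff max_het = 0", {
  g <- c(1L, rep(0L, 30), 1L, rep(2L, 30), 1L)
  gm <- make_gm(matrix(g, 1), pos = seq_along(g) * 1000)
  s0 <- detect_roh(gm, min_markers = 10, max_het = 0, max_missing = 0,
                   min_length_bp = 0)
  expect_equal(nrow(s0), 2)
  s1 <- detect_roh(gm, min_markers = 10, max_het = 1, max_missing = 0,
                   min_length_bp = 0)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$n_het, 1L)
  expect_equal(s1$n_markers, 61L)
})

test_that("detected runs match the brute-force window oracle", {
  set.seed(17)
  for (rep in 1:12) {
    m <- 40
    g <- sample(c(0L, 1L, 2L, NA), m, replace = TRUE,
                prob = c(0.4, 0.25, 0.25, 0.1))
    pos <- sort(sample(1e6, m))
    pars <- list(c(3, 0, 1), c(4, 1, 2), c(5, 2, 0))[[rep %% 3 + 1]]
    gm <- make_gm(matrix(g, 1), pos = pos)
    got <- detect_roh(gm, min_markers = pars[1], max_het = pars[2],
                      max_missing = pars[3], min_length_bp = 0)
    want <- roh_oracle(g, pos, pars[1], pars[2], pars[3], 0)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      want_bp <- cbind(pos[want[, 1]], pos[want[, 2]])
      got_bp <- as.matrix(got[order(got$start), c("start", "end")])
      expect_equal(unname(got_bp),
                   unname(want_bp[order(want_bp[, 1]), , drop = FALSE]))
    }
  }
})

test_that("every reported run is verified homozygous by a re-scan", {
  cfg <- sim_config(n_samples = 40, n_cases = 4, n_markers_per_chrom = 80,
                    seed = 19)
  sim <- simulate_cohort(cfg)
  segs <- detect_roh(sim$gm, min_markers = 10, min_length_bp = 2e5)
  for (r in seq_len(nrow(segs))) {
    idx <- which(sim$gm$markers$chrom == segs$chrom[r] &
                   sim$gm$markers$pos >= segs$start[r] &
                   sim$gm$markers$pos <= segs$end[r])
    g <- sim$gm$geno[match(segs$sample[r], sim$gm$samples), idx]
    expect_lte(sum(g == 1L, na.rm = TRUE), 0)
    expect_lte(sum(is.na(g)), 2)
    expect_true(g[1] %in% c(0L, 2L) && g[length(g)] %in% c(0L, 2L))
  }
})

test_that("unsorted markers raise an error", {
  gm <- make_gm(matrix(0L, 1, 4), pos = c(10, 30, 20, 40))
  expect_error(detect_roh(gm), "sorted")
})

test_that("case-segment intersection matches enumeration and the paper-style fixture", {
  segs <- data.frame(
    sample = c("a", "b", "c"), chrom = "1",
    start = c(100, 300, 50), end = c(900, 1200, 700))
  sh <- intersect_case_segments(segs)
  expect_equal(c(sh$start, sh$end), c(300, 700))
  # identical intervals return that interval
  segs2 <- data.frame(sample = c("a", "b"), chrom = "2",
                      start = c(5, 5), end = c(50, 50))
  sh2 <- intersect_case_segments(segs2)
  expect_equal(c(sh2$start, sh2$end), c(5, 5) * c(1, 10))
  # brute-force equivalence on random segment sets
  set.seed(23)
  for (rep in 1:8) {
    cases <- paste0("c", 1:4)
    segs3 <- do.call(rbind, lapply(cases, function(cs) {
      k <- sample(1:3, 1)
      st <- sort(sample(1000, k))
      data.frame(sample = cs, chrom = "1", start = st,
                 end = st + sample(50:400, k, replace = TRUE))
    }))
    got <- intersect_case_segments(segs3, case_ids = cases)
    want <- shared_oracle(segs3, cases)
    if (is.null(want)) {
      expect_true(got$empty)
    } else {
      expect_equal(got$end - got$start,
                   as.numeric(want[2]) - as.numeric(want[1]))
    }
  }
})

test_that("eroded case copies intersect to exactly the printed coordinates", {
  # eight cases whose homozygous runs erode asymmetrically around the core
  set.seed(29)
  core <- c(70550045, 71573501)
  segs <- data.frame(
    sample = paste0("case", 1:8), chrom = "21",
    start = core[1] - sample(0:80000, 8), end = core[2] + sample(0:80000, 8))
  # at least one case must stop exactly at each core boundary
  segs$start[3] <- core[1]
  segs$end[6] <- core[2]
  sh <- intersect_case_segments(segs)
  expect_equal(sh$start, 70550045)
  expect_equal(sh$end, 71573501)
  expect_equal(sh$length_bp, 1023457)
  expect_equal(round(sh$length_bp / 1000), 1023)
})

test_that("intersection is monotone: adding a case can only shrink it", {
  set.seed(31)
  cases <- paste0("c", 1:5)
  segs <- do.call(rbind, lapply(cases, function(cs) {
    st <- sample(500, 1)
    data.frame(sample = cs, chrom = "1", start = st,
               end = st + sample(200:800, 1))
  }))
  prev <- Inf
  for (k in 2:5) {
    sh <- intersect_case_segments(segs[segs$sample %in% cases[1:k], ],
                                  case_ids = cases[1:k])
    len <- if (sh$empty) 0 else sh$length_bp
    expect_lte(len, prev)
    prev <- len
  }
})

test_that("homozygous controls over the shared segment are found", {
  cfg <- sim_config(n_samples = 150, n_cases = 6, n_markers_per_chrom = 80,
                    array_missing_rate = 0, haplotype_freq = 0.08,
                    mutation_on_haplotype = 0.5, seed = 37)
  sim <- simulate_cohort(cfg)
  cases <- sim$cohort$id[sim$cohort$affected]
  segs <- detect_roh(sim$gm, samples = cases, min_markers = 15)
  # restrict to the founder core: outside it founder copies erode
  # individually, so haplotype homozygotes are only guaranteed identical
  # within the core
  sh <- intersect_case_segments(segs, case_ids = cases,
                                region_hint = list(chrom = "21",
                                                   start = cfg$segment_start,
                                                   end = cfg$segment_end))
  expect_false(sh$empty)
  hom <- find_homozygous_controls(sim$gm, sh, max_het = 0, max_missing = 0)
  # founder-homozygous animals (affected or not) must all be detected
  founder_hom <- sim$cohort$id[sim$cohort$n_founder_copies == 2]
  expect_true(all(founder_hom %in% hom))
  # every reported control verifies by direct scan
  idx <- which(sim$gm$markers$chrom == sh$chrom &
                 sim$gm$markers$pos >= sh$start &
                 sim$gm$markers$pos <= sh$end)
  for (s in hom) {
    g <- sim$gm$geno[match(s, sim$gm$samples), idx]
    expect_equal(sum(g == 1L, na.rm = TRUE), 0)
  }
  # a control het at one segment marker is excluded under max_het = 0
  g2 <- sim$gm
  mid <- idx[ceiling(length(idx) / 2)]
  victim <- match(hom[1], g2$samples)
  g2$geno[victim, mid] <- 1L
  hom2 <- find_homozygous_controls(g2, sh, max_het = 0, max_missing = 0)
  expect_false(hom[1] %in% hom2)
})
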