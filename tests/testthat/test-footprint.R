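test_that("build_pwm computes background-pseudocount log odds", {
  pfm <- pfm_matrix(c(10, 0, 0, 0),
                    c(0, 10, 0, 0),
                    c(0, 0, 10, 0),
                    c(0, 0, 0, 10))
  pwm <- build_pwm(pfm, pseudocount = 0.8)
  # score[b, j] = log2(((n + pc*bg) / (N + pc)) / bg)
  hit <- log2(((10 + 0.8 * 0.25) / 10.8) / 0.25)
  miss <- log2(((0 + 0.8 * 0.25) / 10.8) / 0.25)
  expect_equal(unname(diag(pwm$scores)), rep(hit, 4))
  expect_equal(pwm$scores["C", 1], miss, ignore_attr = TRUE)
  expect_equal(pwm$max_score, 4 * hit)
  expect_equal(pwm$min_score, 4 * miss)
  # a uniform column scores zero everywhere
  uni <- build_pwm(pfm_matrix(c(5, 5, 5, 5), c(5, 5, 5, 5),
                              c(5, 5, 5, 5), c(5, 5, 5, 5)))
  expect_equal(unname(uni$scores), matrix(0, 4, 4))
  expect_error(build_pwm(pfm, pseudocount = 0), "positive")
  expect_error(build_pwm(pfm, background = c(0.5, 0.5, 0.2, 0.2)), "summing")
})

test_that("pwm_score_distribution is a probability distribution", {
  set.seed(121)
  for (W in c(4, 6)) {
    pwm <- build_pwm(random_pfm(W))
    dist <- pwm_score_distribution(pwm)
    expect_equal(sum(dist$prob), 1)
    expect_false(is.unsorted(dist$score))
    expect_true(all(dist$prob > 0))
    expect_lte(max(dist$score), pwm$max_score + 1e-3 * W)
    expect_gte(min(dist$score), pwm$min_score - 1e-3 * W)
  }
})

test_that("DP score distribution equals exhaustive enumeration", {
  set.seed(131)
  pwm <- build_pwm(random_pfm(5))
  dist <- pwm_score_distribution(pwm)
  oracle <- oracle_pwm_tail(pwm)
  expect_equal(dist$score, oracle$score)
  expect_equal(dist$prob, oracle$prob)
})

test_that("score_threshold yields an exact tail p-value bound", {
  set.seed(141)
  pwm <- build_pwm(random_pfm(6))
  dist <- pwm_score_distribution(pwm)
  tailp <- function(t) sum(dist$prob[dist$score >= t - 1e-12])
  for (p in c(1e-2, 1e-3)) {
    t <- score_threshold(pwm, p)
    expect_lte(tailp(t), p)
    # the next lattice score down would exceed p
    below <- dist$score[dist$score < t - 1e-12]
    if (length(below)) expect_gt(tailp(max(below)), p)
  }
  # p below the best word's probability (4^-6 under a uniform background)
  # falls back to the maximum achievable score
  expect_equal(score_threshold(pwm, 1e-4), max(dist$score))
  # unattainably small p falls back to the maximum achievable score
  expect_equal(score_threshold(pwm, 1e-12), max(dist$score))
  expect_error(score_threshold(pwm, 0), "in \\(0, 1\\)")
})

test_that("scan_motifs finds planted sites on both strands", {
  consensus <- "TGACGTCAAG"
  pfm <- pfm_matrix(
    as.numeric(strsplit(consensus, "")[[1]] == "A") * 20,
    as.numeric(strsplit(consensus, "")[[1]] == "C") * 20,
    as.numeric(strsplit(consensus, "")[[1]] == "G") * 20,
    as.numeric(strsplit(consensus, "")[[1]] == "T") * 20)
  pwm <- build_pwm(pfm)
  set.seed(151)
  bg <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
  plant <- function(s, at, ins) {
    paste0(substr(s, 1, at - 1), ins, substr(s, at + nchar(ins), nchar(s)))
  }
  g <- plant(bg, 500, consensus)
  g <- plant(g, 1500, revcomp_chr(consensus))
  sites <- scan_motifs(c(chr1 = g), pwm, score_threshold(pwm, 1e-4))
  expect_gte(length(sites), 2L)
  expect_true(any(GenomicRanges::start(sites) == 500L &
                    GenomicRanges::strand(sites) == "+"))
  expect_true(any(GenomicRanges::start(sites) == 1500L &
                    GenomicRanges::strand(sites) == "-"))
})

test_that("scanning the reverse-complemented genome mirrors hits", {
  set.seed(161)
  pwm <- build_pwm(random_pfm(8))
  g <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  thr <- score_threshold(pwm, 1e-3)
  fwd <- scan_motifs(c(chr1 = g), pwm, thr)
  rc <- scan_motifs(c(chr1 = revcomp_chr(g)), pwm, thr)
  expect_equal(length(fwd), length(rc))
  # a hit at [s, e] on one strand maps to [L-e+1, L-s+1] on the other
  mirrored <- sort(2000L - GenomicRanges::end(fwd) + 1L)
  expect_equal(sort(GenomicRanges::start(rc)), mirrored)
  expect_equal(sort(S4Vectors::mcols(fwd)$score), sort(S4Vectors::mcols(rc)$score))
})

test_that("scan_motifs skips windows containing ambiguous bases", {
  pwm <- build_pwm(pfm_matrix(c(20, 0, 0, 0), c(20, 0, 0, 0),
                              c(20, 0, 0, 0), c(20, 0, 0, 0)))
  sites <- scan_motifs(c(chr1 = "AAAANAAAA"), pwm, 1)
  # windows 2..5 touch the N; AAAA at 1 and 6 remain (both strands may hit)
  expect_true(all(GenomicRanges::start(sites) %in% c(1L, 6L)))
})

test_that("intersect_open keeps only sites inside peaks", {
  sites <- gr0("chr1", c(100, 500), c(110, 510), strand = "+")
  peaks <- gr0("chr1", 90, 120)
  expect_equal(start0(intersect_open(sites, peaks)), 100L)
})

test_that("mappability_mask flags repeated and palindromic k-mers", {
  # ACGT is its own reverse complement: always counted at least twice
  m <- mappability_mask(c(chr1 = "ACGTACGT"), k = 4L)
  expect_false(any(m$chr1))
  # unique non-palindromic k-mers are mappable
  m2 <- mappability_mask(c(chr1 = "AAACCC"), k = 3L)
  expect_equal(unname(m2$chr1), c(TRUE, TRUE, TRUE, TRUE))
  # a repeated k-mer is not
  m3 <- mappability_mask(c(chr1 = "AACAAC"), k = 3L)
  expect_false(m3$chr1[1])
  expect_false(m3$chr1[4])
  # ambiguous bases disqualify the k-mer
  m4 <- mappability_mask(c(chr1 = "AANCCC"), k = 3L)
  expect_false(any(m4$chr1[1:3]))
  expect_error(mappability_mask(c(chr1 = "ACGT"), k = 10L), "exceeds")
})

test_that("most positions of a random genome are uniquely mappable at k=50", {
  set.seed(171)
  g <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
  m <- mappability_mask(c(chr1 = g), k = 50L)
  expect_gt(mean(m$chr1), 0.999)
})

test_that("hexamer ids, names and reverse complements are consistent", {
  nm <- hexamer_names()
  expect_length(nm, 4096L)
  expect_equal(nm[1], "AAAAAA")
  expect_equal(nm[4096], "TTTTTT")
  expect_false(any(duplicated(nm)))
  rc <- atacqc:::hexamer_rc_table()
  # involution: rc(rc(h)) == h
  expect_equal(rc[rc], seq_len(4096L))
  set.seed(181)
  for (i in sample(4096L, 20)) {
    expect_equal(nm[rc[i]], revcomp_chr(nm[i]))
  }
})

test_that("hexamer_model on a homopolymer assigns all rate to one hexamer", {
  g <- c(chr1 = paste(rep("A", 300), collapse = ""))
  mask <- structure(list(chr1 = rep(TRUE, 296L)),
                    class = "mappability_mask", k = 5L)
  cuts <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(50:99, width = 1L),
                                 strand = "+")
  bias <- hexamer_model(cuts, g, mask)
  expect_equal(unname(bias$rates["AAAAAA"]), 1)
  expect_equal(sum(bias$rates), 1)
  expect_equal(bias$total_cuts, 50L)
  # minus-strand cuts on poly-A read the reverse complement TTTTTT
  cuts_m <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(50:99, width = 1L),
                                   strand = "-")
  bias_m <- hexamer_model(cuts_m, g, mask)
  expect_equal(unname(bias_m$rates["TTTTTT"]), 1)
})

test_that("hexamer_model errors when every cut is masked", {
  g <- c(chr1 = paste(rep("A", 300), collapse = ""))
  mask <- structure(list(chr1 = rep(FALSE, 296L)),
                    class = "mappability_mask", k = 5L)
  cuts <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50L, width = 1L),
                                 strand = "+")
  expect_error(hexamer_model(cuts, g, mask), "no cuts remain")
})

test_that("footprint_profile is near zero without protection", {
  spec <- simulation_spec(contigs = c(chr1 = 30000L, chrM = 2000L),
                          seed = 7L, n_fragments = 150000L,
                          tss_enrichment_factor = 1, n_genes = 0L,
                          n_motif_sites = 0L, n_open_regions = 0L,
                          mito_fraction = 0)
  gen <- make_genome(spec)
  sim <- simulate_cuts(spec, gen$genome, gen$truth, paired = FALSE)
  mask <- mappability_mask(gen$genome["chr1"], k = 50L)
  bias <- hexamer_model(sim$cuts, gen$genome["chr1"], mask)
  sites <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(seq(2000L, 28000L, 250L),
                                                   width = 10L),
                                  strand = "+")
  fp <- footprint_profile(sim$cuts, sites, bias, mask, gen$genome["chr1"])
  expect_s3_class(fp, "footprint_profile")
  expect_length(fp$offsets, 60L)
  expect_lt(abs(fp$depth), 0.1)
  expect_equal(fp$n_sites, length(sites))
  df <- as.data.frame(fp)
  expect_equal(nrow(df), 60L)
})

test_that("footprint_profile validates its inputs", {
  g <- c(chr1 = paste(rep(c("A", "C", "G", "T"), 100), collapse = ""))
  mask <- mappability_mask(g, k = 10L)
  cuts <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100L, width = 1L),
                                 strand = "+")
  bias <- structure(list(rates = rep(1 / 4096, 4096),
                         abundance = rep(1, 4096), total_cuts = 1L,
                         masked_cuts = 0L, k = 10L, centering = ""),
                    class = "hexamer_bias")
  names(bias$rates) <- names(bias$abundance) <- hexamer_names()
  expect_error(footprint_profile(cuts, GenomicRanges::GRanges(), bias, mask, g),
               "no motif sites")
  mixed <- gr0("chr1", c(50, 100), c(60, 120), strand = "+")
  expect_error(footprint_profile(cuts, mixed, bias, mask, g), "one width")
})
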