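# Shared fixtures and independent oracles for the test suite.

# GRanges from BED-style 0-based half-open coordinates
gr0 <- function(chrom, start0, end0, strand = "*") {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start0 + 1L, end0),
                         strand = strand)
}

start0 <- function(gr) GenomicRanges::start(gr) - 1L
end0 <- function(gr) GenomicRanges::end(gr)

# random interval set on one contig (0-based coords in [0, L))
random_intervals <- function(n, L = 10000L, max_w = 300L, chrom = "chr1") {
  s <- sample.int(L - max_w, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  gr0(chrom, s, s + w)
}

# per-base brute-force oracle: fraction of each a-interval covered by bs
oracle_overlap_fraction <- function(a, bs) {
  vapply(seq_along(a), function(i) {
    bases <- seq.int(start0(a)[i], end0(a)[i] - 1L)
    ch <- as.character(GenomicRanges::seqnames(a))[i]
    sel <- as.character(GenomicRanges::seqnames(bs)) == ch
    if (!any(sel)) return(0)
    covered <- rep(FALSE, length(bases))
    for (j in which(sel)) {
      covered <- covered | (bases >= start0(bs)[j] & bases < end0(bs)[j])
    }
    mean(covered)
  }, 0)
}

# O(n*m) brute-force PRC oracle
oracle_prc <- function(hotspots, reference) {
  hit <- vapply(seq_along(reference), function(i) {
    ch <- as.character(GenomicRanges::seqnames(reference))[i]
    sel <- as.character(GenomicRanges::seqnames(hotspots)) == ch
    any(sel &
          start0(hotspots) < end0(reference)[i] &
          end0(hotspots) > start0(reference)[i])
  }, TRUE)
  100 * mean(hit)
}

# exhaustive PWM score distribution on the DP lattice
oracle_pwm_tail <- function(pwm, granularity = 1e-3) {
  W <- pwm$width
  si <- round(pwm$scores / granularity)
  words <- as.matrix(expand.grid(rep(list(1:4), W)))
  sc <- integer(nrow(words))
  pr <- rep(1, nrow(words))
  for (j in seq_len(W)) {
    sc <- sc + si[cbind(words[, j], j)]
    pr <- pr * pwm$background[words[, j]]
  }
  agg <- tapply(pr, sc, sum)
  data.frame(score = as.numeric(names(agg)) * granularity,
             prob = as.numeric(agg))
}

# small SAM fixture: list of proper pairs -> temp .sam path
write_sam_fixture <- function(pairs, contigs = c(chr1 = 100000L, chrM = 16000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  recs <- unlist(lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    mapq <- if (is.null(p$mapq)) 60L else p$mapq
    flag1 <- if (isTRUE(p$improper)) 65L else 99L
    flag2 <- if (isTRUE(p$improper)) 129L else 147L
    tlen <- if (isTRUE(p$improper)) 0L else p$len
    mpos <- p$pos + p$len - 50L
    c(sprintf("%s\t%d\t%s\t%d\t%d\t50M\t=\t%d\t%d\t*\t*",
              paste0("r", i), flag1, p$chrom, p$pos, mapq, mpos, tlen),
      sprintf("%s\t%d\t%s\t%d\t%d\t50M\t=\t%d\t%d\t*\t*",
              paste0("r", i), flag2, p$chrom, mpos, mapq, p$pos, -tlen))
  }))
  path <- tempfile(fileext = ".sam")
  writeLines(c(hdr, recs), path)
  path
}

# 4 x W PFM with A/C/G/T rownames
pfm_matrix <- function(...) {
  m <- rbind(...)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

# random PFM of a given width (counts 0..50, no zero columns)
random_pfm <- function(W) {
  m <- matrix(sample(0:50, 4L * W, replace = TRUE), nrow = 4L)
  zero <- colSums(m) == 0
  m[1L, zero] <- 1L
  rownames(m) <- c("A", "C", "G", "T")
  m
}
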