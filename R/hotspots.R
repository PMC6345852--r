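#' Fraction of each interval covered by a peak set
#'
#' The primitive behind the replicate-concordance rule: for every query
#' interval, the fraction of its bases covered by the union of the
#' subject intervals (overlaps within the subject are merged first, so
#' no base counts twice).
#'
#' @param a Query `GRanges`.
#' @param bs Subject `GRanges` (a replicate's peaks).
#' @return Numeric vector in `[0, 1]`, one value per query interval.
#' @export
overlap_fraction <- function(a, bs) {
  stopifnot(methods::is(a, "GRanges"), methods::is(bs, "GRanges"))
  if (length(a) == 0L) return(numeric(0))
  if (length(bs) == 0L) return(rep(0, length(a)))
  red <- GenomicRanges::reduce(bs, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(a, red, ignore.strand = TRUE)
  ov <- IRanges::pintersect(a[S4Vectors::queryHits(hits)],
                            red[S4Vectors::subjectHits(hits)],
                            ignore.strand = TRUE)
  covered <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
  out <- rep(0, length(a))
  out[as.integer(names(covered))] <- as.numeric(covered)
  out / GenomicRanges::width(a)
}

#' Replicate-concordant hotspots
#'
#' Peaks are called on the pooled replicates, then a pooled peak is
#' retained as a hotspot only if at least `min_frac` (default 50%) of
#' its bases are covered by the peaks of *every* individual replicate.
#' The comparison is inclusive: exactly 50% coverage is retained.
#'
#' @param pooled `GRanges` of peaks called on pooled data.
#' @param replicates A list of `GRanges`, one per replicate.
#' @param min_frac Required covered fraction in `(0, 1]`.
#' @return The retained subset of `pooled`, original order preserved.
#' @export
concordant_hotspots <- function(pooled, replicates, min_frac = 0.5) {
  stopifnot(methods::is(pooled, "GRanges"))
  if (!is.list(replicates) || length(replicates) < 1L) {
    stop("at least one replicate peak set is required", call. = FALSE)
  }
  if (!is.numeric(min_frac) || length(min_frac) != 1L ||
      min_frac <= 0 || min_frac > 1) {
    stop("min_frac must be in (0, 1]", call. = FALSE)
  }
  keep <- rep(TRUE, length(pooled))
  for (rep_gr in replicates) {
    keep <- keep & overlap_fraction(pooled, rep_gr) >= min_frac
  }
  pooled[keep]
}

#' Venn region counts for 2 or 3 peak sets
#'
#' Each set is first self-merged; merged intervals from all sets are
#' then clustered by overlap (>= 1 bp, any strand), and each cluster
#' contributes one count to the Venn region named by the sets it
#' touches. Clustering avoids double-counting peaks that one caller
#' splits and another reports whole.
#'
#' @param sets Named list of 2 or 3 `GRanges`. Unnamed lists get
#'   labels `A`, `B`, `C`.
#' @return Named integer vector over Venn regions, e.g. `A`, `B`,
#'   `A&B` for two sets.
#' @export
venn_counts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L) {
    stop("venn_counts takes 2 or 3 peak sets", call. = FALSE)
  }
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- LETTERS[seq_along(sets)]
  }
  merged <- lapply(sets, GenomicRanges::reduce, ignore.strand = TRUE)
  all_iv <- GenomicRanges::reduce(do.call(c, unname(merged)), ignore.strand = TRUE)
  member <- vapply(merged, function(s) {
    IRanges::overlapsAny(all_iv, s, ignore.strand = TRUE)
  }, logical(length(all_iv)))
  member <- matrix(member, nrow = length(all_iv))
  region <- apply(member, 1L, function(m) paste(labels[m], collapse = "&"))
  regions <- unlist(lapply(seq_along(labels), function(k) {
    utils::combn(labels, k, paste, collapse = "&")
  }))
  counts <- table(factor(region, levels = regions))
  stats::setNames(as.integer(counts), regions)
}

#' Genomic distribution of peaks
#'
#' Assigns each peak to one category by the location of its midpoint,
#' with precedence promoter > exon > intron > other > intergenic.
#' The promoter is a window around the TSS honouring strand
#' (`promoter_up` bp upstream to `promoter_down` bp downstream);
#' "other" captures transcript-end neighbourhoods (`tx_end_flank` bp
#' either side of the 3' end) and any annotation gaps inside the
#' transcript span.
#'
#' @param peaks `GRanges` of hotspots.
#' @param genes Gene model from [read_gene_model()].
#' @param promoter_up,promoter_down Promoter window half-sizes in bp.
#' @param tx_end_flank Window around the transcript 3' end assigned to
#'   "other".
#' @return A list of class `"genomic_distribution"` with integer
#'   `counts` and numeric `fractions` over
#'   promoter/exon/intron/other/intergenic; fractions sum to 1.
#' @export
annotate_distribution <- function(peaks, genes, promoter_up = 2000L,
                                  promoter_down = 2000L, tx_end_flank = 1000L) {
  stopifnot(methods::is(peaks, "GRanges"), methods::is(genes, "GRanges"))
  if (length(genes) == 0L) stop("gene model is empty", call. = FALSE)
  mid <- (GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) %/% 2L
  midpoints <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                      IRanges::IRanges(mid, width = 1L))
  st <- as.character(GenomicRanges::strand(genes))
  tss <- ifelse(st == "+", GenomicRanges::start(genes), GenomicRanges::end(genes))
  tes <- ifelse(st == "+", GenomicRanges::end(genes), GenomicRanges::start(genes))
  up <- ifelse(st == "+", promoter_up, promoter_down)
  dn <- ifelse(st == "+", promoter_down, promoter_up)
  chrom <- GenomicRanges::seqnames(genes)
  promoters <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(pmax(1L, tss - up), tss + dn))
  exons <- GenomicRanges::GRanges(
    rep(chrom, lengths(S4Vectors::mcols(genes)$exons)),
    unlist(S4Vectors::mcols(genes)$exons))
  tx <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
    GenomicRanges::start(genes), GenomicRanges::end(genes)))
  tx_end <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(pmax(1L, tes - tx_end_flank), tes + tx_end_flank))
  in_cat <- function(region) IRanges::overlapsAny(midpoints, region,
                                                  ignore.strand = TRUE)
  cat <- rep("intergenic", length(peaks))
  cat[in_cat(tx_end)] <- "other"
  cat[in_cat(tx)] <- "intron"
  cat[in_cat(exons)] <- "exon"
  cat[in_cat(promoters)] <- "promoter"
  levels <- c("promoter", "exon", "intron", "other", "intergenic")
  counts <- table(factor(cat, levels = levels))
  counts <- stats::setNames(as.integer(counts), levels)
  fractions <- if (length(peaks)) counts / length(peaks) else counts * 0
  structure(list(counts = counts, fractions = fractions,
                 total = length(peaks)),
            class = "genomic_distribution")
}

#' @export
print.genomic_distribution <- function(x, ...) {
  cat("Genomic distribution of", x$total, "peaks:\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Maximum normalized tag density per peak
#'
#' For each peak, the highest per-base cut count inside the peak,
#' scaled to a fixed depth (default 10 million tags). Pairs of these
#' vectors from two replicates feed [density_correlation()] for the
#' replicate-reproducibility scatter.
#'
#' @param peaks `GRanges` of hotspots.
#' @param cuts Width-1 `GRanges` of cut sites.
#' @param total_tags Library size used for normalization; defaults to
#'   `length(cuts)`.
#' @param target Normalization depth, default `1e7`.
#' @return Numeric vector, one value per peak.
#' @export
max_tag_density <- function(peaks, cuts, total_tags = length(cuts),
                            target = 1e7) {
  stopifnot(methods::is(peaks, "GRanges"), methods::is(cuts, "GRanges"))
  out <- numeric(length(peaks))
  if (length(cuts) == 0L || length(peaks) == 0L) return(out)
  cov <- GenomicRanges::coverage(cuts)
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (!ch %in% names(cov)) next
    r <- cov[[ch]]
    s <- pmin(GenomicRanges::start(peaks)[idx], length(r))
    e <- pmin(GenomicRanges::end(peaks)[idx], length(r))
    ok <- s <= e & s >= 1L
    if (any(ok)) {
      v <- IRanges::Views(r, start = s[ok], end = e[ok])
      out[idx[ok]] <- IRanges::viewMaxs(v)
    }
  }
  normalize_tag_count(out, total_tags, target)
}

#' Pearson correlation of per-peak densities between replicates
#'
#' @param x,y Paired per-peak values (e.g. from [max_tag_density()]).
#' @return Pearson product-moment correlation.
#' @export
density_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors differ in length", call. = FALSE)
  if (length(x) < 2L) {
    stop("at least 2 peaks are required for a correlation", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Peak-centred tag density matrix for heatmaps
#'
#' One row per peak, centred on the peak midpoint, covering
#' `window` bp on each side in bins of `bin` bp; entries are cut
#' counts per bin scaled to `target` total tags.
#'
#' @param peaks `GRanges` of peaks.
#' @param cuts Width-1 `GRanges` of cut sites.
#' @param window Half-window in bp (default 5000, i.e. a 10-kb view).
#' @param bin Bin width in bp; must divide `2 * window`.
#' @param total_tags Library size; defaults to `length(cuts)`.
#' @param target Normalization depth, default `1e7`.
#' @return A numeric matrix `length(peaks)` x `2*window/bin`; column
#'   names give the bin-start offset from the peak centre.
#' @export
heatmap_matrix <- function(peaks, cuts, window = 5000L, bin = 100L,
                           total_tags = length(cuts), target = 1e7) {
  stopifnot(methods::is(peaks, "GRanges"), methods::is(cuts, "GRanges"))
  if (window <= 0L) stop("window must be positive", call. = FALSE)
  if ((2L * window) %% bin != 0L) {
    stop("bin must divide 2 * window", call. = FALSE)
  }
  nbin <- as.integer(2L * window / bin)
  mat <- matrix(0, nrow = length(peaks), ncol = nbin)
  colnames(mat) <- seq(-window, window - bin, by = bin)
  if (length(peaks) == 0L) return(mat)
  mid <- (GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) %/% 2L
  win <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                IRanges::IRanges(pmax(1L, mid - window),
                                                 mid + window - 1L))
  if (length(cuts)) {
    hits <- GenomicRanges::findOverlaps(cuts, win, ignore.strand = TRUE)
    if (length(hits)) {
      p <- S4Vectors::subjectHits(hits)
      off <- GenomicRanges::start(cuts)[S4Vectors::queryHits(hits)] - (mid[p] - window)
      b <- off %/% bin + 1L
      ok <- b >= 1L & b <= nbin
      inc <- table(factor(paste(p[ok], b[ok]), exclude = NULL))
      idx <- do.call(rbind, strsplit(names(inc), " ", fixed = TRUE))
      mat[cbind(as.integer(idx[, 1L]), as.integer(idx[, 2L]))] <- as.integer(inc)
    }
  }
  normalize_tag_count(mat, max(total_tags, 1L), target)
}
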