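#' Tn5 offset correction: fragments to single-base cut sites
#'
#' Each sequenced ATAC template arises from two Tn5 insertion events,
#' one at each end. To place a single-base cut site at the centre of
#' the transposon binding event, the forward-strand read end is shifted
#' +4 bp and the reverse-strand read end -5 bp. In 0-based terms the
#' forward cut is `start + 4` and the reverse cut is `(end - 1) - 5`;
#' both are emitted for every fragment.
#'
#' @param fragments A `GRanges` of aligned templates (e.g. from
#'   [read_alignments()]`$fragments`).
#' @return A list with `cuts`, a width-1 `GRanges` of cut sites whose
#'   strand records the generating read end, and `dropped`, the number
#'   of cut sites discarded because the shift ran off the contig start.
#' @export
tn5_shift <- function(fragments) {
  stopifnot(methods::is(fragments, "GRanges"))
  if (any(GenomicRanges::width(fragments) < 1L)) {
    stop("fragments must have positive template length", call. = FALSE)
  }
  chrom <- as.character(GenomicRanges::seqnames(fragments))
  fwd <- GenomicRanges::start(fragments) + 4L   # 0-based start + 4
  rev <- GenomicRanges::end(fragments) - 5L     # 0-based (end-1) - 5
  pos <- c(fwd, rev)
  strand <- rep(c("+", "-"), each = length(fragments))
  chrom2 <- c(chrom, chrom)
  ok <- pos >= 1L
  dropped <- sum(!ok)
  if (dropped) {
    warning(dropped, " cut site(s) shifted past the contig start were dropped")
  }
  cuts <- GenomicRanges::GRanges(chrom2[ok],
                                 IRanges::IRanges(pos[ok], width = 1L),
                                 strand = strand[ok])
  list(cuts = cuts, dropped = dropped)
}

#' Percentage of mitochondrial reads
#'
#' @param contig_tallies Named integer vector of per-contig template
#'   counts, e.g. `read_alignments()$contig_tallies`.
#' @param mito_names Contig names counted as mitochondrial.
#' @return Percentage in `[0, 100]`.
#' @export
mito_fraction <- function(contig_tallies, mito_names = mito_contigs()) {
  total <- sum(contig_tallies)
  if (is.na(total) || total <= 0) {
    stop("no mapped reads: cannot compute mitochondrial fraction", call. = FALSE)
  }
  mito <- sum(contig_tallies[names(contig_tallies) %in% mito_names])
  100 * mito / total
}

#' Fragment-size distribution and nucleosome phasing score
#'
#' ATAC libraries from intact chromatin show a ladder of fragment
#' lengths at multiples of the nucleosome repeat (~190-200 bp),
#' visible on a Bioanalyzer trace. This summarises it numerically: a
#' 1-bp histogram of template lengths up to `max_len`, and a phasing
#' score defined as the fraction of spectral power of the
#' mean-subtracted histogram falling at periods in `period_range`.
#' Degraded chromatin (e.g. flash-frozen nuclei) loses the ladder and
#' scores near zero.
#'
#' @param fragments `GRanges` of templates, or an integer vector of
#'   template lengths.
#' @param max_len Histogram cap in bp (default 1000, the library
#'   size-selection upper bound).
#' @param period_range Nucleosome repeat periods (bp) whose power
#'   counts toward the score; default `c(190, 200)`.
#' @return A list of class `"fragment_size_profile"` with `lengths`
#'   (1..max_len), `counts`, `n` and `phasing_score`.
#' @export
fragment_size_profile <- function(fragments, max_len = 1000L,
                                  period_range = c(190, 200)) {
  len <- if (methods::is(fragments, "GRanges")) {
    GenomicRanges::width(fragments)
  } else {
    as.integer(fragments)
  }
  len <- len[!is.na(len) & len >= 1L & len <= max_len]
  counts <- tabulate(len, nbins = max_len)
  score <- 0
  if (length(len) > 0L && stats::var(counts) > 0) {
    x <- counts - mean(counts)
    p <- Mod(stats::fft(x))^2
    n <- length(x)
    # frequency bin k corresponds to period n / k
    k <- seq_len(floor(n / 2))
    periods <- n / k
    in_band <- periods >= period_range[1L] & periods <= period_range[2L]
    score <- sum(p[1L + k[in_band]]) / sum(p[1L + k])
  }
  structure(list(lengths = seq_len(max_len), counts = counts,
                 n = length(len), phasing_score = score),
            class = "fragment_size_profile")
}

#' @export
print.fragment_size_profile <- function(x, ...) {
  cat("Fragment size profile:", x$n, "fragments <=", length(x$counts),
      "bp; phasing score", format(x$phasing_score, digits = 3), "\n")
  invisible(x)
}

#' Scale tag counts to a fixed sequencing depth
#'
#' Multiplies per-position (or per-bin) counts by `target / total_tags`
#' so that samples of different depth are comparable. QC histograms
#' and heatmaps use a 10-million-read target; footprint profiles use
#' 100 million.
#'
#' @param counts Numeric vector/matrix of tag counts.
#' @param total_tags Total tags in the sample (> 0).
#' @param target Target depth; default `1e7`.
#' @return `counts * target / total_tags`, ratios between entries
#'   preserved exactly.
#' @export
normalize_tag_count <- function(counts, total_tags, target = 1e7) {
  if (length(total_tags) != 1L || is.na(total_tags) || total_tags <= 0) {
    stop("total_tags must be a single positive number", call. = FALSE)
  }
  counts * (target / total_tags)
}
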