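#' Calibrate ubiquitous open-chromatin reference peaks
#'
#' Given a collection of peak sets from many samples (e.g. DNase
#' hypersensitivity calls across cell types), finds the genome
#' positions covered in more than `presence_threshold` of the sets and
#' merges them into reference peaks. These "always open" sites anchor
#' the PRC metric: a well-digested library should recover nearly all
#' of them. Two calibration modes are supported: the human-style
#' strict mode (`comparator = ">"`, e.g. accessible in more than 97%
#' of samples) and the common-to-all mode (`comparator = ">="` with
#' `presence_threshold = 1`).
#'
#' Presence is assessed per base, which is robust to peak boundaries
#' shifting or peaks fragmenting between samples; each input set is
#' self-merged first so one sample never counts twice at a base.
#' Slivers narrower than `min_width` bp are discarded.
#'
#' @param peak_sets List of >= 2 `GRanges` peak sets.
#' @param presence_threshold Fraction of sets in `(0, 1]` a base must
#'   be present in; default 0.97.
#' @param comparator `">"` (strictly greater, default) or `">="`.
#' @param min_width Minimum reference-peak width in bp; default 20.
#' @return A `GRanges` of disjoint, sorted reference peaks with
#'   attributes `n_source_sets`, `presence_threshold` and `comparator`.
#' @export
calibrate_reference_peaks <- function(peak_sets, presence_threshold = 0.97,
                                      comparator = c(">", ">="),
                                      min_width = 20L) {
  comparator <- match.arg(comparator)
  if (!is.list(peak_sets) || length(peak_sets) < 2L) {
    stop("reference calibration needs at least 2 peak sets", call. = FALSE)
  }
  if (presence_threshold <= 0 || presence_threshold > 1) {
    stop("presence_threshold must be in (0, 1]", call. = FALSE)
  }
  n <- length(peak_sets)
  merged <- lapply(peak_sets, GenomicRanges::reduce, ignore.strand = TRUE)
  # per-base count of sets present; threshold on the fraction
  need <- if (comparator == ">") {
    function(x) x / n > presence_threshold
  } else {
    function(x) x / n >= presence_threshold
  }
  chrom_of <- function(g) as.character(GenomicRanges::seqnames(g))
  all_ch <- sort(unique(unlist(lapply(merged, function(g) unique(chrom_of(g))))))
  out <- GenomicRanges::GRanges()
  for (ch in all_ch) {
    # coverages are summed on a common per-contig width so every set
    # contributes a zero run past its last peak
    irs <- lapply(merged, function(g) {
      IRanges::ranges(g[chrom_of(g) == ch])
    })
    L <- max(vapply(irs, function(ir) {
      if (length(ir)) max(IRanges::end(ir)) else 0L
    }, 0L))
    r <- Reduce(`+`, lapply(irs, IRanges::coverage, width = L))
    keep <- need(r)
    ir <- IRanges::reduce(methods::as(keep, "IRanges"))
    ir <- ir[IRanges::width(ir) >= min_width]
    if (length(ir)) {
      out <- c(out, GenomicRanges::GRanges(ch, ir))
    }
  }
  out <- GenomicRanges::sort(out, ignore.strand = TRUE)
  attr(out, "n_source_sets") <- n
  attr(out, "presence_threshold") <- presence_threshold
  attr(out, "comparator") <- comparator
  out
}

#' Percent Reference peak Coverage (PRC)
#'
#' The fraction (as a percentage) of calibrated reference peaks that
#' are overlapped by at least 1 bp of any hotspot. Because the
#' reference peaks are open in essentially every cell type, PRC
#' measures digestion depth and genome-wide coverage: a shallow or
#' poorly tagmented library misses reference peaks and scores low,
#' independently of TSS-proximal signal.
#'
#' @param hotspots `GRanges` of the sample's hotspots.
#' @param reference `GRanges` of reference peaks from
#'   [calibrate_reference_peaks()] (or any non-empty peak set).
#' @return Percentage in `[0, 100]`.
#' @export
prc <- function(hotspots, reference) {
  stopifnot(methods::is(hotspots, "GRanges"), methods::is(reference, "GRanges"))
  if (length(reference) == 0L) {
    stop("reference peak set is empty", call. = FALSE)
  }
  covered <- IRanges::overlapsAny(reference, hotspots, ignore.strand = TRUE)
  100 * sum(covered) / length(reference)
}
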