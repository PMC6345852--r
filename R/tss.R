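#' Aggregate cut-site profile around transcription start sites
#'
#' Counts Tn5 transposition events in 1-bp bins at relative offsets
#' around every TSS, orienting by gene strand so that positive offsets
#' are always downstream of transcription, and summing across TSSs.
#' Counts are scaled to a fixed depth (default 10 million tags) so
#' profiles are comparable between libraries.
#'
#' @param cuts Width-1 `GRanges` of cut sites (see [tn5_shift()]).
#' @param tss Stranded width-1 `GRanges` of TSS positions (see
#'   [tss_sites()]).
#' @param halfwidth Window half-size in bp: offsets run from
#'   `-halfwidth` to `halfwidth - 1`. 2000 for the TSS score; 5000 for
#'   the published-style histograms.
#' @param total_tags Library size; defaults to `length(cuts)`.
#' @param target Normalization depth, default `1e7`.
#' @param dedup Collapse duplicate TSS positions (isoforms sharing a
#'   start) before aggregating. Default `TRUE`.
#' @return A list of class `"tss_aggregate"`: `offsets`, `counts`
#'   (depth-normalized), `raw_counts`, `n_tss`, `halfwidth`,
#'   `total_tags`, `target`.
#' @export
tss_aggregate <- function(cuts, tss, halfwidth = 2000L,
                          total_tags = length(cuts), target = 1e7,
                          dedup = TRUE) {
  stopifnot(methods::is(cuts, "GRanges"), methods::is(tss, "GRanges"))
  if (length(tss) == 0L) stop("TSS list is empty", call. = FALSE)
  st <- as.character(GenomicRanges::strand(tss))
  if (any(st == "*")) stop("TSS positions must be stranded", call. = FALSE)
  if (dedup) {
    key <- paste(GenomicRanges::seqnames(tss), GenomicRanges::start(tss), st)
    tss <- tss[!duplicated(key)]
    st <- st[!duplicated(key)]
  }
  W <- as.integer(halfwidth)
  offsets <- seq.int(-W, W - 1L)
  raw <- numeric(2L * W)
  if (length(cuts)) {
    tpos <- GenomicRanges::start(tss)
    win <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(tss),
      IRanges::IRanges(pmax(1L, ifelse(st == "+", tpos - W, tpos - W + 1L)),
                       ifelse(st == "+", tpos + W - 1L, tpos + W)))
    hits <- GenomicRanges::findOverlaps(cuts, win, ignore.strand = TRUE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      cpos <- GenomicRanges::start(cuts)[q]
      o <- ifelse(st[s] == "+", cpos - tpos[s], tpos[s] - cpos)
      ok <- o >= -W & o <= W - 1L
      raw <- tabulate(o[ok] + W + 1L, nbins = 2L * W)
    }
  }
  structure(list(offsets = offsets,
                 counts = normalize_tag_count(raw, max(total_tags, 1L), target),
                 raw_counts = raw,
                 n_tss = length(tss),
                 halfwidth = W,
                 total_tags = total_tags,
                 target = target),
            class = "tss_aggregate")
}

#' @export
print.tss_aggregate <- function(x, ...) {
  cat("TSS aggregate over", x$n_tss, "sites, +/-", x$halfwidth,
      "bp,", x$total_tags, "tags\n")
  invisible(x)
}

#' TSS enrichment score
#'
#' The signal-to-noise QC metric recommended by ENCODE: the mean
#' per-bp cut count in a central window around the TSS divided by the
#' mean in the two outermost flank windows of the aggregate profile.
#' A score near 1 indicates no enrichment (background); well-digested
#' open-chromatin libraries score substantially higher.
#'
#' @param agg A `"tss_aggregate"` from [tss_aggregate()].
#' @param center_halfwidth Central window half-size in bp; default 50
#'   (window `[-50, 50]`).
#' @param flank_width Width of each outermost flank window in bp;
#'   default 100.
#' @return Non-negative score; `Inf` (with a warning) when the flanks
#'   carry no signal but the centre does.
#' @export
tss_score <- function(agg, center_halfwidth = 50L, flank_width = 100L) {
  stopifnot(inherits(agg, "tss_aggregate"))
  if (agg$halfwidth < center_halfwidth + flank_width) {
    stop("aggregate window too small for the requested score windows",
         call. = FALSE)
  }
  counts <- agg$counts
  n <- length(counts)
  center <- counts[abs(agg$offsets) <= center_halfwidth]
  flank <- c(counts[seq_len(flank_width)],
             counts[seq.int(n - flank_width + 1L, n)])
  cm <- mean(center); fm <- mean(flank)
  if (fm == 0) {
    if (cm == 0) return(0)
    warning("flank signal is zero; TSS score reported as Inf")
    return(Inf)
  }
  cm / fm
}
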