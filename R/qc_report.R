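#' Run the full ATAC-seq QC pipeline
#'
#' Composes the package's metrics into the standard QC quartet for one
#' sample: mitochondrial read percentage, replicate-concordant hotspot
#' count, Percent Reference peak Coverage, and TSS enrichment score,
#' together with the fragment-size phasing score and a provenance
#' block recording inputs and parameters. Each stage failure is
#' re-raised with the stage name.
#'
#' @param alignments Path to a BAM/SAM/fragment-BED file, or a list as
#'   returned by [read_alignments()].
#' @param pooled_peaks `GRanges` or narrowPeak/BED path: peaks called
#'   on pooled replicates.
#' @param replicate_peaks List of `GRanges` or paths, one per
#'   replicate.
#' @param reference `GRanges` or BED path of calibrated reference
#'   peaks.
#' @param gene_model `GRanges` from [read_gene_model()] or a BED12
#'   path.
#' @param min_frac Concordance threshold, default 0.5.
#' @param tss_halfwidth TSS aggregation half-window, default 2000 bp.
#' @param min_mapq,exclude_contigs Passed to [read_alignments()].
#' @param seed Seed recorded in the provenance block (the pipeline
#'   itself is deterministic).
#' @return A list of class `"qc_report"` with fields `hotspot_count`,
#'   `prc_percent`, `tss_score`, `mito_percent`, `phasing_score`,
#'   `n_fragments`, `n_cuts` and `provenance`.
#' @export
run_qc <- function(alignments, pooled_peaks, replicate_peaks, reference,
                   gene_model, min_frac = 0.5, tss_halfwidth = 2000L,
                   min_mapq = 0L, exclude_contigs = mito_contigs(),
                   seed = NA_integer_) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  as_peaks <- function(x, what) {
    if (methods::is(x, "GRanges")) return(x)
    stage(what, {
      if (!file.exists(x)) stop("file not found: ", x)
      if (grepl("\\.narrowPeak$", x, ignore.case = TRUE)) {
        read_narrowpeak(x)
      } else {
        read_bed(x)
      }
    })
  }
  aln <- if (is.list(alignments) && !is.null(alignments$fragments)) {
    alignments
  } else {
    stage("alignments", read_alignments(alignments, min_mapq = min_mapq,
                                        exclude_contigs = exclude_contigs))
  }
  pooled <- as_peaks(pooled_peaks, "pooled_peaks")
  reps <- lapply(replicate_peaks, as_peaks, what = "replicate_peaks")
  ref <- as_peaks(reference, "prc")
  genes <- if (methods::is(gene_model, "GRanges")) gene_model else {
    stage("gene_model", read_gene_model(gene_model, dialect = "bed12"))
  }
  mito <- stage("mito_fraction",
                mito_fraction(aln$contig_tallies, exclude_contigs))
  fsp <- stage("fragment_size_profile", fragment_size_profile(aln$fragments))
  cuts <- stage("tn5_shift", tn5_shift(aln$fragments)$cuts)
  hotspots <- stage("concordant_hotspots",
                    concordant_hotspots(pooled, reps, min_frac = min_frac))
  prc_val <- stage("prc", prc(hotspots, ref))
  agg <- stage("tss_aggregate",
               tss_aggregate(cuts, tss_sites(genes), halfwidth = tss_halfwidth))
  score <- stage("tss_score", tss_score(agg))
  structure(list(
    hotspot_count = length(hotspots),
    prc_percent = prc_val,
    tss_score = score,
    mito_percent = mito,
    phasing_score = fsp$phasing_score,
    n_fragments = length(aln$fragments),
    n_cuts = length(cuts),
    provenance = list(
      tool = "atacqc",
      version = as.character(utils::packageVersion("atacqc")),
      seed = seed,
      parameters = list(min_frac = min_frac, tss_halfwidth = tss_halfwidth,
                        min_mapq = min_mapq,
                        exclude_contigs = exclude_contigs),
      n_pooled_peaks = length(pooled),
      n_replicates = length(reps),
      n_reference_peaks = length(ref),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("ATAC-seq QC report\n",
      "  hotspots:      ", x$hotspot_count, "\n",
      "  PRC:           ", format(x$prc_percent, digits = 4), "%\n",
      "  TSS score:     ", format(x$tss_score, digits = 4), "\n",
      "  % mito reads:  ", format(x$mito_percent, digits = 4), "\n",
      "  phasing score: ", format(x$phasing_score, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Serialize a QC report
#'
#' JSON is the canonical form (all fields including provenance); the
#' TSV is a one-row projection of the metric fields.
#'
#' @param report A `"qc_report"`.
#' @param json_path,tsv_path Output paths (either may be `NULL`).
#' @param timestamp Include the provenance timestamp; set `FALSE` for
#'   byte-reproducible output.
#' @return The report, invisibly.
#' @export
write_qc_report <- function(report, json_path = NULL, tsv_path = NULL,
                            timestamp = TRUE) {
  stopifnot(inherits(report, "qc_report"))
  out <- unclass(report)
  if (!timestamp) out$provenance$timestamp <- NULL
  if (!is.null(json_path)) {
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(hotspot_count = report$hotspot_count,
                     prc_percent = report$prc_percent,
                     tss_score = report$tss_score,
                     mito_percent = report$mito_percent,
                     phasing_score = report$phasing_score,
                     n_fragments = report$n_fragments,
                     n_cuts = report$n_cuts)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}
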