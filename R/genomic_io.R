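#' Default mitochondrial contig names
#'
#' Aliases under which the mitochondrial genome appears in common
#' reference assemblies. Used by [read_alignments()] and
#' [mito_fraction()]; pass your own vector to override.
#'
#' @return Character vector of contig names.
#' @export
mito_contigs <- function() c("chrM", "chrMT", "MT", "M")

## BED files are 0-based half-open; GRanges are 1-based closed.
## These two helpers are the only place the conversion happens.
bed_to_granges <- function(chrom, start0, end0, strand = NULL, ...) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = if (is.null(strand)) "*" else strand,
    ...
  )
}

granges_start0 <- function(gr) GenomicRanges::start(gr) - 1L
granges_end0 <- function(gr) GenomicRanges::end(gr)

read_tab_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a BED3/BED6 file of genomic intervals
#'
#' Track, browser and comment lines are skipped. Coordinates are
#' converted from BED's 0-based half-open convention to the 1-based
#' closed convention of `GRanges`; widths are preserved exactly.
#'
#' @param path Path to a tab-separated BED file with at least 3 columns.
#' @return A [GenomicRanges::GRanges] in file order. For BED6 input the
#'   `name` and `score` columns are kept as metadata columns and the
#'   strand column is honoured (`.` becomes `*`).
#' @export
read_bed <- function(path) {
  tl <- read_tab_lines(path)
  if (length(tl$lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", tl$lineno[which(nf < 3L)[1L]],
         ": fewer than 3 columns", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0) | !nzchar(chrom))
  if (length(bad)) {
    stop("malformed BED line ", tl$lineno[bad[1L]],
         ": non-numeric coordinates", call. = FALSE)
  }
  bad <- which(end0 <= start0 | start0 < 0L)
  if (length(bad)) {
    stop("malformed BED line ", tl$lineno[bad[1L]],
         ": end <= start (or negative start)", call. = FALSE)
  }
  strand <- rep("*", length(fields))
  name <- score <- NULL
  if (all(nf >= 6L)) {
    s <- vapply(fields, `[[`, "", 6L)
    if (any(!s %in% c("+", "-", "."))) {
      stop("malformed BED line ", tl$lineno[which(!s %in% c("+", "-", "."))[1L]],
           ": invalid strand", call. = FALSE)
    }
    strand <- ifelse(s == ".", "*", s)
    name <- vapply(fields, `[[`, "", 4L)
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  }
  gr <- bed_to_granges(chrom, start0, end0, strand)
  if (!is.null(name)) {
    S4Vectors::mcols(gr)$name <- name
    S4Vectors::mcols(gr)$score <- score
  }
  gr
}

#' Write intervals as BED3/BED6
#'
#' The inverse of [read_bed()]: GRanges coordinates are converted back
#' to 0-based half-open. If the input carries `name`/`score` metadata
#' columns (or a non-`*` strand) a 6-column BED is written, otherwise
#' 3 columns. Reading a canonical BED6 file and writing it back
#' reproduces it byte for byte.
#'
#' @param gr A [GenomicRanges::GRanges].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  stopifnot(methods::is(gr, "GRanges"))
  m <- S4Vectors::mcols(gr)
  six <- ("name" %in% colnames(m)) || any(as.character(GenomicRanges::strand(gr)) != "*")
  cols <- list(as.character(GenomicRanges::seqnames(gr)),
               format_coord(granges_start0(gr)), format_coord(granges_end0(gr)))
  if (six) {
    nm <- if ("name" %in% colnames(m)) m$name else rep(".", length(gr))
    sc <- if ("score" %in% colnames(m)) m$score else rep(0, length(gr))
    st <- as.character(GenomicRanges::strand(gr))
    st[st == "*"] <- "."
    cols <- c(cols, list(nm, format_coord(sc), st))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

## integer-valued scores/coordinates print without a decimal point
format_coord <- function(x) {
  out <- as.character(x)
  whole <- !is.na(x) & x == round(x)
  out[whole] <- format(round(x[whole]), scientific = FALSE, trim = TRUE)
  out
}

#' Read an ENCODE narrowPeak file
#'
#' narrowPeak is a strict 10-column BED6+4 format: chrom, start, end,
#' name, score, strand, signalValue, pValue, qValue, summit offset.
#'
#' @param path Path to a 10-column narrowPeak file.
#' @return A [GenomicRanges::GRanges] with metadata columns `name`,
#'   `score` (the signalValue, per peak-ranking convention), `pValue`,
#'   `qValue`, and `summit` (0-based offset from peak start; `NA` when
#'   the file records -1, i.e. no summit call).
#' @export
read_narrowpeak <- function(path) {
  tl <- read_tab_lines(path)
  if (length(tl$lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10L)) {
    stop("narrowPeak line ", tl$lineno[which(nf != 10L)[1L]],
         ": expected 10 columns, got ", nf[which(nf != 10L)[1L]], call. = FALSE)
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  start0 <- as.integer(col(2)); end0 <- as.integer(col(3))
  bad <- which(is.na(start0) | is.na(end0) | end0 <= start0)
  if (length(bad)) {
    stop("narrowPeak line ", tl$lineno[bad[1L]], ": invalid interval", call. = FALSE)
  }
  s <- col(6); s[s == "."] <- "*"
  summit <- as.integer(col(10))
  summit[summit < 0L] <- NA_integer_
  gr <- bed_to_granges(col(1), start0, end0, s)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = col(4),
    score = as.numeric(col(7)),
    pValue = as.numeric(col(8)),
    qValue = as.numeric(col(9)),
    summit = summit
  )
  gr
}

#' Write intervals as narrowPeak
#'
#' @param gr A `GRanges`, ideally from [read_narrowpeak()]; missing
#'   metadata columns are filled with narrowPeak's conventional
#'   placeholders (`-1` for absent statistics and summit).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(gr, path) {
  stopifnot(methods::is(gr, "GRanges"))
  m <- S4Vectors::mcols(gr)
  getcol <- function(nm, default) if (nm %in% colnames(m)) m[[nm]] else rep(default, length(gr))
  st <- as.character(GenomicRanges::strand(gr)); st[st == "*"] <- "."
  summit <- getcol("summit", NA_integer_)
  summit[is.na(summit)] <- -1L
  lines <- paste(as.character(GenomicRanges::seqnames(gr)),
                 format_coord(granges_start0(gr)), format_coord(granges_end0(gr)),
                 getcol("name", "."), "0", st,
                 format_coord(getcol("score", 0)),
                 format_coord(getcol("pValue", -1)),
                 format_coord(getcol("qValue", -1)),
                 format_coord(summit), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read aligned paired-end fragments with QC tallies
#'
#' Accepts a coordinate-sorted BAM, a SAM text file (converted on the
#' fly), or a BED6 "fragment dialect" where each line is one sequenced
#' template with the strand of read 1 in column 6. For SAM/BAM only
#' proper pairs are used and each template is counted once (from the
#' mate with positive template length). Fragments on excluded contigs
#' (typically the mitochondrial genome) are tallied but not returned,
#' so the mitochondrial fraction can be computed; fragments below the
#' MAPQ cutoff go to a `low_mapq` tally.
#'
#' @param path Path to a `.bam`, `.sam`, or BED fragment file.
#' @param min_mapq Minimum mapping quality; defaults to 0 (no filter).
#' @param exclude_contigs Contig names tallied but not emitted;
#'   defaults to [mito_contigs()].
#' @param dedup If `TRUE`, fragments duplicated by exact coordinates
#'   and strand are collapsed to one. Off by default.
#' @param include_secondary If `TRUE`, secondary/supplementary SAM
#'   records are kept; excluded by default.
#' @return A list with elements `fragments` (a `GRanges` with a `mapq`
#'   metadata column; strand is that of read 1), `contig_tallies`
#'   (named integer vector over all contigs seen, summing to every
#'   proper-pair template scanned), and `dropped` (counts of
#'   `low_mapq`, `improper`, `excluded`, `duplicate` templates).
#' @export
read_alignments <- function(path, min_mapq = 0L,
                            exclude_contigs = mito_contigs(),
                            dedup = FALSE, include_secondary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bam", "sam")) {
    frag <- read_fragments_bam(path, include_secondary)
  } else {
    frag <- read_fragments_bed(path)
  }
  gr <- frag$fragments
  improper <- frag$improper
  tallies <- table(factor(as.character(GenomicRanges::seqnames(gr))))
  contig_tallies <- stats::setNames(as.integer(tallies), names(tallies))
  low <- S4Vectors::mcols(gr)$mapq < min_mapq
  n_low <- sum(low)
  gr <- gr[!low]
  excl <- as.character(GenomicRanges::seqnames(gr)) %in% exclude_contigs
  n_excl <- sum(excl)
  gr <- gr[!excl]
  n_dup <- 0L
  if (dedup && length(gr)) {
    key <- paste(GenomicRanges::seqnames(gr), GenomicRanges::start(gr),
                 GenomicRanges::end(gr), GenomicRanges::strand(gr))
    keep <- !duplicated(key)
    n_dup <- sum(!keep)
    gr <- gr[keep]
  }
  list(fragments = gr,
       contig_tallies = contig_tallies,
       dropped = list(low_mapq = n_low, improper = improper,
                      excluded = n_excl, duplicate = n_dup))
}

read_fragments_bam <- function(path, include_secondary) {
  if (tolower(tools::file_ext(path)) == "sam") {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  what <- c("rname", "pos", "isize", "mapq", "flag")
  res <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(what = what))[[1L]]
  flag <- res$flag
  mapped <- !bitwAnd(flag, 4L)
  paired <- bitwAnd(flag, 1L) > 0L
  proper <- bitwAnd(flag, 2L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  keep_rec <- mapped & (!secondary | include_secondary)
  improper <- sum(keep_rec & paired & !proper) %/% 2L
  # one record per template: the leftmost mate carries TLEN > 0
  sel <- keep_rec & proper & res$isize > 0L
  if (!any(sel)) {
    return(list(fragments = GenomicRanges::GRanges(), improper = improper))
  }
  # strand of read 1: this record's strand if it is read 1, else flipped
  rev <- bitwAnd(flag[sel], 16L) > 0L
  first <- bitwAnd(flag[sel], 64L) > 0L
  r1_rev <- ifelse(first, rev, !rev)
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(res$rname[sel]),
    ranges = IRanges::IRanges(start = res$pos[sel],
                              width = res$isize[sel]),
    strand = ifelse(r1_rev, "-", "+"),
    mapq = res$mapq[sel]
  )
  list(fragments = gr, improper = improper)
}

read_fragments_bed <- function(path) {
  gr <- read_bed(path)
  m <- S4Vectors::mcols(gr)
  mapq <- if ("score" %in% colnames(m)) as.integer(m$score) else rep(255L, length(gr))
  mapq[is.na(mapq)] <- 255L
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(mapq = mapq)
  list(fragments = gr, improper = 0L)
}

#' Read a JASPAR-format position frequency matrix
#'
#' Supports the JASPAR text layouts: a `>ID name` header followed by
#' four rows (A, C, G, T), either bare numbers or the bracketed
#' `A [ 1 2 3 ]` form.
#'
#' @param path Path to a JASPAR PFM text file.
#' @return A 4 x W numeric count matrix with rownames A/C/G/T, class
#'   `"pfm"`, and attributes `motif_id` and `motif_name`.
#' @export
read_pfm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  motif_id <- motif_name <- NA_character_
  if (length(lines) && startsWith(lines[1L], ">")) {
    hdr <- strsplit(sub("^>", "", lines[1L]), "\\s+")[[1L]]
    motif_id <- hdr[1L]
    if (length(hdr) > 1L) motif_name <- paste(hdr[-1L], collapse = " ")
    lines <- lines[-1L]
  }
  if (length(lines) != 4L) {
    stop("PFM must have exactly 4 count rows (A,C,G,T), found ",
         length(lines), call. = FALSE)
  }
  rows <- lapply(lines, function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("[][]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  })
  if (length(unique(lengths(rows))) != 1L) {
    stop("ragged PFM: rows have lengths ",
         paste(lengths(rows), collapse = ", "), call. = FALSE)
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- c("A", "C", "G", "T")
  validate_pfm(mat)
  structure(mat, class = c("pfm", class(mat)),
            motif_id = motif_id, motif_name = motif_name)
}

validate_pfm <- function(mat) {
  if (any(is.na(mat))) stop("PFM contains non-numeric counts", call. = FALSE)
  if (any(mat < 0)) stop("PFM contains negative counts", call. = FALSE)
  if (ncol(mat) < 4L) stop("PFM width must be >= 4, got ", ncol(mat), call. = FALSE)
  if (any(colSums(mat) <= 0)) stop("PFM has a zero-total column", call. = FALSE)
  invisible(mat)
}

#' Read a gene model (BED12 or refFlat)
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed12"` (UCSC BED with block columns) or
#'   `"refflat"` (geneName, name, chrom, strand, txStart, txEnd,
#'   cdsStart, cdsEnd, exonCount, exonStarts, exonEnds).
#' @return A [GenomicRanges::GRanges] of transcript spans (stranded)
#'   with metadata columns `name` (gene/transcript label) and `exons`,
#'   an [IRanges::IRangesList] of exon intervals in genomic 1-based
#'   coordinates, sorted, non-overlapping and contained in the span.
#' @seealso [tss_sites()] to derive transcription start sites.
#' @export
read_gene_model <- function(path, dialect = c("bed12", "refflat")) {
  dialect <- match.arg(dialect)
  tl <- read_tab_lines(path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  if (dialect == "bed12") {
    if (any(lengths(fields) < 12L)) {
      stop("BED12 line ", tl$lineno[which(lengths(fields) < 12L)[1L]],
           ": fewer than 12 columns", call. = FALSE)
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- as.integer(vapply(fields, `[[`, "", 2L))
    end0 <- as.integer(vapply(fields, `[[`, "", 3L))
    name <- vapply(fields, `[[`, "", 4L)
    strand <- vapply(fields, `[[`, "", 6L)
    sizes <- lapply(fields, function(f) as.integer(strsplit(f[[11L]], ",")[[1L]]))
    offs <- lapply(fields, function(f) as.integer(strsplit(f[[12L]], ",")[[1L]]))
    exon_start0 <- Map(function(s, o) s + o, start0, offs)
    exon_end0 <- Map(`+`, exon_start0, sizes)
  } else {
    if (any(lengths(fields) < 11L)) {
      stop("refFlat line ", tl$lineno[which(lengths(fields) < 11L)[1L]],
           ": fewer than 11 columns", call. = FALSE)
    }
    name <- vapply(fields, `[[`, "", 1L)
    chrom <- vapply(fields, `[[`, "", 3L)
    strand <- vapply(fields, `[[`, "", 4L)
    start0 <- as.integer(vapply(fields, `[[`, "", 5L))
    end0 <- as.integer(vapply(fields, `[[`, "", 6L))
    exon_start0 <- lapply(fields, function(f) as.integer(strsplit(f[[10L]], ",")[[1L]]))
    exon_end0 <- lapply(fields, function(f) as.integer(strsplit(f[[11L]], ",")[[1L]]))
  }
  if (any(!strand %in% c("+", "-"))) {
    stop("gene model line ", tl$lineno[which(!strand %in% c("+", "-"))[1L]],
         ": strand must be + or -", call. = FALSE)
  }
  for (i in seq_along(fields)) {
    es <- exon_start0[[i]]; ee <- exon_end0[[i]]
    if (any(ee <= es)) {
      stop("gene model line ", tl$lineno[i], ": empty exon block", call. = FALSE)
    }
    if (is.unsorted(es, strictly = TRUE) || any(es[-1L] < ee[-length(ee)])) {
      stop("gene model line ", tl$lineno[i],
           ": exons must be sorted and non-overlapping", call. = FALSE)
    }
    if (min(es) < start0[i] || max(ee) > end0[i]) {
      stop("gene model line ", tl$lineno[i],
           ": exon block outside transcript span", call. = FALSE)
    }
  }
  gr <- bed_to_granges(chrom, start0, end0, strand)
  S4Vectors::mcols(gr)$name <- name
  S4Vectors::mcols(gr)$exons <- IRanges::IRangesList(
    Map(function(s, e) IRanges::IRanges(start = s + 1L, end = e),
        exon_start0, exon_end0)
  )
  gr
}

#' Transcription start sites of a gene model
#'
#' The TSS is the transcript's 5' end: `txStart` on the plus strand
#' and `txEnd - 1` (0-based; the last transcribed base) on the minus
#' strand.
#'
#' @param genes A `GRanges` from [read_gene_model()], or any stranded
#'   `GRanges` of transcript spans.
#' @param dedup Collapse transcripts sharing a TSS (same contig,
#'   position and strand) to one site. Default `TRUE`.
#' @return A width-1 stranded `GRanges` of TSS positions.
#' @export
tss_sites <- function(genes, dedup = TRUE) {
  stopifnot(methods::is(genes, "GRanges"))
  st <- as.character(GenomicRanges::strand(genes))
  if (any(st == "*")) stop("gene model records must be stranded", call. = FALSE)
  pos <- ifelse(st == "+", GenomicRanges::start(genes), GenomicRanges::end(genes))
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                               IRanges::IRanges(pos, width = 1L),
                               strand = st)
  if (dedup) {
    key <- paste(GenomicRanges::seqnames(gr), GenomicRanges::start(gr), st)
    gr <- gr[!duplicated(key)]
  }
  gr
}
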