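## Run expr under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## Draw n indices from 1..length(w) with probability proportional to w.
sample_weighted <- function(n, w) {
  cum <- cumsum(as.numeric(w))
  tot <- cum[length(cum)]
  if (tot <= 0) stop("all weights are zero", call. = FALSE)
  findInterval(stats::runif(n) * tot, cum, rightmost.closed = FALSE) + 1L
}

#' Specification for a synthetic ATAC-seq experiment
#'
#' Bundles every parameter of the generator: the contig layout
#' (including a mitochondrial contig), the fragment count, the planted
#' TSS enrichment (a Gaussian intensity kernel of width `tss_sigma`
#' peaking at `tss_enrichment_factor` times background), the hexamer
#' insertion-preference table, the planted motif and its footprint
#' protection factor, the mitochondrial fragment share, the
#' nucleosomal fragment-length mixture, and the open-region layout.
#' Defaults emulate a healthy ~50k-cell ATAC library at desk scale:
#' mono/di/tri-nucleosome length modes at 75/265/455 bp, a few percent
#' mitochondrial contamination, and several-fold TSS enrichment.
#'
#' @param contigs Named integer vector of contig lengths; must include
#'   `mito_contig`. Non-mito contigs must be >= 10 kb.
#' @param mito_contig Name of the mitochondrial contig.
#' @param seed Integer seed recorded in all outputs.
#' @param n_fragments Number of templates to simulate.
#' @param tss_enrichment_factor Intensity multiple at the TSS (>= 1).
#' @param tss_sigma Gaussian kernel width in bp.
#' @param hexamer_rates `NULL` for uniform insertion, or a named
#'   numeric vector of relative per-hexamer cut rates (hexamers not
#'   named default to 1).
#' @param motif_consensus Consensus sequence planted into the genome.
#' @param n_motif_sites Number of planted motif instances.
#' @param protection_factor Multiplicative cut protection over motif
#'   positions (1 = unbound, < 1 = footprint).
#' @param mito_fraction Share of fragments placed on the mito contig.
#' @param frag_weights,frag_means,frag_sds Fragment-length mixture
#'   (weights sum to 1).
#' @param n_genes Transcripts in the gene model.
#' @param tss_spacing Minimum separation between TSSs in bp.
#' @param n_open_regions,open_width,open_factor Accessible-region
#'   layout: count, width (bp) and intensity multiple.
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(contigs = c(chr1 = 200000L, chrM = 16000L),
                            mito_contig = "chrM",
                            seed = 1L,
                            n_fragments = 100000L,
                            tss_enrichment_factor = 5,
                            tss_sigma = 75,
                            hexamer_rates = NULL,
                            motif_consensus = "TGACGTCAAG",
                            n_motif_sites = 20L,
                            protection_factor = 1,
                            mito_fraction = 0.05,
                            frag_weights = c(0.45, 0.35, 0.20),
                            frag_means = c(75, 265, 455),
                            frag_sds = c(15, 25, 30),
                            n_genes = 12L,
                            tss_spacing = 12000L,
                            n_open_regions = 25L,
                            open_width = 800L,
                            open_factor = 8) {
  if (!mito_contig %in% names(contigs)) {
    stop("contigs must include the mitochondrial contig", call. = FALSE)
  }
  if (any(contigs <= 0L)) stop("zero-length contig", call. = FALSE)
  main <- contigs[names(contigs) != mito_contig]
  if (any(main < 10000L)) {
    stop("non-mitochondrial contigs must be at least 10 kb", call. = FALSE)
  }
  if (mito_fraction < 0 || mito_fraction > 1) {
    stop("mito_fraction must be in [0, 1]", call. = FALSE)
  }
  if (abs(sum(frag_weights) - 1) > 1e-8 || any(frag_weights < 0)) {
    stop("fragment mixture weights must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (protection_factor < 0) stop("protection_factor must be >= 0", call. = FALSE)
  if (tss_enrichment_factor < 1) {
    stop("tss_enrichment_factor must be >= 1", call. = FALSE)
  }
  structure(list(contigs = contigs, mito_contig = mito_contig,
                 seed = as.integer(seed), n_fragments = as.integer(n_fragments),
                 tss_enrichment_factor = tss_enrichment_factor,
                 tss_sigma = tss_sigma, hexamer_rates = hexamer_rates,
                 motif_consensus = toupper(motif_consensus),
                 n_motif_sites = as.integer(n_motif_sites),
                 protection_factor = protection_factor,
                 mito_fraction = mito_fraction,
                 frag_weights = frag_weights, frag_means = frag_means,
                 frag_sds = frag_sds,
                 n_genes = as.integer(n_genes),
                 tss_spacing = as.integer(tss_spacing),
                 n_open_regions = as.integer(n_open_regions),
                 open_width = as.integer(open_width),
                 open_factor = open_factor),
            class = "simulation_spec")
}

## place n non-overlapping intervals of width w in 1..L, min gap `gap`
place_intervals <- function(n, w, L, gap = 0L, lower = 1L) {
  if (n == 0L) return(integer(0))
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < n && tries < 50L * n + 200L) {
    cand <- floor(stats::runif(1, lower, L - w))
    if (all(abs(cand - starts) >= w + gap)) starts <- c(starts, cand)
    tries <- tries + 1L
  }
  if (length(starts) < n) {
    stop("could not place ", n, " intervals of width ", w,
         " on a ", L, " bp contig", call. = FALSE)
  }
  sort(as.integer(starts))
}

#' Generate a synthetic genome with known truth
#'
#' Draws i.i.d. uniform A/C/G/T sequence for every contig, plants
#' `n_motif_sites` copies of the motif consensus inside accessible
#' regions on the main contigs, and lays out a gene model with known
#' TSS positions. The mitochondrial contig carries no genes, open
#' regions or motifs. Deterministic for a given spec and seed.
#'
#' @param spec A [simulation_spec()].
#' @return A list: `genome` (named character vector), `genes`
#'   (`GRanges` with `name` and `exons`, as [read_gene_model()]
#'   returns), and `truth` with `motif_sites`, `open_regions`, `tss`
#'   (`GRanges`), `consensus` and `seed`.
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  W <- nchar(spec$motif_consensus)
  if (W > min(spec$contigs)) stop("motif longer than a contig", call. = FALSE)
  with_seed(spec$seed, {
    genome <- vapply(spec$contigs, function(L) {
      paste(sample(BASES, L, replace = TRUE), collapse = "")
    }, "")
    names(genome) <- names(spec$contigs)
    main <- names(spec$contigs)[names(spec$contigs) != spec$mito_contig]
    # open regions and motif plants on the first main contig
    ch <- main[1L]
    L <- spec$contigs[[ch]]
    open_starts <- place_intervals(spec$n_open_regions, spec$open_width, L,
                                   gap = 200L)
    open <- if (length(open_starts)) {
      GenomicRanges::GRanges(ch, IRanges::IRanges(open_starts,
                                                  width = spec$open_width))
    } else GenomicRanges::GRanges()
    motif_sites <- GenomicRanges::GRanges()
    if (spec$n_motif_sites > 0L) {
      host <- sample(rep_len(seq_along(open), spec$n_motif_sites))
      offs <- floor(stats::runif(spec$n_motif_sites, 50,
                                 spec$open_width - 50 - W))
      mstart <- open_starts[host] + as.integer(offs)
      mstr <- sample(c("+", "-"), spec$n_motif_sites, replace = TRUE)
      keep <- !duplicated(floor(mstart / (W + 10L)))  # avoid overlap collisions
      mstart <- mstart[keep]; mstr <- mstr[keep]
      seqchars <- strsplit(genome[[ch]], "")[[1L]]
      for (i in seq_along(mstart)) {
        ins <- if (mstr[i] == "+") spec$motif_consensus else {
          revcomp_chr(spec$motif_consensus)
        }
        seqchars[mstart[i]:(mstart[i] + W - 1L)] <- strsplit(ins, "")[[1L]]
      }
      genome[[ch]] <- paste(seqchars, collapse = "")
      motif_sites <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(mstart, width = W), strand = mstr)
    }
    # gene model: evenly spaced TSSs with jitter, random strand, 2-3 exons
    genes <- GenomicRanges::GRanges()
    if (spec$n_genes > 0L) {
      slots <- floor(seq(6000, L - 6000, length.out = spec$n_genes))
      tss_pos <- as.integer(slots + floor(stats::runif(spec$n_genes, -500, 500)))
      strand <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
      tx_len <- as.integer(floor(stats::runif(spec$n_genes, 2000, 5000)))
      tx_start <- ifelse(strand == "+", tss_pos, pmax(1L, tss_pos - tx_len + 1L))
      tx_end <- ifelse(strand == "+", pmin(L, tss_pos + tx_len - 1L), tss_pos)
      exons <- vector("list", spec$n_genes)
      for (i in seq_len(spec$n_genes)) {
        len <- tx_end[i] - tx_start[i] + 1L
        e1 <- IRanges::IRanges(tx_start[i], width = max(100L, len %/% 5L))
        e2 <- IRanges::IRanges(tx_end[i] - max(100L, len %/% 5L) + 1L,
                               tx_end[i])
        exons[[i]] <- c(e1, e2)
      }
      genes <- GenomicRanges::GRanges(ch, IRanges::IRanges(tx_start, tx_end),
                                      strand = strand)
      S4Vectors::mcols(genes)$name <- sprintf("gene%03d", seq_len(spec$n_genes))
      S4Vectors::mcols(genes)$exons <- IRanges::IRangesList(exons)
    }
    truth <- list(motif_sites = motif_sites,
                  open_regions = open,
                  tss = if (length(genes)) tss_sites(genes) else GenomicRanges::GRanges(),
                  consensus = spec$motif_consensus,
                  seed = spec$seed)
    list(genome = genome, genes = genes, truth = truth)
  })
}

## per-contig, per-strand cut intensity implied by a spec
cut_intensity <- function(spec, genome, truth, protect = NULL) {
  if (is.null(protect)) protect <- truth$motif_sites
  rates <- rep(1, 4L^HEX_K)
  if (!is.null(spec$hexamer_rates)) {
    hr <- spec$hexamer_rates
    if (is.null(names(hr)) && length(hr) == 4L^HEX_K) {
      rates <- as.numeric(hr)
    } else {
      idx <- match(names(hr), hexamer_names())
      if (any(is.na(idx))) stop("unknown hexamer in rate table", call. = FALSE)
      rates[idx] <- as.numeric(hr)
    }
    if (any(rates < 0)) stop("hexamer rates must be >= 0", call. = FALSE)
  }
  tss <- truth$tss
  out <- list()
  for (ch in names(genome)) {
    L <- nchar(genome[[ch]])
    ph <- position_hexamers(base_codes(genome[[ch]]))
    ip <- ifelse(is.na(ph$plus_hex), 1, rates[ph$plus_hex])
    im <- ifelse(is.na(ph$minus_hex), 1, rates[ph$minus_hex])
    if (ch != spec$mito_contig) {
      mult <- rep(1, L)
      if (length(tss)) {
        tt <- tss[as.character(GenomicRanges::seqnames(tss)) == ch]
        E <- spec$tss_enrichment_factor; sg <- spec$tss_sigma
        if (E > 1 && length(tt)) {
          span <- ceiling(8 * sg)
          for (t in GenomicRanges::start(tt)) {
            lo <- max(1L, t - span); hi <- min(L, t + span)
            d <- seq.int(lo, hi) - t
            mult[lo:hi] <- mult[lo:hi] * (1 + (E - 1) * exp(-d^2 / (2 * sg^2)))
          }
        }
      }
      op <- truth$open_regions
      if (!is.null(op) && length(op) && spec$open_factor != 1) {
        opc <- op[as.character(GenomicRanges::seqnames(op)) == ch]
        for (i in seq_along(opc)) {
          lo <- GenomicRanges::start(opc)[i]; hi <- min(L, GenomicRanges::end(opc)[i])
          mult[lo:hi] <- mult[lo:hi] * spec$open_factor
        }
      }
      if (!is.null(protect) && length(protect) && spec$protection_factor != 1) {
        pr <- protect[as.character(GenomicRanges::seqnames(protect)) == ch]
        for (i in seq_along(pr)) {
          lo <- max(1L, GenomicRanges::start(pr)[i])
          hi <- min(L, GenomicRanges::end(pr)[i])
          mult[lo:hi] <- mult[lo:hi] * spec$protection_factor
        }
      }
      ip <- ip * mult
      im <- im * mult
    }
    out[[ch]] <- list(plus = ip, minus = im)
  }
  out
}

#' Simulate cut sites and fragments from a spec
#'
#' The per-position, per-strand cut intensity is the product of the
#' base rate, the hexamer preference at that position, the Gaussian
#' TSS enrichment kernel, the open-region factor, and the footprint
#' protection factor over protected intervals. In `paired` mode each
#' template draws its forward cut from the plus-strand intensity and
#' its reverse cut at a nucleosomal-mixture distance, accepted in
#' proportion to the minus-strand intensity there, so both template
#' ends carry the planted bias; cut sites are then exactly
#' [tn5_shift()] of the fragments. With `paired = FALSE`,
#' `2 * n_fragments` cut sites are drawn i.i.d. from the intensity
#' (no fragments), which is the cleanest input for cut-level analyses.
#' A binomial `mito_fraction` share of templates lands uniformly on
#' the mitochondrial contig.
#'
#' @param spec A [simulation_spec()].
#' @param genome,truth From [make_genome()].
#' @param paired Emit fragments and derive cuts from them (default),
#'   or draw cuts directly.
#' @param protect Optional `GRanges` of protected intervals; defaults
#'   to the planted motif sites.
#' @return A list: `fragments` (`GRanges` or `NULL`), `cuts` (width-1
#'   stranded `GRanges`), `n_mito`, `seed`.
#' @export
simulate_cuts <- function(spec, genome, truth, paired = TRUE,
                          protect = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  intensity <- cut_intensity(spec, genome, truth, protect)
  with_seed(spec$seed + 1L, {
    n <- spec$n_fragments
    n_mito <- stats::rbinom(1L, n, spec$mito_fraction)
    main <- names(genome)[names(genome) != spec$mito_contig]
    tot <- vapply(main, function(ch) {
      sum(intensity[[ch]]$plus) + sum(intensity[[ch]]$minus)
    }, 0)
    alloc <- stats::setNames(
      as.integer(round((n - n_mito) * tot / sum(tot))), main)
    alloc[spec$mito_contig] <- n_mito
    frag_list <- cut_list <- list()
    for (ch in names(alloc)) {
      m <- alloc[[ch]]
      if (m == 0L) next
      ipl <- intensity[[ch]]$plus
      imi <- intensity[[ch]]$minus
      L <- length(ipl)
      if (paired) {
        a <- sample_weighted(m, ipl)
        b <- draw_partner_cuts(a, imi, spec)
        # forward cut at a (0-based a-1+? see tn5_shift): start = a - 4,
        # end = b + 5 reproduces cuts (a, +) and (b, -) exactly
        keep <- a - 4L >= 1L & b + 5L <= L & b > a
        a <- a[keep]; b <- b[keep]
        frag_list[[ch]] <- GenomicRanges::GRanges(
          ch, IRanges::IRanges(a - 4L, b + 5L), strand = "+")
      } else {
        idx <- sample_weighted(2L * m, c(ipl, imi))
        minus <- idx > L
        pos <- ifelse(minus, idx - L, idx)
        cut_list[[ch]] <- GenomicRanges::GRanges(
          ch, IRanges::IRanges(pos, width = 1L),
          strand = ifelse(minus, "-", "+"))
      }
    }
    frags <- if (paired && length(frag_list)) {
      suppressWarnings(
        GenomicRanges::sort(do.call(c, unname(frag_list)), ignore.strand = TRUE))
    } else NULL
    cuts <- if (paired && !is.null(frags)) {
      tn5_shift(frags)$cuts
    } else {
      suppressWarnings(
        GenomicRanges::sort(do.call(c, unname(cut_list)), ignore.strand = TRUE))
    }
    list(fragments = frags, cuts = cuts, n_mito = n_mito, seed = spec$seed)
  })
}

## reverse cuts at nucleosomal distances, accepted by local minus-strand
## intensity (vectorized rejection; falls back to plain draw after 40 rounds)
draw_partner_cuts <- function(a, imi, spec) {
  L <- length(imi)
  mx <- max(imi)
  b <- integer(length(a))
  todo <- seq_along(a)
  for (round in 1:40) {
    if (!length(todo)) break
    k <- sample_weighted(length(todo), spec$frag_weights)
    len <- round(stats::rnorm(length(todo), spec$frag_means[k], spec$frag_sds[k]))
    len <- pmax(20, len)
    cand <- a[todo] + as.integer(len) - 10L
    ok <- cand >= 1L & cand <= L
    ok[ok] <- stats::runif(sum(ok)) < imi[cand[ok]] / mx
    b[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  if (length(todo)) {
    k <- sample_weighted(length(todo), spec$frag_weights)
    len <- pmax(20, round(stats::rnorm(length(todo), spec$frag_means[k],
                                       spec$frag_sds[k])))
    b[todo] <- pmin(L, pmax(1L, a[todo] + as.integer(len) - 10L))
  }
  b
}

#' Simulate replicate peak-set collections with controlled presence
#'
#' Builds `n_sets` peak sets sharing planted loci: a locus with
#' presence fraction `f` appears, with +/- `jitter` bp coordinate
#' noise, in exactly `round(f * n_sets)` of the sets; the rest of each
#' set is filled with private random peaks. This exercises
#' reference-peak calibration: loci above the presence threshold must
#' be recovered, those below rejected.
#'
#' @param n_sets Number of peak sets (>= 2).
#' @param presence_fractions Numeric vector in `[0, 1]`, one entry per
#'   group of planted loci.
#' @param n_loci Loci planted per presence fraction; default 10.
#' @param seed Integer seed.
#' @param contig,contig_length Contig the sets live on.
#' @param locus_width Planted locus width in bp.
#' @param jitter Maximum absolute coordinate jitter in bp.
#' @param n_private Private peaks per set.
#' @param dir If non-`NULL`, each set is also written to
#'   `<dir>/set_<i>.narrowPeak`.
#' @return A list: `sets` (list of `GRanges`), `truth` (`GRanges` of
#'   planted loci with `presence_fraction` and `n_sets_present`
#'   metadata), `n_sets`, `seed`.
#' @export
simulate_peak_collections <- function(n_sets, presence_fractions,
                                      n_loci = 10L, seed = 1L,
                                      contig = "chr1",
                                      contig_length = 1000000L,
                                      locus_width = 200L, jitter = 20L,
                                      n_private = 50L, dir = NULL) {
  if (n_sets < 2L) stop("n_sets must be >= 2", call. = FALSE)
  if (any(presence_fractions < 0 | presence_fractions > 1)) {
    stop("presence fractions must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    n_groups <- length(presence_fractions)
    total_loci <- n_groups * n_loci
    starts <- place_intervals(total_loci, locus_width, contig_length,
                              gap = 2000L, lower = 3000L)
    starts <- sample(starts)  # decouple position from group
    frac <- rep(presence_fractions, each = n_loci)
    n_present <- as.integer(round(frac * n_sets))
    truth <- GenomicRanges::GRanges(
      contig, IRanges::IRanges(sort(starts), width = locus_width))
    o <- order(starts)
    S4Vectors::mcols(truth)$presence_fraction <- frac[o]
    S4Vectors::mcols(truth)$n_sets_present <- n_present[o]
    membership <- lapply(seq_len(total_loci), function(i) {
      sample(n_sets, n_present[o][i])
    })
    sets <- vector("list", n_sets)
    for (s in seq_len(n_sets)) {
      idx <- which(vapply(membership, function(m) s %in% m, TRUE))
      planted <- GenomicRanges::GRanges()
      if (length(idx)) {
        j1 <- as.integer(floor(stats::runif(length(idx), -jitter, jitter + 1)))
        j2 <- as.integer(floor(stats::runif(length(idx), -jitter, jitter + 1)))
        planted <- GenomicRanges::GRanges(
          contig,
          IRanges::IRanges(pmax(1L, GenomicRanges::start(truth)[idx] + j1),
                           GenomicRanges::end(truth)[idx] + j2))
      }
      # private peaks, kept clear of planted loci
      priv_start <- integer(0)
      while (length(priv_start) < n_private) {
        cand <- as.integer(floor(stats::runif(n_private, 1,
                                              contig_length - locus_width)))
        far <- vapply(cand, function(p) {
          all(abs(p - GenomicRanges::start(truth)) > 3000L)
        }, TRUE)
        priv_start <- utils::head(c(priv_start, cand[far]), n_private)
      }
      private <- GenomicRanges::GRanges(
        contig, IRanges::IRanges(priv_start, width = locus_width))
      gr <- GenomicRanges::sort(c(planted, private), ignore.strand = TRUE)
      S4Vectors::mcols(gr)$name <- sprintf("peak_%d_%d", s, seq_along(gr))
      S4Vectors::mcols(gr)$score <- rep(10, length(gr))
      S4Vectors::mcols(gr)$pValue <- rep(-1, length(gr))
      S4Vectors::mcols(gr)$qValue <- rep(-1, length(gr))
      S4Vectors::mcols(gr)$summit <- rep(NA_integer_, length(gr))
      sets[[s]] <- gr
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        write_narrowpeak(gr, file.path(dir, sprintf("set_%03d.narrowPeak", s)))
      }
    }
    list(sets = sets, truth = truth, n_sets = n_sets, seed = seed)
  })
}

#' Write a genome as FASTA
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(genome_seqs(genome))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a gene model as BED12
#'
#' The inverse of `read_gene_model(..., dialect = "bed12")`.
#'
#' @param genes `GRanges` with `name` and `exons` metadata columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(genes, path) {
  stopifnot(methods::is(genes, "GRanges"))
  ex <- S4Vectors::mcols(genes)$exons
  start0 <- GenomicRanges::start(genes) - 1L
  lines <- vapply(seq_along(genes), function(i) {
    e <- ex[[i]]
    sizes <- paste0(paste(IRanges::width(e), collapse = ","), ",")
    offs <- paste0(paste(IRanges::start(e) - 1L - start0[i], collapse = ","), ",")
    paste(as.character(GenomicRanges::seqnames(genes))[i],
          start0[i], GenomicRanges::end(genes)[i],
          S4Vectors::mcols(genes)$name[i], 0,
          as.character(GenomicRanges::strand(genes))[i],
          start0[i], GenomicRanges::end(genes)[i], 0,
          length(e), sizes, offs, sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
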