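## ---- sequence helpers -------------------------------------------------

BASES <- c("A", "C", "G", "T")

#' Normalize a genome to named uppercase sequences
#'
#' Accepts the genome representations used across the package — a
#' `Biostrings::DNAStringSet`, a named character vector, or a FASTA
#' file path — and returns a named character vector of uppercase
#' sequences (FASTA descriptions are trimmed to the first word).
#'
#' @param genome A `DNAStringSet`, named character vector of
#'   sequences, or path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
genome_seqs <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (methods::is(genome, "DNAString")) {
    seqs <- stats::setNames(as.character(genome), "seq1")
  } else if (is.character(genome)) {
    if (length(genome) == 1L && file.exists(genome)) {
      seqs <- as.character(Biostrings::readDNAStringSet(genome))
      names(seqs) <- sub("\\s.*$", "", names(seqs))
    } else {
      seqs <- genome
      if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    }
  } else {
    stop("genome must be a DNAStringSet, character vector, or FASTA path",
         call. = FALSE)
  }
  toupper(seqs)
}

## A,C,G,T -> 1..4, anything else NA
base_codes <- function(seq) {
  code <- match(strsplit(seq, "", fixed = TRUE)[[1L]], BASES)
  code
}

#' Reverse complement of DNA sequences
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## ---- PWM construction and exact p-value threshold ---------------------

#' Build a log-odds position weight matrix
#'
#' Converts a position frequency matrix into log2-odds scores with a
#' background-weighted pseudocount:
#' `score[b, j] = log2(((count[b, j] + pc * bg[b]) / (total[j] + pc)) / bg[b])`.
#'
#' @param pfm A 4 x W count matrix (rows A,C,G,T), e.g. from
#'   [read_pfm()].
#' @param pseudocount Positive pseudocount mass, default 0.8.
#' @param background Background base probabilities (A,C,G,T), summing
#'   to 1, all positive. Default uniform.
#' @return A list of class `"pwm_model"`: `scores` (4 x W), `width`,
#'   `background`, `max_score`, `min_score`, `motif_id`.
#' @export
build_pwm <- function(pfm, pseudocount = 0.8,
                      background = rep(0.25, 4)) {
  mat <- unclass(pfm)
  if (!is.matrix(mat) || nrow(mat) != 4L) {
    stop("pfm must be a 4-row count matrix", call. = FALSE)
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be positive", call. = FALSE)
  }
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 positive probabilities summing to 1",
         call. = FALSE)
  }
  background <- background / sum(background)
  totals <- colSums(mat)
  prob <- sweep(mat + pseudocount * background, 2L, totals + pseudocount, "/")
  scores <- log2(prob / background)
  rownames(scores) <- BASES
  structure(list(scores = scores, width = ncol(mat),
                 background = stats::setNames(background, BASES),
                 max_score = sum(apply(scores, 2L, max)),
                 min_score = sum(apply(scores, 2L, min)),
                 motif_id = attr(pfm, "motif_id")),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat("PWM", if (!is.null(x$motif_id) && !is.na(x$motif_id)) x$motif_id else "",
      "width", x$width, "; score range [",
      format(x$min_score, digits = 4), ",", format(x$max_score, digits = 4),
      "]\n")
  invisible(x)
}

#' Exact score distribution of a PWM under its background
#'
#' Dynamic programming over the column-wise convolution of the
#' discretized score distribution: per-column scores are rounded to
#' `granularity` bits, and the distribution of the W-column sum under
#' independent background draws is computed exactly on that lattice.
#'
#' @param pwm A `"pwm_model"`.
#' @param granularity Score lattice spacing in bits, default `1e-3`.
#' @return A data.frame with columns `score` (lattice values) and
#'   `prob`, ascending in score, probabilities summing to 1.
#' @export
pwm_score_distribution <- function(pwm, granularity = 1e-3) {
  stopifnot(inherits(pwm, "pwm_model"))
  si <- round(pwm$scores / granularity)
  bg <- pwm$background
  lo <- hi <- 0
  probs <- 1  # distribution over lattice offsets lo..hi
  for (j in seq_len(pwm$width)) {
    s <- si[, j]
    nlo <- lo + min(s); nhi <- hi + max(s)
    new <- numeric(nhi - nlo + 1)
    for (b in 1:4) {
      idx <- (lo + s[b] - nlo + 1):(hi + s[b] - nlo + 1)
      new[idx] <- new[idx] + probs * bg[b]
    }
    probs <- new; lo <- nlo; hi <- nhi
  }
  keep <- probs > 0
  data.frame(score = (seq.int(lo, hi)[keep]) * granularity,
             prob = probs[keep])
}

#' Score threshold for an exact motif p-value
#'
#' The smallest achievable PWM score `t` such that a random background
#' sequence scores `>= t` with probability at most `p`, from the exact
#' discretized score distribution. Matches the FIMO-style `p < 1e-4`
#' scanning convention.
#'
#' @param pwm A `"pwm_model"`.
#' @param p Target p-value in `(0, 1)`; default `1e-4`.
#' @param granularity Score lattice spacing in bits.
#' @return The threshold score in bits (a lattice value). When `p` is
#'   below the probability of the single best word, the maximum
#'   achievable score is returned.
#' @export
score_threshold <- function(pwm, p = 1e-4, granularity = 1e-3) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("p must be in (0, 1)", call. = FALSE)
  }
  dist <- pwm_score_distribution(pwm, granularity)
  tail <- rev(cumsum(rev(dist$prob)))  # P(score >= score_i)
  ok <- which(tail <= p)
  if (length(ok) == 0L) return(dist$score[nrow(dist)])
  dist$score[ok[1L]]
}

#' Scan a genome for motif sites above a score threshold
#'
#' Scores every window on both strands (reverse strand via the
#' reverse complement) and reports sites with score at or above the
#' threshold, in forward-strand coordinates. Windows containing
#' non-ACGT bases are skipped.
#'
#' @param genome A `DNAStringSet`, named character vector, or FASTA
#'   path.
#' @param pwm A `"pwm_model"`.
#' @param threshold Minimum score in bits, e.g. from
#'   [score_threshold()].
#' @return A stranded `GRanges` of motif-width sites with a `score`
#'   metadata column.
#' @export
scan_motifs <- function(genome, pwm, threshold) {
  stopifnot(inherits(pwm, "pwm_model"))
  seqs <- genome_seqs(genome)
  if (length(seqs) == 0L || all(nchar(seqs) == 0L)) {
    stop("genome is empty", call. = FALSE)
  }
  W <- pwm$width
  S <- pwm$scores
  # reverse-strand match at forward window [i, i+W-1] equals a forward
  # match of the reverse-complemented PWM
  Src <- S[4:1, W:1, drop = FALSE]
  out <- list()
  for (ch in names(seqs)) {
    L <- nchar(seqs[[ch]])
    if (L < W) next
    code <- base_codes(seqs[[ch]])
    n <- L - W + 1L
    fwd <- rev_ <- numeric(n)
    for (j in seq_len(W)) {
      cj <- code[j:(j + n - 1L)]
      fwd <- fwd + S[cbind(cj, j)]
      rev_ <- rev_ + Src[cbind(cj, j)]
    }
    eps <- 1e-9
    for (str in c("+", "-")) {
      sc <- if (str == "+") fwd else rev_
      hit <- which(!is.na(sc) & sc >= threshold - eps)
      if (length(hit)) {
        out[[length(out) + 1L]] <- GenomicRanges::GRanges(
          ch, IRanges::IRanges(hit, width = W), strand = str,
          score = sc[hit])
      }
    }
  }
  if (length(out) == 0L) {
    return(GenomicRanges::GRanges(score = numeric(0)))
  }
  GenomicRanges::sort(do.call(c, out), ignore.strand = TRUE)
}

#' Restrict motif sites to open chromatin
#'
#' Keeps sites overlapping at least 1 bp of any peak.
#'
#' @param sites `GRanges` of motif sites.
#' @param peaks `GRanges` of accessible regions (hotspots).
#' @return The overlapping subset of `sites`.
#' @export
intersect_open <- function(sites, peaks) {
  stopifnot(methods::is(sites, "GRanges"), methods::is(peaks, "GRanges"))
  sites[IRanges::overlapsAny(sites, peaks, ignore.strand = TRUE)]
}

## ---- mappability ------------------------------------------------------

#' Brute-force k-mer mappability mask
#'
#' A position is uniquely mappable when the k-mer starting there
#' occurs exactly once across both strands of the genome; reads whose
#' k-mer is repeated (including reverse-complement palindromes, which
#' always occur at least twice) cannot be placed unambiguously and are
#' excluded from bias and footprint counts. The uniqueness catalogue
#' is exhaustive, intended for desk-scale or synthetic genomes; for a
#' full mammalian genome a precomputed track can be supplied in the
#' same list-of-logical layout.
#'
#' @param genome A `DNAStringSet`, named character vector, or FASTA
#'   path.
#' @param k Read length in bp, default 50.
#' @return A list of class `"mappability_mask"`, one logical vector
#'   per contig over start positions `1..L-k+1` (k-mers containing
#'   non-ACGT bases are marked non-unique), with attribute `k`.
#' @export
mappability_mask <- function(genome, k = 50L) {
  seqs <- genome_seqs(genome)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (any(nchar(seqs) < k)) {
    stop("k exceeds the length of contig ",
         names(seqs)[which(nchar(seqs) < k)[1L]], call. = FALSE)
  }
  kmers_of <- function(s) {
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  }
  fwd <- lapply(seqs, kmers_of)
  rc <- lapply(seqs, function(s) kmers_of(revcomp_chr(s)))
  all_fwd <- unlist(fwd, use.names = FALSE)
  all_rc <- unlist(rc, use.names = FALSE)
  u <- unique(all_fwd)
  cnt_f <- tabulate(match(all_fwd, u), nbins = length(u))
  m_rc <- match(all_rc, u)
  cnt_r <- tabulate(m_rc[!is.na(m_rc)], nbins = length(u))
  total <- cnt_f + cnt_r
  mask <- lapply(fwd, function(km) {
    ok <- total[match(km, u)] == 1L
    ok & !grepl("[^ACGT]", km)
  })
  structure(mask, class = "mappability_mask", k = k)
}

## mask lookup: is a k-mer START at position p usable on this contig?
mask_at <- function(mask, contig, pos) {
  v <- mask[[contig]]
  if (is.null(v)) return(rep(FALSE, length(pos)))
  ok <- pos >= 1L & pos <= length(v)
  out <- rep(FALSE, length(pos))
  out[ok] <- v[pos[ok]]
  out
}

## ---- hexamer bias model -----------------------------------------------

HEX_K <- 6L

#' The 4096 hexamer labels in model order
#'
#' Order matches the `rates` and `abundance` vectors of
#' [hexamer_model()] and the names expected for the `hexamer_rates`
#' argument of [simulation_spec()]: `AAAAAA`, `AAAAAC`, ... `TTTTTT`,
#' with the first base most significant.
#'
#' @return Character vector of length 4096.
#' @export
hexamer_names <- function() {
  g <- expand.grid(BASES, BASES, BASES, BASES, BASES, BASES,
                   stringsAsFactors = FALSE)
  # first base is the most significant digit
  apply(g[, 6:1], 1L, paste, collapse = "")
}

## hexamer ids (1..4096) at each start position of a code vector
hexamer_ids_at_starts <- function(code) {
  L <- length(code)
  n <- L - HEX_K + 1L
  if (n < 1L) return(integer(0))
  h <- code - 1L
  id <- integer(n)
  for (j in 0:(HEX_K - 1L)) {
    id <- id + h[(1L + j):(n + j)] * 4L^(HEX_K - 1L - j)
  }
  id + 1L
}

.hex_cache <- new.env(parent = emptyenv())

## reverse-complement lookup for hexamer ids (memoized)
hexamer_rc_table <- function() {
  if (!is.null(.hex_cache$rc)) return(.hex_cache$rc)
  ids <- 0:(4L^HEX_K - 1L)
  digits <- sapply(0:(HEX_K - 1L), function(j) (ids %/% 4L^j) %% 4L)
  # digit j counts from the least significant (3'-most) base;
  # reverse complement: complement (3 - d) and reverse digit order
  rc <- rowSums(sapply(0:(HEX_K - 1L), function(j) {
    (3L - digits[, HEX_K - j]) * 4L^j
  }))
  .hex_cache$rc <- as.integer(rc) + 1L
  .hex_cache$rc
}

## Cut-site hexamer frame: a plus-strand cut at 1-based position P reads
## the hexamer at [P-3, P+2]; a minus-strand cut reads the reverse
## complement of [P-2, P+3], so the cut base occupies the same slot
## relative to the insertion's 5' side on either strand.
position_hexamers <- function(code) {
  rc_tab <- hexamer_rc_table()
  L <- length(code)
  hex_start <- hexamer_ids_at_starts(code)  # NA at ambiguous bases
  pos <- seq_len(L)
  plus_hex <- rep(NA_integer_, L)
  fit <- pos >= 4L & pos <= L - 2L
  plus_hex[fit] <- hex_start[pos[fit] - 3L]
  minus_hex <- rep(NA_integer_, L)
  fit_m <- pos >= 3L & pos <= L - 3L
  minus_hex[fit_m] <- rc_tab[hex_start[pos[fit_m] - 2L]]
  list(plus_hex = plus_hex, minus_hex = minus_hex)
}

cut_hexamer_info <- function(seqs, mask) {
  k <- attr(mask, "k")
  per_contig <- lapply(names(seqs), function(ch) {
    code <- base_codes(seqs[[ch]])
    L <- length(code)
    ph <- position_hexamers(code)
    pos <- seq_len(L)
    # the plus-strand read's k-mer starts at the cut; the minus-strand
    # read extends leftwards, so its k-mer starts at P-k+1
    plus_ok <- !is.na(ph$plus_hex) & mask_at(mask, ch, pos)
    minus_ok <- !is.na(ph$minus_hex) & mask_at(mask, ch, pos - k + 1L)
    list(plus_hex = ph$plus_hex, plus_ok = plus_ok,
         minus_hex = ph$minus_hex, minus_ok = minus_ok)
  })
  stats::setNames(per_contig, names(seqs))
}

#' Hexamer Tn5 insertion-bias model
#'
#' Tn5 prefers particular local sequence contexts; uncorrected, this
#' bias masquerades as footprint structure. The model tallies the
#' hexamer centred at each cut (strand-oriented: minus-strand cuts
#' read the reverse complement) at uniquely mappable positions, and
#' the genome-wide abundance of each hexamer over the same usable
#' positions, so that the expected cut rate at a position is the
#' hexamer's cut share divided by its abundance.
#'
#' @param cuts Width-1 stranded `GRanges` of cut sites.
#' @param genome A `DNAStringSet`, named character vector, or FASTA
#'   path.
#' @param mask A `"mappability_mask"` over the same genome.
#' @return A list of class `"hexamer_bias"`: `rates` (named over the
#'   4096 hexamers, observed rates summing to 1), `abundance`
#'   (usable-position counts per hexamer, both strands), `per_position`
#'   rate lookup components, `total_cuts` used, `masked_cuts`
#'   excluded, `k`, and the centering convention.
#' @export
hexamer_model <- function(cuts, genome, mask) {
  stopifnot(methods::is(cuts, "GRanges"), inherits(mask, "mappability_mask"))
  seqs <- genome_seqs(genome)
  info <- cut_hexamer_info(seqs, mask)
  tally <- numeric(4L^HEX_K)
  abund <- numeric(4L^HEX_K)
  used <- 0L; masked <- 0L
  chrom <- as.character(GenomicRanges::seqnames(cuts))
  pos <- GenomicRanges::start(cuts)
  str <- as.character(GenomicRanges::strand(cuts))
  for (ch in names(seqs)) {
    ci <- info[[ch]]
    sel <- chrom == ch
    if (any(sel)) {
      for (s in c("+", "-")) {
        p <- pos[sel & str == s]
        if (!length(p)) next
        ok <- if (s == "+") ci$plus_ok[p] else ci$minus_ok[p]
        hex <- if (s == "+") ci$plus_hex[p] else ci$minus_hex[p]
        masked <- masked + sum(!ok)
        hex <- hex[ok]
        used <- used + length(hex)
        if (length(hex)) {
          t <- tabulate(hex, nbins = 4L^HEX_K)
          tally <- tally + t
        }
      }
    }
    abund <- abund + tabulate(ci$plus_hex[ci$plus_ok], nbins = 4L^HEX_K) +
      tabulate(ci$minus_hex[ci$minus_ok], nbins = 4L^HEX_K)
  }
  if (used == 0L) {
    stop("no cuts remain at uniquely mappable positions", call. = FALSE)
  }
  rates <- tally / used
  names(rates) <- names(abund) <- hexamer_names()
  structure(list(rates = rates, abundance = abund,
                 total_cuts = used, masked_cuts = masked,
                 k = attr(mask, "k"),
                 centering = "plus: [p-3,p+2]; minus: revcomp([p-2,p+3])"),
            class = "hexamer_bias")
}

#' @export
print.hexamer_bias <- function(x, ...) {
  cat("Hexamer bias model from", x$total_cuts, "cuts (",
      x$masked_cuts, "masked );", sum(x$rates > 0), "hexamers observed\n")
  invisible(x)
}

## expected relative cut rate at given positions/strand on one contig
expected_rate_at <- function(bias, ci, pos, strand) {
  hex <- if (strand == "+") ci$plus_hex[pos] else ci$minus_hex[pos]
  ok <- if (strand == "+") ci$plus_ok[pos] else ci$minus_ok[pos]
  r <- rep(0, length(pos))
  good <- ok & !is.na(hex) & bias$abundance[hex] > 0
  r[good] <- bias$rates[hex[good]] / bias$abundance[hex[good]]
  list(rate = r, usable = ok & !is.na(hex))
}

## ---- footprint profile ------------------------------------------------

#' Aggregate footprint profile and depth over motif sites
#'
#' Sums observed cut counts at strand-oriented offsets around a set of
#' motif sites and compares them with the counts expected from the
#' hexamer bias model alone. Both are restricted to uniquely mappable
#' positions, the expected profile is scaled to match the observed
#' total over the window, and both are normalized to `target` total
#' tags (default 100 million). The per-offset deviation is
#' `log2((obs + eps) / (exp + eps))`; a baseline, the mean deviation
#' over the outermost flank offsets, is subtracted so a bias-only
#' library is flat at zero, and the footprint depth is the mean
#' adjusted deviation over the motif offsets. Bound factors protect
#' the motif from insertion, so depth is negative with magnitude
#' tracking occupancy.
#'
#' @param cuts Width-1 stranded `GRanges` of cut sites.
#' @param sites Stranded `GRanges` of motif sites, all the same width
#'   (e.g. [scan_motifs()] filtered by [intersect_open()]).
#' @param bias A `"hexamer_bias"` built from the same genome and mask.
#' @param mask The `"mappability_mask"` used for `bias`.
#' @param genome The genome the sites refer to.
#' @param flank Flank size in bp on each side of the motif; default 25.
#' @param total_tags Library size; defaults to `length(cuts)`.
#' @param target Normalization depth, default `1e8`.
#' @param eps Pseudocount guarding the log ratio, default 0.5 (raw
#'   count scale).
#' @param baseline_frac Fraction of each flank (outermost offsets)
#'   averaged into the baseline; default 0.4.
#' @return A list of class `"footprint_profile"`: `offsets` (relative
#'   to motif start), `observed`, `expected` (normalized),
#'   `log2_ratio`, `adjusted_log2_ratio`, `baseline`, `depth`,
#'   `motif_width`, `flank`, `n_sites`.
#' @export
footprint_profile <- function(cuts, sites, bias, mask, genome,
                              flank = 25L, total_tags = length(cuts),
                              target = 1e8, eps = 0.5,
                              baseline_frac = 0.4) {
  stopifnot(methods::is(cuts, "GRanges"), methods::is(sites, "GRanges"),
            inherits(bias, "hexamer_bias"),
            inherits(mask, "mappability_mask"))
  if (length(sites) == 0L) stop("no motif sites supplied", call. = FALSE)
  W <- unique(GenomicRanges::width(sites))
  if (length(W) != 1L) stop("motif sites must share one width", call. = FALSE)
  seqs <- genome_seqs(genome)
  info <- cut_hexamer_info(seqs, mask)
  offsets <- seq.int(-flank, W - 1L + flank)
  n_off <- length(offsets)
  obs <- exp_ <- numeric(n_off)
  # per-contig, per-strand cut count arrays
  cut_counts <- list()
  chrom_cut <- as.character(GenomicRanges::seqnames(cuts))
  str_cut <- as.character(GenomicRanges::strand(cuts))
  for (ch in names(seqs)) {
    L <- nchar(seqs[[ch]])
    cut_counts[[ch]] <- list(
      "+" = tabulate(GenomicRanges::start(cuts)[chrom_cut == ch & str_cut == "+"],
                     nbins = L),
      "-" = tabulate(GenomicRanges::start(cuts)[chrom_cut == ch & str_cut == "-"],
                     nbins = L))
  }
  s_chrom <- as.character(GenomicRanges::seqnames(sites))
  s_start <- GenomicRanges::start(sites)
  s_end <- GenomicRanges::end(sites)
  s_str <- as.character(GenomicRanges::strand(sites))
  for (i in seq_along(sites)) {
    ch <- s_chrom[i]
    ci <- info[[ch]]
    if (is.null(ci)) next
    L <- nchar(seqs[[ch]])
    pos <- if (s_str[i] == "-") s_end[i] - offsets else s_start[i] + offsets
    inb <- pos >= 1L & pos <= L
    for (s in c("+", "-")) {
      er <- expected_rate_at(bias, ci, pos[inb], s)
      cc <- cut_counts[[ch]][[s]][pos[inb]]
      cc[!er$usable] <- 0
      obs[inb] <- obs[inb] + cc
      exp_[inb] <- exp_[inb] + er$rate
    }
  }
  if (sum(exp_) == 0) {
    stop("expected profile is identically zero (all positions masked?)",
         call. = FALSE)
  }
  exp_scaled <- exp_ * (sum(obs) / sum(exp_))
  log2_ratio <- log2((obs + eps) / (exp_scaled + eps))
  n_base <- max(1L, ceiling(baseline_frac * flank))
  baseline <- mean(c(log2_ratio[seq_len(n_base)],
                     log2_ratio[seq.int(n_off - n_base + 1L, n_off)]))
  adjusted <- log2_ratio - baseline
  motif_idx <- which(offsets >= 0L & offsets <= W - 1L)
  norm <- target / max(total_tags, 1L)
  structure(list(offsets = offsets,
                 observed = obs * norm,
                 expected = exp_scaled * norm,
                 log2_ratio = log2_ratio,
                 adjusted_log2_ratio = adjusted,
                 baseline = baseline,
                 depth = mean(adjusted[motif_idx]),
                 motif_width = W, flank = flank,
                 n_sites = length(sites)),
            class = "footprint_profile")
}

#' @export
print.footprint_profile <- function(x, ...) {
  cat("Footprint over", x$n_sites, "sites (motif", x$motif_width,
      "bp, flank", x$flank, "bp): depth",
      format(x$depth, digits = 3), "; baseline",
      format(x$baseline, digits = 3), "\n")
  invisible(x)
}

#' @export
as.data.frame.footprint_profile <- function(x, ...) {
  data.frame(offset = x$offsets, observed = x$observed,
             expected = x$expected, log2ratio = x$log2_ratio,
             adjusted_log2ratio = x$adjusted_log2_ratio)
}
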