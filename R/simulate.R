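# Synthetic-data generator: toy genomes with planted multi-copy repeat
# instances, Illumina-like paired-end reads with ground-truth coordinates,
# and pulldown libraries over-sampled from chosen repeat families.

#' Default repeat catalog for toy genomes
#'
#' Eight subfamilies in five families spanning the major repeat classes,
#' with copy numbers and lengths scaled so the planted instances occupy
#' roughly 11% of a 1 Mb genome — enough copies per subfamily for stable
#' counting without crowding the background.
#'
#' @return Data frame with columns `name`, `family`, `cls`, `length`,
#'   `copies`, `divergence` (per-copy substitution rate vs consensus).
#' @export
default_repeat_catalog <- function() {
  data.frame(
    name = c("AluY", "AluSx", "L1HS", "L1PA2", "SVA_E", "SVA_F",
             "MER41B", "(CATTC)n"),
    family = c("Alu", "Alu", "L1", "L1", "SVA", "SVA",
               "ERV1", "Simple_repeat"),
    cls = c("SINE", "SINE", "LINE", "LINE", "Retroposon", "Retroposon",
            "LTR", "Simple_repeat"),
    length = c(300L, 300L, 3000L, 2500L, 1400L, 1600L, 600L, 200L),
    copies = c(60L, 50L, 6L, 6L, 12L, 10L, 8L, 30L),
    divergence = c(0.05, 0.10, 0.02, 0.05, 0.05, 0.03, 0.08, 0.02),
    stringsAsFactors = FALSE)
}

#' Specification of a toy genome with planted repeats
#'
#' @param n_chroms Number of chromosomes (default 2).
#' @param chrom_length Length of each chromosome in bp (default 5e5, i.e.
#'   a 1 Mb genome with the defaults).
#' @param catalog Repeat catalog data frame as in
#'   [default_repeat_catalog()].
#' @param gc Background GC content (default 0.41, human-like).
#' @param seed Integer seed; all placement, divergence and sequence draws
#'   are deterministic given the seed.
#' @return List of class `toy_genome_spec`.
#' @export
toy_genome_spec <- function(n_chroms = 2L, chrom_length = 500000L,
                            catalog = default_repeat_catalog(),
                            gc = 0.41, seed = 1L) {
  stopifnot(n_chroms >= 1L, chrom_length > 0L, gc > 0, gc < 1)
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 catalog = catalog, gc = gc, seed = as.integer(seed)),
            class = "toy_genome_spec")
}

.random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "")[[1L]]
  for (i in pos) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Build a toy genome with planted repeat instances
#'
#' Draws one random consensus sequence per subfamily, plants the requested
#' number of copies at non-overlapping uniform positions (random strand,
#' per-copy substitution divergence), and records every placement. Tandem
#' simple repeats get a repeated-motif consensus; all other consensi are
#' random sequence at background composition.
#'
#' @param spec A [toy_genome_spec()].
#' @return List of class `toy_genome`: `genome`
#'   ([Biostrings::DNAStringSet]), `annotation` (`GRanges` of planted
#'   instances with `name`, `family`, `cls`), `grouping` (`re_grouping`),
#'   `consensus` (named character), `spec`.
#' @export
build_toy_genome <- function(spec = toy_genome_spec()) {
  set.seed(spec$seed)
  cat <- spec$catalog
  consensus <- stats::setNames(vector("character", nrow(cat)), cat$name)
  for (i in seq_len(nrow(cat))) {
    nm <- cat$name[i]
    if (grepl("^\\(([ACGT]+)\\)n$", nm)) {
      motif <- sub("^\\((.*)\\)n$", "\\1", nm)
      reps <- ceiling(cat$length[i] / nchar(motif))
      consensus[nm] <- substr(strrep(motif, reps), 1L, cat$length[i])
    } else {
      consensus[nm] <- .random_dna(cat$length[i], spec$gc)
    }
  }

  chrom_names <- paste0("chr", seq_len(spec$n_chroms))
  chroms <- lapply(chrom_names, function(x)
    .random_dna(spec$chrom_length, spec$gc))
  names(chroms) <- chrom_names

  total_repeat <- sum(cat$length * cat$copies)
  if (total_repeat > 0.8 * spec$n_chroms * spec$chrom_length)
    stop("placement error: repeat catalog too large for the genome")

  occupied <- lapply(chrom_names, function(x) IRanges::IRanges())
  names(occupied) <- chrom_names
  rows <- list()
  order_idx <- order(-cat$length)  # place long elements first
  for (i in order_idx) {
    for (cp in seq_len(cat$copies[i])) {
      len <- cat$length[i]
      placed <- FALSE
      for (try in 1:200) {
        chr <- sample(chrom_names, 1L)
        st <- sample.int(spec$chrom_length - len + 1L, 1L)
        cand <- IRanges::IRanges(st, st + len - 1L)
        if (length(IRanges::findOverlaps(cand, occupied[[chr]])) == 0L) {
          occupied[[chr]] <- c(occupied[[chr]], cand)
          strand <- sample(c("+", "-"), 1L)
          seq <- .mutate_seq(consensus[cat$name[i]], cat$divergence[i])
          if (strand == "-")
            seq <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(seq)))
          substr(chroms[[chr]], st, st + len - 1L) <- seq
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chr, start = st, end = st + len - 1L, strand = strand,
            name = cat$name[i], family = cat$family[i], cls = cat$cls[i],
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("placement error: could not place copy of ", cat$name[i])
    }
  }
  if (!length(rows)) {  # empty catalog: background-only genome
    genome <- Biostrings::DNAStringSet(unlist(chroms))
    names(genome) <- chrom_names
    ann <- GenomicRanges::GRanges(
      name = character(), family = character(), cls = character(),
      seqinfo = GenomeInfoDb::Seqinfo(
        chrom_names, rep(spec$chrom_length, spec$n_chroms)))
    return(structure(list(genome = genome, annotation = ann,
                          grouping = NULL, consensus = consensus,
                          spec = spec),
                     class = "toy_genome"))
  }
  df <- do.call(rbind, rows)
  ann <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = chrom_names),
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    name = df$name, family = df$family, cls = df$cls,
    seqinfo = GenomeInfoDb::Seqinfo(
      chrom_names, rep(spec$chrom_length, spec$n_chroms)))
  ann <- BiocGenerics::sort(ann, ignore.strand = TRUE)
  genome <- Biostrings::DNAStringSet(unlist(chroms))
  names(genome) <- chrom_names
  structure(list(genome = genome, annotation = ann,
                 grouping = build_grouping(sidecar = unique(
                   data.frame(name = df$name, family = df$family,
                              cls = df$cls, stringsAsFactors = FALSE))),
                 consensus = consensus, spec = spec),
            class = "toy_genome")
}

#' Write toy-genome fixtures to disk
#'
#' Emits `genome.fa`, `repeats.bed` (BED12, one single-block row per
#' planted instance, 0-based half-open as the format requires) and
#' `grouping.tsv`.
#'
#' @param tg A `toy_genome` from [build_toy_genome()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_toy_genome <- function(tg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(tg$genome, fa)
  bed <- file.path(dir, "repeats.bed")
  a <- tg$annotation
  len <- BiocGenerics::width(a)
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(a)),
    start = BiocGenerics::start(a) - 1L,
    end = BiocGenerics::end(a),
    name = a$name, score = 0L,
    strand = as.character(BiocGenerics::strand(a)),
    thickStart = BiocGenerics::start(a) - 1L,
    thickEnd = BiocGenerics::end(a),
    rgb = 0L, blockCount = 1L,
    blockSizes = paste0(len, ","), blockStarts = "0,",
    stringsAsFactors = FALSE)
  utils::write.table(df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  grp <- file.path(dir, "grouping.tsv")
  write_grouping(tg$grouping, grp)
  invisible(c(genome = fa, bed = bed, grouping = grp))
}

#' Read-simulation parameters
#'
#' Defaults follow a HiSeqX-like paired-end run: 150 bp reads, fragment
#' lengths Normal(450, 30) truncated below at the read length, uniform
#' fragment placement, uniform substitution errors with a flat Phred
#' quality consistent with the error rate. No indel errors, so every truth
#' interval is exact.
#'
#' @param read_length Read length in bp (default 150).
#' @param frag_mean,frag_sd Fragment-length Normal parameters (450, 30).
#' @param error_rate Per-base substitution rate (default 0.001).
#' @param coverage Fold coverage; number of fragments is
#'   `round(coverage * genome_length / (2 * read_length))`. Ignored when
#'   `n_pairs` is given.
#' @param n_pairs Explicit number of fragments (optional).
#' @param seed Integer seed.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(read_length = 150L, frag_mean = 450, frag_sd = 30,
                     error_rate = 0.001, coverage = 1, n_pairs = NULL,
                     seed = 1L) {
  stopifnot(frag_mean > read_length, coverage > 0 || !is.null(n_pairs),
            error_rate >= 0, error_rate < 1)
  structure(list(read_length = as.integer(read_length),
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 error_rate = error_rate, coverage = coverage,
                 n_pairs = n_pairs, seed = as.integer(seed)),
            class = "sim_spec")
}

# Draw n fragments uniformly over the genome: chromosome proportional to
# length, start uniform, length Normal truncated at [read_length, chrom].
.draw_fragments <- function(seqlens, n, spec) {
  chr <- sample(names(seqlens), n, replace = TRUE,
                prob = as.numeric(seqlens))
  fl <- pmax(spec$read_length, round(stats::rnorm(n, spec$frag_mean,
                                                  spec$frag_sd)))
  fl <- pmin(fl, as.integer(seqlens[chr]))
  maxstart <- as.integer(seqlens[chr]) - fl + 1L
  st <- floor(stats::runif(n) * maxstart) + 1L
  GenomicRanges::GRanges(chr, IRanges::IRanges(st, width = fl))
}

# Truth table for a set of fragments: two mates per fragment. Mate 1 is the
# plus-strand read at the fragment start, mate 2 the minus-strand read at
# the fragment end.
.fragments_to_truth <- function(frags, spec, id_prefix = "sim") {
  n <- length(frags)
  L <- spec$read_length
  chr <- as.character(GenomeInfoDb::seqnames(frags))
  fs <- BiocGenerics::start(frags)
  fe <- BiocGenerics::end(frags)
  fl <- BiocGenerics::width(frags)
  data.frame(
    read_id = rep(sprintf("%s:%d", id_prefix, seq_len(n)), each = 2L),
    mate = rep(1:2, times = n),
    chrom = rep(chr, each = 2L),
    start = as.vector(rbind(fs, fe - L + 1L)),
    end = as.vector(rbind(fs + L - 1L, fe)),
    strand = rep(c("+", "-"), times = n),
    tlen = as.vector(rbind(fl, -fl)),
    stringsAsFactors = FALSE)
}

# Extract windows from a DNAStringSet by chromosome/start/end, in order.
.extract_windows <- function(genome, chrom, start, end) {
  n <- length(chrom)
  out <- character(n)
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    ir <- IRanges::IRanges(start[idx], end[idx])
    out[idx] <- as.character(Biostrings::extractAt(genome[[chr]], ir))
  }
  Biostrings::DNAStringSet(out)
}

# Extract mate sequences for a truth table and inject substitution errors.
.truth_to_reads <- function(genome, truth, spec) {
  seqs <- .extract_windows(genome, truth$chrom, truth$start, truth$end)
  minus <- truth$strand == "-"
  seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  if (spec$error_rate > 0) {
    L <- spec$read_length
    nerr <- stats::rbinom(length(seqs), L, spec$error_rate)
    idx <- which(nerr > 0L)
    if (length(idx)) {
      at <- lapply(nerr[idx], function(k) sample.int(L, k))
      subst <- lapply(at, function(pos)
        sample(c("A", "C", "G", "T"), length(pos), replace = TRUE))
      # replaceLetterAt keeps the base when the replacement equals it; a
      # uniform draw over all 4 bases realises rate 3/4 * nominal, so draw
      # from the 3 alternatives explicitly.
      mat <- as.character(seqs[idx])
      for (j in seq_along(idx)) {
        ch <- strsplit(mat[j], "")[[1L]]
        for (q in seq_along(at[[j]])) {
          pos <- at[[j]][q]
          ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1L)
        }
        mat[j] <- paste(ch, collapse = "")
      }
      seqs[idx] <- Biostrings::DNAStringSet(mat)
    }
  }
  seqs
}

.flat_qual <- function(error_rate, read_length, n) {
  q <- if (error_rate <= 0) 40L else
    max(2L, min(40L, as.integer(round(-10 * log10(error_rate)))))
  Biostrings::BStringSet(rep(strrep(rawToChar(as.raw(q + 33L)),
                                    read_length), n))
}

#' Simulate uniform paired-end reads with ground truth
#'
#' @param genome A `DNAStringSet` (or `toy_genome`).
#' @param spec A [sim_spec()].
#' @param fastq_prefix Optional path prefix; when given, writes
#'   `<prefix>_R1.fastq[.gz]` and `<prefix>_R2.fastq[.gz]` (gzip when
#'   `gz = TRUE`).
#' @param sam Optional path for a ground-truth SAM of perfect alignments.
#' @param gz Compress FASTQ output (default TRUE).
#' @return List of class `sim_reads`: `truth` (data frame, two rows per
#'   fragment: `read_id`, `mate`, `chrom`, `start`, `end`, `strand`,
#'   `tlen`), `n_pairs`, `spec`, plus the paths written.
#' @export
simulate_reads <- function(genome, spec = sim_spec(), fastq_prefix = NULL,
                           sam = NULL, gz = TRUE) {
  if (inherits(genome, "toy_genome")) genome <- genome$genome
  stopifnot(length(genome) > 0L)
  set.seed(spec$seed)
  seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
  n <- if (!is.null(spec$n_pairs)) spec$n_pairs else
    round(spec$coverage * sum(as.numeric(seqlens)) / (2 * spec$read_length))
  if (n < 1L) {
    warning("coverage too low: zero fragments simulated")
    return(structure(list(truth = .fragments_to_truth(
      GenomicRanges::GRanges(), spec), n_pairs = 0L, spec = spec),
      class = "sim_reads"))
  }
  frags <- .draw_fragments(seqlens, n, spec)
  truth <- .fragments_to_truth(frags, spec)
  out <- structure(list(truth = truth, n_pairs = n, spec = spec,
                        seqlens = seqlens),
                   class = "sim_reads")
  if (!is.null(fastq_prefix))
    out$fastq <- write_sim_fastq(genome, out, fastq_prefix, gz = gz)
  if (!is.null(sam))
    out$sam <- write_truth_sam(out, sam, genome = genome)
  out
}

#' Write simulated reads as a FASTQ pair
#'
#' @param genome `DNAStringSet` the truth refers to.
#' @param sim A `sim_reads` object.
#' @param prefix Output prefix.
#' @param gz Gzip-compress (default TRUE).
#' @return Character vector of the two paths.
#' @export
write_sim_fastq <- function(genome, sim, prefix, gz = TRUE) {
  truth <- sim$truth
  seqs <- .truth_to_reads(genome, truth, sim$spec)
  qual <- .flat_qual(sim$spec$error_rate, sim$spec$read_length,
                     length(seqs))
  ext <- if (gz) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_R1", "_R2"), ext)
  for (m in 1:2) {
    sel <- truth$mate == m
    x <- Biostrings::QualityScaledDNAStringSet(
      seqs[sel], Biostrings::PhredQuality(qual[sel]))
    names(x) <- paste0(truth$read_id[sel], "/", m)
    Biostrings::writeQualityScaledXStringSet(x, paths[m], compress = gz)
  }
  paths
}

#' Write a ground-truth SAM of perfect alignments
#'
#' One record per mate with the true coordinates, CIGAR `<L>M`, MAPQ 60
#' and proper-pair flags (99/147). The file is a valid SAM accepted by
#' [stream_primary()].
#'
#' @param sim A `sim_reads` object (or a truth data frame, in which case
#'   `seqlens` must be supplied).
#' @param path Output path.
#' @param genome Optional `DNAStringSet`; when given, read sequences are
#'   embedded, otherwise SEQ/QUAL are `*`.
#' @param seqlens Named vector of chromosome lengths (taken from `sim`
#'   when absent).
#' @return `path`, invisibly.
#' @export
write_truth_sam <- function(sim, path, genome = NULL, seqlens = NULL) {
  if (inherits(sim, "sim_reads")) {
    truth <- sim$truth
    if (is.null(seqlens)) seqlens <- sim$seqlens
    spec <- sim$spec
  } else {
    truth <- sim
    spec <- NULL
  }
  if (is.null(seqlens))
    stop("write_truth_sam: chromosome lengths unknown")
  L <- if (nrow(truth)) truth$end[1L] - truth$start[1L] + 1L else 0L
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens),
                      as.integer(seqlens)))
  if (nrow(truth) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  flag <- ifelse(truth$mate == 1L, 99L, 147L)
  # mate's leftmost position: mate2 sits at fragment end (start + tlen - L
  # from mate1's start), mate1 at the fragment start (end + tlen + 1 seen
  # from mate2, whose tlen is negative)
  pnext <- ifelse(truth$mate == 1L, truth$start + truth$tlen - L,
                  truth$end + truth$tlen + 1L)
  seq <- "*"; qual <- "*"
  if (!is.null(genome)) {
    seqs <- .truth_to_reads(genome, truth,
                            if (is.null(spec)) sim_spec(error_rate = 0)
                            else within_error0(spec))
    minus <- truth$strand == "-"
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
    seq <- as.character(seqs)
    qual <- strrep("I", L)
  }
  lines <- paste(truth$read_id, flag, truth$chrom, truth$start, 60L,
                 paste0(L, "M"), "=", pnext, truth$tlen, seq, qual,
                 sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

# copy of a sim_spec with errors disabled (SAM stores the aligned bases)
within_error0 <- function(spec) { spec$error_rate <- 0; spec }

#' Simulate a pulldown experiment (chip + input libraries)
#'
#' The input library samples fragments uniformly. The chip library weights
#' each candidate fragment by the enrichment factor of any repeat family it
#' overlaps (the largest factor when several apply, 1 elsewhere) and
#' samples by rejection, which renormalizes the start distribution exactly
#' as stated: fragment probability proportional to its factor.
#'
#' @param genome `DNAStringSet` or `toy_genome`.
#' @param annotation `GRanges` of repeat instances with `family` column
#'   (taken from the `toy_genome` when omitted).
#' @param enrichment_map Named numeric vector, family -> factor (> 0).
#'   Families absent from the map have factor 1; unknown family names are
#'   an error.
#' @param spec A [sim_spec()]; `n_pairs`/`coverage` give the library depth.
#' @return List of class `sim_pulldown` with `chip` and `input`, each a
#'   `sim_reads` object.
#' @export
simulate_pulldown <- function(genome, annotation = NULL,
                              enrichment_map = numeric(), spec = sim_spec()) {
  if (inherits(genome, "toy_genome")) {
    if (is.null(annotation)) annotation <- genome$annotation
    genome <- genome$genome
  }
  stopifnot(!is.null(annotation))
  fams <- unique(annotation$family)
  if (length(enrichment_map)) {
    unknown <- setdiff(names(enrichment_map), fams)
    if (length(unknown))
      stop("unknown family in enrichment map: ",
           paste(unknown, collapse = ", "))
    if (any(enrichment_map <= 0))
      stop("enrichment factors must be > 0")
  }
  set.seed(spec$seed)
  seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
  n <- if (!is.null(spec$n_pairs)) spec$n_pairs else
    round(spec$coverage * sum(as.numeric(seqlens)) / (2 * spec$read_length))

  factor_of <- function(frags) {
    w <- rep(1, length(frags))
    if (length(enrichment_map)) {
      sel <- annotation[annotation$family %in% names(enrichment_map)]
      ov <- GenomicRanges::findOverlaps(frags, sel, ignore.strand = TRUE)
      if (length(ov)) {
        f <- enrichment_map[sel$family[S4Vectors::subjectHits(ov)]]
        agg <- tapply(f, S4Vectors::queryHits(ov), max)
        w[as.integer(names(agg))] <- pmax(w[as.integer(names(agg))],
                                          as.numeric(agg))
        # factors < 1 (depletion) replace the baseline weight
        lt <- tapply(f, S4Vectors::queryHits(ov), min)
        lt_idx <- as.integer(names(lt))
        dep <- lt < 1
        w[lt_idx[dep]] <- as.numeric(lt[dep])
      }
    }
    w
  }
  wmax <- max(1, if (length(enrichment_map)) max(enrichment_map) else 1)

  draw_library <- function(n, weighted) {
    if (!weighted || wmax == 1 && all(enrichment_map == 1)) {
      kept <- .draw_fragments(seqlens, n, spec)
    } else {
      kept <- GenomicRanges::GRanges()
      while (length(kept) < n) {
        need <- n - length(kept)
        batch <- max(1000L, ceiling(need * wmax * 1.2))
        cand <- .draw_fragments(seqlens, batch, spec)
        w <- factor_of(cand)
        acc <- stats::runif(batch) < w / wmax
        kept <- c(kept, cand[acc])
      }
      kept <- kept[seq_len(n)]
    }
    kept
  }

  chip_frags <- draw_library(n, weighted = length(enrichment_map) > 0)
  input_frags <- draw_library(n, weighted = FALSE)
  mk <- function(frags, tag) {
    structure(list(truth = .fragments_to_truth(frags, spec, tag),
                   n_pairs = length(frags), spec = spec,
                   seqlens = seqlens),
              class = "sim_reads")
  }
  structure(list(chip = mk(chip_frags, "chip"),
                 input = mk(input_frags, "input"),
                 enrichment_map = enrichment_map, spec = spec),
            class = "sim_pulldown")
}
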