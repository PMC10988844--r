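# Coverage profiles: full-length RE detection by reciprocal overlap,
# RPKM-normalised binned coverage tracks, and strand-aware anchored
# matrices for heatmap/profile plots.

#' Filter repeat regions for full-length instances
#'
#' Keeps a region when some model span overlaps it reciprocally: the
#' overlap covers at least fraction `f` of the region *and* at least `f`
#' of the model. Each region is reported at most once however many models
#' qualify. `f = 0.9` mirrors the usual full-length criterion; `f = 1`
#' rejects instances even one base short of their model and is therefore
#' prone to false negatives.
#'
#' @param regions `GRanges` of annotated instances.
#' @param models `GRanges` of full model spans.
#' @param f Reciprocal overlap fraction in (0, 1] (default 0.9).
#' @return The qualifying subset of `regions`, in input order.
#' @export
full_length_filter <- function(regions, models, f = 0.9) {
  stopifnot(f > 0, f <= 1)
  if (length(regions) == 0L || length(models) == 0L)
    return(regions[0])
  ov <- GenomicRanges::findOverlaps(regions, models, ignore.strand = TRUE)
  if (length(ov) == 0L) return(regions[0])
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  iw <- BiocGenerics::width(IRanges::pintersect(
    GenomicRanges::granges(regions)[q], GenomicRanges::granges(models)[s]))
  good <- iw >= f * BiocGenerics::width(regions)[q] &
    iw >= f * BiocGenerics::width(models)[s]
  regions[sort(unique(q[good]))]
}

#' RPKM-normalised binned coverage track
#'
#' Counts primary alignments per fixed-width bin (a read contributes to
#' every bin its reference span overlaps) and scales to RPKM:
#' `count * 1e9 / (bin_size * library_size)`.
#'
#' @param aln `GAlignments` from [stream_primary()] or a `GRanges` of read
#'   spans. Chromosome lengths must be known (`seqlengths`), or supplied.
#' @param bin_size Bin width in bp (default 10).
#' @param lib_size Library size (default [library_size()] of `aln`).
#' @param seqlens Optional named vector of chromosome lengths.
#' @return Object of class `coverage_track`: list with `bins` (`GRanges`
#'   with `score` = RPKM), `rle` (per-bp `RleList` of bin values),
#'   `bin_size`, `library_size`.
#' @export
coverage_track <- function(aln, bin_size = 10L, lib_size = library_size(aln),
                           seqlens = NULL) {
  stopifnot(bin_size > 0L)
  if (is.null(lib_size) || lib_size <= 0)
    stop("coverage_track: empty library")
  reads <- if (inherits(aln, "GAlignments"))
    GenomicRanges::granges(aln) else aln
  if (is.null(seqlens)) {
    sl <- GenomeInfoDb::seqlengths(reads)
    if (length(sl) && !anyNA(sl)) seqlens <- sl
  }
  if (is.null(seqlens)) {  # fall back to the rightmost read per chromosome
    mx <- tapply(BiocGenerics::end(reads),
                 as.character(GenomeInfoDb::seqnames(reads)), max)
    seqlens <- stats::setNames(as.integer(mx), names(mx))
  }
  bins <- GenomicRanges::tileGenome(seqlens, tilewidth = bin_size,
                                    cut.last.tile.in.chrom = TRUE)
  cnt <- GenomicRanges::countOverlaps(bins, reads, ignore.strand = TRUE)
  score <- cnt * 1e9 / (bin_size * lib_size)
  bins$score <- score
  rle <- methods::as(GenomicRanges::coverage(bins, weight = "score"),
                     "RleList")
  structure(list(bins = bins, rle = rle, bin_size = bin_size,
                 library_size = lib_size, seqlens = seqlens),
            class = "coverage_track")
}

#' Pool replicate coverage tracks by mean
#'
#' @param ... Two or more `coverage_track` objects over the same bins.
#' @return A `coverage_track` whose scores are the element-wise mean.
#' @export
pool_tracks <- function(...) {
  tracks <- list(...)
  stopifnot(length(tracks) >= 2L)
  out <- tracks[[1L]]
  sc <- Reduce(`+`, lapply(tracks, function(t) t$bins$score))
  out$bins$score <- sc / length(tracks)
  out$rle <- methods::as(GenomicRanges::coverage(out$bins, weight = "score"),
                         "RleList")
  out
}

#' Export a coverage track as bedGraph
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(track, path) {
  gr <- track$bins
  GenomeInfoDb::seqlengths(gr) <- track$seqlens[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Anchored coverage matrix around region ends
#'
#' Extracts the track signal in fixed-width bins over `[-flank, +flank)`
#' around the 5' or 3' end of each region, strand-aware: minus-strand
#' regions are flipped so that columns always run 5'->3'. Windows beyond
#' chromosome ends are zero-filled. The mean profile is the column mean.
#'
#' @param track A `coverage_track`.
#' @param regions `GRanges` (strand used for anchoring).
#' @param anchor `"five_prime"` or `"three_prime"`.
#' @param flank Flank size in bp on each side; multiple of `bin_size`.
#' @param bin_size Matrix bin width (default 50).
#' @param sort_rows `"mean"` (default, descending mean row intensity) or
#'   `"none"` (input order).
#' @return List of class `anchored_matrix`: `matrix` (rows = regions,
#'   rownames from region names or indices), `profile` (column means over
#'   all rows), `anchor`, `flank`, `bin_size`.
#' @export
anchored_matrix <- function(track, regions, anchor = c("five_prime",
                                                       "three_prime"),
                            flank, bin_size = 50L, sort_rows = c("mean",
                                                                 "none")) {
  anchor <- match.arg(anchor)
  sort_rows <- match.arg(sort_rows)
  stopifnot(flank > 0L, flank %% bin_size == 0L)
  ncol <- as.integer(2L * flank / bin_size)
  n <- length(regions)
  mat <- matrix(0, nrow = n, ncol = ncol)
  if (n) {
    minus <- as.character(BiocGenerics::strand(regions)) == "-"
    five <- ifelse(minus, BiocGenerics::end(regions),
                   BiocGenerics::start(regions))
    three <- ifelse(minus, BiocGenerics::start(regions),
                    BiocGenerics::end(regions))
    a <- if (anchor == "five_prime") five else three
    chr <- as.character(GenomeInfoDb::seqnames(regions))
    offs <- seq.int(-flank, flank - bin_size, by = bin_size)
    for (i in seq_len(n)) {
      # bin at 5'->3' offset o covers [a+o, a+o+bin-1] on plus strand and
      # the mirrored window [a-o-bin+1, a-o] on minus strand
      starts <- if (minus[i]) a[i] - offs - bin_size + 1L else a[i] + offs
      # value of a bin: mean per-bp track value over the window
      v <- numeric(ncol)
      r <- track$rle[[chr[i]]]
      if (!is.null(r)) {
        len <- length(r)
        for (j in seq_len(ncol)) {
          s <- starts[j]; e <- s + bin_size - 1L
          ss <- max(1L, s); ee <- min(len, e)
          if (ss <= ee) {
            # zero fill outside the chromosome
            v[j] <- sum(as.numeric(r[ss:ee])) / bin_size
          }
        }
      }
      mat[i, ] <- v
    }
    rn <- if (!is.null(regions$name)) make.unique(regions$name)
    else as.character(seq_len(n))
    rownames(mat) <- rn
    if (sort_rows == "mean" && n > 1L)  # tie-break on name for determinism
      mat <- mat[order(-rowMeans(mat), rownames(mat)), , drop = FALSE]
  }
  colnames(mat) <- sprintf("bin_%d", seq.int(-flank, flank - bin_size,
                                             by = bin_size))
  structure(list(matrix = mat, profile = colMeans(mat),
                 anchor = anchor, flank = flank, bin_size = bin_size),
            class = "anchored_matrix")
}

#' Write an anchored matrix and its mean profile as TSV
#'
#' @param am An `anchored_matrix`.
#' @param prefix Output prefix; writes `<prefix>.matrix.tsv` and
#'   `<prefix>.profile.tsv`.
#' @return The matrix path, invisibly.
#' @export
write_anchored_matrix <- function(am, prefix) {
  mp <- paste0(prefix, ".matrix.tsv")
  df <- data.frame(region = rownames(am$matrix), am$matrix,
                   check.names = FALSE)
  utils::write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  pp <- paste0(prefix, ".profile.tsv")
  utils::write.table(
    data.frame(offset = as.integer(sub("bin_", "", names(am$profile))),
               mean_signal = as.numeric(am$profile)),
    pp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mp)
}
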