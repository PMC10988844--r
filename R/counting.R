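# Read counting onto merged RE intervals with meta-feature semantics, plus
# library-size and alignment-QC metrics (insert-size outliers, MAPQ).

#' Load primary mapped alignments from SAM/BAM
#'
#' Keeps only mapped records that are neither secondary (flag 256) nor
#' supplementary (flag 2048), so each multimapping read is represented once,
#' by its primary alignment. The number of records returned is the library
#' size in the flagstat "primary mapped" sense, attached as the
#' `library_size` attribute.
#'
#' @param path SAM (plain text) or BAM file.
#' @return A [GenomicAlignments::GAlignments] with metadata columns `qname`,
#'   `flag`, `mapq`, `isize` and attribute `library_size`.
#' @export
stream_primary <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- path
  if (is_sam) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("SAM parse error in '", path, "': ",
                               conditionMessage(e)))
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("qname", "flag", "mapq", "isize"))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  if (is_sam) unlink(c(bam, paste0(bam, ".bai")))
  attr(aln, "library_size") <- length(aln)
  aln
}

#' Library size of an alignment set
#'
#' Number of primary mapped reads: the `library_size` attribute when the
#' object came from [stream_primary()], otherwise its length.
#' @param aln Alignments (`GAlignments` or `GRanges`).
#' @return Integer scalar.
#' @export
library_size <- function(aln) {
  ls <- attr(aln, "library_size")
  if (is.null(ls)) length(aln) else ls
}

# Core meta-feature counter: unique (read, name) pairs over >=1 bp overlaps.
# `reads` is a GRanges of reference spans (CIGAR-derived for real alignments).
.count_core <- function(reads, annotation) {
  all_names <- sort(unique(annotation$name))
  counts <- stats::setNames(integer(length(all_names)), all_names)
  if (length(reads) == 0L || length(annotation) == 0L)
    return(list(counts = counts, total_assigned = 0L))
  ov <- GenomicRanges::findOverlaps(reads, annotation, minoverlap = 1L,
                                    ignore.strand = TRUE)
  if (length(ov) == 0L)
    return(list(counts = counts, total_assigned = 0L))
  q <- S4Vectors::queryHits(ov)
  nm <- annotation$name[S4Vectors::subjectHits(ov)]
  keep <- !duplicated(paste0(q, "\r", nm))
  tab <- table(factor(nm[keep], levels = all_names))
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts, total_assigned = length(unique(q)))
}

#' Count reads on repeat elements
#'
#' Assigns each primary mapped read to every distinct RE *name* whose merged
#' intervals it overlaps by at least one base. A read overlapping two
#' instances (or two exons) of the same name increments that name once;
#' a read overlapping instances of several names increments each of them
#' (overlap-tolerant meta-feature semantics). Mates of a pair are counted
#' independently and MAPQ is not filtered. The overlap of an alignment is
#' its CIGAR reference span, not its read length.
#'
#' @param aln `GAlignments` from [stream_primary()], or a `GRanges` of read
#'   reference spans (e.g. ground-truth intervals).
#' @param annotation `GRanges` of merged RE instances with a `name` column.
#' @param lib_size Library size; defaults to [library_size()] of `aln`.
#' @return An object of class `re_counts`: list with `counts` (named integer
#'   vector over all annotation names), `library_size`, `total_assigned`.
#' @export
count_reads <- function(aln, annotation, lib_size = library_size(aln)) {
  if (length(annotation) == 0L)
    warning("empty annotation: all counts are zero")
  reads <- if (inherits(aln, "GAlignments"))
    GenomicRanges::granges(aln) else aln
  core <- .count_core(reads, annotation)
  structure(list(counts = core$counts,
                 library_size = as.integer(lib_size),
                 total_assigned = core$total_assigned),
            class = "re_counts")
}

#' @export
print.re_counts <- function(x, ...) {
  cat("RE count table:", length(x$counts), "names; library size",
      x$library_size, "; assigned", x$total_assigned, "\n")
  invisible(x)
}

#' Write a count table as TSV plus a JSON sidecar
#'
#' @param ct `re_counts` object.
#' @param prefix Output prefix; writes `<prefix>.counts.tsv` (columns `name`,
#'   `count`, name-sorted) and `<prefix>.counts.json` (library size and
#'   total assigned).
#' @return The TSV path, invisibly.
#' @export
write_counts <- function(ct, prefix) {
  tsv <- paste0(prefix, ".counts.tsv")
  df <- data.frame(name = names(ct$counts), count = as.integer(ct$counts))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(library_size = ct$library_size,
         total_assigned = ct$total_assigned),
    paste0(prefix, ".counts.json"), auto_unbox = TRUE)
  invisible(tsv)
}

#' Read a count table written by [write_counts()]
#' @param prefix Prefix used at write time.
#' @return An `re_counts` object.
#' @export
read_counts <- function(prefix) {
  df <- utils::read.table(paste0(prefix, ".counts.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, ".counts.json"))
  structure(list(counts = stats::setNames(as.integer(df$count), df$name),
                 library_size = as.integer(meta$library_size),
                 total_assigned = as.integer(meta$total_assigned)),
            class = "re_counts")
}

#' Insert-size statistics and outlier fraction
#'
#' Each template is measured once, via the TLEN of the mate with positive
#' sign. Outliers are inserts at least twice the maximum fragment size
#' reliably observed for the library (`|TLEN| >= 2 * max_fs`, boundary
#' inclusive); `outlier_mapped_bases` sums the aligned reference bases of
#' every primary record (either mate) belonging to an outlier template.
#'
#' @param aln `GAlignments` from [stream_primary()].
#' @param max_fs Maximum reliable fragment size of the library, in bp.
#' @return List of class `is_stats`: `n`, `median`, `q25`, `q75`,
#'   `outlier_fraction`, `outlier_mapped_bases`.
#' @export
insert_size_stats <- function(aln, max_fs) {
  stopifnot(max_fs > 0)
  tlen <- S4Vectors::mcols(aln)$isize
  tlen[is.na(tlen)] <- 0L
  measured <- tlen > 0L
  vals <- tlen[measured]
  cutoff <- 2 * max_fs
  out_rec <- abs(tlen) >= cutoff & tlen != 0L
  structure(list(
    n = length(vals),
    median = if (length(vals)) stats::median(vals) else NA_real_,
    q25 = if (length(vals)) unname(stats::quantile(vals, 0.25)) else NA_real_,
    q75 = if (length(vals)) unname(stats::quantile(vals, 0.75)) else NA_real_,
    outlier_fraction = if (length(vals)) mean(vals >= cutoff) else NA_real_,
    outlier_mapped_bases =
      sum(BiocGenerics::width(GenomicRanges::granges(aln))[out_rec])),
    class = "is_stats")
}

#' Count primary alignments at or above a MAPQ threshold
#'
#' @param aln `GAlignments` from [stream_primary()].
#' @param threshold MAPQ cutoff, inclusive (default 40, the conventional
#'   "unique, high-quality" criterion).
#' @return Integer count.
#' @export
mapq_ge_count <- function(aln, threshold = 40L) {
  stopifnot(threshold >= 0)
  mq <- S4Vectors::mcols(aln)$mapq
  sum(!is.na(mq) & mq >= threshold)
}
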