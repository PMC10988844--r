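# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles deliberately use naive quadratic scans / direct
# formula transcription, not the package's code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# Quadratic per-read x per-instance overlap scan (single chromosome set,
# 1-based closed coordinates), meta-feature semantics: a read increments
# each distinct name it overlaps once.
oracle_count <- function(read_chrom, read_start, read_end,
                         ann_chrom, ann_start, ann_end, ann_name) {
  all_names <- sort(unique(ann_name))
  counts <- stats::setNames(integer(length(all_names)), all_names)
  assigned <- 0L
  for (i in seq_along(read_start)) {
    hit <- ann_chrom == read_chrom[i] &
      ann_start <= read_end[i] & ann_end >= read_start[i]
    nms <- unique(ann_name[hit])
    if (length(nms)) {
      assigned <- assigned + 1L
      counts[nms] <- counts[nms] + 1L
    }
  }
  list(counts = counts, total_assigned = assigned)
}

# Direct transcription of the rank-based FDR formula: floor, stable
# ascending sort, p*N/k, cap at 1, original order. Written as an explicit
# loop to stay independent of the vectorised implementation.
oracle_fdr <- function(p, N = length(p), names = NULL, floor = 1e-16) {
  pf <- pmax(p, floor)
  key <- if (is.null(names)) as.character(seq_along(pf)) else names
  ord <- order(pf, key)
  adj <- numeric(length(pf))
  for (k in seq_along(ord)) {
    adj[ord[k]] <- min(pf[ord[k]] * N / k, 1)
  }
  adj
}

# Reciprocal-overlap check by direct arithmetic on one region/model pair.
oracle_reciprocal <- function(rs, re, ms, me, f) {
  ov <- min(re, me) - max(rs, ms) + 1L
  ov > 0 && ov >= f * (re - rs + 1L) && ov >= f * (me - ms + 1L)
}

# Textbook Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Random merged single-chromosome annotation: k intervals over m names.
# (Fully qualified so the helper works whatever the test env's parent is.)
random_annotation <- function(k, names_pool, max_pos = 10000L,
                              max_len = 300L) {
  st <- sample.int(max_pos, k, replace = TRUE)
  len <- sample.int(max_len, k, replace = TRUE)
  GenomicRanges::GRanges("chr1", IRanges::IRanges(st, st + len - 1L),
                         name = sample(names_pool, k, replace = TRUE))
}

# Hand-rolled SAM writer for flag-audit fixtures. `records` is a data
# frame with qname, flag, rname, pos, mapq, cigar, tlen.
write_test_sam <- function(records, seqlens, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens),
                      as.integer(seqlens)))
  body <- character(0)
  if (nrow(records)) {
    body <- paste(records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, "*", 0L, records$tlen,
                  "*", "*", sep = "\t")
  }
  writeLines(c(header, body), path)
  path
}

# Small deterministic toy genome shared by the heavier tests.
shared_toy_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_toy_genome(toy_genome_spec(seed = 11))
    cache
  }
})
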