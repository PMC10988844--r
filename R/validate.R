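# Benchmarking loop: assign ground-truth reads to REs, then compare
# reference (truth-derived) against analysed densities via relative error,
# recovery percentage and Pearson correlation.

#' Count ground-truth reads on repeat elements
#'
#' Applies exactly the counting semantics of [count_reads()] to the true
#' read intervals of a simulation: each mate is one read, assigned to every
#' distinct RE name it overlaps by at least one base.
#'
#' @param truth A `sim_reads` object or its truth data frame (`chrom`,
#'   `start`, `end` per mate).
#' @param annotation `GRanges` of merged RE instances with `name`.
#' @return An `re_counts` object whose library size is the number of truth
#'   reads.
#' @export
assign_truth <- function(truth, annotation) {
  df <- if (inherits(truth, "sim_reads")) truth$truth else truth
  if (nrow(df) > 0 &&
      !all(unique(df$chrom) %in%
           as.character(GenomeInfoDb::seqnames(annotation)@values)) &&
      length(annotation) > 0L) {
    miss <- setdiff(unique(df$chrom),
                    unique(as.character(GenomeInfoDb::seqnames(annotation))))
    if (length(miss) == length(unique(df$chrom)))
      stop("assign_truth: no truth chromosome found in annotation (",
           paste(utils::head(miss, 5L), collapse = ", "), ")")
  }
  reads <- GenomicRanges::GRanges(df$chrom,
                                  IRanges::IRanges(df$start, df$end))
  count_reads(reads, annotation, lib_size = nrow(df))
}

#' Relative error and recovery between reference and analysed densities
#'
#' Per RE name the relative error is `200 * |ref - ana| / (ref + ana)`
#' (percent, in `[0, 200]`) and the recovery is `100 * ana / ref`. The
#' summary mean excludes families in `exclude` (default: Simple repeats,
#' which are intrinsically unstable at low coverage) when a grouping is
#' supplied.
#'
#' @param ref,ana `re_norm` objects over identical name sets (reference =
#'   truth-derived, analysis = pipeline-derived).
#' @param grouping Optional `re_grouping` used for the exclusion.
#' @param exclude Families excluded from the summary mean (default
#'   `"Simple_repeat"`).
#' @return List of class `re_recovery`: `table` (data frame `name`,
#'   `ref_density`, `ana_density`, `relative_error_percent`,
#'   `recovery_percent`), `mean_relative_error` (over non-excluded names),
#'   `mean_relative_error_all`.
#' @export
relative_error <- function(ref, ana, grouping = NULL,
                           exclude = "Simple_repeat") {
  a <- names(ref$density); b <- names(ana$density)
  if (!setequal(a, b) || length(a) != length(b))
    stop("relative_error: name sets differ: ",
         paste(utils::head(union(setdiff(a, b), setdiff(b, a)), 10L),
               collapse = ", "))
  r <- ref$density
  x <- ana$density[a]
  rel <- 200 * abs(r - x) / (r + x)
  rec <- 100 * x / r
  tab <- data.frame(name = a, ref_density = unname(r),
                    ana_density = unname(x),
                    relative_error_percent = unname(rel),
                    recovery_percent = unname(rec),
                    stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(grouping) && length(exclude)) {
    fam <- grouping$map$family[match(tab$name, grouping$map$name)]
    keep <- !(fam %in% exclude)
  }
  structure(list(table = tab,
                 mean_relative_error = mean(rel[keep]),
                 mean_relative_error_all = mean(rel)),
            class = "re_recovery")
}

#' @export
print.re_recovery <- function(x, ...) {
  cat("RE recovery over", nrow(x$table), "names: mean relative error",
      format(x$mean_relative_error, digits = 4), "%",
      "(excl. filtered families);", format(x$mean_relative_error_all,
                                           digits = 4), "% overall\n")
  invisible(x)
}

#' Pearson correlation between reference and analysed densities
#'
#' @param ref,ana `re_norm` objects over identical name sets (at least 3
#'   names).
#' @param log_scale Correlate `log10` densities instead of raw (default
#'   FALSE).
#' @return Pearson r, or `NA` with a warning when either side has zero
#'   variance.
#' @export
correlation_density <- function(ref, ana, log_scale = FALSE) {
  a <- names(ref$density)
  stopifnot(length(a) >= 3L)
  x <- ref$density
  y <- ana$density[a]
  if (log_scale) { x <- log10(x); y <- log10(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined: zero variance")
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

#' Write a recovery table and its summary
#'
#' @param rec An `re_recovery` from [relative_error()].
#' @param prefix Output prefix; writes `<prefix>.recovery.tsv` and
#'   `<prefix>.recovery.json`.
#' @return The TSV path, invisibly.
#' @export
write_recovery <- function(rec, prefix) {
  tsv <- paste0(prefix, ".recovery.tsv")
  tab <- rec$table[order(rec$table$name), , drop = FALSE]
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(mean_relative_error = rec$mean_relative_error,
         mean_relative_error_all = rec$mean_relative_error_all,
         n_names = nrow(rec$table)),
    paste0(prefix, ".recovery.json"), auto_unbox = TRUE, digits = NA)
  invisible(tsv)
}
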