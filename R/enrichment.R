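# Enrichment statistics: pseudocounted library-size normalization,
# ChIP/input ratios, two-replicate Z-score reproducibility statistic,
# rank-based FDR adjustment, and per-family summaries.

#' Normalize a count table to library size with pseudocounts
#'
#' Zero counts are replaced by the pseudocount (default 0.1) before
#' division by the library size (number of primary mapped reads), so every
#' density is strictly positive and downstream ratios stay finite.
#'
#' @param ct An `re_counts` object from [count_reads()].
#' @param pseudocount Value replacing zero counts (default 0.1).
#' @return Object of class `re_norm`: list with `density` (named numeric),
#'   `library_size`, `pseudocount`.
#' @export
normalize_counts <- function(ct, pseudocount = 0.1) {
  if (is.null(ct$library_size) || ct$library_size <= 0)
    stop("normalize_counts: empty library (library_size must be > 0)")
  dens <- pmax(as.numeric(ct$counts), pseudocount) / ct$library_size
  structure(list(density = stats::setNames(dens, names(ct$counts)),
                 library_size = ct$library_size,
                 pseudocount = pseudocount),
            class = "re_norm")
}

#' ChIP over input enrichment ratios
#'
#' @param chip,input `re_norm` objects over identical name sets.
#' @return Named numeric vector of ratios (always finite).
#' @export
enrichment_ratio <- function(chip, input) {
  a <- names(chip$density); b <- names(input$density)
  if (!setequal(a, b) || length(a) != length(b)) {
    diff <- union(setdiff(a, b), setdiff(b, a))
    stop("enrichment_ratio: name sets differ: ",
         paste(utils::head(diff, 10L), collapse = ", "))
  }
  chip$density / input$density[a]
}

#' Two-replicate enrichment statistics
#'
#' Combines per-replicate ChIP/input ratios into the reproducibility
#' statistic: arithmetic mean, population SD (n divisor, n = 2),
#' `z = |mean - 1| / sd`, and the one-sided p-value `P(N(0,1) > z)`.
#' When the two ratios are identical the statistic is undefined: with
#' mean != 1 the row is reported as z = Inf, p = 0; with mean == 1 as
#' z = 0, p = 0.5. Both cases are flagged in `degenerate_sd`.
#'
#' @param enr1,enr2 Named numeric vectors of per-replicate ratios (same
#'   names, finite, positive).
#' @return Data frame with columns `name`, `enr1`, `enr2`, `mean`, `sd`,
#'   `z`, `p`, `degenerate_sd`.
#' @export
replicate_stats <- function(enr1, enr2) {
  if (is.null(names(enr1))) names(enr1) <- as.character(seq_along(enr1))
  enr2 <- if (is.null(names(enr2))) {
    stats::setNames(enr2, names(enr1))
  } else enr2[names(enr1)]
  stopifnot(all(is.finite(enr1)), all(is.finite(enr2)))
  m <- (enr1 + enr2) / 2
  s <- abs(enr1 - enr2) / 2  # population SD of two values
  z <- ifelse(s > 0, abs(m - 1) / s, ifelse(m == 1, 0, Inf))
  p <- ifelse(s > 0, stats::pnorm(z, lower.tail = FALSE),
              ifelse(m == 1, 0.5, 0))
  data.frame(name = names(enr1), enr1 = unname(enr1), enr2 = unname(enr2),
             mean = unname(m), sd = unname(s), z = unname(z), p = unname(p),
             degenerate_sd = unname(s == 0),
             stringsAsFactors = FALSE)
}

#' Rank-based FDR adjustment
#'
#' P-values are floored at `floor` (default 1e-16), sorted ascending with a
#' stable tie-break on `names`, ranked k = 1..N, and each adjusted to
#' `p * N / k`, capped at 1. This is the plain rank formula, applied
#' verbatim without the step-up monotonization of the classical
#' Benjamini-Hochberg procedure; set `method = "bh"` for the standard
#' monotone variant (applied to the floored values).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param N Total number of tests (default `length(p)`).
#' @param names Optional character vector used as stable tie-break key.
#' @param floor Minimum p-value before ranking (default 1e-16).
#' @param method `"rank"` (verbatim formula, default) or `"bh"`.
#' @return Adjusted p-values in the original order of `p`.
#' @export
fdr_adjust <- function(p, N = length(p), names = NULL, floor = 1e-16,
                       method = c("rank", "bh")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("fdr_adjust: p-values must lie in [0, 1]")
  if (N != length(p))
    stopifnot(N >= length(p))
  pf <- pmax(p, floor)
  if (method == "bh")
    return(stats::p.adjust(pf, method = "BH", n = N))
  key <- if (is.null(names)) as.character(seq_along(pf)) else names
  ord <- order(pf, key)
  k <- seq_along(ord)
  adj <- numeric(length(pf))
  adj[ord] <- pmin(pf[ord] * N / k, 1)
  adj
}

#' Assemble the per-RE enrichment table from four libraries
#'
#' @param chip1,input1,chip2,input2 `re_counts` objects over the same
#'   annotation (replicate pairs chip1/input1 and chip2/input2).
#' @param grouping An `re_grouping` covering all names.
#' @param pseudocount Passed to [normalize_counts()].
#' @return Data frame of class `re_enrichment` with columns `name`,
#'   `family`, `class`, the four raw counts, `enr1`, `enr2`, `mean`, `sd`,
#'   `z`, `p`, `p_fdr`, `log2_mean`, `degenerate_sd`, sorted by name.
#' @export
enrichment_table <- function(chip1, input1, chip2, input2, grouping,
                             pseudocount = 0.1) {
  n1 <- normalize_counts(chip1, pseudocount)
  i1 <- normalize_counts(input1, pseudocount)
  n2 <- normalize_counts(chip2, pseudocount)
  i2 <- normalize_counts(input2, pseudocount)
  e1 <- enrichment_ratio(n1, i1)
  e2 <- enrichment_ratio(n2, i2)[names(e1)]
  st <- replicate_stats(e1, e2)
  idx <- match(st$name, grouping$map$name)
  if (anyNA(idx))
    stop("names missing from grouping: ",
         paste(utils::head(st$name[is.na(idx)], 10L), collapse = ", "))
  out <- data.frame(
    name = st$name,
    family = grouping$map$family[idx],
    class = grouping$map$cls[idx],
    count_chip1 = as.integer(chip1$counts[st$name]),
    count_input1 = as.integer(input1$counts[st$name]),
    count_chip2 = as.integer(chip2$counts[st$name]),
    count_input2 = as.integer(input2$counts[st$name]),
    enr1 = st$enr1, enr2 = st$enr2, mean = st$mean, sd = st$sd,
    z = st$z, p = st$p,
    p_fdr = fdr_adjust(st$p, names = st$name),
    log2_mean = log2(st$mean),
    degenerate_sd = st$degenerate_sd,
    stringsAsFactors = FALSE)
  out <- out[order(out$name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("re_enrichment", "data.frame")
  out
}

#' Per-family (or per-class) enrichment summaries
#'
#' For each grouping level the pseudocounted member densities of a library
#' are summed and divided by the group size (number of distinct member
#' names); ratios and the two-replicate statistic are then computed on
#' these group densities exactly as for single REs. Family p-values are
#' FDR-adjusted with N = number of groups.
#'
#' @param norm_chip1,norm_input1,norm_chip2,norm_input2 `re_norm` objects.
#' @param grouping An `re_grouping`.
#' @param level `"family"` (default) or `"cls"`.
#' @return Data frame with columns `family`, `n_members`, `dens_chip1`,
#'   `dens_input1`, `dens_chip2`, `dens_input2`, `enr1`, `enr2`, `mean`,
#'   `sd`, `z`, `p`, `p_fdr`, `log2_mean`, `degenerate_sd`.
#' @export
summarize_families <- function(norm_chip1, norm_input1, norm_chip2,
                               norm_input2, grouping, level = c("family", "cls")) {
  level <- match.arg(level)
  map <- grouping$map
  nms <- names(norm_chip1$density)
  idx <- match(nms, map$name)
  if (anyNA(idx))
    stop("names missing from grouping: ",
         paste(utils::head(nms[is.na(idx)], 10L), collapse = ", "))
  grp <- map[[level]][idx]
  gsize <- vapply(split(map$name, map[[level]]), length, 1L)
  gdens <- function(norm) {
    s <- vapply(split(norm$density[nms], grp), sum, numeric(1L))
    s / gsize[names(s)]
  }
  d_c1 <- gdens(norm_chip1); d_i1 <- gdens(norm_input1)
  d_c2 <- gdens(norm_chip2); d_i2 <- gdens(norm_input2)
  st <- replicate_stats(d_c1 / d_i1, d_c2 / d_i2)
  out <- data.frame(
    family = st$name, n_members = as.integer(gsize[st$name]),
    dens_chip1 = unname(d_c1[st$name]), dens_input1 = unname(d_i1[st$name]),
    dens_chip2 = unname(d_c2[st$name]), dens_input2 = unname(d_i2[st$name]),
    enr1 = st$enr1, enr2 = st$enr2, mean = st$mean, sd = st$sd,
    z = st$z, p = st$p,
    p_fdr = fdr_adjust(st$p, names = st$name),
    log2_mean = log2(st$mean),
    degenerate_sd = st$degenerate_sd,
    stringsAsFactors = FALSE)
  out <- out[order(out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#'
#' Fixed column order and name-sorted rows, so identical inputs produce
#' byte-identical files.
#'
#' @param rows Data frame from [enrichment_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(rows, path) {
  cols <- c("name", "family", "class", "count_chip1", "count_input1",
            "count_chip2", "count_input2", "enr1", "enr2", "mean", "sd",
            "z", "p", "p_fdr", "log2_mean")
  cols <- cols[cols %in% names(rows)]
  df <- as.data.frame(rows)[, cols, drop = FALSE]
  df <- df[order(df[[1L]]), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
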