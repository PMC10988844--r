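# Annotation handling: RepeatMasker BED12 -> per-exon intervals -> merged
# per-name instances (GRanges) plus the subfamily/family/class grouping.
#
# All in-memory intervals are GRanges (1-based, closed), the native R/Bioc
# convention. Conversion to/from 0-based half-open happens only at the BED
# boundary; GTF output is 1-based closed and therefore needs no shift.

#' Parse a RepeatMasker BED12 file
#'
#' Reads a 12-column BED file (one row per repeat-element instance) and
#' expands the block structure into per-exon intervals, the adjustment that
#' turns a model-span annotation into intervals that reflect the aligned
#' repeat segments. The BED `name` field may carry the grouping hierarchy in
#' the form `name#family/class`; the plain name is kept in `name` and the
#' grouping, when present, in `family` and `cls`.
#'
#' @param path Path to a BED12 file (tab-separated, 12 columns, no header).
#' @return A list with components `models` (a [GenomicRanges::GRanges] with
#'   one range per BED row, the full model span) and `exons` (a `GRanges`
#'   of block-derived exon intervals, with a `model_id` column giving the
#'   1-based BED row each exon came from). Both carry `name`, `family`,
#'   `cls` metadata columns (`family`/`cls` are `NA` when the name field
#'   has no `#family/class` suffix).
#' @export
parse_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
  if (!length(lines)) stop("BED12 parse error: no data rows in ", path)
  raw <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 12L)
    stop("BED12 parse error: expected 12 columns, found ", ncol(raw))
  raw <- raw[, 1:12]
  names(raw) <- c("chrom", "start", "end", "name", "score", "strand",
                  "thickStart", "thickEnd", "rgb", "blockCount",
                  "blockSizes", "blockStarts")

  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("BED12 parse error at line ", bad[1L], ": non-numeric ", what)
    v
  }
  start <- num("start", "chromStart")
  end <- num("end", "chromEnd")
  bad <- which(start >= end)
  if (length(bad))
    stop("BED12 parse error at line ", bad[1L], ": chromStart >= chromEnd")
  if (any(raw$name == ""))
    stop("BED12 parse error at line ", which(raw$name == "")[1L],
         ": empty name")
  n_block <- num("blockCount", "blockCount")

  split_ints <- function(s) lapply(strsplit(s, ","), function(x) {
    v <- suppressWarnings(as.numeric(x[nzchar(x)]))
    v
  })
  sizes <- split_ints(raw$blockSizes)
  offs <- split_ints(raw$blockStarts)

  for (i in seq_len(nrow(raw))) {
    if (length(sizes[[i]]) != n_block[i] || length(offs[[i]]) != n_block[i] ||
        anyNA(sizes[[i]]) || anyNA(offs[[i]]))
      stop("BED12 structural error at line ", i,
           ": blockCount does not match blockSizes/blockStarts")
    ends <- start[i] + offs[[i]] + sizes[[i]]
    if (offs[[i]][1L] != 0 || any(ends > end[i]))
      stop("BED12 structural error at line ", i,
           ": blocks extend outside chromStart..chromEnd")
  }

  grouping <- .parse_name_grouping(raw$name)
  strand <- ifelse(raw$strand %in% c("+", "-"), raw$strand, "*")

  models <- GenomicRanges::GRanges(
    seqnames = raw$chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand,
    name = grouping$name, family = grouping$family, cls = grouping$cls)

  per_row <- lengths(sizes)
  row_id <- rep(seq_len(nrow(raw)), per_row)
  ex_start <- unlist(offs) + start[row_id] + 1L
  ex_end <- ex_start + unlist(sizes) - 1L
  exons <- GenomicRanges::GRanges(
    seqnames = raw$chrom[row_id],
    ranges = IRanges::IRanges(start = ex_start, end = ex_end),
    strand = strand[row_id],
    name = grouping$name[row_id],
    family = grouping$family[row_id],
    cls = grouping$cls[row_id],
    model_id = row_id)

  list(models = models, exons = exons)
}

# "AluY#Alu/SINE" -> name AluY, family Alu, cls SINE; plain names pass
# through with NA grouping.
.parse_name_grouping <- function(nm) {
  has <- grepl("#", nm, fixed = TRUE)
  name <- sub("#.*$", "", nm)
  rest <- ifelse(has, sub("^[^#]*#", "", nm), NA_character_)
  family <- ifelse(is.na(rest), NA_character_, sub("/.*$", "", rest))
  cls <- ifelse(is.na(rest) | !grepl("/", rest), family,
                sub("^[^/]*/", "", rest))
  list(name = name, family = family, cls = cls)
}

#' Merge overlapping same-name exon intervals
#'
#' Sorts exon intervals and merges overlapping intervals of identical name,
#' applied in two passes. Intervals of different names are never merged, and
#' abutting intervals (end of one equals start of the next minus one, i.e.
#' zero-gap book-ends) are kept separate: only genuine overlaps collapse.
#' Strand is retained when all merged members agree and set to `*` otherwise;
#' downstream counting ignores strand in any case (unstranded pulldowns).
#'
#' @param exons A `GRanges` with a `name` metadata column (and optionally
#'   `family`/`cls`), e.g. the `exons` element from [parse_bed12()].
#' @return A `GRanges` sorted by (seqname, start) in which no two ranges of
#'   the same name overlap; metadata columns `name`, `family`, `cls`.
#' @export
extract_and_merge <- function(exons) {
  if (length(exons) == 0L) {
    return(GenomicRanges::GRanges(
      name = character(), family = character(), cls = character()))
  }
  grouping <- .grouping_of(exons)
  merge_once <- function(gr) {
    parts <- S4Vectors::split(gr, gr$name)
    merged <- lapply(names(parts), function(nm) {
      g <- parts[[nm]]
      red <- GenomicRanges::reduce(g, min.gapwidth = 0L,
                                   ignore.strand = TRUE, with.revmap = TRUE)
      st <- vapply(red$revmap, function(idx) {
        s <- unique(as.character(BiocGenerics::strand(g)[idx]))
        if (length(s) == 1L) s else "*"
      }, character(1L))
      BiocGenerics::strand(red) <- st
      red$revmap <- NULL
      red$name <- nm
      red
    })
    out <- suppressWarnings(do.call(c, merged))
    BiocGenerics::sort(out, ignore.strand = TRUE)
  }
  out <- merge_once(merge_once(exons))
  idx <- match(out$name, grouping$name)
  out$family <- grouping$family[idx]
  out$cls <- grouping$cls[idx]
  out
}

.grouping_of <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  fam <- if ("family" %in% names(mc)) mc$family else rep(NA_character_, length(gr))
  cls <- if ("cls" %in% names(mc)) mc$cls else rep(NA_character_, length(gr))
  unique(data.frame(name = mc$name, family = fam, cls = cls,
                    stringsAsFactors = FALSE))
}

#' Write merged repeat instances as a GTF annotation
#'
#' Emits one `exon` feature per interval with a `gene_id` attribute equal to
#' the RE name (plus `family_id`/`class_id` attributes when known), the form
#' consumed by meta-feature read counters. GTF coordinates are 1-based
#' closed, identical to the in-memory `GRanges` representation.
#'
#' @param instances A `GRanges` with a `name` column, e.g. from
#'   [extract_and_merge()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(instances, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  if (length(instances) == 0L) return(invisible(path))
  mc <- S4Vectors::mcols(instances)
  attr_str <- sprintf("gene_id \"%s\";", mc$name)
  if ("family" %in% names(mc)) {
    extra <- ifelse(is.na(mc$family), "",
                    sprintf(" family_id \"%s\"; class_id \"%s\";",
                            mc$family, mc$cls))
    attr_str <- paste0(attr_str, extra)
  }
  lines <- paste(as.character(GenomeInfoDb::seqnames(instances)),
                 "rmsk_adjusted", "exon",
                 BiocGenerics::start(instances),
                 BiocGenerics::end(instances),
                 ".", as.character(BiocGenerics::strand(instances)), ".",
                 attr_str, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read an adjusted-annotation GTF back into repeat instances
#'
#' @param path GTF file written by [write_gtf()] (or any GTF whose `exon`
#'   features carry `gene_id`).
#' @return A `GRanges` with `name`, `family`, `cls` columns, sorted as in
#'   [extract_and_merge()].
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  out <- GenomicRanges::granges(gr)
  out$name <- gr$gene_id
  out$family <- if (!is.null(gr$family_id)) gr$family_id else NA_character_
  out$cls <- if (!is.null(gr$class_id)) gr$class_id else NA_character_
  BiocGenerics::sort(out, ignore.strand = TRUE)
}

#' Build the RE grouping hierarchy
#'
#' Maps each RE subfamily name to one (family, class) pair, from either the
#' annotation's metadata columns or a sidecar table (columns `name`,
#' `family`, `class`). When both are given the sidecar wins on conflict.
#'
#' @param instances Optional `GRanges` with `name`/`family`/`cls` columns.
#' @param sidecar Optional data frame (or TSV path) with columns `name`,
#'   `family`, `class`.
#' @return An object of class `re_grouping`: list with `map` (data frame
#'   `name`, `family`, `cls`), `family_sizes` and `class_sizes` (named
#'   integer vectors of distinct-name counts per group).
#' @export
build_grouping <- function(instances = NULL, sidecar = NULL) {
  map <- NULL
  if (!is.null(instances)) map <- .grouping_of(instances)
  if (!is.null(sidecar)) {
    if (is.character(sidecar))
      sidecar <- utils::read.table(sidecar, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
    names(sidecar)[names(sidecar) == "class"] <- "cls"
    side <- unique(sidecar[, c("name", "family", "cls")])
    if (is.null(map)) {
      map <- side
    } else {
      keep <- map[!(map$name %in% side$name), , drop = FALSE]
      map <- rbind(side, keep)
    }
  }
  if (is.null(map)) stop("build_grouping: no grouping source given")
  map$family[is.na(map$family)] <- "Unknown"
  map$cls[is.na(map$cls)] <- "Unknown"
  map <- unique(map)
  dup <- unique(map$name[duplicated(map$name)])
  if (length(dup))
    stop("conflicting family/class assignment for name(s): ",
         paste(dup, collapse = ", "))
  map <- map[order(map$name), , drop = FALSE]
  rownames(map) <- NULL
  structure(
    list(map = map,
         family_sizes = vapply(split(map$name, map$family), length, 1L),
         class_sizes = vapply(split(map$name, map$cls), length, 1L)),
    class = "re_grouping")
}

#' @export
print.re_grouping <- function(x, ...) {
  cat("RE grouping:", nrow(x$map), "names,",
      length(x$family_sizes), "families,",
      length(x$class_sizes), "classes\n")
  invisible(x)
}

#' Write a grouping sidecar TSV (name, family, class)
#' @param grouping An `re_grouping` object or its `map` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grouping <- function(grouping, path) {
  map <- if (inherits(grouping, "re_grouping")) grouping$map else grouping
  out <- data.frame(name = map$name, family = map$family, class = map$cls)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
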