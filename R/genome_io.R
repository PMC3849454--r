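# Internal coordinate convention: 0-based half-open [start, end), BED-native.
# TSV readers for externally produced tables accept `one_based = TRUE` to
# convert 1-based inclusive coordinates on the way in.

CNA_STATES <- c("gain", "loss", "CNLOH", "neutral")
CHIP_MARKS <- c("H3K4me1", "H3K4me3", "H3K27me3", "PolII", "input", "mRNA")

#' Distance between genomic intervals
#'
#' Gap in bp between two half-open intervals on the same chromosome.
#' Overlapping or touching intervals have distance 0; intervals on different
#' chromosomes are infinitely far apart, so proximity predicates reduce to
#' `distance <= threshold`.
#'
#' @param chrom_a,start_a,end_a first interval (vectors recycle).
#' @param chrom_b,start_b,end_b second interval.
#' @return numeric vector of distances in bp (`Inf` across chromosomes).
#' @export
interval_distance <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  d <- pmax(0, pmax(start_a, start_b) - pmin(end_a, end_b))
  d[as.character(chrom_a) != as.character(chrom_b)] <- Inf
  d
}

validate_intervals <- function(start, end, chrom = NULL, what = "interval") {
  if (any(start < 0)) stop(what, ": start must be >= 0")
  if (any(end <= start)) stop(what, ": end must be > start")
  if (!is.null(chrom) && any(!nzchar(as.character(chrom))))
    stop(what, ": chrom must be non-empty")
  invisible(TRUE)
}

#' Construct a set of aligned tags for one mark/sample
#'
#' @param tags data.frame with columns `chrom`, `pos` (5' position, 0-based)
#'   and `strand`.
#' @param mark one of H3K4me1, H3K4me3, H3K27me3, PolII, input, mRNA.
#' @param sample sample label.
#' @return object of class `tag_set` with `library_size = nrow(tags)`.
#' @export
tag_set <- function(tags, mark, sample) {
  mark <- match.arg(mark, CHIP_MARKS)
  stopifnot(is.data.frame(tags), all(c("chrom", "pos", "strand") %in% names(tags)))
  if (nrow(tags) > 0 && any(tags$pos < 0)) stop("tag positions must be >= 0")
  tags <- tags[order(tags$chrom, tags$pos), c("chrom", "pos", "strand"), drop = FALSE]
  rownames(tags) <- NULL
  structure(list(mark = mark, sample = sample, tags = tags,
                 library_size = nrow(tags)),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("<tag_set> %s / %s: %d tags on %d chromosome(s)\n",
              x$mark, x$sample, x$library_size,
              length(unique(x$tags$chrom))))
  invisible(x)
}

#' Read aligned tags from a BED file
#'
#' The tag position is the 5' end of the aligned interval: `start` for
#' plus-strand rows, `end - 1` for minus-strand rows. A missing strand column
#' defaults to `+`.
#'
#' @param path BED3/BED6 file.
#' @inheritParams tag_set
#' @return a `tag_set`.
#' @export
read_tags <- function(path, mark, sample) {
  if (length(readLines(path, n = 1)) == 0)
    return(tag_set(data.frame(chrom = character(), pos = integer(),
                              strand = character()), mark, sample))
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character",
                         col.names = paste0("V", 1:6), fill = TRUE)
  if (nrow(x) == 0)
    return(tag_set(data.frame(chrom = character(), pos = integer(),
                              strand = character()), mark, sample))
  start <- as.numeric(x$V2); end <- as.numeric(x$V3)
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinates in ", path)
  if (any(start < 0)) stop("negative coordinates in ", path)
  validate_intervals(start, end, x$V1, "tag")
  strand <- x$V6
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "+"
  pos <- ifelse(strand == "+", start, end - 1)
  tag_set(data.frame(chrom = x$V1, pos = pos, strand = strand,
                     stringsAsFactors = FALSE), mark, sample)
}

#' Write a tag set as BED6
#'
#' Tags are written as 1-bp intervals at their 5' position, sorted
#' lexicographically by chromosome then position.
#'
#' @param x a `tag_set`.
#' @param path output path.
#' @export
write_tags <- function(x, path) {
  stopifnot(inherits(x, "tag_set"))
  t <- x$tags[order(x$tags$chrom, x$tags$pos), , drop = FALSE]
  out <- data.frame(t$chrom, t$pos, t$pos + 1L, ".", 0L, t$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

parse_block_list <- function(s) {
  lapply(strsplit(sub(",$", "", s), ","), as.numeric)
}

#' Read gene models from BED12
#'
#' Produces one gene model per record with the TSS derived from strand
#' (`start` for `+`, `end - 1` for `-`), exon intervals from the block
#' fields, total exon length, and the CDS bounds from thickStart/thickEnd
#' (used to split exonic sequence into UTRs and coding exons).
#'
#' @param path BED12 file.
#' @return data.frame of class `gene_models`, ordered by (chrom, start), with
#'   columns gene_id, chrom, start, end, strand, tss, exon_length_bp,
#'   thick_start, thick_end and list-columns exon_starts, exon_ends.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fld <- lengths(fields)
  bad <- which(n_fld < 12)
  if (length(bad))
    stop("malformed BED12 line ", bad[1], ": expected 12 fields, got ", n_fld[bad[1]])
  m <- do.call(rbind, fields)
  start <- as.numeric(m[, 2]); end <- as.numeric(m[, 3])
  validate_intervals(start, end, m[, 1], "gene")
  strand <- m[, 6]
  if (any(!strand %in% c("+", "-"))) stop("gene strand must be + or -")
  n_blocks <- as.integer(m[, 10])
  if (any(n_blocks < 1)) stop("zero-exon gene at line ", which(n_blocks < 1)[1])
  sizes <- parse_block_list(m[, 11])
  rel_starts <- parse_block_list(m[, 12])
  exon_starts <- exon_ends <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    if (length(sizes[[i]]) != n_blocks[i] || length(rel_starts[[i]]) != n_blocks[i])
      stop("inconsistent exon blocks at line ", i)
    es <- start[i] + rel_starts[[i]]
    ee <- es + sizes[[i]]
    if (is.unsorted(es, strictly = TRUE) || any(ee[-length(ee)] > es[-1]))
      stop("overlapping or unsorted exon blocks at line ", i)
    if (es[1] < start[i] || ee[length(ee)] > end[i])
      stop("exon blocks outside gene interval at line ", i)
    exon_starts[[i]] <- es; exon_ends[[i]] <- ee
  }
  g <- data.frame(gene_id = m[, 4], chrom = m[, 1], start = start, end = end,
                  strand = strand,
                  tss = ifelse(strand == "+", start, end - 1),
                  exon_length_bp = vapply(seq_along(sizes),
                                          function(i) sum(sizes[[i]]), 0),
                  thick_start = as.numeric(m[, 7]),
                  thick_end = as.numeric(m[, 8]),
                  stringsAsFactors = FALSE)
  g$exon_starts <- exon_starts
  g$exon_ends <- exon_ends
  g <- g[order(g$chrom, g$start, g$gene_id), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("gene_models", "data.frame")
  g
}

#' Write gene models as BED12
#'
#' @param genes a `gene_models` data.frame (see [read_gene_models()]).
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  g <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  sizes <- vapply(seq_len(nrow(g)), function(i)
    paste0(paste(format(g$exon_ends[[i]] - g$exon_starts[[i]], scientific = FALSE,
                        trim = TRUE), collapse = ","), ","), "")
  rel <- vapply(seq_len(nrow(g)), function(i)
    paste0(paste(format(g$exon_starts[[i]] - g$start[i], scientific = FALSE,
                        trim = TRUE), collapse = ","), ","), "")
  out <- data.frame(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand,
                    g$thick_start, g$thick_end, "0,0,0",
                    lengths(g$exon_starts), sizes, rel)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read copy-number segments from TSV
#'
#' Expects a header with columns `chrom`, `start`, `end`, `state`; states must
#' be gain, loss, CNLOH or neutral.
#'
#' @param path TSV file.
#' @param one_based set TRUE when the file carries 1-based inclusive
#'   coordinates; they are converted to 0-based half-open.
#' @return data.frame with columns chrom, start, end, state.
#' @export
read_cna_segments <- function(path, one_based = FALSE) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(x)))
  if (one_based) x$start <- x$start - 1
  if (any(!x$state %in% CNA_STATES))
    stop("unknown CNA state: ", paste(setdiff(x$state, CNA_STATES), collapse = ", "))
  validate_intervals(x$start, x$end, x$chrom, "CNA segment")
  x <- x[order(x$chrom, x$start), c("chrom", "start", "end", "state")]
  rownames(x) <- NULL
  x
}

#' Write copy-number segments as TSV
#' @param segments data.frame chrom/start/end/state.
#' @param path output path.
#' @export
write_cna_segments <- function(segments, path) {
  s <- segments[order(segments$chrom, segments$start),
                c("chrom", "start", "end", "state")]
  utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-level count table
#'
#' @param path TSV with header: `gene_id` then one column per sample.
#' @return data.frame, gene_id first.
#' @export
read_count_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(names(x)[1] == "gene_id")
  x
}

#' Read a qPCR Cq table
#'
#' Long format with header columns `sample`, `group`, `assay`, `replicate`,
#' `cq`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_cq_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group", "assay", "replicate", "cq") %in% names(x)))
  x
}

#' Write a generic table with deterministic ordering
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write islands as BED6+ (extra columns: counts, fold, p, fdr)
#' @param islands island or differential-island data.frame.
#' @param path output path.
#' @export
write_islands <- function(islands, path) {
  if (nrow(islands) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  isl <- islands[order(islands$chrom, islands$start), , drop = FALSE]
  extra <- setdiff(names(isl), c("chrom", "start", "end"))
  out <- cbind(isl[c("chrom", "start", "end")],
               name = sprintf("island_%05d", seq_len(nrow(isl))),
               score = 0L, strand = ".",
               isl[extra])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# midpoint of half-open intervals, used by every "assign by midpoint" rule
interval_midpoint <- function(start, end) floor((start + end) / 2)
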