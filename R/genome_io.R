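# Readers/writers for the standard interval formats plus interval
# arithmetic.  Internal coordinates are 1-based fully-closed throughout the
# package (the convention under which the printed dac PRE2 interval
# chr2L:16,485,929-16,486,572 has length 644 bp); on-disk BED/bedGraph/BEDPE
# stay 0-based half-open with exact conversion at the read/write boundary.

#' Read a UCSC chrom.sizes file
#'
#' @param path Path to a two-column whitespace-separated text file
#'   (chromosome name, length in bp).
#' @return A named numeric vector of chromosome lengths with class
#'   \code{"ChromSizes"}. Order follows the file.
#' @examples
#' f <- tempfile()
#' writeLines("chr2L\t23513712", f)
#' read_chromsizes(f)
#' @export
read_chromsizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(chrom_sizes(numeric(0)))
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    stop("malformed chrom.sizes line ", bad[1], ": ", lines[bad[1]])
  nm <- vapply(parts, `[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(len))
    stop("malformed chrom.sizes line ", which(is.na(len))[1], ": non-numeric length")
  chrom_sizes(setNames(len, nm))
}

#' Construct a ChromSizes object
#'
#' @param sizes Named numeric vector of chromosome lengths (bp).
#' @return The validated vector with class \code{"ChromSizes"}.
#' @export
chrom_sizes <- function(sizes) {
  sizes <- unlist(sizes)
  if (length(sizes)) {
    if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
      stop("chromosome names required")
    if (anyDuplicated(names(sizes)))
      stop("duplicate chromosome names: ",
           paste(unique(names(sizes)[duplicated(names(sizes))]), collapse = ", "))
    if (any(!is.finite(sizes)) || any(sizes <= 0))
      stop("chromosome lengths must be positive")
  }
  structure(setNames(as.numeric(sizes), names(sizes)), class = "ChromSizes")
}

#' @export
print.ChromSizes <- function(x, ...) {
  cat("ChromSizes with", length(x), "chromosome(s)\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Construct genomic intervals (1-based, fully closed)
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer start/end positions, 1-based and inclusive.
#' @param chromsizes Optional \code{ChromSizes} used to validate bounds.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end}.
#' @export
gintervals <- function(chrom, start, end, chromsizes = NULL) {
  iv <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (any(iv$start < 1)) stop("interval start must be >= 1")
  if (any(iv$end < iv$start)) stop("interval start must be <= end")
  if (!is.null(chromsizes)) {
    unknown <- setdiff(iv$chrom, names(chromsizes))
    if (length(unknown)) stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    if (any(iv$end > chromsizes[iv$chrom]))
      stop("interval end exceeds chromosome length")
  }
  iv
}

#' Length of genomic intervals
#'
#' Under the fully-closed convention an interval chr:100-100 spans one base.
#'
#' @param iv Interval data.frame (\code{chrom}, \code{start}, \code{end}).
#' @return Numeric vector of lengths in bp (\code{end - start + 1}).
#' @export
interval_length <- function(iv) {
  iv$end - iv$start + 1
}

# Internal: intervals -> GRanges (coordinates are already 1-based closed,
# which is the GRanges native convention).
.as_granges <- function(iv) {
  GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start, iv$end))
}

#' Read a BED or bedGraph file as internal intervals
#'
#' On-disk coordinates (0-based half-open) are converted to the internal
#' 1-based fully-closed convention; \code{\link{write_intervals}} inverts the
#' conversion exactly.
#'
#' @param path File path.
#' @param format \code{"auto"} (by extension), \code{"bed"} or
#'   \code{"bedGraph"}.
#' @return Interval data.frame; bedGraph input adds a \code{value} column,
#'   BED name/score columns are kept when present.
#' @export
read_intervals <- function(path, format = c("auto", "bed", "bedGraph")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
      "bedGraph" else "bed"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "bedGraph")
  iv <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (format == "bedGraph") {
    iv$value <- md$score
    o <- order(iv$chrom, iv$start)
    ivo <- iv[o, ]
    ov <- unlist(lapply(split(seq_len(nrow(ivo)), ivo$chrom), function(k) {
      if (length(k) > 1 && any(ivo$start[k][-1] <= ivo$end[k][-length(k)])) TRUE else FALSE
    }))
    if (any(ov)) warning("overlapping bedGraph intervals")
  } else if (ncol(md)) {
    iv <- cbind(iv, md)
  }
  iv
}

#' Write intervals as BED or bedGraph
#'
#' @param iv Interval data.frame in internal coordinates.
#' @param path Output path.
#' @param format \code{"bed"} or \code{"bedGraph"} (default chosen by the
#'   presence of a \code{value} column).
#' @export
write_intervals <- function(iv, path, format = NULL) {
  if (is.null(format)) format <- if ("value" %in% names(iv)) "bedGraph" else "bed"
  out <- data.frame(chrom = iv$chrom, start = format(iv$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(iv$end, scientific = FALSE, trim = TRUE))
  if (format == "bedGraph") {
    out$value <- iv$value
  } else {
    if ("name" %in% names(iv)) {
      out$name <- iv$name
      out$score <- if ("score" %in% names(iv)) iv$score else 0
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# canonical anchor ordering: anchor1 upstream of anchor2 for cis records
.canonicalize_loops <- function(lp) {
  swap <- lp$chrom1 == lp$chrom2 &
    (lp$start2 < lp$start1 | (lp$start2 == lp$start1 & lp$end2 < lp$end1))
  if (any(swap)) {
    tmp <- lp[swap, c("start1", "end1")]
    lp[swap, c("start1", "end1")] <- lp[swap, c("start2", "end2")]
    lp[swap, c("start2", "end2")] <- tmp
  }
  lp
}

#' Read loops from a BEDPE file
#'
#' The first six columns are the two anchors (0-based half-open on disk,
#' converted to the internal convention); extra columns are preserved.
#' Anchors of cis records are reordered so anchor1 is upstream. Trans
#' records are kept but flagged in the \code{trans} column.
#'
#' @param path BEDPE file path.
#' @return Loop data.frame with columns \code{chrom1,start1,end1,chrom2,
#'   start2,end2,trans} plus any extra BEDPE columns.
#' @export
read_loops <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 6) stop("BEDPE requires at least 6 columns")
  extra_names <- c("name", "score", "strand1", "strand2")
  nm <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  n_extra <- ncol(df) - 6
  if (n_extra > 0) {
    en <- extra_names[seq_len(min(n_extra, 4))]
    if (n_extra > 4) en <- c(en, paste0("attr", seq_len(n_extra - 4)))
    nm <- c(nm, en)
  }
  names(df) <- nm
  df$start1 <- df$start1 + 1
  df$start2 <- df$start2 + 1
  df$trans <- df$chrom1 != df$chrom2
  .canonicalize_loops(df)
}

#' Write loops as BEDPE
#'
#' @param loops Loop data.frame in internal coordinates.
#' @param path Output path.
#' @export
write_loops <- function(loops, path) {
  core <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  extra <- setdiff(names(loops), c(core, "trans"))
  out <- loops[, core]
  out$start1 <- format(out$start1 - 1, scientific = FALSE, trim = TRUE)
  out$start2 <- format(out$start2 - 1, scientific = FALSE, trim = TRUE)
  out$end1 <- format(out$end1, scientific = FALSE, trim = TRUE)
  out$end2 <- format(out$end2, scientific = FALSE, trim = TRUE)
  if (length(extra)) out <- cbind(out, loops[, extra, drop = FALSE])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Classify loops by peak overlap at their anchors
#'
#' A loop falls in class \code{both_anchors} iff each anchor overlaps at
#' least one peak by >= 1 bp, \code{one_anchor} if exactly one does, and
#' \code{none} otherwise.
#'
#' @param loops Loop data.frame.
#' @param peaks Interval data.frame of peaks.
#' @return Character vector of classes, one per loop, with a \code{counts}
#'   attribute tabulating the three classes.
#' @export
interval_overlap_class <- function(loops, peaks) {
  n <- nrow(loops)
  if (n == 0L) return(structure(character(0), counts = c(both_anchors = 0L, one_anchor = 0L, none = 0L)))
  if (is.null(peaks) || nrow(peaks) == 0L) {
    cls <- rep("none", n)
  } else {
    pk <- .as_granges(peaks)
    a1 <- GenomicRanges::GRanges(loops$chrom1, IRanges::IRanges(loops$start1, loops$end1))
    a2 <- GenomicRanges::GRanges(loops$chrom2, IRanges::IRanges(loops$start2, loops$end2))
    h1 <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(a1, pk)))
    h2 <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(a2, pk)))
    n_hit <- (seq_len(n) %in% h1) + (seq_len(n) %in% h2)
    cls <- c("none", "one_anchor", "both_anchors")[n_hit + 1L]
  }
  counts <- c(both_anchors = sum(cls == "both_anchors"),
              one_anchor = sum(cls == "one_anchor"),
              none = sum(cls == "none"))
  structure(cls, counts = counts)
}

#' Pericentromeric regions of the dm6 assembly
#'
#' The six low-mappability regions masked during loop calling.
#'
#' @return Interval data.frame with six rows.
#' @export
pericentromeric_dm6 <- function() {
  gintervals(
    chrom = c("chr2L", "chr2R", "chr3L", "chr3R", "chrX", "chrX"),
    start = c(22113700, 1, 22933988, 1, 21572709, 22929901),
    end   = c(23513712, 5756000, 28110227, 4027467, 22396687, 23542271))
}

#' Remove records overlapping masked regions
#'
#' Any record (interval or loop) with either anchor overlapping one of the
#' masked regions by >= 1 bp is removed.
#'
#' @param records Interval data.frame (\code{chrom,start,end}) or loop
#'   data.frame (\code{chrom1,...,end2}).
#' @param regions Interval data.frame of regions to mask; defaults to
#'   \code{\link{pericentromeric_dm6}()}.
#' @return The kept records; removed records are attached as the
#'   \code{removed} attribute and their count as \code{n_removed}.
#' @export
mask_pericentromeric <- function(records, regions = pericentromeric_dm6()) {
  if (nrow(records) == 0L)
    return(structure(records, removed = records, n_removed = 0L))
  rg <- .as_granges(regions)
  # records on chromosomes absent from the mask produce a harmless
  # disjoint-seqlevels warning
  if (all(c("chrom1", "chrom2") %in% names(records))) {
    a1 <- GenomicRanges::GRanges(records$chrom1, IRanges::IRanges(records$start1, records$end1))
    a2 <- GenomicRanges::GRanges(records$chrom2, IRanges::IRanges(records$start2, records$end2))
    hit <- seq_len(nrow(records)) %in%
      suppressWarnings(
        c(S4Vectors::queryHits(GenomicRanges::findOverlaps(a1, rg)),
          S4Vectors::queryHits(GenomicRanges::findOverlaps(a2, rg))))
  } else {
    hit <- seq_len(nrow(records)) %in%
      suppressWarnings(
        S4Vectors::queryHits(GenomicRanges::findOverlaps(.as_granges(records), rg)))
  }
  kept <- records[!hit, , drop = FALSE]
  structure(kept, removed = records[hit, , drop = FALSE], n_removed = sum(hit))
}

#' Named anchor-window presets for PRE loop quantification
#'
#' Printed coordinate pairs for quantifying contacts between PRE-containing
#' windows: \code{dac_pre} (the dac PRE1/PRE2 windows on chr2L) and
#' \code{net_pre} (the NetA/NetB PRE windows on chrX). Coordinates are kept
#' verbatim; note their lengths are 6002/6001 bp (dac) and 9002/6001 bp
#' (net), not exactly 6 kb.
#'
#' @return Named list; each element has single-row interval data.frames
#'   \code{window1} and \code{window2}.
#' @export
anchor_presets <- function() {
  list(
    dac_pre = list(
      window1 = gintervals("chr2L", 16419514, 16425515),
      window2 = gintervals("chr2L", 16482929, 16488930)),
    net_pre = list(
      window1 = gintervals("chrX", 14650251, 14659252),
      window2 = gintervals("chrX", 14748251, 14754251)))
}
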