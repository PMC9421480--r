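#' Genomic intervals
#'
#' All coordinates inside the package are 0-based, half-open
#' (`[start, end)`), BED-style.  GTF/GFF 1-based inclusive coordinates are
#' converted at the I/O boundary and converted back on export.  Strand is
#' one of `"+"`, `"-"`, `"."`; `"."` means "unknown" and matches either
#' strand in every strand-aware rule (many public RNA-seq libraries are
#' unstranded, so a hard strand requirement would discard valid loci).
#'
#' @param chrom character vector of sequence names.
#' @param start,end integer vectors; 0-based half-open.
#' @param strand character vector in `{"+", "-", "."}`, recycled.
#' @param id optional character vector of feature identifiers.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (and `id` when supplied) of class `linc_intervals`.
#' @examples
#' intervals("chr1", 100, 200, "+")
#' @export
intervals <- function(chrom, start, end, strand = ".", id = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(start, n),
    end = rep_len(end, n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(id)) df$id <- rep_len(as.character(id), n)
  validate_intervals(df)
  class(df) <- c("linc_intervals", "data.frame")
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$end <= df$start)) stop("interval end must be > start")
  bad <- !df$strand %in% c("+", "-", ".")
  if (any(bad)) stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

#' Interval width
#' @param x an intervals data.frame.
#' @return integer vector of widths (`end - start`).
#' @export
interval_width <- function(x) x$end - x$start

#' Pairwise overlap in base pairs
#'
#' Vectorized overlap length between matched rows of two interval tables
#' (0 on different chromosomes).  Strand is ignored.
#'
#' @param a,b interval data.frames, recycled to common length.
#' @return integer vector of overlap lengths in bp.
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmax(0L, pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]))
  ov[a$chrom[ai] != b$chrom[bi]] <- 0L
  as.integer(ov)
}

# Union overlap of a single target interval with a set of features,
# merging overlapping features first (IRanges reduce).
union_overlap_bp <- function(target, features) {
  stopifnot(nrow(target) == 1)
  f <- features[features$chrom == target$chrom, , drop = FALSE]
  if (nrow(f) == 0) return(0L)
  r <- IRanges::reduce(IRanges::IRanges(start = f$start + 1L, end = f$end))
  t <- IRanges::IRanges(start = target$start + 1L, end = target$end)
  sum(IRanges::width(IRanges::intersect(r, t)))
}

# TRUE where strands are compatible; "." matches either strand.
strand_compatible <- function(a, b) {
  a == "." | b == "." | a == b
}

# internal -> GFF-style 1-based inclusive
to_gff_coords <- function(start, end) {
  list(start = start + 1L, end = end)
}

# GFF-style 1-based inclusive -> internal
from_gff_coords <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}
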