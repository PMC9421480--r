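#' Annotation sets
#'
#' An annotation set bundles transcript models (exon structures) with named
#' collections of genomic features (transposable elements, small-RNA loci,
#' covariance-model hits, conserved noncoding sequences, protein-protected
#' sites, ...).  Exons per transcript must share one chromosome and strand,
#' be sorted, and be non-overlapping.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (0-based half-open), and optionally `source`
#'   (one of `"ONT"`, `"SHORT_READ"`, `"REFERENCE"`) and `biotype`.
#' @param features named list of interval data.frames (see [intervals()]).
#' @return An object of class `annotation_set` with elements `tx` (one row
#'   per transcript: id, gene_id, chrom, strand, start, end, n_exons,
#'   length, source, biotype), `exons`, and `features`.
#' @export
annotation_set <- function(exons = NULL, features = list()) {
  if (is.null(exons) || nrow(exons) == 0) {
    exons <- data.frame(
      transcript_id = character(), gene_id = character(),
      chrom = character(), start = integer(), end = integer(),
      strand = character(), source = character(), biotype = character(),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(exons$source)) exons$source <- "SHORT_READ"
  if (is.null(exons$biotype)) exons$biotype <- "other"
  validate_intervals(exons)
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (ix in sp) {
    e <- exons[ix, , drop = FALSE]
    if (length(unique(e$chrom)) > 1)
      stop("transcript ", e$transcript_id[1], ": exons on multiple chromosomes")
    if (length(unique(e$strand)) > 1)
      stop("transcript ", e$transcript_id[1], ": exons on mixed strands")
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("transcript ", e$transcript_id[1], ": overlapping exons")
  }

  tx <- do.call(rbind, lapply(sp, function(ix) {
    e <- exons[ix, , drop = FALSE]
    data.frame(
      id = e$transcript_id[1], gene_id = e$gene_id[1],
      chrom = e$chrom[1], strand = e$strand[1],
      start = min(e$start), end = max(e$end),
      n_exons = nrow(e), length = sum(e$end - e$start),
      source = e$source[1], biotype = e$biotype[1],
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(tx)) {
    tx <- data.frame(
      id = character(), gene_id = character(), chrom = character(),
      strand = character(), start = integer(), end = integer(),
      n_exons = integer(), length = integer(), source = character(),
      biotype = character(), stringsAsFactors = FALSE
    )
  }
  rownames(tx) <- NULL
  for (nm in names(features)) {
    f <- features[[nm]]
    validate_intervals(f)
    if (!is.null(f$id) && anyDuplicated(f$id))
      stop("duplicated feature ids in '", nm, "'")
  }
  structure(list(tx = tx, exons = exons, features = features),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$tx), "transcripts,",
      length(x$features), "feature tracks\n")
  invisible(x)
}

# cheap line-level validation so parse failures name the offending line
check_tabular_lines <- function(path, min_fields, numeric_fields,
                                comment = "#") {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, comment)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < min_fields)
      stop(sprintf("%s: line %d: expected >= %d tab-separated fields, got %d",
                   basename(path), i, min_fields, length(f)))
    for (j in numeric_fields) {
      if (is.na(suppressWarnings(as.numeric(f[j]))))
        stop(sprintf("%s: line %d: field %d ('%s') is not numeric",
                     basename(path), i, j, f[j]))
    }
  }
  invisible(TRUE)
}

#' Read a genome annotation into an annotation set
#'
#' GTF/GFF3 files (1-based inclusive) are converted to the internal 0-based
#' half-open convention; BED files pass through unchanged.  BED6 files
#' become a named feature track; BED12 files become transcript models with
#' one exon per block.
#'
#' @param path file path.
#' @param format one of `"GTF"`, `"GFF3"`, `"BED"`, `"BED12"`.
#' @param feature_name track name for BED6 features (default `"features"`).
#' @return An [annotation_set()].
#' @export
read_annotation <- function(path, format = c("GTF", "GFF3", "BED", "BED12"),
                            feature_name = "features") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format %in% c("GTF", "GFF3")) {
    check_tabular_lines(path, min_fields = 9, numeric_fields = c(4, 5))
    gr <- rtracklayer::import(path, format = tolower(format))
    df <- as.data.frame(gr)
    ex <- df[df$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0) stop("no exon records in ", path)
    if (format == "GTF") {
      tx_id <- ex$transcript_id
      gene_id <- ex$gene_id
      biot <- if (!is.null(ex$transcript_biotype)) ex$transcript_biotype else "other"
    } else {
      parent <- vapply(ex$Parent, function(p) as.character(p)[1], character(1))
      tx_id <- parent
      parents <- df[df$ID %in% unique(parent) & !is.na(df$ID), , drop = FALSE]
      g_of <- stats::setNames(
        vapply(seq_len(nrow(parents)), function(i) {
          p <- parents$Parent[[i]]
          if (length(p) == 0) NA_character_ else as.character(p)[1]
        }, character(1)),
        parents$ID
      )
      b_of <- stats::setNames(as.character(parents$type), parents$ID)
      gene_id <- ifelse(is.na(g_of[tx_id]), tx_id, g_of[tx_id])
      biot <- unname(b_of[tx_id])
      biot[is.na(biot)] <- "other"
    }
    biot <- map_biotype(biot)
    src <- if (!is.null(ex$source)) map_source(as.character(ex$source)) else "SHORT_READ"
    cc <- from_gff_coords(ex$start, ex$end)
    exons <- data.frame(
      transcript_id = tx_id, gene_id = gene_id,
      chrom = as.character(ex$seqnames), start = cc$start, end = cc$end,
      strand = chartr("*", ".", as.character(ex$strand)),
      source = src, biotype = biot, stringsAsFactors = FALSE
    )
    return(annotation_set(exons))
  }
  if (format == "BED") {
    check_tabular_lines(path, min_fields = 3, numeric_fields = c(2, 3))
    gr <- rtracklayer::import(path, format = "bed")
    f <- intervals(
      as.character(GenomicRanges::seqnames(gr)),
      GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
      chartr("*", ".", as.character(GenomicRanges::strand(gr))),
      id = if (!is.null(gr$name)) gr$name else
        paste0(feature_name, "_", seq_along(gr))
    )
    return(annotation_set(features = stats::setNames(list(f), feature_name)))
  }
  # BED12: one transcript per line, exons from blocks
  check_tabular_lines(path, min_fields = 12, numeric_fields = c(2, 3))
  gr <- rtracklayer::import(path, format = "bed")
  rows <- lapply(seq_along(gr), function(i) {
    bl <- gr$blocks[[i]]
    data.frame(
      transcript_id = gr$name[i], gene_id = gr$name[i],
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      start = GenomicRanges::start(gr)[i] - 1L + IRanges::start(bl) - 1L,
      end = GenomicRanges::start(gr)[i] - 1L + IRanges::end(bl),
      strand = chartr("*", ".", as.character(GenomicRanges::strand(gr))[i]),
      stringsAsFactors = FALSE
    )
  })
  annotation_set(do.call(rbind, rows))
}

map_biotype <- function(x) {
  out <- rep("other", length(x))
  out[x %in% c("mRNA", "protein_coding")] <- "mRNA"
  out[x %in% c("lincRNA_candidate", "lincRNA")] <- "lincRNA_candidate"
  out[x == "lnc_RNA"] <- "lnc_RNA"
  out[x %in% c("ncRNA", "noncoding_rna")] <- "ncRNA"
  out[x %in% c("NTR", "novel_transcribed_region")] <- "NTR"
  out
}

map_source <- function(x) {
  out <- rep("SHORT_READ", length(x))
  out[grepl("ont|nanopore", x, ignore.case = TRUE)] <- "ONT"
  out[grepl("araport|reference|tair", x, ignore.case = TRUE)] <- "REFERENCE"
  out
}

#' Expression matrices with sample metadata
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples
#'   in columns.
#' @param samples data.frame with columns `sample`, `tissue`, `bioproject`,
#'   `condition` (optional `replicate`); one row per matrix column.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, samples) {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene ids (rownames) must be present and unique")
  if (anyNA(values)) stop("expression matrix contains missing values")
  need <- c("sample", "tissue", "bioproject", "condition")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample metadata lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!setequal(colnames(values), samples$sample) ||
      ncol(values) != nrow(samples))
    stop("matrix columns and metadata samples do not match")
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples (",
      length(unique(x$samples$tissue)), "tissues,",
      length(unique(x$samples$bioproject)), "bioprojects )\n")
  invisible(x)
}

#' Read an expression matrix plus sample metadata
#'
#' @param path TSV with header; first column gene id, remaining columns one
#'   per sample.  Missing values are an error: an absent gene is not zero.
#' @param metadata_path TSV with header; columns `sample`, `tissue`,
#'   `bioproject`, `condition`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1]])) stop("duplicated gene id in ", path)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab[[1]]
  unknown <- setdiff(colnames(vals), meta$sample)
  if (length(unknown))
    stop("samples missing from metadata: ", paste(unknown, collapse = ", "))
  expression_matrix(vals, meta[meta$sample %in% colnames(vals), , drop = FALSE])
}

outfmt6_cols <- c("query", "subject", "pident", "length", "mismatches",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read a 12-column tabular homology hit table
#'
#' The standard tabular alignment format (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore) uses 1-based
#' inclusive coordinates, with `sstart > send` encoding a minus-strand hit.
#' Coordinates are normalized to the internal 0-based half-open convention
#' and the subject strand is made explicit.
#'
#' @param path file path (no header).
#' @return data.frame with the 12 standard columns plus `q_start`, `q_end`,
#'   `s_start`, `s_end` (internal convention) and `s_strand`.
#' @export
read_hits <- function(path) {
  check_tabular_lines(path, min_fields = 12,
                      numeric_fields = c(3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
                      comment = "#")
  h <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(h) < 12) stop("expected 12 columns in ", path)
  h <- h[, 1:12]
  names(h) <- outfmt6_cols
  h$q_start <- as.integer(h$qstart) - 1L
  h$q_end <- as.integer(h$qend)
  minus <- h$sstart > h$send
  h$s_strand <- ifelse(minus, "-", "+")
  h$s_start <- as.integer(ifelse(minus, h$send, h$sstart)) - 1L
  h$s_end <- as.integer(ifelse(minus, h$sstart, h$send))
  h
}

#' Write / read the merged per-lincRNA annotation table
#'
#' Deterministic column order, rows sorted by (chrom, start, id); a
#' write-then-read round trip reproduces the input exactly.
#'
#' @param records data.frame of merged lincRNA records; must contain
#'   `id`, `chrom`, `start`.
#' @param path output TSV path.
#' @return `write_linc_table` invisibly returns the sorted records;
#'   `read_linc_table` returns the records data.frame.
#' @export
write_linc_table <- function(records, path) {
  stopifnot(all(c("id", "chrom", "start") %in% names(records)))
  first <- intersect(c("id", "chrom", "start", "end", "strand"),
                     names(records))
  rest <- sort(setdiff(names(records), first))
  records <- records[order(records$chrom, records$start, records$id),
                     c(first, rest), drop = FALSE]
  rownames(records) <- NULL
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#types\t", paste(
    vapply(records, function(col) class(col)[1], character(1)),
    collapse = "\t")), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(records)
}

#' @rdname write_linc_table
#' @export
read_linc_table <- function(path) {
  hdr <- readLines(path, n = 1)
  types <- strsplit(sub("^#types\t", "", hdr), "\t", fixed = TRUE)[[1]]
  tab <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE,
                           colClasses = types, check.names = FALSE)
  tab
}
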