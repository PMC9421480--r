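#' Multiple-sequence-alignment families
#'
#' One family = the query lincRNA plus its sequence homologs, aligned.
#' Rows are keyed by species; the ungapped query row must equal the
#' lincRNA sequence.
#'
#' @param aln named character vector of aligned sequences (gap `-`), or a
#'   path to an aligned FASTA whose ids are `"species|locus"`.
#' @param query species name of the query row.
#' @return list of class `msa_family`: `aln`, `query`, `query_cols`
#'   (alignment column of each ungapped query position).
#' @export
msa_family <- function(aln, query) {
  if (length(aln) == 1 && file.exists(aln[1])) {
    ss <- Biostrings::readBStringSet(aln[1])
    nm <- sub("\\|.*$", "", names(ss))
    aln <- stats::setNames(as.character(ss), nm)
  }
  if (is.null(names(aln))) stop("alignment rows must be named by species")
  if (!query %in% names(aln)) stop("query row absent: ", query)
  if (length(unique(nchar(aln))) != 1) stop("aligned rows differ in length")
  aln <- toupper(aln)
  qc <- which(strsplit(aln[[query]], "", fixed = TRUE)[[1]] != "-")
  structure(list(aln = aln, query = query, query_cols = qc),
            class = "msa_family")
}

aln_chars <- function(msa, species) {
  strsplit(msa$aln[[species]], "", fixed = TRUE)[[1]]
}

# alignment columns covering query positions [start, end) (0-based,
# ungapped query coordinates)
query_interval_cols <- function(msa, start, end) {
  if (start < 0 || end > length(msa$query_cols) || end <= start)
    stop("motif interval outside the query sequence")
  msa$query_cols[(start + 1):end]
}

# ungapped position (0-based) in `species` of an alignment column,
# counting residues at or before the column; NA if none
col_to_ungapped <- function(msa, species, col) {
  ch <- aln_chars(msa, species)
  n <- sum(ch[seq_len(col)] != "-")
  if (n == 0) NA_integer_ else n - 1L
}

ungapped_seq <- function(msa, species) {
  gsub("-", "", msa$aln[[species]], fixed = TRUE)
}

#' Motif specifications
#'
#' @param kind `"SORF"`, `"MIRNA_SITE"`, or `"STRUCTURE"`.
#' @param start,end motif interval on the ungapped query, 0-based
#'   half-open nt; for an sORF this spans ATG through the stop codon.
#' @param sorf_pos_tol_aa positional tolerance for sORF start/stop
#'   (default 3 AA).
#' @param sorf_min_identity minimum pairwise peptide identity
#'   (default 0.75).
#' @param mirna_max_mismatch maximum mismatches in a miRNA-site alignment
#'   (default 2).
#' @return list of class `motif_spec`.
#' @export
motif_spec <- function(kind = c("SORF", "MIRNA_SITE", "STRUCTURE"),
                       start, end, sorf_pos_tol_aa = 3L,
                       sorf_min_identity = 0.75, mirna_max_mismatch = 2L) {
  kind <- match.arg(kind)
  stopifnot(end > start, start >= 0,
            sorf_pos_tol_aa >= 0, mirna_max_mismatch >= 0)
  structure(list(kind = kind, start = as.integer(start),
                 end = as.integer(end), sorf_pos_tol_aa = sorf_pos_tol_aa,
                 sorf_min_identity = sorf_min_identity,
                 mirna_max_mismatch = mirna_max_mismatch),
            class = "motif_spec")
}

translate_nt <- function(seq) {
  if (nchar(seq) < 3) return("")
  seq <- substr(seq, 1, 3 * (nchar(seq) %/% 3))
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     if.fuzzy.codon = "X"))
}

# identity of homolog peptide vs query peptide: position-by-position,
# denominator = query peptide length, length differences count as
# mismatches
peptide_identity <- function(query_pep, hom_pep) {
  qn <- nchar(query_pep)
  if (qn == 0) return(0)
  q <- strsplit(query_pep, "", fixed = TRUE)[[1]]
  h <- strsplit(hom_pep, "", fixed = TRUE)[[1]]
  k <- min(length(q), length(h))
  matches <- if (k > 0) sum(q[seq_len(k)] == h[seq_len(k)]) else 0
  matches / qn
}

#' Small-ORF conservation on an alignment
#'
#' A homolog conserves the query sORF when it contains an ATG and an
#' in-frame stop whose positions, projected through the alignment into
#' query amino-acid coordinates, fall within +/- `sorf_pos_tol_aa` of the
#' query start/stop, and the translated peptide is at least
#' `sorf_min_identity` identical to the query peptide (denominator =
#' query peptide length; the search is confined to the tolerance window).
#'
#' @param msa an [msa_family()].
#' @param spec a [motif_spec()] of kind `SORF`; `start`..`end` spans the
#'   query ORF including its stop codon.
#' @return named logical vector over non-query species.
#' @export
check_sorf_conservation <- function(msa, spec) {
  stopifnot(inherits(spec, "motif_spec"), spec$kind == "SORF")
  qseq <- ungapped_seq(msa, msa$query)
  orf_nt <- substr(qseq, spec$start + 1, spec$end)
  if (substr(orf_nt, 1, 3) != "ATG" ||
      !substr(orf_nt, nchar(orf_nt) - 2, nchar(orf_nt)) %in%
        c("TAA", "TAG", "TGA"))
    stop("query sORF must run ATG..stop")
  query_pep <- translate_nt(substr(orf_nt, 1, nchar(orf_nt) - 3))
  tol_nt <- spec$sorf_pos_tol_aa * 3L
  species <- setdiff(names(msa$aln), msa$query)
  # map homolog ungapped positions into query nt coordinates
  res <- vapply(species, function(sp) {
    hseq <- ungapped_seq(msa, sp)
    ch <- aln_chars(msa, sp)
    qch <- aln_chars(msa, msa$query)
    hpos <- cumsum(ch != "-")      # 1-based homolog residue no. per column
    qpos <- cumsum(qch != "-")     # 1-based query residue no. per column
    # query coordinate of homolog residue i (0-based)
    h2q <- function(i) {
      col <- match(i + 1L, hpos)
      if (is.na(col)) return(NA_integer_)
      if (qch[col] == "-") {
        prev <- which(qch[seq_len(col)] != "-")
        if (length(prev) == 0) return(NA_integer_)
        col <- max(prev)
      }
      qpos[col] - 1L
    }
    hn <- nchar(hseq)
    for (h0 in 0:(max(hn - 6, 0))) {
      if (substr(hseq, h0 + 1, h0 + 3) != "ATG") next
      qs <- h2q(h0)
      if (is.na(qs) || abs(qs - spec$start) > tol_nt) next
      stop_at <- NA_integer_
      if (h0 + 3 > hn - 3) next
      for (p in seq(h0 + 3, hn - 3, by = 3)) {
        if (substr(hseq, p + 1, p + 3) %in% c("TAA", "TAG", "TGA")) {
          stop_at <- p
          break
        }
      }
      if (is.na(stop_at)) next
      qe <- h2q(stop_at + 2L)
      if (is.na(qe) || abs((qe + 1L) - spec$end) > tol_nt) next
      pep <- translate_nt(substr(hseq, h0 + 1, stop_at))
      if (peptide_identity(query_pep, pep) >= spec$sorf_min_identity)
        return(TRUE)
    }
    FALSE
  }, logical(1))
  res
}

#' miRNA-site conservation on an alignment
#'
#' A site is conserved in a species when every query column of the site
#' aligns to a non-gap residue of that species (complete coverage) and
#' the number of substitutions over those columns is at most
#' `mirna_max_mismatch`.  Homolog insertions inside the site do not break
#' coverage and are not counted.
#'
#' @param msa an [msa_family()].
#' @param spec a [motif_spec()] of kind `MIRNA_SITE`.
#' @return named logical vector over non-query species.
#' @export
check_mirna_conservation <- function(msa, spec) {
  stopifnot(inherits(spec, "motif_spec"), spec$kind == "MIRNA_SITE")
  cols <- query_interval_cols(msa, spec$start, spec$end)
  qch <- aln_chars(msa, msa$query)[cols]
  species <- setdiff(names(msa$aln), msa$query)
  vapply(species, function(sp) {
    hch <- aln_chars(msa, sp)[cols]
    if (any(hch == "-")) return(FALSE)
    sum(hch != qch) <= spec$mirna_max_mismatch
  }, logical(1))
}

#' Structured/protein-bound motif conservation
#'
#' A structural motif is conserved in a species when the entire motif is
#' contained in an alignable region of that homolog: every query column
#' of the motif interval carries a non-gap character in the homolog row.
#'
#' @param msa an [msa_family()].
#' @param spec a [motif_spec()] of kind `STRUCTURE`.
#' @return named logical vector over non-query species.
#' @export
check_structure_conservation <- function(msa, spec) {
  stopifnot(inherits(spec, "motif_spec"), spec$kind == "STRUCTURE")
  cols <- query_interval_cols(msa, spec$start, spec$end)
  species <- setdiff(names(msa$aln), msa$query)
  vapply(species, function(sp) {
    all(aln_chars(msa, sp)[cols] != "-")
  }, logical(1))
}

#' Node of conservation for a motif
#'
#' The deepest node sharing at least one species in which the motif is
#' conserved: the conservation booleans are treated as pseudo-hits and
#' scored exactly like sequence homologs.
#'
#' @param conserved named logical vector (species -> conserved).
#' @param tree a [species_tree()].
#' @return integer node index (0 = conserved nowhere else).
#' @export
assign_motif_node <- function(conserved, tree) {
  assign_conservation_node(names(conserved)[conserved], tree)
}
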