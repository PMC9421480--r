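#' Filter thresholds for lincRNA identification
#'
#' Defaults follow the hierarchical filtering scheme used throughout the
#' package: a lincRNA must be longer than `min_len_nt` (200 nt), encode no
#' open reading frame of `max_orf_aa` (100 AA) or more, and not overlap any
#' annotated gene exon.  Candidates passing those definitional filters are
#' promoted to high confidence (HC) by long-read support, multi-exonic
#' structure, synteny-backed conservation, mono-exonic length
#' `> hc_mono_len_nt` (500 nt), or expression `> hc_tpm` (3 TPM) in at
#' least `hc_min_experiments` (10) experiments from distinct bioprojects.
#' Reference (pre-annotated) transcripts are re-validated with the looser
#' `harmonize_tpm` (1 TPM) expression rule.  Feature-overlap rules: a
#' transposable element or covariance-model hit must cover at least
#' `te_frac`/`rfam_frac` (50%) of the lincRNA; a conserved noncoding
#' sequence must itself be covered at least `cns_frac` (50%); small-RNA
#' loci of 21-24 nt need only `srna_min_overlap_bp` (1 bp).
#'
#' @param min_len_nt,max_orf_aa,hc_mono_len_nt,hc_tpm,hc_min_experiments
#'   definitional and confidence thresholds (see Description).
#' @param harmonize_tpm,harmonize_min_experiments expression support rule
#'   for re-validating reference annotations.
#' @param te_frac,rfam_frac,cns_frac,srna_min_overlap_bp,srna_len_range
#'   feature-overlap rules.
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_len_nt = 200L, max_orf_aa = 100L,
                              hc_mono_len_nt = 500L, hc_tpm = 3,
                              hc_min_experiments = 10L,
                              harmonize_tpm = 1,
                              harmonize_min_experiments = 10L,
                              te_frac = 0.5, rfam_frac = 0.5,
                              cns_frac = 0.5, srna_min_overlap_bp = 1L,
                              srna_len_range = c(21L, 24L)) {
  th <- list(
    min_len_nt = min_len_nt, max_orf_aa = max_orf_aa,
    hc_mono_len_nt = hc_mono_len_nt, hc_tpm = hc_tpm,
    hc_min_experiments = hc_min_experiments,
    harmonize_tpm = harmonize_tpm,
    harmonize_min_experiments = harmonize_min_experiments,
    te_frac = te_frac, rfam_frac = rfam_frac, cns_frac = cns_frac,
    srna_min_overlap_bp = srna_min_overlap_bp,
    srna_len_range = srna_len_range
  )
  num <- unlist(th[c("min_len_nt", "max_orf_aa", "hc_mono_len_nt", "hc_tpm",
                     "hc_min_experiments", "harmonize_tpm",
                     "harmonize_min_experiments", "srna_min_overlap_bp")])
  if (any(num <= 0)) stop("all thresholds must be > 0")
  frc <- unlist(th[c("te_frac", "rfam_frac", "cns_frac")])
  if (any(frc <= 0 | frc > 1)) stop("fractions must lie in (0, 1]")
  structure(th, class = "filter_thresholds")
}

#' Longest sense-strand open reading frame
#'
#' Scans the three forward frames for the longest ATG-to-stop ORF.  The
#' reported length in amino acids excludes the stop codon.  A codon
#' containing `N` can be neither a start nor a stop.  ORFs without an
#' in-frame stop codon do not count.
#'
#' @param seq a single nucleotide sequence (character, A/C/G/T/N).
#' @return list with `aa` (longest ORF length in AA; 0 when none),
#'   `start`, `end` (0-based half-open nt coordinates of the ORF including
#'   its stop codon; `NA` when none).
#' @examples
#' find_longest_orf("ATGAAATAA")$aa  # 2
#' @export
find_longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- list(aa = 0L, start = NA_integer_, end = NA_integer_)
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq.int(frame + 1, n - 2, by = 3)
    if (length(starts) == 0) next
    codons <- substring(seq, starts, starts + 2)
    has_n <- grepl("N", codons, fixed = TRUE)
    is_atg <- codons == "ATG" & !has_n
    is_stop <- codons %in% stops & !has_n
    open_from <- NA_integer_  # codon index of earliest unclosed ATG
    for (k in seq_along(codons)) {
      if (is.na(open_from) && is_atg[k]) open_from <- k
      if (!is.na(open_from) && is_stop[k]) {
        aa <- k - open_from
        if (aa > best$aa) {
          best <- list(aa = as.integer(aa),
                       start = starts[open_from] - 1L,
                       end = starts[k] + 2L)
        }
        open_from <- NA_integer_
      }
    }
  }
  best
}

#' Definitional lincRNA candidate filter
#'
#' Applies, in fixed order, the filters that define a lincRNA: minimum
#' length, intergenicity (no exonic overlap with any annotated gene on
#' either strand), maximum ORF size, and a coding-potential veto supplied
#' as a boolean.  The first failing rule is recorded.
#'
#' @param t transcript id present in `annot`.
#' @param annot an [annotation_set()] whose transcripts include `t`; all
#'   transcripts with biotype `mRNA` count as annotated genes for the
#'   intergenicity test.
#' @param seq the transcript's nucleotide sequence (spliced).
#' @param coding_flag externally supplied coding-potential call.
#' @param th a [filter_thresholds()].
#' @return list with `label` (`"REJECTED"` or `"CANDIDATE"`), `rule_fired`
#'   (`REJ_LENGTH`, `REJ_OVERLAP`, `REJ_ORF`, `REJ_CODING`, or `NONE`),
#'   and `orf_aa`.
#' @export
is_linc_candidate <- function(t, annot, seq, coding_flag = FALSE,
                              th = filter_thresholds()) {
  row <- annot$tx[annot$tx$id == t, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown transcript: ", t)
  if (is.null(seq) || !nzchar(seq)) stop("missing sequence for ", t)
  if (nchar(seq) != row$length)
    stop("sequence length does not match transcript length for ", t)
  orf <- find_longest_orf(seq)
  if (row$length <= th$min_len_nt)
    return(list(label = "REJECTED", rule_fired = "REJ_LENGTH", orf_aa = orf$aa))
  gene_ex <- annot$exons[annot$exons$biotype == "mRNA" &
                           annot$exons$transcript_id != t, , drop = FALSE]
  my_ex <- annot$exons[annot$exons$transcript_id == t, , drop = FALSE]
  if (nrow(gene_ex) > 0) {
    ov <- vapply(seq_len(nrow(my_ex)), function(i)
      union_overlap_bp(my_ex[i, , drop = FALSE], gene_ex), numeric(1))
    if (sum(ov) >= 1)
      return(list(label = "REJECTED", rule_fired = "REJ_OVERLAP",
                  orf_aa = orf$aa))
  }
  if (orf$aa >= th$max_orf_aa)
    return(list(label = "REJECTED", rule_fired = "REJ_ORF", orf_aa = orf$aa))
  if (isTRUE(coding_flag))
    return(list(label = "REJECTED", rule_fired = "REJ_CODING", orf_aa = orf$aa))
  list(label = "CANDIDATE", rule_fired = "NONE", orf_aa = orf$aa)
}

# distinct bioprojects containing >=1 experiment with expression > tpm
n_supporting_bioprojects <- function(gene, expr, tpm) {
  if (!gene %in% rownames(expr$values)) return(0L)
  v <- expr$values[gene, ]
  length(unique(expr$samples$bioproject[v > tpm]))
}

#' Hierarchical confidence assignment
#'
#' Evidence cascade, first hit wins: long-read (ONT) support; multi-exonic
#' structure; then, for mono-exonic transcripts, synteny-backed sequence
#' conservation, length above `hc_mono_len_nt` (strict), or expression
#' above `hc_tpm` in at least `hc_min_experiments` experiments each from a
#' distinct bioproject.  Transcripts matching none stay low confidence.
#'
#' @param t transcript id (must be a candidate in `annot`).
#' @param annot an [annotation_set()].
#' @param evidence list with logicals `ont_supported` and
#'   `conserved_syntenic`.
#' @param expr an [expression_matrix()] of supporting experiments (TPM).
#' @param th a [filter_thresholds()].
#' @return list with `label` (`"HC"` or `"LC"`) and `rule_fired`.
#' @export
assign_confidence <- function(t, annot, evidence = list(), expr = NULL,
                              th = filter_thresholds()) {
  row <- annot$tx[annot$tx$id == t, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown transcript: ", t)
  if (isTRUE(evidence$ont_supported) || row$source == "ONT")
    return(list(label = "HC", rule_fired = "ONT_SUPPORT"))
  if (row$n_exons >= 2)
    return(list(label = "HC", rule_fired = "MULTIEXONIC"))
  if (isTRUE(evidence$conserved_syntenic))
    return(list(label = "HC", rule_fired = "MONO_CONSERVED"))
  if (row$length > th$hc_mono_len_nt)
    return(list(label = "HC", rule_fired = "MONO_LENGTH"))
  if (!is.null(expr) &&
      n_supporting_bioprojects(t, expr, th$hc_tpm) >= th$hc_min_experiments)
    return(list(label = "HC", rule_fired = "MONO_EXPRESSION"))
  list(label = "LC", rule_fired = "NONE")
}

#' Harmonize a reference-annotated noncoding transcript
#'
#' Reference transcripts annotated as `lnc_RNA`, `ncRNA` or `NTR` (novel
#' transcribed region) are re-validated: transcripts overlapping a
#' protein-coding gene are set aside as not intergenic; NTRs additionally
#' pass through the full definitional filters; remaining transcripts need
#' expression support (`> harmonize_tpm` TPM in at least
#' `harmonize_min_experiments` distinct-bioproject experiments) to be
#' confirmed HC, and fall to `LC_REFERENCE` otherwise.
#'
#' @inheritParams assign_confidence
#' @param seq transcript sequence (required for NTRs).
#' @param coding_flag coding-potential call (used for NTRs).
#' @return one of `"HC"`, `"LC_REFERENCE"`, `"NOT_INTERGENIC"`,
#'   `"REJECTED"`.
#' @export
harmonize_reference <- function(t, annot, expr, seq = NULL,
                                coding_flag = FALSE,
                                th = filter_thresholds()) {
  row <- annot$tx[annot$tx$id == t, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown transcript: ", t)
  if (!row$biotype %in% c("lnc_RNA", "ncRNA", "NTR"))
    stop(t, " does not carry a reference noncoding biotype")
  gene_ex <- annot$exons[annot$exons$biotype == "mRNA", , drop = FALSE]
  my_ex <- annot$exons[annot$exons$transcript_id == t, , drop = FALSE]
  ov <- if (nrow(gene_ex) > 0)
    sum(vapply(seq_len(nrow(my_ex)), function(i)
      union_overlap_bp(my_ex[i, , drop = FALSE], gene_ex), numeric(1)))
  else 0
  if (ov >= 1) return("NOT_INTERGENIC")
  if (row$biotype == "NTR") {
    cand <- is_linc_candidate(t, annot, seq, coding_flag, th)
    if (cand$label == "REJECTED") return("REJECTED")
  } else if (row$length <= th$min_len_nt) {
    return("REJECTED")
  }
  if (n_supporting_bioprojects(t, expr, th$harmonize_tpm) >=
        th$harmonize_min_experiments) "HC" else "LC_REFERENCE"
}

#' Flag putative mRNA extensions using long reads
#'
#' A lincRNA is flagged as a possible unannotated mRNA extension when at
#' least one stranded long read overlaps both the lincRNA (>= 1 bp) and an
#' exon of a neighboring mRNA (>= 1 bp), with read, mRNA, and lincRNA all
#' on one strand (an unknown-strand lincRNA matches either).
#'
#' @param t lincRNA transcript id in `annot`.
#' @param long_reads an [annotation_set()] of long-read alignments (BED12),
#'   or an interval data.frame of read spans (multi-exon reads use their
#'   exon intervals).
#' @param annot [annotation_set()] containing the lincRNA and mRNAs.
#' @return logical.
#' @export
flag_mrna_extension <- function(t, long_reads, annot) {
  linc <- annot$tx[annot$tx$id == t, , drop = FALSE]
  if (nrow(linc) != 1) stop("unknown transcript: ", t)
  reads <- if (inherits(long_reads, "annotation_set")) long_reads$exons
           else long_reads
  if (is.null(reads$id) && !is.null(reads$transcript_id))
    reads$id <- reads$transcript_id
  mr_ex <- annot$exons[annot$exons$biotype == "mRNA", , drop = FALSE]
  if (nrow(reads) == 0 || nrow(mr_ex) == 0) return(FALSE)
  for (rid in unique(reads$id)) {
    r <- reads[reads$id == rid, , drop = FALSE]
    rs <- r$strand[1]
    if (rs == ".") next  # long reads must be stranded
    if (!strand_compatible(rs, linc$strand)) next
    hit_linc <- any(overlap_bp(
      r, linc[rep(1, nrow(r)), c("chrom", "start", "end", "strand")]) > 0)
    if (!hit_linc) next
    same_strand_ex <- mr_ex[mr_ex$strand == rs, , drop = FALSE]
    if (nrow(same_strand_ex) == 0) next
    for (i in seq_len(nrow(r))) {
      if (any(overlap_bp(same_strand_ex,
                         r[rep(i, nrow(same_strand_ex)), , drop = FALSE]) > 0))
        return(TRUE)
    }
  }
  FALSE
}

#' Fractional feature overlap call
#'
#' Three modes cover the feature-annotation rules: `FRAC_OF_LINC` (union
#' of overlapping features must cover at least `threshold` of the lincRNA;
#' used for transposable elements and covariance-model hits),
#' `FRAC_OF_FEATURE` (some single feature must itself be covered at least
#' `threshold`; used for conserved noncoding sequences), and `MIN_BP`
#' (at least `threshold` bp with any feature whose length falls in
#' `len_range`; used for 21-24 nt small-RNA loci).  Strand is ignored.
#'
#' @param linc single-row interval data.frame (the lincRNA locus).
#' @param features interval data.frame of one feature class.
#' @param mode one of `"FRAC_OF_LINC"`, `"FRAC_OF_FEATURE"`, `"MIN_BP"`.
#' @param threshold fraction (fractional modes) or bp (`MIN_BP`).
#' @param len_range optional feature-length filter `c(min, max)`.
#' @return list with `hit` (logical), `best_feature` (id of the feature
#'   with the largest overlap, or `NA`), and `value` (the union fraction
#'   or overlap bp that was compared to `threshold`).
#' @export
annotate_fractional_overlap <- function(linc, features,
                                        mode = c("FRAC_OF_LINC",
                                                 "FRAC_OF_FEATURE",
                                                 "MIN_BP"),
                                        threshold = 0.5, len_range = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(linc) == 1)
  if (!is.null(len_range)) {
    w <- interval_width(features)
    features <- features[w >= len_range[1] & w <= len_range[2], , drop = FALSE]
  }
  if (nrow(features) == 0)
    return(list(hit = FALSE, best_feature = NA_character_, value = 0))
  per_feat <- overlap_bp(features, linc[rep(1, nrow(features)), , drop = FALSE])
  ids <- if (!is.null(features$id)) features$id else as.character(seq_len(nrow(features)))
  best <- if (any(per_feat > 0)) ids[which.max(per_feat)] else NA_character_
  if (mode == "FRAC_OF_LINC") {
    frac <- union_overlap_bp(linc, features) / interval_width(linc)
    return(list(hit = frac >= threshold, best_feature = best, value = frac))
  }
  if (mode == "FRAC_OF_FEATURE") {
    fracs <- per_feat / interval_width(features)
    hit <- any(fracs >= threshold)
    best <- if (any(fracs > 0)) ids[which.max(fracs)] else NA_character_
    return(list(hit = hit, best_feature = best, value = max(fracs)))
  }
  bp <- max(per_feat)
  list(hit = bp >= threshold, best_feature = best, value = bp)
}

#' Classify a whole transcript set
#'
#' Convenience wrapper: runs [is_linc_candidate()] and, for surviving
#' candidates, [assign_confidence()] over every transcript with biotype
#' `lincRNA_candidate` in `annot`.
#'
#' @param annot an [annotation_set()].
#' @param seqs named character vector of spliced transcript sequences.
#' @param coding_flags named logical vector (default all `FALSE`).
#' @param evidence data.frame with columns `id`, `ont_supported`,
#'   `conserved_syntenic` (missing ids default to `FALSE`).
#' @param expr optional [expression_matrix()] of supporting experiments.
#' @param th a [filter_thresholds()].
#' @return data.frame: `id`, `label` (`HC`/`LC`/`REJECTED`), `rule_fired`,
#'   `orf_aa`.
#' @export
classify_transcripts <- function(annot, seqs, coding_flags = NULL,
                                 evidence = NULL, expr = NULL,
                                 th = filter_thresholds()) {
  ids <- annot$tx$id[annot$tx$biotype == "lincRNA_candidate"]
  out <- lapply(ids, function(t) {
    cf <- if (!is.null(coding_flags) && t %in% names(coding_flags))
      coding_flags[[t]] else FALSE
    cand <- is_linc_candidate(t, annot, seqs[[t]], cf, th)
    if (cand$label == "REJECTED")
      return(data.frame(id = t, label = "REJECTED",
                        rule_fired = cand$rule_fired, orf_aa = cand$orf_aa,
                        stringsAsFactors = FALSE))
    ev <- list(ont_supported = FALSE, conserved_syntenic = FALSE)
    if (!is.null(evidence) && t %in% evidence$id) {
      r <- evidence[evidence$id == t, , drop = FALSE]
      ev$ont_supported <- isTRUE(r$ont_supported[1])
      ev$conserved_syntenic <- isTRUE(r$conserved_syntenic[1])
    }
    conf <- assign_confidence(t, annot, ev, expr, th)
    data.frame(id = t, label = conf$label, rule_fired = conf$rule_fired,
               orf_aa = cand$orf_aa, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(id = character(), label = character(),
                      rule_fired = character(), orf_aa = integer(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
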