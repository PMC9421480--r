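test_that("longest-ORF scanner matches simple cases and N handling", {
  expect_equal(find_longest_orf("ATGAAATAA")$aa, 2L)
  expect_equal(find_longest_orf("CCCCCCCCC")$aa, 0L)
  # ATG with no in-frame stop does not count
  expect_equal(find_longest_orf("ATGAAAAAA")$aa, 0L)
  # N inside the start codon disqualifies it
  expect_equal(find_longest_orf("ATNAAATAA")$aa, 0L)
  # N inside an internal codon is tolerated
  expect_equal(find_longest_orf("ATGANATAA")$aa, 2L)
})

test_that("longest-ORF scanner equals exhaustive enumeration on random sequences", {
  brute <- function(seq) {
    n <- nchar(seq)
    best <- 0L
    for (s in 1:max(n - 5, 1)) {
      if (substr(seq, s, s + 2) != "ATG") next
      p <- s + 3
      while (p + 2 <= n) {
        if (substr(seq, p, p + 2) %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, (p - s) / 3)
          break
        }
        p <- p + 3
      }
    }
    as.integer(best)
  }
  set.seed(99)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
               collapse = "")
    expect_equal(find_longest_orf(s)$aa, brute(s), info = paste("seq", i))
  }
})

make_cand_annot <- function(len, overlap_gene = FALSE, n_exons = 1) {
  gene <- data.frame(
    transcript_id = "g1", gene_id = "g1", chrom = "chr1",
    start = 1000L, end = 2000L, strand = "+", source = "REFERENCE",
    biotype = "mRNA", stringsAsFactors = FALSE)
  start <- if (overlap_gene) 1900L else 5000L
  if (n_exons == 1) {
    linc <- data.frame(
      transcript_id = "linc", gene_id = "linc", chrom = "chr1",
      start = start, end = start + len, strand = "+",
      source = "SHORT_READ", biotype = "lincRNA_candidate",
      stringsAsFactors = FALSE)
  } else {
    half <- len %/% 2L
    linc <- data.frame(
      transcript_id = "linc", gene_id = "linc", chrom = "chr1",
      start = c(start, start + half + 500L),
      end = c(start + half, start + len + 500L),
      strand = "+", source = "SHORT_READ", biotype = "lincRNA_candidate",
      stringsAsFactors = FALSE)
  }
  annotation_set(rbind(gene, linc))
}

no_orf_seq <- function(len) paste(rep("C", len), collapse = "")

test_that("definitional filters fire in fixed order with correct rules", {
  # 150 nt intergenic -> too short
  a <- make_cand_annot(150L)
  expect_equal(is_linc_candidate("linc", a, no_orf_seq(150))$rule_fired,
               "REJ_LENGTH")
  # 300 nt with a 120-AA ORF -> ORF rejection
  a <- make_cand_annot(450L)
  orf_seq <- paste0("ATG", strrep("GCT", 120), "TAA",
                    no_orf_seq(450 - 3 * 122))
  r <- is_linc_candidate("linc", a, orf_seq)
  expect_equal(r$rule_fired, "REJ_ORF")
  expect_gte(r$orf_aa, 100L)
  # overlap beats ORF in the cascade
  a <- make_cand_annot(450L, overlap_gene = TRUE)
  expect_equal(is_linc_candidate("linc", a, orf_seq)$rule_fired,
               "REJ_OVERLAP")
  # coding flag fires last
  a <- make_cand_annot(250L)
  expect_equal(
    is_linc_candidate("linc", a, no_orf_seq(250), coding_flag = TRUE)$rule_fired,
    "REJ_CODING")
  # clean candidate passes
  r <- is_linc_candidate("linc", a, no_orf_seq(250))
  expect_equal(r$label, "CANDIDATE")
  # boundary: exactly 200 nt is rejected ("over 200 nt")
  a <- make_cand_annot(200L)
  expect_equal(is_linc_candidate("linc", a, no_orf_seq(200))$rule_fired,
               "REJ_LENGTH")
})

test_that("definitional filter equals a rule-table oracle over all predicates", {
  th <- filter_thresholds()
  for (short in c(TRUE, FALSE)) for (ov in c(TRUE, FALSE))
    for (orf in c(TRUE, FALSE)) for (cp in c(TRUE, FALSE)) {
      len <- if (short) 150L else 450L
      a <- make_cand_annot(len, overlap_gene = ov)
      seq <- if (orf && !short)
        paste0("ATG", strrep("GCT", 120), "TAA", no_orf_seq(len - 366))
      else no_orf_seq(len)
      got <- is_linc_candidate("linc", a, seq, cp, th)$rule_fired
      expected <- if (short) "REJ_LENGTH"
        else if (ov) "REJ_OVERLAP"
        else if (orf) "REJ_ORF"
        else if (cp) "REJ_CODING"
        else "NONE"
      expect_equal(got, expected,
                   info = sprintf("short=%s ov=%s orf=%s cp=%s",
                                  short, ov, orf, cp))
    }
})

support_matrix <- function(gene, tpm, n_experiments, n_bioprojects) {
  vals <- matrix(0, 1, n_experiments,
                 dimnames = list(gene, paste0("e", seq_len(n_experiments))))
  vals[1, ] <- tpm
  expr_from_matrix(vals, tissue = "mixed",
                   bioproject = paste0(
                     "bp", rep_len(seq_len(n_bioprojects), n_experiments)))
}

test_that("confidence cascade honors order and strict boundaries", {
  # mono-exonic 501 nt -> HC by length; exactly 500 -> LC
  a <- make_cand_annot(501L)
  expect_equal(assign_confidence("linc", a)$rule_fired, "MONO_LENGTH")
  a <- make_cand_annot(500L)
  expect_equal(assign_confidence("linc", a)$label, "LC")
  # multi-exonic short transcript is HC regardless
  a <- make_cand_annot(220L, n_exons = 2)
  expect_equal(assign_confidence("linc", a)$rule_fired, "MULTIEXONIC")
  # ONT support wins over everything
  a <- make_cand_annot(220L, n_exons = 2)
  expect_equal(
    assign_confidence("linc", a, list(ont_supported = TRUE))$rule_fired,
    "ONT_SUPPORT")
  # synteny conservation promotes a mono-exonic candidate
  a <- make_cand_annot(300L)
  expect_equal(
    assign_confidence("linc", a, list(conserved_syntenic = TRUE))$rule_fired,
    "MONO_CONSERVED")
})

test_that("expression support counts distinct bioprojects, not experiments", {
  a <- make_cand_annot(300L)
  # 12 experiments spanning only 9 bioprojects -> LC
  m9 <- support_matrix("linc", 3.5, 12, 9)
  expect_equal(assign_confidence("linc", a, expr = m9)$label, "LC")
  # 10 experiments in 10 distinct bioprojects -> HC
  m10 <- support_matrix("linc", 3.5, 10, 10)
  expect_equal(assign_confidence("linc", a, expr = m10)$rule_fired,
               "MONO_EXPRESSION")
  # expression must exceed 3 TPM strictly
  m_eq <- support_matrix("linc", 3.0, 10, 10)
  expect_equal(assign_confidence("linc", a, expr = m_eq)$label, "LC")
})

test_that("raising expression thresholds never promotes LC to HC", {
  a <- make_cand_annot(300L)
  m <- support_matrix("linc", 3.5, 12, 12)
  base <- assign_confidence("linc", a, expr = m)$label
  for (tpm in c(3, 4, 10)) for (ne in c(10, 12, 15)) {
    th <- filter_thresholds(hc_tpm = tpm, hc_min_experiments = ne)
    lab <- assign_confidence("linc", a, expr = m, th = th)$label
    if (base == "LC") expect_equal(lab, "LC")
    if (lab == "HC") expect_equal(base, "HC")
  }
})

test_that("reference harmonization separates overlap, expression, and rejection", {
  gene <- data.frame(
    transcript_id = "g1", gene_id = "g1", chrom = "chr1", start = 1000L,
    end = 2000L, strand = "+", source = "REFERENCE", biotype = "mRNA",
    stringsAsFactors = FALSE)
  ref <- function(start, len, biotype) data.frame(
    transcript_id = "ref1", gene_id = "ref1", chrom = "chr1",
    start = start, end = start + len, strand = "+", source = "REFERENCE",
    biotype = biotype, stringsAsFactors = FALSE)

  a <- annotation_set(rbind(gene, ref(1900L, 400L, "lnc_RNA")))
  m <- support_matrix("ref1", 1.2, 10, 10)
  expect_equal(harmonize_reference("ref1", a, m), "NOT_INTERGENIC")

  a <- annotation_set(rbind(gene, ref(5000L, 400L, "lnc_RNA")))
  expect_equal(harmonize_reference("ref1", a, m), "HC")
  m9 <- support_matrix("ref1", 1.2, 9, 9)
  expect_equal(harmonize_reference("ref1", a, m9), "LC_REFERENCE")

  # NTRs additionally pass the definitional filters
  a <- annotation_set(rbind(gene, ref(5000L, 400L, "NTR")))
  orf_seq <- paste0("ATG", strrep("GCT", 120), "TAA", strrep("C", 34))
  expect_equal(harmonize_reference("ref1", a, m, seq = orf_seq), "REJECTED")
  expect_equal(harmonize_reference("ref1", a, m, seq = strrep("C", 400)),
               "HC")
})

test_that("mRNA-extension flag needs one read spanning linc and mRNA exon on one strand", {
  a <- tiny_annot()  # linc1 at [5000,5400)+, g1 exons [1000,1500) [2000,2500)+
  read_span <- function(start, end, strand, id = "r1")
    data.frame(id = id, chrom = "chr1", start = start, end = end,
               strand = strand, stringsAsFactors = FALSE)
  # read covering linc and an mRNA exon, same strand -> flagged
  expect_true(flag_mrna_extension("linc1", read_span(2400L, 5100L, "+"), a))
  # opposite strand -> not flagged
  expect_false(flag_mrna_extension("linc1", read_span(2400L, 5100L, "-"), a))
  # read covering the linc only -> not flagged
  expect_false(flag_mrna_extension("linc1", read_span(4900L, 5200L, "+"), a))
})

test_that("fractional overlap rules follow their modes and boundaries", {
  linc <- intervals("chr1", 0L, 100L)
  # 50-bp TE on a 100-bp linc: boundary inclusive
  te <- intervals("chr1", 0L, 50L, id = "te1")
  r <- annotate_fractional_overlap(linc, te, "FRAC_OF_LINC", 0.5)
  expect_true(r$hit)
  expect_equal(r$value, 0.5)
  # 49 bp fails
  expect_false(annotate_fractional_overlap(
    linc, intervals("chr1", 0L, 49L), "FRAC_OF_LINC", 0.5)$hit)
  # union of two non-overlapping TEs 30+25 = 55%
  two <- intervals("chr1", c(0L, 40L), c(30L, 65L), id = c("a", "b"))
  r <- annotate_fractional_overlap(linc, two, "FRAC_OF_LINC", 0.5)
  expect_true(r$hit)
  expect_equal(r$value, 0.55)
  # CNS: fraction of the feature; 20 of 40 bp inside -> hit
  cns <- intervals("chr1", 80L, 120L, id = "cns1")
  expect_true(annotate_fractional_overlap(
    linc, cns, "FRAC_OF_FEATURE", 0.5)$hit)
  expect_false(annotate_fractional_overlap(
    linc, intervals("chr1", 81L, 121L), "FRAC_OF_FEATURE", 0.5)$hit)
  # sRNA: 1 bp of a 21-24 nt feature; longer features are ignored
  s21 <- intervals("chr1", 99L, 121L, id = "s")  # 22 nt, 1 bp overlap
  expect_true(annotate_fractional_overlap(
    linc, s21, "MIN_BP", 1, len_range = c(21, 24))$hit)
  s40 <- intervals("chr1", 60L, 100L + 0L, id = "s40")  # 40 nt
  expect_false(annotate_fractional_overlap(
    linc, s40, "MIN_BP", 1, len_range = c(21, 24))$hit)
})

test_that("fractional union overlap equals the base-by-base oracle", {
  set.seed(5)
  for (i in 1:20) {
    linc <- intervals("c", 100L, 100L + sample(200:1000, 1))
    n <- sample(1:6, 1)
    fs <- sample(0:1500, n)
    feats <- intervals("c", fs, fs + sample(50:400, n, replace = TRUE))
    got <- annotate_fractional_overlap(linc, feats, "FRAC_OF_LINC", 0.5)
    oracle <- bp_overlap_oracle(linc, feats) / interval_width(linc)
    expect_equal(got$value, oracle)
    expect_equal(got$hit, oracle >= 0.5)
  }
})

test_that("classification partitions transcripts and ignores input order", {
  cfg <- fixture_config(seed = 21, n_lincs = 45, n_genes = 10)
  fx <- make_annotation_fixture(cfg)
  cl <- classify_transcripts(fx$annot, fx$seqs, fx$coding_flags,
                             fx$evidence, fx$support_expr)
  expect_setequal(cl$id, fx$truth$id)
  expect_true(all(cl$label %in% c("HC", "LC", "REJECTED")))
  expect_equal(nrow(cl), length(unique(cl$id)))
  # candidates = HC + LC (count conservation)
  expect_equal(sum(cl$label %in% c("HC", "LC")) + sum(cl$label == "REJECTED"),
               nrow(fx$truth))
  # order independence: permute the evidence and expression row order
  ev2 <- fx$evidence[rev(seq_len(nrow(fx$evidence))), ]
  cl2 <- classify_transcripts(fx$annot, fx$seqs, fx$coding_flags,
                              ev2, fx$support_expr)
  expect_equal(cl[order(cl$id), ], cl2[order(cl2$id), ])
})
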