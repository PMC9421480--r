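ladder_tree <- function() species_tree(
  "(((((query,S1),S2),S3),S4),S5);", "query")

test_that("node assignment follows the max rule and flags unknown species", {
  tr <- ladder_tree()
  expect_equal(assign_conservation_node(c("S1", "S3"), tr), 3L)
  expect_equal(assign_conservation_node(character(0), tr), 0L)
  expect_equal(assign_conservation_node("S5", tr), 5L)
  expect_error(assign_conservation_node("ghost", tr), "absent from tree")
  expect_error(species_tree(ape::rtree(4, rooted = FALSE), "t1"), "rooted")
})

test_that("node assignment equals the exhaustive clade oracle on all patterns", {
  # non-ladder topology exercises shared internal nodes
  trees <- c("(((((query,S1),S2),S3),S4),S5);",
             "((((query,(S1,S2)),(S3,S4)),S5),(S6,S7));",
             "((query,S1),((S2,S3),(S4,S5)));")
  for (txt in trees) {
    tr <- species_tree(txt, "query")
    others <- names(tr$node_index)
    n <- length(others)
    for (mask in 0:(2^n - 1)) {
      hit <- others[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      expect_equal(assign_conservation_node(hit, tr),
                   node_oracle(tr$phylo, "query", hit),
                   info = paste(txt, mask))
    }
  }
})

test_that("adding a more distant hit never decreases the node", {
  tr <- ladder_tree()
  set.seed(12)
  others <- names(tr$node_index)
  for (i in 1:30) {
    hit <- sample(others, sample.int(length(others) - 1, 1))
    n0 <- assign_conservation_node(hit, tr)
    extra <- sample(setdiff(others, hit), 1)
    expect_gte(assign_conservation_node(c(hit, extra), tr), n0)
    drop <- sample(hit, 1)
    expect_lte(assign_conservation_node(setdiff(hit, drop), tr), n0)
  }
})

test_that("homolog targets classify by 50% same-strand overlap, lincRNA first", {
  annot <- annotation_set(data.frame(
    transcript_id = c("m1", "l1"), gene_id = c("m1", "l1"),
    chrom = "c1", start = c(1000L, 5000L), end = c(2000L, 5400L),
    strand = c("-", "+"), source = "REFERENCE",
    biotype = c("mRNA", "lincRNA_candidate"), stringsAsFactors = FALSE))
  hit <- function(s, e, strand) data.frame(
    chrom = "c1", start = s, end = e, strand = strand,
    stringsAsFactors = FALSE)
  # 100-bp hit, exactly 50 bp on a same-strand lincRNA
  expect_equal(classify_homolog_target(hit(4950L, 5050L, "+"), annot),
               "lincRNA")
  # opposite strand on the mRNA -> unannotated despite 80% overlap
  expect_equal(classify_homolog_target(hit(1000L, 1100L, "+"), annot),
               "unannotated")
  expect_equal(classify_homolog_target(hit(1000L, 1100L, "-"), annot),
               "mRNA")
  # gene desert
  expect_equal(classify_homolog_target(hit(9000L, 9100L, "+"), annot),
               "unannotated")
  # 49% overlap fails the boundary
  expect_equal(classify_homolog_target(hit(1951L, 2051L, "-"), annot),
               "unannotated")
})

test_that("SBSD detection accepts planted loci and rejects every decoy class", {
  cfg <- fixture_config(seed = 41, planted_sbsd_count = 10,
                        sbsd_decoy_count = 12)
  fx <- make_synteny_fixture(cfg)
  res <- lapply(fx$lincs, function(l) {
    linc <- fx$annot_a$tx[fx$annot_a$tx$id == l, , drop = FALSE]
    detect_sbsd(linc, fx$blocks, fx$annot_b, 0L, fx$tree)
  })
  got <- vapply(res, function(r) any(r$sbsd), logical(1))
  expect_equal(got, fx$truth$sbsd)
  # reasons line up with decoy classes
  reasons <- vapply(res, function(r) r$reason[1], character(1))
  expect_true(all(reasons[fx$truth$decoy_class == "flipped"] ==
                    "orientation mismatch"))
  expect_true(all(reasons[fx$truth$decoy_class == "no_target_locus"] ==
                    "no transcribed syntelog"))
})

test_that("SBSD requires a deep enough block and no prior sequence homolog", {
  cfg <- fixture_config(seed = 43, planted_sbsd_count = 4,
                        sbsd_decoy_count = 4)
  fx <- make_synteny_fixture(cfg)
  planted <- fx$truth$id[fx$truth$sbsd][1]
  linc <- fx$annot_a$tx[fx$annot_a$tx$id == planted, , drop = FALSE]
  # a sequence homolog already at the target node suppresses the call
  res <- detect_sbsd(linc, fx$blocks, fx$annot_b, 1L, fx$tree)
  expect_false(any(res$sbsd))
  expect_equal(res$reason[1], "sequence homolog at node")
  # raising min_anchors above the block size disqualifies everything
  res2 <- detect_sbsd(linc, fx$blocks, fx$annot_b, 0L, fx$tree,
                      min_anchors = 20)
  expect_false(any(res2$sbsd))
  # a lincRNA sitting on an anchor is rejected with its own reason
  anchor <- fx$blocks[1, ]
  on_anchor <- data.frame(
    id = "onA", gene_id = "onA", chrom = anchor$a_chrom,
    strand = "+", start = anchor$a_start + 10L,
    end = anchor$a_start + 300L, n_exons = 1L, length = 290L,
    source = "SHORT_READ", biotype = "lincRNA_candidate",
    stringsAsFactors = FALSE)
  res3 <- detect_sbsd(on_anchor, fx$blocks, fx$annot_b, 0L, fx$tree)
  expect_false(any(res3$sbsd))
  expect_equal(res3$reason[1], "on anchor")
})

test_that("family dynamics follow the rounded ancestral mean and WGD factor", {
  expect_equal(infer_family_dynamics(3, c(a = 2, b = 1, c = 1)), "EXPANSION")
  expect_equal(infer_family_dynamics(1, c(a = 1, b = 1, c = 1),
                                     wgd_factor = 3), "CONTRACTION")
  expect_equal(infer_family_dynamics(1, c(a = 1, b = 1, c = 1)), "NC")
  expect_equal(infer_family_dynamics(2, c(a = 2, b = 1)), "NOT_EVALUATED")
  # round-half-to-even vs half-up is configurable
  expect_equal(infer_family_dynamics(2, c(a = 1, b = 2, c = 1, d = 2)),
               "NC")  # mean 1.5 -> 2 under half-even
  expect_equal(infer_family_dynamics(
    2, c(a = 1, b = 2, c = 2, d = 5)), "NC")  # mean 2.5 -> 2 (half-even)
  expect_equal(infer_family_dynamics(
    2, c(a = 1, b = 2, c = 2, d = 5), rounding = "half_up"),
    "CONTRACTION")  # half-up: 2.5 -> 3 > query
})

test_that("family dynamics classes are stable under WGD scaling", {
  set.seed(77)
  for (i in 1:25) {
    rel <- stats::setNames(sample(0:4, 3, replace = TRUE), letters[1:3])
    q <- sample(0:6, 1)
    if (sum(rel) == 0 && q <= 1) next
    base <- infer_family_dynamics(q, rel, wgd_factor = 1)
    scaled <- infer_family_dynamics(q * 3, rel, wgd_factor = 3)
    expect_equal(scaled, base, info = paste(q, paste(rel, collapse = ",")))
  }
})

test_that("reduced-stringency recovery demands reciprocity and synteny", {
  linc <- data.frame(
    id = "sb1", gene_id = "sb1", chrom = "A_chr1", strand = "+",
    start = 10000L, end = 10400L, n_exons = 1L, length = 400L,
    source = "SHORT_READ", biotype = "lincRNA_candidate",
    stringsAsFactors = FALSE)
  segs <- linc_segments(linc)
  expect_equal(segs$`5p`$start, 10000L)
  expect_equal(segs$`3p`$end, 10400L)
  expect_equal(segs$promoter$end, 10000L)
  syntenic <- intervals("B_chr1", 50000L, 60000L)
  fwd_row <- function(q, sstart, send, bits = 200, ev = 1e-30)
    sprintf("%s\tB_chr1\t95\t200\t5\t0\t1\t200\t%d\t%d\t%g\t%g",
            q, sstart, send, ev, bits)
  rev_row <- function(q, sstart, send, bits = 200)
    sprintf("%s\tA_chr1\t95\t200\t5\t0\t1\t200\t%d\t%d\t1e-30\t%g",
            q, sstart, send, bits)
  fwd <- tempfile(); rev <- tempfile()
  # promoter segment hits inside the syntenic window; reverse hit lands
  # back on the promoter -> PROMOTER
  writeLines(fwd_row("sb1|promoter", 55001, 55200), fwd)
  writeLines(rev_row("B_chr1:55000-55200", 9801, 10000), rev)
  r <- reduced_stringency_recovery(linc, read_hits(fwd), read_hits(rev),
                                   syntenic)
  expect_equal(r$label, "PROMOTER")
  # non-reciprocal: the reverse best hit lands elsewhere -> NONE
  writeLines(rev_row("B_chr1:55000-55200", 90001, 90200), rev)
  r2 <- reduced_stringency_recovery(linc, read_hits(fwd), read_hits(rev),
                                    syntenic)
  expect_equal(r2$label, "NONE")
  # reciprocal but outside the syntenic interval -> NONE
  writeLines(fwd_row("sb1|promoter", 95001, 95200), fwd)
  writeLines(rev_row("B_chr1:95000-95200", 9801, 10000), rev)
  r3 <- reduced_stringency_recovery(linc, read_hits(fwd), read_hits(rev),
                                    syntenic)
  expect_equal(r3$label, "NONE")
  # 5p recovery outranks promoter in the reported label
  writeLines(c(fwd_row("sb1|5p", 56001, 56200),
               fwd_row("sb1|promoter", 55001, 55200)), fwd)
  writeLines(c(rev_row("B_chr1:56000-56200", 10001, 10200),
               rev_row("B_chr1:55000-55200", 9801, 10000)), rev)
  r4 <- reduced_stringency_recovery(linc, read_hits(fwd), read_hits(rev),
                                    syntenic)
  expect_equal(r4$label, "GENE_BODY_5p")
  expect_true(r4$recovered[["promoter"]])
  # exact best-hit ties mean no best hit -> NONE
  writeLines(c(fwd_row("sb1|promoter", 55001, 55200),
               fwd_row("sb1|promoter", 57001, 57200)), fwd)
  writeLines(rev_row("B_chr1:55000-55200", 9801, 10000), rev)
  r5 <- reduced_stringency_recovery(linc, read_hits(fwd), read_hits(rev),
                                    syntenic)
  expect_equal(r5$label, "NONE")
})
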