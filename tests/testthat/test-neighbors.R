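tx_row <- function(id, start, end, chrom = "c1", strand = "+",
                   biotype = "mRNA") {
  data.frame(id = id, gene_id = id, chrom = chrom, strand = strand,
             start = start, end = end, n_exons = 1L,
             length = end - start, source = "REFERENCE",
             biotype = biotype, stringsAsFactors = FALSE)
}

test_that("adjacent pairs keep a 100-bp gap and drop 99-bp gaps", {
  linc <- tx_row("l1", 1000L, 1500L, biotype = "lincRNA_candidate")
  mrnas <- rbind(tx_row("up", 500L, 900L), tx_row("down", 1550L, 2000L))
  p <- build_adjacent_pairs(linc, mrnas)
  # upstream gap 100 kept; downstream gap 50 removed
  expect_equal(p$partner, "up")
  expect_equal(p$separation_bp, 100L)
  expect_equal(p$relation, "upstream")
  # a 99-bp gap is "fewer than 100" and removed
  m99 <- rbind(tx_row("up", 500L, 901L))
  expect_equal(nrow(build_adjacent_pairs(linc, m99)), 0L)
  # lincRNA with mRNAs on one side only yields a single pair
  one <- tx_row("up", 100L, 400L)
  p1 <- build_adjacent_pairs(linc, one)
  expect_equal(nrow(p1), 1L)
})

test_that("nearest-mRNA choice equals a brute-force distance scan", {
  set.seed(19)
  for (rep in 1:10) {
    n <- 12
    starts <- sort(sample.int(50000, n)) * 10L
    mrnas <- do.call(rbind, lapply(seq_len(n), function(i)
      tx_row(paste0("m", i), starts[i], starts[i] + 800L)))
    lpos <- sample(5000:400000, 1)
    linc <- tx_row("l", lpos, lpos + 400L, biotype = "lincRNA_candidate")
    p <- build_adjacent_pairs(linc, mrnas, min_separation = 0L)
    up <- mrnas[mrnas$end <= linc$start, ]
    dn <- mrnas[mrnas$start >= linc$end, ]
    if (nrow(up) > 0) {
      best_up <- up$id[which.max(up$end)]
      expect_equal(p$partner[p$relation == "upstream"], best_up)
    }
    if (nrow(dn) > 0) {
      best_dn <- dn$id[which.min(dn$start)]
      expect_equal(p$partner[p$relation == "downstream"], best_dn)
    }
  }
})

test_that("distance sets are nested, inclusive at the boundary, and typed", {
  lincs <- tx_row("l1", 10000L, 10500L, biotype = "lincRNA_candidate")
  mrnas <- rbind(
    tx_row("m1", 10700L, 11000L),   # sep 200 -> in the 200 set
    tx_row("m2", 10851L, 11200L),   # sep 351 -> in the 500 set only
    tx_row("m3", 30000L, 30500L))   # far away
  sets <- pairs_within_distance(lincs, mrnas)
  in_set <- function(th, a, b) {
    s <- sets[[as.character(th)]]
    any((s$gene_a == a & s$gene_b == b) | (s$gene_a == b & s$gene_b == a))
  }
  expect_true(in_set(200, "l1", "m1"))    # "within" is inclusive
  expect_false(in_set(200, "l1", "m2"))
  expect_true(in_set(500, "l1", "m2"))
  # mRNA-mRNA pairs are carried with their own type
  s200 <- sets[["200"]]
  expect_true("mRNA-mRNA" %in%
                s200$pair_type[s200$gene_a == "m1" & s200$gene_b == "m2"])
  # nesting on random layouts
  set.seed(23)
  starts <- sort(sample.int(40000, 30)) * 5L
  mr <- do.call(rbind, lapply(seq_along(starts), function(i)
    tx_row(paste0("g", i), starts[i], starts[i] + 300L)))
  li <- do.call(rbind, lapply(1:10, function(i) {
    s <- sample(1:150000, 1)
    tx_row(paste0("L", i), s, s + 250L, biotype = "lincRNA_candidate")
  }))
  sets2 <- pairs_within_distance(li, mr)
  key <- function(s) paste(s$gene_a, s$gene_b)
  for (i in seq_len(length(sets2) - 1))
    expect_true(all(key(sets2[[i]]) %in% key(sets2[[i + 1]])))
})

test_that("pair correlation matches closed-form Pearson values", {
  raw <- rbind(x = c(1, 2, 3), y = c(6, 4, 2), z = c(1, 2, 4),
               flat = c(2, 2, 2))
  vals <- 2^raw - 1  # so log2(TPM + 1) recovers the rows exactly
  colnames(vals) <- paste0("s", 1:3)
  m <- expr_from_matrix(vals, tissue = paste0("t", 1:3))
  pairs <- data.frame(gene_a = c("x", "x", "x"),
                      gene_b = c("y", "z", "flat"),
                      stringsAsFactors = FALSE)
  pc <- correlate_pairs(pairs, m, mad_quantile = 0, min_expr = 0)
  expect_equal(pc$r[pc$gene_b == "y"], -1)
  expect_equal(pc$r[pc$gene_b == "z"], 0.982, tolerance = 1e-3)
  # zero-variance partner -> ABSENT
  expect_equal(pc$status[pc$gene_b == "flat"], "ABSENT")
  expect_true(is.na(pc$r[pc$gene_b == "flat"]))
  expect_error(correlate_pairs(pairs, expr_from_matrix(
    vals[, 1:2], tissue = c("t1", "t2"))), ">= 3 samples")
})

test_that("correlation is symmetric in member order and MAD-filtered", {
  set.seed(29)
  vals <- matrix(rlnorm(120, 1, 1), 12, 10,
                 dimnames = list(paste0("g", 1:12), paste0("s", 1:10)))
  m <- expr_from_matrix(vals, tissue = paste0("t", 1:10))
  ab <- correlate_pairs(data.frame(gene_a = "g1", gene_b = "g2"), m)
  ba <- correlate_pairs(data.frame(gene_a = "g2", gene_b = "g1"), m)
  expect_equal(ab$r, ba$r)
  # genes below the MAD cutoff produce ABSENT pairs
  lg <- log2(vals + 1)
  mads <- apply(lg, 1, mad)
  weak <- names(which.min(mads))
  strong <- names(which.max(mads))
  pc <- correlate_pairs(data.frame(gene_a = weak, gene_b = strong), m,
                        mad_quantile = 0.75)
  expect_equal(pc$status, "ABSENT")
})

test_that("random pair sampling is deterministic, exhaustive, and roughly uniform", {
  genes <- paste0("g", 1:8)
  a <- sample_random_pairs(genes, 10, seed = 5)
  b <- sample_random_pairs(genes, 10, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, sample_random_pairs(genes, 10, seed = 6)))
  full <- sample_random_pairs(genes, choose(8, 2), seed = 1)
  expect_equal(nrow(unique(full)), choose(8, 2))
  expect_true(all(full$gene_a != full$gene_b))
  expect_error(sample_random_pairs(genes, 29), "more pairs")
  # frequency check: each unordered pair of 5 genes appears with
  # probability 2/10 per draw of 2 pairs over many seeded draws
  genes5 <- paste0("h", 1:5)
  counts <- table(unlist(lapply(1:400, function(s) {
    p <- sample_random_pairs(genes5, 2, seed = s)
    paste(p$gene_a, p$gene_b)
  })))
  expect_equal(length(counts), 10L)
  expect_true(all(counts > 40 & counts < 120))  # expected 80, binomial CI
})

test_that("pair consistency classes follow sign patterns across experiments", {
  expect_equal(classify_pair_consistency(c(0.4, 0.6)), "CONSISTENT_POSITIVE")
  expect_equal(classify_pair_consistency(c(-0.4, -0.6)),
               "CONSISTENT_NEGATIVE")
  expect_equal(classify_pair_consistency(c(0.4, -0.2)),
               "CORRELATION_CHANGES")
  expect_equal(classify_pair_consistency(c(0.4, NA)), "SINGLE_EXPERIMENT")
  expect_error(classify_pair_consistency(c(NA_real_, NA_real_)),
               "no experiment")
})

test_that("Fisher-z comparison matches closed forms and detects shifts", {
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  same <- c(0.1, 0.3, 0.5, -0.2)
  r <- compare_correlation_distributions(same, same)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_warning(compare_correlation_distributions(c(1, 0.5, 0.2),
                                                   c(0.1, 0.2, 0.3)),
                 "clipped")
  # shifted synthetic sets: delta-z = 1, n = 50, sd = 0.3 -> p < 0.001
  for (s in 1:20) {
    set.seed(s)
    za <- rnorm(50, 0, 0.3); zb <- rnorm(50, 1, 0.3)
    res <- compare_correlation_distributions(tanh(za), tanh(zb))
    expect_lt(res$p, 1e-3)
  }
})

test_that("planted co-expressed neighbors out-correlate random pairs", {
  set.seed(37)
  n_pairs <- 30; n_other <- 60; ns <- 20
  latent <- matrix(rnorm(n_pairs * ns), n_pairs, ns)
  make_gene <- function(base, noise) 2^(base + rnorm(ns, 0, noise)) - 1
  vals <- rbind(
    do.call(rbind, lapply(1:n_pairs, function(i) make_gene(latent[i, ], 0.4))),
    do.call(rbind, lapply(1:n_pairs, function(i) make_gene(latent[i, ], 0.4))),
    matrix(2^matrix(rnorm(n_other * ns), n_other, ns) - 1, n_other, ns))
  vals <- pmax(vals, 0)
  rownames(vals) <- c(paste0("la", 1:n_pairs), paste0("ma", 1:n_pairs),
                      paste0("r", 1:n_other))
  colnames(vals) <- paste0("s", 1:ns)
  m <- expr_from_matrix(vals, tissue = paste0("t", 1:ns))
  planted <- data.frame(gene_a = paste0("la", 1:n_pairs),
                        gene_b = paste0("ma", 1:n_pairs))
  rnd <- sample_random_pairs(paste0("r", 1:n_other), 60, seed = 2)
  rp <- correlate_pairs(planted, m, mad_quantile = 0, min_expr = 0)
  rr <- correlate_pairs(rnd, m, mad_quantile = 0, min_expr = 0)
  expect_gt(mean(rp$r, na.rm = TRUE), mean(rr$r, na.rm = TRUE) + 0.3)
})
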