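#' Fixture configuration
#'
#' One configuration object drives all synthetic fixtures.  Identical
#' configurations (including the seed) produce byte-identical outputs;
#' every generated file draws from its own RNG stream derived from the
#' master seed, so regenerating one fixture never perturbs another.
#'
#' @param seed master integer seed.
#' @param n_chroms,n_genes,n_lincs genome layout: chromosomes,
#'   protein-coding genes, candidate lincRNAs.
#' @param intergenic_gap_bp gap planted between neighboring loci.
#' @param chrom_length_bp optional hard chromosome length; loci that do
#'   not fit raise a configuration error (default: sized to content).
#' @param n_tissues,n_bioprojects,replicate_count expression-atlas shape.
#' @param tau_profile_mix named proportions over profile shapes
#'   `uniform`, `graded`, `single` (must sum to 1).
#' @param cs_fraction fraction of lincRNAs planted below the atlas
#'   detection ceiling (context-specific truth).
#' @param noise_sigma lognormal replicate noise (0 = noiseless).
#' @param planted_sbsd_count,sbsd_decoy_count synteny fixture content.
#' @param planted_motif_decay per-node per-site substitution rate used
#'   for homolog background divergence.
#' @param gc_linc,gc_mrna GC content of generated sequences by biotype
#'   (lincRNAs are measurably GC-poorer than mRNAs).
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_chroms = 2L, n_genes = 60L,
                           n_lincs = 200L, intergenic_gap_bp = 1000L,
                           chrom_length_bp = NULL,
                           n_tissues = 8L, n_bioprojects = 12L,
                           replicate_count = 3L,
                           tau_profile_mix = c(uniform = 0.25,
                                               graded = 0.4,
                                               single = 0.35),
                           cs_fraction = 0.3, noise_sigma = 0,
                           planted_sbsd_count = 20L,
                           sbsd_decoy_count = 52L,
                           planted_motif_decay = 0.02,
                           gc_linc = 0.34, gc_mrna = 0.42) {
  stopifnot(abs(sum(tau_profile_mix) - 1) < 1e-9,
            all(c("uniform", "graded", "single") %in%
                  names(tau_profile_mix)),
            n_tissues >= 2, n_lincs >= 0, n_genes >= 0,
            replicate_count >= 1, noise_sigma >= 0)
  structure(as.list(environment()), class = "fixture_config")
}

# deterministic per-stream seed derived from the master seed
sub_seed <- function(seed, name) {
  v <- utf8ToInt(name)
  h <- sum(v * (seq_along(v) * 131)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483611 + 1)
}

# weak second-order Markov background sequence at a target GC content
markov_seq <- function(n, gc) {
  base <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  letters4 <- names(base)
  out <- character(n)
  prev2 <- c("A", "A")
  for (i in seq_len(n)) {
    p <- base
    p[prev2[1]] <- p[prev2[1]] + 0.03
    p[prev2[2]] <- p[prev2[2]] + 0.05
    out[i] <- sample(letters4, 1, prob = p / sum(p))
    prev2 <- c(prev2[2], out[i])
  }
  paste(out, collapse = "")
}

# background sequence guaranteed to contain no sense-strand ORF of
# max_orf_aa or more
bounded_orf_seq <- function(n, gc, max_orf_aa = 100L) {
  for (try in 1:100) {
    s <- markov_seq(n, gc)
    if (find_longest_orf(s)$aa < max_orf_aa) return(s)
  }
  stop("could not generate an ORF-bounded sequence")
}

# sequence of length n carrying an ORF of orf_aa amino acids at offset
plant_orf_seq <- function(n, gc, orf_aa, offset = 3L) {
  orf_nt <- 3L * (orf_aa + 1L) + 3L  # ATG + aa codons + stop
  stopifnot(offset + orf_nt <= n)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste,
                  collapse = "")
  safe <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
  body <- paste(sample(safe, orf_aa, replace = TRUE), collapse = "")
  orf <- paste0("ATG", body, "TAA")
  pre <- if (offset > 0) markov_seq(offset, gc) else ""
  post_n <- n - offset - nchar(orf)
  post <- if (post_n > 0) markov_seq(post_n, gc) else ""
  s <- paste0(pre, orf, post)
  # background segments may by chance extend or add ORFs; re-draw them
  for (try in 1:100) {
    if (find_longest_orf(s)$aa == orf_aa + 1L) return(s)
    pre <- if (offset > 0) markov_seq(offset, gc) else ""
    post <- if (post_n > 0) markov_seq(post_n, gc) else ""
    s <- paste0(pre, orf, post)
  }
  stop("could not isolate the planted ORF")
}

#' Annotation fixture with planted confidence truth
#'
#' Lays out protein-coding genes and candidate lincRNAs on synthetic
#' chromosomes.  Each candidate is constructed to fire exactly one rule
#' of the confidence cascade (long-read support, multi-exonic,
#' mono-exonic length, mono-exonic expression support, low confidence) or
#' one rejection filter (too short, not intergenic, large ORF, coding
#' potential).  Feature tracks (TE, sRNA, Rfam, CNS) are planted with
#' controlled overlap fractions.
#'
#' @param config a [fixture_config()].
#' @param dir optional directory; when given, the fixture is also written
#'   as `annotation.gtf`, `transcripts.fa`, `support_expr.tsv`,
#'   `support_samples.tsv`, and `annotation_truth.tsv`.
#' @return list: `annot` ([annotation_set()]), `seqs` (named character),
#'   `coding_flags`, `evidence` (data.frame), `support_expr`
#'   ([expression_matrix()]), `truth` (data.frame).
#' @export
make_annotation_fixture <- function(config, dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(sub_seed(config$seed, "annotation"))
  gap <- config$intergenic_gap_bp
  n_lincs <- config$n_lincs
  classes <- c("HC_ONT", "HC_MULTI", "HC_MONO_LEN", "HC_MONO_EXPR", "LC",
               "REJ_LENGTH", "REJ_OVERLAP", "REJ_ORF", "REJ_CODING")
  plan <- rep(classes, length.out = n_lincs)
  chrom_of <- rep(paste0("chr", seq_len(config$n_chroms)),
                  length.out = n_lincs)

  exons <- list()
  seqs <- character(0)
  truth <- list()
  features <- list(TE = list(), sRNA = list(), Rfam = list(), CNS = list())
  cursor <- stats::setNames(rep(1000L, config$n_chroms),
                            paste0("chr", seq_len(config$n_chroms)))
  gene_i <- 0L

  place_gene <- function(ch) {
    gene_i <<- gene_i + 1L
    gid <- sprintf("MG%04d", gene_i)
    s <- cursor[[ch]]
    e1 <- c(s, s + 400L)
    e2 <- c(s + 700L, s + 1100L)
    exons[[length(exons) + 1L]] <<- data.frame(
      transcript_id = gid, gene_id = gid, chrom = ch,
      start = c(e1[1], e2[1]), end = c(e1[2], e2[2]),
      strand = sample(c("+", "-"), 1), source = "REFERENCE",
      biotype = "mRNA", stringsAsFactors = FALSE)
    cursor[[ch]] <<- s + 1100L + gap
    gid
  }

  # seed each chromosome with protein-coding context
  for (g in seq_len(config$n_genes)) {
    place_gene(paste0("chr", (g - 1L) %% config$n_chroms + 1L))
  }

  feat_i <- c(TE = 0L, sRNA = 0L, Rfam = 0L, CNS = 0L)
  add_feat <- function(track, ch, start, end) {
    feat_i[[track]] <<- feat_i[[track]] + 1L
    features[[track]][[length(features[[track]]) + 1L]] <<- data.frame(
      chrom = ch, start = start, end = end, strand = ".",
      id = sprintf("%s%04d", track, feat_i[[track]]),
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_lincs)) {
    cls <- plan[i]
    ch <- chrom_of[i]
    id <- sprintf("LINC%04d", i)
    strand <- sample(c("+", "-"), 1)
    src <- if (cls == "HC_ONT") "ONT" else "SHORT_READ"
    len <- switch(cls,
      HC_ONT = 400L, HC_MULTI = 300L, HC_MONO_LEN = 501L + sample(0:300, 1),
      HC_MONO_EXPR = 300L + sample(0:150, 1), LC = 300L + sample(0:150, 1),
      REJ_LENGTH = 150L, REJ_OVERLAP = 400L, REJ_ORF = 450L,
      REJ_CODING = 400L)
    if (cls == "REJ_OVERLAP") {
      gid <- place_gene(ch)
      grow <- exons[[length(exons)]]
      start <- grow$start[1] + 100L  # overlaps first exon of that gene
    } else {
      start <- cursor[[ch]]
      cursor[[ch]] <- cursor[[ch]] + len + gap
    }
    if (!is.null(config$chrom_length_bp) &&
        cursor[[ch]] > config$chrom_length_bp)
      stop("fixture does not fit configured chromosome length")
    if (cls == "HC_MULTI") {
      e <- data.frame(
        transcript_id = id, gene_id = id, chrom = ch,
        start = c(start, start + 200L), end = c(start + 120L, start + 380L),
        strand = strand, source = src, biotype = "lincRNA_candidate",
        stringsAsFactors = FALSE)
    } else {
      e <- data.frame(
        transcript_id = id, gene_id = id, chrom = ch,
        start = start, end = start + len, strand = strand,
        source = src, biotype = "lincRNA_candidate",
        stringsAsFactors = FALSE)
    }
    exons[[length(exons) + 1L]] <- e
    tlen <- sum(e$end - e$start)
    seqs[[id]] <- if (cls == "REJ_ORF")
      plant_orf_seq(tlen, config$gc_linc, 119L)
    else bounded_orf_seq(tlen, config$gc_linc)

    # feature tracks with controlled overlap of the locus span
    span <- c(min(e$start), max(e$end))
    w <- span[2] - span[1]
    te <- i %% 3 == 0
    if (te) add_feat("TE", ch, span[1], span[1] + ceiling(0.6 * w))
    else if (i %% 3 == 1)
      add_feat("TE", ch, span[1], span[1] + floor(0.3 * w))
    srna <- i %% 4 == 0
    if (srna) add_feat("sRNA", ch, span[1] + 5L, span[1] + 27L)
    else if (i %% 4 == 1)
      add_feat("sRNA", ch, span[1] + 5L, span[1] + 45L)  # 40 nt: out of range
    rfam <- i %% 5 == 0
    if (rfam) add_feat("Rfam", ch, span[1], span[1] + ceiling(0.55 * w))
    cns <- i %% 6 == 0
    if (cns) add_feat("CNS", ch, span[1] + 10L, span[1] + 50L)
    else if (i %% 6 == 1 && w > 80L)
      add_feat("CNS", ch, span[2] - 10L, span[2] + 30L)  # only 25% inside

    truth[[i]] <- data.frame(
      id = id, planted_class = cls,
      label = if (startsWith(cls, "REJ")) "REJECTED"
              else if (cls == "LC") "LC" else "HC",
      rule_fired = switch(cls,
        HC_ONT = "ONT_SUPPORT", HC_MULTI = "MULTIEXONIC",
        HC_MONO_LEN = "MONO_LENGTH", HC_MONO_EXPR = "MONO_EXPRESSION",
        LC = "NONE", REJ_LENGTH = "REJ_LENGTH",
        REJ_OVERLAP = "REJ_OVERLAP", REJ_ORF = "REJ_ORF",
        REJ_CODING = "REJ_CODING"),
      te_associated = te, srna_overlap = srna, rfam_overlap = rfam,
      cns_overlap = cns, stringsAsFactors = FALSE)
  }

  exons <- do.call(rbind, exons)
  features <- lapply(features, function(fl) {
    f <- do.call(rbind, fl)
    if (is.null(f)) intervals(character(), integer(), integer())[0, ]
    else f
  })
  annot <- annotation_set(exons, features)
  truth <- do.call(rbind, truth)

  # supporting expression: HC_MONO_EXPR lincRNAs get > 3 TPM in 12
  # distinct bioprojects; LC lincRNAs in only 9 (insufficient)
  nbp <- max(config$n_bioprojects, 12L)
  samples <- data.frame(
    sample = sprintf("supp%02d", seq_len(nbp)),
    tissue = "mixed", bioproject = sprintf("PRJ%03d", seq_len(nbp)),
    condition = "support", stringsAsFactors = FALSE)
  vals <- matrix(stats::runif(n_lincs * nbp, 0, 0.5), nrow = n_lincs,
                 dimnames = list(truth$id, samples$sample))
  vals[truth$planted_class == "HC_MONO_EXPR", seq_len(12)] <- 5
  vals[truth$planted_class == "LC", seq_len(9)] <- 5
  support_expr <- expression_matrix(vals, samples)

  coding_flags <- stats::setNames(truth$planted_class == "REJ_CODING",
                                  truth$id)
  evidence <- data.frame(id = truth$id,
                         ont_supported = truth$planted_class == "HC_ONT",
                         conserved_syntenic = FALSE,
                         stringsAsFactors = FALSE)

  out <- list(annot = annot, seqs = seqs, coding_flags = coding_flags,
              evidence = evidence, support_expr = support_expr,
              truth = truth)
  if (!is.null(dir)) write_annotation_fixture(out, dir)
  out
}

write_annotation_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- fx$annot$exons
  gff <- to_gff_coords(ex$start, ex$end)
  lines <- sprintf(
    "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; transcript_biotype \"%s\";",
    ex$chrom, ex$source, gff$start, gff$end, ex$strand,
    ex$gene_id, ex$transcript_id, ex$biotype)
  writeLines(lines, file.path(dir, "annotation.gtf"))
  ss <- Biostrings::DNAStringSet(fx$seqs)
  Biostrings::writeXStringSet(ss, file.path(dir, "transcripts.fa"))
  for (track in names(fx$annot$features)) {
    f <- fx$annot$features[[track]]
    if (nrow(f) == 0) next
    utils::write.table(
      data.frame(f$chrom, f$start, f$end, f$id, 0L, f$strand),
      file.path(dir, paste0(tolower(track), ".bed")),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  m <- fx$support_expr
  utils::write.table(
    data.frame(gene = rownames(m$values), m$values, check.names = FALSE),
    file.path(dir, "support_expr.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(m$samples, file.path(dir, "support_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fx$truth, file.path(dir, "annotation_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# independent rank-mean quantile map used for analytic truth values
truth_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "min")
    val <- vapply(seq_len(nrow(m)), function(i) {
      k <- r[i]
      t <- sum(m[, j] == m[i, j])
      mean(ref[k:(k + t - 1)])
    }, numeric(1))
    out[, j] <- val
  }
  out
}

#' Expression-atlas fixture with planted tissue-specificity truth
#'
#' Genes draw their tissue profiles from the configured mixture (uniform,
#' graded, single-tissue); replicate values are the planted tissue means
#' under multiplicative lognormal noise.  A configurable subset of
#' lincRNAs is planted below the 0.1-TPM atlas ceiling (context-specific
#' truth).  Differential-expression tables for heat/cold/salt/ABA
#' contrasts are emitted with planted fold-change signs.  Truth tau is
#' computed analytically from the planted means (replicate averaging,
#' rank-mean quantile map, specificity index).
#'
#' @param config a [fixture_config()].
#' @param dir optional output directory (`atlas.tsv`, `atlas_samples.tsv`,
#'   `de_table.tsv`, `expression_truth.tsv`).
#' @return list: `atlas` ([expression_matrix()]), `de` (data.frame),
#'   `expr_records`, `category_map`, `truth` (data.frame: `gene`,
#'   `profile`, `tau`, `max_tissue`, `cs_flag`, `cs_category`,
#'   `stresses`, `temperature_class`).
#' @export
make_expression_fixture <- function(config, dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  if (config$n_tissues < 2) stop("tau needs >= 2 tissues")
  set.seed(sub_seed(config$seed, "expression"))
  nt <- config$n_tissues
  tissues <- sprintf("tissue%02d", seq_len(nt))
  n <- max(config$n_lincs, 200L)
  ids <- sprintf("LINC%04d", seq_len(n))
  profiles <- sample(names(config$tau_profile_mix), n, replace = TRUE,
                     prob = config$tau_profile_mix)
  n_cs <- round(config$cs_fraction * n)
  cs_flag <- seq_len(n) %in% sample.int(n, n_cs)

  means <- matrix(0, n, nt, dimnames = list(ids, tissues))
  for (i in seq_len(n)) {
    # round-robin peak assignment keeps tissue coverage balanced, so a
    # pure single-tissue population has identical per-column zero counts
    # and the quantile map leaves its zeros at zero
    peak <- (i - 1L) %% nt + 1L
    level <- stats::rlnorm(1, meanlog = 2, sdlog = 0.8)
    if (cs_flag[i]) level <- stats::runif(1, 0.01, 0.05)
    means[i, ] <- switch(profiles[i],
      uniform = rep(level, nt),
      graded = level * 0.55^((seq_len(nt) + peak) %% nt),
      single = {
        v <- rep(0, nt)
        v[peak] <- level
        v
      })
  }

  reps <- config$replicate_count
  samples <- data.frame(
    sample = sprintf("%s_r%d", rep(tissues, each = reps),
                     rep(seq_len(reps), nt)),
    tissue = rep(tissues, each = reps),
    bioproject = "PRJ_atlas",
    condition = "atlas",
    replicate = rep(seq_len(reps), nt),
    stringsAsFactors = FALSE)
  noise <- if (config$noise_sigma > 0)
    matrix(exp(stats::rnorm(n * nt * reps, 0, config$noise_sigma)),
           n, nt * reps)
  else matrix(1, n, nt * reps)
  vals <- means[, rep(seq_len(nt), each = reps)] * noise
  colnames(vals) <- samples$sample
  atlas <- expression_matrix(vals, samples)

  qn <- truth_quantile_normalize(means)
  tau_truth <- apply(qn, 1, tau_index)
  max_tissue <- tissues[apply(means, 1, which.max)]

  # context-specific lincRNAs peak in non-atlas experiments
  categories <- c("Meristem", "Stress", "Accession")
  cat_bp <- c(Meristem = "PRJ_meristem", Stress = "PRJ_stress",
              Accession = "PRJ_accession")
  cs_category <- rep(NA_character_, n)
  cs_category[cs_flag] <- sample(categories, sum(cs_flag), replace = TRUE)
  expr_records <- data.frame(
    gene = ids[cs_flag],
    experiment = sprintf("exp_%s", ids[cs_flag]),
    bioproject = unname(cat_bp[cs_category[cs_flag]]),
    value = stats::runif(sum(cs_flag), 1, 20),
    stringsAsFactors = FALSE)
  category_map <- stats::setNames(names(cat_bp), unname(cat_bp))

  # planted stress responses
  stress_plan <- sample(c("none", "heat_up_cold_down", "heat_only",
                          "salt_aba"), n, replace = TRUE)
  de <- list()
  for (i in seq_len(n)) {
    rows <- switch(stress_plan[i],
      none = data.frame(gene = ids[i], contrast = "heat_1",
                        stress = "heat", log2fc = stats::runif(1, -0.5, 0.5),
                        padj = stats::runif(1, 0.2, 1)),
      heat_up_cold_down = data.frame(
        gene = ids[i], contrast = c("heat_1", "cold_1"),
        stress = c("heat", "cold"),
        log2fc = c(stats::runif(1, 1.2, 3), -stats::runif(1, 1.2, 3)),
        padj = stats::runif(2, 0.0001, 0.01)),
      heat_only = data.frame(gene = ids[i], contrast = "heat_1",
                             stress = "heat",
                             log2fc = stats::runif(1, 1.2, 3),
                             padj = stats::runif(1, 0.0001, 0.01)),
      salt_aba = data.frame(
        gene = ids[i], contrast = c("salt_1", "aba_1"),
        stress = c("salt", "ABA"),
        log2fc = stats::runif(2, 1.2, 3),
        padj = stats::runif(2, 0.0001, 0.01)))
    de[[i]] <- rows
  }
  de <- do.call(rbind, de)

  truth <- data.frame(
    gene = ids, profile = profiles, tau = unname(tau_truth),
    max_tissue = max_tissue, cs_flag = cs_flag, cs_category = cs_category,
    stresses = vapply(stress_plan, function(p) switch(p,
      none = "", heat_up_cold_down = "cold,heat", heat_only = "heat",
      salt_aba = "ABA,salt"), character(1)),
    temperature_class = vapply(stress_plan, function(p) switch(p,
      none = "none", heat_up_cold_down = "up_heat_down_cold",
      heat_only = "single", salt_aba = "none"), character(1)),
    stringsAsFactors = FALSE)

  out <- list(atlas = atlas, de = de, expr_records = expr_records,
              category_map = category_map, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      data.frame(gene = rownames(vals), vals, check.names = FALSE),
      file.path(dir, "atlas.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(samples, file.path(dir, "atlas_samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(de, file.path(dir, "de_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "expression_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

default_species_tree_text <-
  "(((((((query,S1),S2),S3),S4),S5),S6),outgroup);"

#' Phylogenetic fixture: hits, alignments and planted motif truth
#'
#' Builds a ladder-shaped species tree around the query, draws a target
#' conservation node per lincRNA, emits homolog hits exactly for species
#' at nodes up to the target, and constructs per-family alignments by
#' mutating the query sequence.  Each lincRNA carries three planted
#' motifs (sORF, 21-nt miRNA site, structured region) that are kept
#' intact in species up to a drawn motif node and degraded past their
#' rule thresholds elsewhere (start codon removed; three substitutions;
#' an internal deletion).
#'
#' @param config a [fixture_config()].
#' @param dir optional output directory (`tree.nwk`, `hits.tsv`,
#'   `msa_<id>.fa`, `phylo_truth.tsv`).
#' @return list: `tree` ([species_tree()]), `hits` (data.frame:
#'   `query_linc`, `target_species`, `chrom`, `start`, `end`, `strand`,
#'   `evalue`), `msas` (named list of [msa_family()]), `motif_specs`
#'   (named list with `sorf`, `mirna`, `structure` [motif_spec()]s),
#'   `truth` (data.frame).
#' @export
make_phylo_fixture <- function(config, dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(sub_seed(config$seed, "phylo"))
  tree <- species_tree(default_species_tree_text, "query")
  species <- names(sort(tree$node_index))  # S1..S6, outgroup
  n <- config$n_lincs
  ids <- sprintf("LINC%04d", seq_len(n))

  seq_len_nt <- 300L
  sorf_aa <- 20L
  sorf_start <- 30L
  sorf_end <- sorf_start + 3L * (sorf_aa + 1L) + 3L
  mirna_start <- 150L; mirna_end <- 171L
  struct_start <- 210L; struct_end <- 240L
  specs <- list(
    sorf = motif_spec("SORF", sorf_start, sorf_end),
    mirna = motif_spec("MIRNA_SITE", mirna_start, mirna_end),
    structure = motif_spec("STRUCTURE", struct_start, struct_end))
  # protect the motifs plus the 9 nt upstream of the sORF, so degraded
  # homologs cannot gain a spurious in-window start codon by mutation
  protected <- c((sorf_start - 8):sorf_end, (mirna_start + 1):mirna_end,
                 (struct_start + 1):struct_end)

  hits <- list()
  msas <- list()
  truth <- list()
  for (i in seq_len(n)) {
    node <- sample(0:tree$max_node, 1)
    motif_node <- if (node == 0) 0L else sample.int(node, 1)
    qseq <- make_motif_query_seq(seq_len_nt, config$gc_linc, specs)
    in_species <- names(tree$node_index)[tree$node_index <= node]
    aln <- c(query = qseq)
    for (sp in in_species) {
      hits[[length(hits) + 1L]] <- data.frame(
        query_linc = ids[i], target_species = sp,
        chrom = paste0(sp, "_chr1"),
        start = 1000L * i, end = 1000L * i + seq_len_nt, strand = "+",
        evalue = 1e-30, stringsAsFactors = FALSE)
      intact <- tree$node_index[[sp]] <= motif_node
      aln[[sp]] <- mutate_homolog(qseq, config$planted_motif_decay *
                                    tree$node_index[[sp]],
                                  protected, specs, intact)
    }
    if (length(in_species) > 0)
      msas[[ids[i]]] <- msa_family(aln, "query")
    truth[[i]] <- data.frame(
      id = ids[i], node = node, motif_node = motif_node,
      stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(query_linc = character(), target_species = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), evalue = numeric(),
               stringsAsFactors = FALSE)
  truth <- do.call(rbind, truth)

  out <- list(tree = tree, hits = hits, msas = msas, motif_specs = specs,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ape::write.tree(out$tree$phylo, file.path(dir, "tree.nwk"))
    utils::write.table(hits, file.path(dir, "hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (id in names(msas)) {
      aln <- msas[[id]]$aln
      writeLines(paste0(">", names(aln), "|", id, "\n", unname(aln)),
                 file.path(dir, paste0("msa_", id, ".fa")))
    }
    utils::write.table(truth, file.path(dir, "phylo_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

# query sequence carrying the three planted motifs at fixed offsets
make_motif_query_seq <- function(n, gc, specs) {
  for (try in 1:100) {
    s <- strsplit(markov_seq(n, gc), "", fixed = TRUE)[[1]]
    sorf <- specs$sorf
    aa <- (sorf$end - sorf$start) / 3 - 2  # minus start and stop codons
    codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1, paste,
                    collapse = "")
    safe <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
    orf <- paste0("ATG", paste(sample(safe, aa, replace = TRUE),
                               collapse = ""), "TAA")
    s[(sorf$start + 1):sorf$end] <- strsplit(orf, "", fixed = TRUE)[[1]]
    # keep the neighborhood of the start codon free of competing (also
    # frame-straddling) ATGs, so degraded homologs have no in-window start
    seqstr <- paste(s, collapse = "")
    win_pos <- max(1, sorf$start - 11):(sorf$start + 10)
    extra_atg <- any(vapply(win_pos, function(p)
      p != sorf$start + 1 && substr(seqstr, p, p + 2) == "ATG",
      logical(1)))
    if (extra_atg) next
    return(seqstr)
  }
  stop("could not construct a motif query sequence")
}

# homolog = query with background substitutions outside protected
# positions; intact homologs keep every motif, degraded homologs break
# all three rules (no start codon nearby, 3 site substitutions, an
# internal deletion in the structured region)
mutate_homolog <- function(qseq, rate, protected, specs, intact) {
  ch <- strsplit(qseq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  mut <- which(stats::runif(n) < rate)
  mut <- setdiff(mut, protected)
  alt <- c(A = "G", C = "T", G = "A", T = "C")
  ch[mut] <- alt[ch[mut]]
  if (!intact) {
    ch[specs$sorf$start + 1L] <- "C"  # ATG -> CTG: no start codon
    site <- (specs$mirna$start + 1):specs$mirna$end
    ch[site[c(2, 8, 15)]] <- alt[ch[site[c(2, 8, 15)]]]
    del <- (specs$structure$start + 6):(specs$structure$start + 10)
    ch[del] <- "-"
  }
  paste(ch, collapse = "")
}

#' Synteny fixture with planted SBSD truth
#'
#' Builds collinear anchor blocks between the query species and one
#' target species, plants true SBSD lincRNAs between consecutive anchors
#' of qualifying blocks (with a transcribed, orientation-matched locus in
#' the target) and four classes of decoys: outside any block, inside a
#' short (8-anchor) block, with orientation flipped relative to both
#' anchors, and without any transcribed target locus.
#'
#' @param config a [fixture_config()].
#' @param dir optional output directory (`synteny_blocks.tsv`,
#'   `synteny_truth.tsv`).
#' @return list: `blocks` (anchor table), `annot_a`, `annot_b`
#'   ([annotation_set()]s for query and target), `tree`
#'   ([species_tree()] with the target species at node 1), `lincs`
#'   (character vector), `truth` (data.frame: `id`, `sbsd`, `decoy_class`).
#' @export
make_synteny_fixture <- function(config, dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(sub_seed(config$seed, "synteny"))
  sp_b <- "speciesB"
  tree <- species_tree(paste0("(query,", sp_b, ");"), "query")

  n_true <- config$planted_sbsd_count
  n_decoy <- config$sbsd_decoy_count
  decoy_classes <- rep(c("outside_block", "short_block", "flipped",
                         "no_target_locus"), length.out = n_decoy)
  slots_needed <- n_true + sum(decoy_classes %in% c("flipped",
                                                    "no_target_locus"))
  anchors_per_block <- 12L
  slots_per_block <- anchors_per_block - 1L
  n_blocks <- ceiling(slots_needed / slots_per_block)

  anchor_len <- 1000L
  pitch <- 5000L
  blocks <- list()
  exons_a <- list()
  exons_b <- list()
  g <- 0L
  block_start <- function(b, side) 10000L + (b - 1L) * 200000L
  for (b in seq_len(n_blocks)) {
    for (k in seq_len(anchors_per_block)) {
      g <- g + 1L
      a_s <- block_start(b, "a") + (k - 1L) * pitch
      b_s <- block_start(b, "b") + (k - 1L) * pitch
      strand_a <- sample(c("+", "-"), 1)
      strand_b <- strand_a  # orthologs keep orientation in this fixture
      blocks[[length(blocks) + 1L]] <- data.frame(
        block_id = sprintf("blk%02d", b), species_b = sp_b,
        a_gene = sprintf("GA%04d", g), a_chrom = "A_chr1",
        a_start = a_s, a_end = a_s + anchor_len, a_strand = strand_a,
        b_gene = sprintf("GB%04d", g), b_chrom = "B_chr1",
        b_start = b_s, b_end = b_s + anchor_len, b_strand = strand_b,
        stringsAsFactors = FALSE)
      exons_a[[length(exons_a) + 1L]] <- data.frame(
        transcript_id = sprintf("GA%04d", g), gene_id = sprintf("GA%04d", g),
        chrom = "A_chr1", start = a_s, end = a_s + anchor_len,
        strand = strand_a, source = "REFERENCE", biotype = "mRNA",
        stringsAsFactors = FALSE)
      exons_b[[length(exons_b) + 1L]] <- data.frame(
        transcript_id = sprintf("GB%04d", g), gene_id = sprintf("GB%04d", g),
        chrom = "B_chr1", start = b_s, end = b_s + anchor_len,
        strand = strand_b, source = "REFERENCE", biotype = "mRNA",
        stringsAsFactors = FALSE)
    }
  }
  blocks <- do.call(rbind, blocks)

  # one short block (8 anchors) for short-block decoys
  short_off <- n_blocks * 200000L + 100000L
  short_rows <- list()
  for (k in seq_len(8L)) {
    g <- g + 1L
    a_s <- short_off + (k - 1L) * pitch
    b_s <- short_off + (k - 1L) * pitch
    short_rows[[k]] <- data.frame(
      block_id = "blk_short", species_b = sp_b,
      a_gene = sprintf("GA%04d", g), a_chrom = "A_chr1",
      a_start = a_s, a_end = a_s + anchor_len, a_strand = "+",
      b_gene = sprintf("GB%04d", g), b_chrom = "B_chr1",
      b_start = b_s, b_end = b_s + anchor_len, b_strand = "+",
      stringsAsFactors = FALSE)
    exons_a[[length(exons_a) + 1L]] <- data.frame(
      transcript_id = sprintf("GA%04d", g), gene_id = sprintf("GA%04d", g),
      chrom = "A_chr1", start = a_s, end = a_s + anchor_len, strand = "+",
      source = "REFERENCE", biotype = "mRNA", stringsAsFactors = FALSE)
    exons_b[[length(exons_b) + 1L]] <- data.frame(
      transcript_id = sprintf("GB%04d", g), gene_id = sprintf("GB%04d", g),
      chrom = "B_chr1", start = b_s, end = b_s + anchor_len, strand = "+",
      source = "REFERENCE", biotype = "mRNA", stringsAsFactors = FALSE)
  }
  blocks <- rbind(blocks, do.call(rbind, short_rows))

  qual <- blocks[blocks$block_id != "blk_short", , drop = FALSE]
  slot_of <- function(j) {  # j-th inter-anchor slot across blocks
    b <- (j - 1L) %/% slots_per_block + 1L
    k <- (j - 1L) %% slots_per_block + 1L
    blk <- qual[qual$block_id == sprintf("blk%02d", b), , drop = FALSE]
    blk <- blk[order(blk$a_start), , drop = FALSE]
    list(a1 = blk[k, ], a2 = blk[k + 1L, ])
  }

  truth <- list()
  linc_i <- 0L
  tgt_i <- 0L
  slot_j <- 0L
  place_linc <- function(a1, a2, flipped, with_target) {
    linc_i <<- linc_i + 1L
    id <- sprintf("SYL%04d", linc_i)
    mid <- (a1$a_end + a2$a_start) %/% 2L
    l_strand <- if (flipped) flip(a1$a_strand) else a1$a_strand
    exons_a[[length(exons_a) + 1L]] <<- data.frame(
      transcript_id = id, gene_id = id, chrom = "A_chr1",
      start = mid, end = mid + 400L, strand = l_strand,
      source = "SHORT_READ", biotype = "lincRNA_candidate",
      stringsAsFactors = FALSE)
    if (with_target) {
      tgt_i <<- tgt_i + 1L
      t_strand <- if (flipped) flip2(a1$b_strand, a2$b_strand, l_strand,
                                     a1$a_strand, a2$a_strand)
                  else a1$b_strand
      t_mid <- (min(a1$b_end, a2$b_end) + max(a1$b_start, a2$b_start)) %/% 2L
      exons_b[[length(exons_b) + 1L]] <<- data.frame(
        transcript_id = sprintf("TLOC%04d", tgt_i),
        gene_id = sprintf("TLOC%04d", tgt_i), chrom = "B_chr1",
        start = t_mid, end = t_mid + 350L, strand = t_strand,
        source = "SHORT_READ", biotype = "other",
        stringsAsFactors = FALSE)
    }
    id
  }
  flip <- function(s) if (s == "+") "-" else "+"
  # a target strand that mismatches the lincRNA's relation to BOTH anchors
  flip2 <- function(b1, b2, l, a1, a2) {
    for (cand in c("+", "-")) {
      ok1 <- (l == a1) == (cand == b1)
      ok2 <- (l == a2) == (cand == b2)
      if (!ok1 && !ok2) return(cand)
    }
    NA_character_
  }

  for (i in seq_len(n_true)) {
    slot_j <- slot_j + 1L
    s <- slot_of(slot_j)
    id <- place_linc(s$a1, s$a2, flipped = FALSE, with_target = TRUE)
    truth[[length(truth) + 1L]] <- data.frame(
      id = id, sbsd = TRUE, decoy_class = "planted",
      stringsAsFactors = FALSE)
  }
  for (dc in decoy_classes) {
    if (dc == "outside_block") {
      linc_i <- linc_i + 1L
      id <- sprintf("SYL%04d", linc_i)
      pos <- short_off + 300000L + linc_i * 2000L
      exons_a[[length(exons_a) + 1L]] <- data.frame(
        transcript_id = id, gene_id = id, chrom = "A_chr1",
        start = pos, end = pos + 400L, strand = "+",
        source = "SHORT_READ", biotype = "lincRNA_candidate",
        stringsAsFactors = FALSE)
    } else if (dc == "short_block") {
      sb <- blocks[blocks$block_id == "blk_short", , drop = FALSE]
      sb <- sb[order(sb$a_start), , drop = FALSE]
      k <- sample.int(nrow(sb) - 1L, 1)
      a1 <- sb[k, ]; a2 <- sb[k + 1L, ]
      names(a1) <- names(a2) <- names(sb)
      id <- place_linc(a1, a2, flipped = FALSE, with_target = TRUE)
    } else if (dc == "flipped") {
      slot_j <- slot_j + 1L
      s <- slot_of(slot_j)
      id <- place_linc(s$a1, s$a2, flipped = TRUE, with_target = TRUE)
    } else {
      slot_j <- slot_j + 1L
      s <- slot_of(slot_j)
      id <- place_linc(s$a1, s$a2, flipped = FALSE, with_target = FALSE)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      id = id, sbsd = FALSE, decoy_class = dc, stringsAsFactors = FALSE)
  }

  annot_a <- annotation_set(do.call(rbind, exons_a))
  annot_b <- annotation_set(do.call(rbind, exons_b))
  truth <- do.call(rbind, truth)
  out <- list(blocks = blocks, annot_a = annot_a, annot_b = annot_b,
              tree = tree, lincs = truth$id, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(blocks, file.path(dir, "synteny_blocks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "synteny_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
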