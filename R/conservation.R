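#' Species trees with query-relative node indices
#'
#' Wraps a rooted `ape::phylo` tree with a focal (query) species and
#' precomputes, for every other tip, the query-relative node index: the
#' number of internal nodes on the path from the query tip up to the most
#' recent common ancestor of query and that tip.  The sister lineage gets
#' index 1, deeper splits larger indices; index 0 is reserved for "no
#' homolog anywhere" (query-specific).
#'
#' @param tree an `ape::phylo` object or path/string of a newick tree.
#' @param query tip label of the focal species.
#' @return list of class `species_tree` with `phylo`, `query`,
#'   `node_index` (named integer vector over non-query tips), and
#'   `max_node`.
#' @export
species_tree <- function(tree, query) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!query %in% tree$tip.label) stop("query tip not in tree: ", query)
  qtip <- match(query, tree$tip.label)
  # ancestors of the query tip, nearest first
  anc <- integer(0)
  node <- qtip
  repeat {
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(parent) == 0) break
    anc <- c(anc, parent)
    node <- parent
  }
  others <- setdiff(tree$tip.label, query)
  mr <- ape::mrca(tree)
  idx <- vapply(others, function(s) {
    match(mr[query, s], anc)
  }, integer(1))
  if (anyNA(idx)) stop("failed to index species against the query path")
  structure(list(phylo = tree, query = query,
                 node_index = idx, max_node = max(idx)),
            class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree: query =", x$query, "|", length(x$node_index),
      "other species, nodes 1..", x$max_node, "\n")
  invisible(x)
}

#' Node of conservation from homolog hits
#'
#' The deepest (largest-index) node at which a sequence homolog of the
#' lincRNA exists: the maximum query-relative node index over all species
#' with a hit, or 0 when there are none (query-specific locus).
#'
#' @param hit_species character vector of species with a homolog of one
#'   lincRNA (possibly empty, duplicates allowed).
#' @param tree a [species_tree()].
#' @return integer node index (0 = query-specific).
#' @export
assign_conservation_node <- function(hit_species, tree) {
  hit_species <- setdiff(unique(hit_species), tree$query)
  if (length(hit_species) == 0) return(0L)
  unknown <- setdiff(hit_species, names(tree$node_index))
  if (length(unknown))
    stop("hit species absent from tree: ", paste(unknown, collapse = ", "))
  max(tree$node_index[hit_species])
}

#' Classify what a homolog hit lands on
#'
#' A hit is conserved "as lincRNA" or "as mRNA" when its interval overlaps
#' an annotated transcript of that biotype on the same strand by at least
#' `min_frac` of the hit; lincRNA is checked before mRNA.  Anything else
#' is unannotated.
#'
#' @param hit single-row data.frame with `chrom`, `start`, `end`, `strand`
#'   (e.g. the subject-side columns of [read_hits()]).
#' @param target_annot [annotation_set()] of the target species.
#' @param min_frac minimum fraction of the hit covered (default 0.5).
#' @return one of `"lincRNA"`, `"mRNA"`, `"unannotated"`.
#' @export
classify_homolog_target <- function(hit, target_annot, min_frac = 0.5) {
  stopifnot(nrow(hit) == 1)
  w <- hit$end - hit$start
  tx <- target_annot$tx
  for (bt in list(c("lincRNA_candidate", "lnc_RNA", "ncRNA"), "mRNA")) {
    cand <- tx[tx$biotype %in% bt & tx$chrom == hit$chrom &
                 strand_compatible(tx$strand, hit$strand), , drop = FALSE]
    if (nrow(cand) == 0) next
    ov <- overlap_bp(cand[, c("chrom", "start", "end", "strand")],
                     hit[rep(1, nrow(cand)), , drop = FALSE])
    if (any(ov / w >= min_frac))
      return(if (identical(bt, "mRNA")) "mRNA" else "lincRNA")
  }
  "unannotated"
}

#' Synteny block tables
#'
#' A block is an ordered run of collinear orthologous anchor-gene pairs
#' between two species.  Expected columns: `block_id`, `species_b`,
#' `a_gene`, `a_chrom`, `a_start`, `a_end`, `a_strand`, `b_gene`,
#' `b_chrom`, `b_start`, `b_end`, `b_strand`; rows within a block ordered
#' along species A.
#'
#' @param path TSV with header.
#' @return data.frame of anchors.
#' @export
read_synteny_blocks <- function(path) {
  b <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("block_id", "species_b", "a_gene", "a_chrom", "a_start", "a_end",
            "a_strand", "b_gene", "b_chrom", "b_start", "b_end", "b_strand")
  miss <- setdiff(need, names(b))
  if (length(miss)) stop("synteny table lacks columns: ",
                         paste(miss, collapse = ", "))
  b
}

#' Syntenic-but-sequence-divergent (SBSD) detection
#'
#' A lincRNA is a transcriptional syntelog in a target species when
#' (a) it lies strictly between two consecutive anchors of a qualifying
#' synteny block (>= `min_anchors` collinear ortholog pairs), (b) the
#' target species has a transcribed locus strictly between the
#' corresponding orthologous anchors, (c) that locus keeps the same
#' orientation relative to at least one flanking anchor as the lincRNA
#' does to the matching anchor, and (d) no sequence homolog already
#' places the lincRNA at or beyond that species' node.  A lincRNA
#' overlapping an anchor gene is never SBSD.
#'
#' @param linc single transcript row (from `annot$tx`) of the query
#'   species.
#' @param blocks anchor table (see [read_synteny_blocks()]), possibly
#'   covering several target species.
#' @param target_annot [annotation_set()] of the target species;
#'   transcripts with biotype in `transcribed_biotypes` count as
#'   transcribed loci.
#' @param seq_conserved_node node already reached by sequence homology
#'   for this lincRNA (0 when none).
#' @param tree a [species_tree()] (for condition d).
#' @param min_anchors minimum anchors per qualifying block (default 10).
#' @param transcribed_biotypes biotypes accepted as evidence of
#'   transcription in the target.
#' @return data.frame: `species`, `sbsd` (logical), `reason`.
#' @export
detect_sbsd <- function(linc, blocks, target_annot, seq_conserved_node,
                        tree, min_anchors = 10,
                        transcribed_biotypes = c("lincRNA_candidate",
                                                 "lnc_RNA", "ncRNA",
                                                 "other")) {
  stopifnot(nrow(linc) == 1)
  out <- list()
  for (sp in unique(blocks$species_b)) {
    res <- list(species = sp, sbsd = FALSE, reason = "no qualifying block")
    bsp <- blocks[blocks$species_b == sp, , drop = FALSE]
    for (bid in unique(bsp$block_id)) {
      blk <- bsp[bsp$block_id == bid, , drop = FALSE]
      if (nrow(blk) < min_anchors) next
      if (blk$a_chrom[1] != linc$chrom) next
      blk <- blk[order(blk$a_start), , drop = FALSE]
      # lincRNA on an anchor disqualifies
      a_iv <- data.frame(chrom = blk$a_chrom, start = blk$a_start,
                         end = blk$a_end, strand = blk$a_strand)
      if (any(overlap_bp(a_iv, linc[rep(1, nrow(blk)),
                                    c("chrom", "start", "end", "strand")]) > 0)) {
        res$reason <- "on anchor"
        next
      }
      slot <- which(linc$start >= blk$a_end[-nrow(blk)] &
                      linc$end <= blk$a_start[-1])
      if (length(slot) == 0) next
      i <- slot[1]
      res$reason <- "no transcribed syntelog"
      b1 <- blk[i, ]; b2 <- blk[i + 1, ]
      if (b1$b_chrom != b2$b_chrom) next
      lo <- min(b1$b_end, b2$b_end)
      hi <- max(b1$b_start, b2$b_start)
      if (hi <= lo) next
      tx <- target_annot$tx
      loci <- tx[tx$biotype %in% transcribed_biotypes &
                   tx$chrom == b1$b_chrom &
                   tx$start >= lo & tx$end <= hi, , drop = FALSE]
      if (nrow(loci) == 0) next
      rel <- function(s1, s2) {
        if (s1 == "." || s2 == ".") NA else s1 == s2
      }
      ok_orient <- vapply(seq_len(nrow(loci)), function(k) {
        t_str <- loci$strand[k]
        for (pair in list(list(a = b1$a_strand, b = b1$b_strand),
                          list(a = b2$a_strand, b = b2$b_strand))) {
          ra <- rel(linc$strand, pair$a)
          rb <- rel(t_str, pair$b)
          if (is.na(ra) || is.na(rb) || ra == rb) return(TRUE)
        }
        FALSE
      }, logical(1))
      if (!any(ok_orient)) {
        res$reason <- "orientation mismatch"
        next
      }
      if (seq_conserved_node >= tree$node_index[[sp]]) {
        res$reason <- "sequence homolog at node"
        next
      }
      res$sbsd <- TRUE
      res$reason <- "syntenic transcribed locus"
      break
    }
    out[[sp]] <- as.data.frame(res, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# best hit of a query in a hit table: highest bitscore, ties by lowest
# evalue then longest alignment; remaining ties -> no best hit (NA row).
best_hit <- function(hits, query) {
  h <- hits[hits$query == query, , drop = FALSE]
  if (nrow(h) == 0) return(NULL)
  h <- h[order(-h$bitscore, h$evalue, -h$length), , drop = FALSE]
  if (nrow(h) > 1 &&
      h$bitscore[1] == h$bitscore[2] && h$evalue[1] == h$evalue[2] &&
      h$length[1] == h$length[2]) return(NULL)
  h[1, , drop = FALSE]
}

#' Reduced-stringency recovery of diverged homology
#'
#' For an SBSD lincRNA, three 200-nt segments (5' end, 3' end, promoter =
#' 200 nt upstream of the transcription start site) are used as queries in
#' a reciprocal-best-hit (RBH) search against the target genome.  A
#' segment is recovered when its best hit reciprocates (the best hit of
#' the target region back in the query genome overlaps the segment) and
#' the target-side hit intersects the expected syntenic interval.
#'
#' @param linc single transcript row (`annot$tx`) of the query species.
#' @param hits_fwd hit table ([read_hits()]) of segment queries against
#'   the target genome; query ids `"<linc id>|5p"`, `"<linc id>|3p"`,
#'   `"<linc id>|promoter"`.
#' @param hits_rev hit table of the reverse search; query ids are
#'   `"<chrom>:<start>-<end>"` labels of the forward best-hit target
#'   regions (internal coordinates), subjects lie in the query genome.
#' @param syntenic_target single-row interval data.frame: the expected
#'   syntenic location in the target genome.
#' @param segment_length segment size in nt (default 200); shorter
#'   lincRNAs use their full length and are flagged truncated.
#' @return list with `label` (`"GENE_BODY_5p"`, `"GENE_BODY_3p"`,
#'   `"PROMOTER"`, or `"NONE"`), `recovered` (named logical per segment),
#'   `truncated` (logical).
#' @export
reduced_stringency_recovery <- function(linc, hits_fwd, hits_rev,
                                        syntenic_target,
                                        segment_length = 200L) {
  stopifnot(nrow(linc) == 1, nrow(syntenic_target) == 1)
  truncated <- linc$length < segment_length
  segs <- linc_segments(linc, segment_length)
  rec <- stats::setNames(logical(3), c("5p", "3p", "promoter"))
  for (sg in names(rec)) {
    q <- paste0(linc$id, "|", sg)
    bh <- best_hit(hits_fwd, q)
    if (is.null(bh)) next
    tgt <- data.frame(chrom = bh$subject, start = bh$s_start,
                      end = bh$s_end, strand = bh$s_strand,
                      stringsAsFactors = FALSE)
    if (overlap_bp(tgt, syntenic_target) == 0) next
    rq <- sprintf("%s:%d-%d", tgt$chrom, tgt$start, tgt$end)
    rb <- best_hit(hits_rev, rq)
    if (is.null(rb)) next
    back <- data.frame(chrom = rb$subject, start = rb$s_start,
                       end = rb$s_end, strand = rb$s_strand,
                       stringsAsFactors = FALSE)
    if (overlap_bp(back, segs[[sg]]) > 0) rec[[sg]] <- TRUE
  }
  label <- if (rec[["5p"]]) "GENE_BODY_5p"
    else if (rec[["3p"]]) "GENE_BODY_3p"
    else if (rec[["promoter"]]) "PROMOTER"
    else "NONE"
  list(label = label, recovered = rec, truncated = truncated)
}

#' Terminal and promoter segments of a transcript
#'
#' @param linc single transcript row (`annot$tx`).
#' @param segment_length nt per segment (default 200).
#' @return named list of single-row interval data.frames
#'   (`5p`, `3p`, `promoter`), strand-aware.
#' @export
linc_segments <- function(linc, segment_length = 200L) {
  stopifnot(nrow(linc) == 1)
  len <- min(segment_length, linc$end - linc$start)
  minus <- identical(linc$strand, "-")
  left <- intervals(linc$chrom, linc$start, linc$start + len, linc$strand)
  right <- intervals(linc$chrom, linc$end - len, linc$end, linc$strand)
  if (minus) {
    p_start <- linc$end
    p_end <- linc$end + segment_length
  } else {
    p_start <- max(0L, linc$start - segment_length)
    p_end <- linc$start
  }
  if (p_end <= p_start) p_end <- p_start + 1L  # degenerate chrom edge
  prom <- intervals(linc$chrom, p_start, p_end, linc$strand)
  list(`5p` = if (minus) right else left,
       `3p` = if (minus) left else right,
       promoter = prom)
}

#' Gene-family dynamics relative to inferred ancestral copy number
#'
#' The ancestral copy number of a lincRNA family is the rounded mean of
#' homolog counts across at least three close reference relatives; the
#' expected present-day count is that value times `wgd_factor` (3 for a
#' lineage-specific whole-genome triplication, 1 otherwise).  A query
#' count above / below / equal to the expectation is an expansion /
#' contraction / no change.  Query-specific lincRNAs (no homolog
#' anywhere) are not evaluated.
#'
#' @param query_count homolog copy number in the query species (the locus
#'   itself plus its within-genome paralogs).
#' @param relative_counts named numeric vector of homolog counts in the
#'   reference relatives.
#' @param wgd_factor integer ploidy correction (default 1).
#' @param rounding `"half_even"` (default, R's `round`) or `"half_up"`.
#' @return one of `"EXPANSION"`, `"CONTRACTION"`, `"NC"`,
#'   `"NOT_EVALUATED"`.
#' @export
infer_family_dynamics <- function(query_count, relative_counts,
                                  wgd_factor = 1L,
                                  rounding = c("half_even", "half_up")) {
  rounding <- match.arg(rounding)
  relative_counts <- relative_counts[!is.na(relative_counts)]
  if (length(relative_counts) < 3) return("NOT_EVALUATED")
  if (sum(relative_counts) == 0 && query_count <= 1) return("NOT_EVALUATED")
  m <- mean(relative_counts)
  ancestral <- if (rounding == "half_even") round(m) else floor(m + 0.5)
  expected <- ancestral * wgd_factor
  if (query_count > expected) "EXPANSION"
  else if (query_count < expected) "CONTRACTION"
  else "NC"
}
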