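# small builders shared across test files

tiny_annot <- function() {
  annotation_set(data.frame(
    transcript_id = c("g1", "g1", "linc1"),
    gene_id = c("g1", "g1", "linc1"),
    chrom = "chr1",
    start = c(1000L, 2000L, 5000L),
    end = c(1500L, 2500L, 5400L),
    strand = c("+", "+", "+"),
    source = c("REFERENCE", "REFERENCE", "SHORT_READ"),
    biotype = c("mRNA", "mRNA", "lincRNA_candidate"),
    stringsAsFactors = FALSE))
}

expr_from_matrix <- function(vals, tissue = NULL, bioproject = NULL,
                             condition = "x") {
  if (is.null(tissue)) tissue <- colnames(vals)
  if (is.null(bioproject)) bioproject <- paste0("bp_", colnames(vals))
  expression_matrix(vals, data.frame(
    sample = colnames(vals), tissue = tissue, bioproject = bioproject,
    condition = condition, stringsAsFactors = FALSE))
}

# one-tissue-per-sample atlas from a genes x tissues mean matrix
atlas_from_means <- function(means) {
  if (is.null(colnames(means)))
    colnames(means) <- paste0("t", seq_len(ncol(means)))
  expr_from_matrix(means)
}

# brute-force base-by-base overlap count between one interval and a
# feature set (union), used as the oracle for interval arithmetic
bp_overlap_oracle <- function(target, features) {
  covered <- logical(target$end - target$start)
  for (i in seq_len(nrow(features))) {
    if (features$chrom[i] != target$chrom) next
    lo <- max(features$start[i], target$start)
    hi <- min(features$end[i], target$end)
    if (hi > lo) covered[(lo - target$start + 1):(hi - target$start)] <- TRUE
  }
  sum(covered)
}

# exhaustive deepest-clade oracle for node assignment: the node index of
# the smallest ancestor clade of the query containing all hit species
node_oracle <- function(phy, query, hit_species) {
  if (length(hit_species) == 0) return(0L)
  qtip <- match(query, phy$tip.label)
  anc <- integer(0)
  node <- qtip
  repeat {
    p <- phy$edge[phy$edge[, 2] == node, 1]
    if (length(p) == 0) break
    anc <- c(anc, p)
    node <- p
  }
  for (i in seq_along(anc)) {
    tips <- ape::extract.clade(phy, anc[i])$tip.label
    if (all(hit_species %in% tips)) return(i)
  }
  stop("no ancestor clade contains all hits")
}
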