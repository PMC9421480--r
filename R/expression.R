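#' Quantile normalization
#'
#' Classic rank-mean quantile normalization: each column's sorted values
#' are replaced by the across-column mean of the values at that rank, so
#' that afterwards every column has an identical empirical distribution.
#' Ties within a column receive the mean of the reference values over the
#' tied ranks.
#'
#' @param m numeric matrix (genes x samples) or an [expression_matrix()].
#' @return object of the same kind with normalized values.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantile_normalize <- function(m) {
  vals <- if (inherits(m, "expr_matrix")) m$values else m
  stopifnot(is.matrix(vals))
  if (ncol(vals) < 2) stop("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(vals, 2, sort))
  out <- vals
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    o <- order(x)
    xs <- x[o]
    # adjacent equal values in the sorted column form tie groups
    grp <- cumsum(c(TRUE, xs[-1] != xs[-length(xs)]))
    repl <- stats::ave(ref, grp, FUN = mean)
    out[o, j] <- repl
  }
  if (inherits(m, "expr_matrix")) {
    m$values <- out
    m
  } else out
}

# replicate-averaged genes x tissues matrix (arithmetic mean of TPM)
tissue_means <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  tiss <- unique(m$samples$tissue)
  res <- vapply(tiss, function(t) {
    cols <- m$samples$sample[m$samples$tissue == t]
    rowMeans(m$values[, cols, drop = FALSE])
  }, numeric(nrow(m$values)))
  if (is.null(dim(res)))
    res <- matrix(res, nrow = 1,
                  dimnames = list(rownames(m$values), tiss))
  res
}

# Yanai-style specificity index on a non-negative vector
tau_index <- function(x) {
  if (all(x == 0)) return(NA_real_)
  xhat <- x / max(x)
  sum(1 - xhat) / (length(x) - 1)
}

#' Tissue-specificity index (tau)
#'
#' TPM values are averaged across replicates within each tissue, the
#' resulting genes x tissues matrix is quantile normalized (optional), and
#' the specificity index tau = sum_i (1 - x_i / max(x)) / (n - 1) is
#' computed per gene.  tau is 0 for uniform expression and 1 for
#' single-tissue expression.  Genes with zero expression in every tissue
#' get `NA`.
#'
#' @param m an [expression_matrix()] (tissue atlas, TPM).
#' @param quantile apply quantile normalization across tissues first
#'   (default `TRUE`, matching the atlas workflow).
#' @return data.frame: `gene`, `tau`, `n_tissues`, `max_tissue`,
#'   `max_value` (replicate-averaged TPM in the peak tissue).
#' @export
compute_tau <- function(m, quantile = TRUE) {
  mt <- tissue_means(m)
  if (ncol(mt) < 2) stop("tau needs >= 2 tissues")
  qn <- if (quantile) quantile_normalize(mt) else mt
  tau <- apply(qn, 1, tau_index)
  peak <- apply(mt, 1, which.max)
  data.frame(
    gene = rownames(mt),
    tau = unname(tau),
    n_tissues = ncol(mt),
    max_tissue = colnames(mt)[peak],
    max_value = mt[cbind(seq_len(nrow(mt)), peak)],
    stringsAsFactors = FALSE
  )
}

#' Tissue of maximal expression
#'
#' Per gene, the tissue with the largest replicate-averaged log2(TPM + 1).
#' The log transform is monotone, so the argmax is identical to the TPM
#' argmax; it is applied because downstream consumers work on that scale.
#' Exact ties are broken by the configured tissue order and flagged.
#'
#' @param m an [expression_matrix()].
#' @param tissue_order optional character vector fixing the tie-break
#'   order (default: order of appearance in the metadata).
#' @return data.frame: `gene`, `max_tissue`, `max_log2`, `tie`.
#' @export
assign_max_tissue <- function(m, tissue_order = NULL) {
  mt <- tissue_means(m)
  if (is.null(tissue_order)) tissue_order <- colnames(mt)
  mt <- mt[, tissue_order, drop = FALSE]
  lg <- log2(mt + 1)
  idx <- apply(lg, 1, which.max)
  tie <- apply(lg, 1, function(r) sum(r == max(r)) > 1)
  data.frame(
    gene = rownames(mt),
    max_tissue = colnames(lg)[idx],
    max_log2 = lg[cbind(seq_len(nrow(lg)), idx)],
    tie = unname(tie),
    stringsAsFactors = FALSE
  )
}

#' Context-specific lincRNAs
#'
#' A lincRNA is context specific (CS) when it is not expressed above
#' `ceiling` (default 0.1 TPM) in any sample of its tissue atlas: such
#' loci were discovered in other experiments and must be expressed only in
#' contexts the atlas does not cover.
#'
#' @param lincs character vector of lincRNA ids.
#' @param atlas an [expression_matrix()]; every id in `lincs` must be a
#'   row (an explicit zero row, never silently absent).
#' @param ceiling atlas detection ceiling in TPM.
#' @return character vector: the CS subset of `lincs`.
#' @export
detect_context_specific <- function(lincs, atlas, ceiling = 0.1) {
  missing <- setdiff(lincs, rownames(atlas$values))
  if (length(missing))
    stop("lincRNAs absent from atlas: ", paste(missing, collapse = ", "))
  mx <- apply(atlas$values[lincs, , drop = FALSE], 1, max)
  lincs[mx <= ceiling]
}

#' Categorize context-specific lincRNAs by peak experiment
#'
#' Each CS lincRNA is assigned the experiment category (via its
#' bioproject) in which its expression is maximal; a bioproject missing
#' from the mapping falls into `"Other"`.
#'
#' @param cs character vector of CS lincRNA ids.
#' @param expr_records data.frame: `gene`, `experiment`, `bioproject`,
#'   `value` (max expression of the gene in that experiment).
#' @param category_map named character vector bioproject -> category.
#' @return data.frame of `category`, `n`, with a final `Total` row.
#' @export
categorize_cs <- function(cs, expr_records, category_map) {
  if (length(cs) == 0)
    return(data.frame(category = "Total", n = 0L, stringsAsFactors = FALSE))
  cats <- vapply(cs, function(g) {
    r <- expr_records[expr_records$gene == g, , drop = FALSE]
    if (nrow(r) == 0) stop("CS lincRNA without expression records: ", g)
    bp <- r$bioproject[which.max(r$value)]
    if (bp %in% names(category_map)) category_map[[bp]] else "Other"
  }, character(1))
  tab <- table(cats)
  out <- data.frame(category = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$category), , drop = FALSE]
  rbind(out, data.frame(category = "Total", n = sum(out$n)))
}

#' Stress-response calls from differential-expression tables
#'
#' A gene responds to a stress when any contrast of that stress reaches
#' `|log2FC| >= lfc` and adjusted P `<= padj` (both boundaries inclusive
#' by default; set `strict = TRUE` for strict inequalities).  Direction is
#' summarized per stress (up/down/mixed), an ABA flag is derived from
#' ABA-labeled contrasts, and heat/cold sign patterns yield a temperature
#' class.
#'
#' @param de data.frame: `gene`, `contrast`, `stress`, `log2fc`, `padj`.
#' @param lfc,padj thresholds (defaults 1 and 0.05).
#' @param strict use strict inequalities instead of inclusive ones.
#' @return data.frame: `gene`, `stresses` (comma-joined), per-stress
#'   direction in `directions` (comma-joined `stress:dir`),
#'   `aba_responsive`, `temperature_class`.
#' @export
build_stress_sets <- function(de, lfc = 1, padj = 0.05, strict = FALSE) {
  stopifnot(all(c("gene", "contrast", "stress", "log2fc", "padj") %in% names(de)))
  pass <- if (strict) abs(de$log2fc) > lfc & de$padj < padj
          else abs(de$log2fc) >= lfc & de$padj <= padj
  sig <- de[pass, , drop = FALSE]
  genes <- unique(de$gene)
  rows <- lapply(genes, function(g) {
    s <- sig[sig$gene == g, , drop = FALSE]
    stresses <- sort(unique(s$stress))
    dirs <- vapply(stresses, function(st) {
      fc <- s$log2fc[s$stress == st]
      if (all(fc > 0)) "up" else if (all(fc < 0)) "down" else "mixed"
    }, character(1))
    heat <- if ("heat" %in% stresses) dirs[["heat"]] else NA
    cold <- if ("cold" %in% stresses) dirs[["cold"]] else NA
    tclass <- if (is.na(heat) && is.na(cold)) "none"
      else if (is.na(heat) || is.na(cold)) "single"
      else if (heat == "up" && cold == "down") "up_heat_down_cold"
      else if (heat == "down" && cold == "up") "down_heat_up_cold"
      else "same_direction"
    data.frame(
      gene = g,
      stresses = paste(stresses, collapse = ","),
      directions = paste(paste0(stresses, ":", dirs), collapse = ","),
      aba_responsive = "ABA" %in% stresses,
      temperature_class = tclass,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
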