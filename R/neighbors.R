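#' Adjacent lincRNA-mRNA pairs
#'
#' For every lincRNA, the nearest mRNA on each side of the locus
#' (strand-agnostic).  Separation is the gap between the closest
#' transcript boundaries (0 when touching or overlapping); pairs
#' separated by fewer than `min_separation` bp are removed so that
#' correlation is not trivially driven by shared promoters or annotation
#' artifacts.
#'
#' @param lincs,mrnas [annotation_set()]s (or `tx` data.frames) on one
#'   assembly.
#' @param min_separation minimum retained gap in bp (default 100;
#'   "fewer than 100" is strict, so a 100-bp gap is kept).
#' @return data.frame: `linc`, `partner`, `partner_type`, `separation_bp`,
#'   `relation` (`upstream` = partner left of the linc in genome
#'   coordinates, `downstream` = right).
#' @export
build_adjacent_pairs <- function(lincs, mrnas, min_separation = 100L) {
  ltx <- if (inherits(lincs, "annotation_set")) lincs$tx else lincs
  mtx <- if (inherits(mrnas, "annotation_set")) mrnas$tx else mrnas
  rows <- list()
  for (i in seq_len(nrow(ltx))) {
    l <- ltx[i, ]
    m <- mtx[mtx$chrom == l$chrom & mtx$id != l$id, , drop = FALSE]
    if (nrow(m) == 0) next
    up <- m[m$end <= l$start, , drop = FALSE]
    if (nrow(up) > 0) {
      j <- which.max(up$end)
      rows[[length(rows) + 1]] <- data.frame(
        linc = l$id, partner = up$id[j], partner_type = "mRNA",
        separation_bp = l$start - up$end[j], relation = "upstream",
        stringsAsFactors = FALSE)
    }
    dn <- m[m$start >= l$end, , drop = FALSE]
    if (nrow(dn) > 0) {
      j <- which.min(dn$start)
      rows[[length(rows) + 1]] <- data.frame(
        linc = l$id, partner = dn$id[j], partner_type = "mRNA",
        separation_bp = dn$start[j] - l$end, relation = "downstream",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(linc = character(), partner = character(),
                      partner_type = character(), separation_bp = integer(),
                      relation = character(), stringsAsFactors = FALSE))
  out <- out[out$separation_bp >= min_separation, , drop = FALSE]
  rownames(out) <- NULL
  out
}

pair_separation <- function(a, b) {
  if (a$chrom != b$chrom) return(NA_integer_)
  max(0L, max(a$start, b$start) - min(a$end, b$end))
}

#' Gene pairs within nested distance thresholds
#'
#' All lincRNA-mRNA and mRNA-mRNA pairs whose boundary-to-boundary
#' separation is at most each threshold ("within" is inclusive).  The
#' returned sets are nested by construction.
#'
#' @param lincs,mrnas [annotation_set()]s or `tx` data.frames.
#' @param thresholds distances in bp.
#' @return named list (one element per threshold) of data.frames
#'   `gene_a`, `gene_b`, `pair_type`, `separation_bp`.
#' @export
pairs_within_distance <- function(lincs, mrnas,
                                  thresholds = c(200, 500, 1000, 2000,
                                                 5000, 10000)) {
  ltx <- if (inherits(lincs, "annotation_set")) lincs$tx else lincs
  mtx <- if (inherits(mrnas, "annotation_set")) mrnas$tx else mrnas
  ltx$.type <- "lincRNA"
  mtx$.type <- "mRNA"
  all_tx <- rbind(ltx[, c("id", "chrom", "start", "end", ".type")],
                  mtx[, c("id", "chrom", "start", "end", ".type")])
  rows <- list()
  for (ch in unique(all_tx$chrom)) {
    g <- all_tx[all_tx$chrom == ch, , drop = FALSE]
    g <- g[order(g$start, g$id), , drop = FALSE]
    n <- nrow(g)
    if (n < 2) next
    ij <- which(upper.tri(matrix(NA, n, n)), arr.ind = TRUE)
    i <- ij[, 1]; j <- ij[, 2]
    sep <- pmax(0L, pmax(g$start[i], g$start[j]) -
                  pmin(g$end[i], g$end[j]))
    ta <- g$.type[i]; tb <- g$.type[j]
    keep <- sep <= max(thresholds) & !(ta == "lincRNA" & tb == "lincRNA")
    if (!any(keep)) next
    rows[[length(rows) + 1]] <- data.frame(
      gene_a = g$id[i][keep], gene_b = g$id[j][keep],
      pair_type = ifelse(ta[keep] == tb[keep], "mRNA-mRNA",
                         "lincRNA-mRNA"),
      separation_bp = as.integer(sep[keep]), stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs))
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        pair_type = character(), separation_bp = integer(),
                        stringsAsFactors = FALSE)
  out <- lapply(thresholds, function(th)
    pairs[pairs$separation_bp <= th, , drop = FALSE])
  names(out) <- as.character(thresholds)
  out
}

#' Expression correlation of gene pairs
#'
#' Genes are filtered to those whose log2(TPM + 1) expression has a median
#' absolute deviation (MAD) in the top 25% (`mad_quantile` = 0.75) and
#' which exceed `min_expr` TPM in at least one sample.  Pearson r is then
#' computed on log2(TPM + 1) across samples for each pair whose members
#' both pass; pairs failing the filter (or with zero variance) get
#' `r = NA` and `status = "ABSENT"`.
#'
#' @param pairs data.frame with columns `linc`/`gene_a` and
#'   `partner`/`gene_b`.
#' @param m an [expression_matrix()] (TPM).
#' @param experiment label stored on each output row.
#' @param mad_quantile MAD quantile cutoff (default 0.75 = top 25%).
#' @param min_expr minimum TPM in at least one sample (default 0.1).
#' @return data.frame: `gene_a`, `gene_b`, `experiment`, `r`,
#'   `n_samples`, `status`.
#' @export
correlate_pairs <- function(pairs, m, experiment = "expt",
                            mad_quantile = 0.75, min_expr = 0.1) {
  if (ncol(m$values) < 3) stop("correlation needs >= 3 samples")
  a <- if (!is.null(pairs$linc)) pairs$linc else pairs$gene_a
  b <- if (!is.null(pairs$partner)) pairs$partner else pairs$gene_b
  lg <- log2(m$values + 1)
  mads <- apply(lg, 1, stats::mad)
  cutoff <- stats::quantile(mads, mad_quantile)
  expressed <- apply(m$values, 1, max) > min_expr
  keep <- rownames(lg)[mads >= cutoff & expressed]
  res <- lapply(seq_along(a), function(i) {
    ok <- a[i] %in% keep && b[i] %in% keep
    r <- NA_real_
    if (ok) {
      x <- lg[a[i], ]
      y <- lg[b[i], ]
      if (stats::sd(x) > 0 && stats::sd(y) > 0)
        r <- stats::cor(x, y, method = "pearson")
      else ok <- FALSE
    }
    data.frame(gene_a = a[i], gene_b = b[i], experiment = experiment,
               r = r, n_samples = ncol(lg),
               status = if (ok) "OK" else "ABSENT",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Uniform random gene pairs
#'
#' Uniform sample, without replacement, of unordered gene pairs; used as
#' the null distribution for neighbor-correlation comparisons.
#'
#' @param genes character vector of gene ids.
#' @param n number of pairs.
#' @param seed integer seed (local RNG; the caller's RNG state is
#'   untouched).
#' @return data.frame `gene_a`, `gene_b`.
#' @export
sample_random_pairs <- function(genes, n, seed = 1L) {
  genes <- unique(genes)
  total <- choose(length(genes), 2)
  if (n > total) stop("requested more pairs than exist (", total, ")")
  idx <- with_local_seed(seed, sample.int(total, n))
  # decode unordered pair index k (1-based) -> (i, j), i < j
  k <- idx - 1
  ng <- length(genes)
  i <- floor(((2 * ng - 1) - sqrt((2 * ng - 1)^2 - 8 * k)) / 2)
  base <- i * ng - i * (i + 1) / 2
  # guard against sqrt round-off at block boundaries
  lo <- base > k
  i[lo] <- i[lo] - 1
  base <- i * ng - i * (i + 1) / 2
  hi <- k - base >= ng - 1 - i
  i[hi] <- i[hi] + 1
  base <- i * ng - i * (i + 1) / 2
  j <- k - base + i + 1
  data.frame(gene_a = genes[i + 1], gene_b = genes[j + 1],
             stringsAsFactors = FALSE)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Cross-experiment consistency of a pair's correlation
#'
#' Over experiments with a usable correlation: all positive -> consistent
#' positive; all negative -> consistent negative; mixed signs -> the
#' correlation changes; a single usable experiment cannot be classified
#' for consistency.
#'
#' @param rs numeric vector of per-experiment r values (`NA` = not
#'   computable in that experiment).
#' @return one of `"CONSISTENT_POSITIVE"`, `"CONSISTENT_NEGATIVE"`,
#'   `"CORRELATION_CHANGES"`, `"SINGLE_EXPERIMENT"`.
#' @export
classify_pair_consistency <- function(rs) {
  usable <- rs[!is.na(rs)]
  if (length(usable) == 0) stop("no experiment with a computable correlation")
  if (length(usable) == 1) return("SINGLE_EXPERIMENT")
  if (all(usable > 0)) "CONSISTENT_POSITIVE"
  else if (all(usable < 0)) "CONSISTENT_NEGATIVE"
  else "CORRELATION_CHANGES"
}

#' Compare two sets of correlation coefficients
#'
#' Fisher z-transform (atanh) applied elementwise, then a two-sample
#' Student's t test on the transformed values.  Coefficients of exactly
#' +/-1 are clipped to +/-(1 - 1e-6) with a warning.
#'
#' @param set_a,set_b numeric vectors of r values in `[-1, 1]`.
#' @return list with `t`, `df`, `p`, and the transformed means.
#' @export
compare_correlation_distributions <- function(set_a, set_b) {
  if (length(set_a) == 0 || length(set_b) == 0)
    stop("empty correlation set")
  clip <- function(r) {
    if (any(abs(r) >= 1)) {
      warning("correlations of +/-1 clipped before Fisher transform")
      r <- pmin(pmax(r, -1 + 1e-6), 1 - 1e-6)
    }
    r
  }
  za <- atanh(clip(set_a))
  zb <- atanh(clip(set_b))
  tt <- stats::t.test(za, zb, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_z_a = mean(za), mean_z_b = mean(zb))
}
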