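#' Merge per-stage outputs into one record table
#'
#' Full outer merge keyed by lincRNA id: a lincRNA present in any stage
#' appears exactly once, stages that did not see it contribute `NA`
#' fields (explicitly missing, never dropped rows).
#'
#' @param stages named list of data.frames; each must have an `id` (or
#'   `gene`) column, unique within the stage.
#' @return data.frame with one row per distinct id.
#' @export
build_records <- function(stages) {
  stopifnot(length(stages) > 0)
  norm <- lapply(names(stages), function(nm) {
    d <- stages[[nm]]
    if (!"id" %in% names(d)) {
      if ("gene" %in% names(d)) names(d)[names(d) == "gene"] <- "id"
      else stop("stage '", nm, "' lacks an id column")
    }
    if (anyDuplicated(d$id))
      stop("stage '", nm, "' has duplicated ids")
    d
  })
  out <- Reduce(function(a, b) merge(a, b, by = "id", all = TRUE,
                                     suffixes = c("", ".dup")),
                norm)
  dup <- grep("\\.dup$", names(out))
  if (length(dup)) {
    for (j in dup) {
      base <- sub("\\.dup$", "", names(out)[j])
      conflict <- !is.na(out[[base]]) & !is.na(out[[j]]) &
        out[[base]] != out[[j]]
      if (any(conflict))
        stop("conflicting values for '", base, "' across stages")
      out[[base]][is.na(out[[base]])] <- out[[j]][is.na(out[[base]])]
    }
    out <- out[, -dup, drop = FALSE]
  }
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Category roll-up with total
#'
#' Counts records per category of a partition field (or sums a supplied
#' named count vector) and appends a `Total` row equal to the category
#' sum.  Because a partition assigns each record to exactly one category,
#' the total always equals the number of records.
#'
#' @param x data.frame of records, or a named numeric vector of
#'   pre-computed category counts.
#' @param partition field name (required when `x` is a data.frame).
#' @return data.frame `category`, `n` with a final `Total` row.
#' @export
rollup <- function(x, partition = NULL) {
  if (is.data.frame(x)) {
    if (is.null(partition) || !partition %in% names(x))
      stop("partition field not found")
    v <- x[[partition]]
    if (anyNA(v)) stop("partition field has missing values")
    tab <- table(v)
    counts <- stats::setNames(as.numeric(tab), names(tab))
  } else {
    if (is.null(names(x)) || anyDuplicated(names(x)))
      stop("counts must have unique category names")
    counts <- x
  }
  out <- data.frame(category = as.character(names(counts)),
                    n = as.numeric(counts), stringsAsFactors = FALSE)
  out <- out[order(out$category), , drop = FALSE]
  rownames(out) <- NULL
  rbind(out, data.frame(category = "Total", n = sum(out$n)))
}

#' Run the full annotation pipeline
#'
#' Orchestrates the stages (classify, expression, conservation, motifs,
#' neighbors, report) over either synthetic fixtures (`simulate:` block)
#' or input files, writes per-stage TSVs, the merged record table, a GFF3
#' with confidence classes, and a provenance log (input checksums,
#' thresholds, seed).  Outputs are byte-identical across reruns with the
#' same configuration.
#'
#' @param config path to a YAML configuration, or an equivalent list.
#'   Keys: `seed`, `out_dir`, either `simulate:` (fixture-config
#'   overrides) or `inputs:` (file paths), optional `thresholds:` and
#'   `stages:` (default: all).
#' @return invisibly, the merged records data.frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config must name out_dir")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- config$stages
  if (is.null(stages))
    stages <- c("classify", "expression", "conservation", "motifs",
                "neighbors", "report")
  th <- do.call(filter_thresholds,
                if (is.null(config$thresholds)) list() else config$thresholds)

  # fail-fast input validation
  if (is.null(config$simulate)) {
    if (is.null(config$inputs)) stop("config needs 'simulate' or 'inputs'")
    need <- c(classify = "annotation", expression = "atlas")
    for (st in intersect(names(need), stages)) {
      p <- config$inputs[[need[[st]]]]
      if (!is.null(p) && !file.exists(p))
        stop("missing input for stage ", st, ": ", p)
    }
  }

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  skipped <- character(0)
  fx <- NULL
  if (!is.null(config$simulate)) {
    args <- config$simulate
    args$seed <- seed
    cfg <- do.call(fixture_config, args)
    fx <- list(
      ann = make_annotation_fixture(cfg),
      expr = make_expression_fixture(cfg),
      phy = make_phylo_fixture(cfg),
      syn = make_synteny_fixture(cfg)
    )
  }

  stage_out <- list()

  if ("classify" %in% stages) {
    if (!is.null(fx)) {
      cls <- classify_transcripts(fx$ann$annot, fx$ann$seqs,
                                  fx$ann$coding_flags, fx$ann$evidence,
                                  fx$ann$support_expr, th)
      feats <- fx$ann$annot$features
      tx <- fx$ann$annot$tx
      ov <- lapply(cls$id, function(id) {
        linc <- tx[tx$id == id, c("chrom", "start", "end", "strand")]
        data.frame(
          id = id,
          te_associated = annotate_fractional_overlap(
            linc, feats$TE, "FRAC_OF_LINC", th$te_frac)$hit,
          srna_overlap = annotate_fractional_overlap(
            linc, feats$sRNA, "MIN_BP", th$srna_min_overlap_bp,
            th$srna_len_range)$hit,
          rfam_overlap = annotate_fractional_overlap(
            linc, feats$Rfam, "FRAC_OF_LINC", th$rfam_frac)$hit,
          cns_overlap = annotate_fractional_overlap(
            linc, feats$CNS, "FRAC_OF_FEATURE", th$cns_frac)$hit,
          stringsAsFactors = FALSE)
      })
      cls <- merge(cls, do.call(rbind, ov), by = "id")
      coords <- tx[match(cls$id, tx$id),
                   c("chrom", "start", "end", "strand")]
      stage_out$classify <- cbind(cls, coords)
    } else {
      annot <- read_annotation(config$inputs$annotation, "GTF")
      seqs <- NULL
      if (!is.null(config$inputs$transcripts_fasta)) {
        ss <- Biostrings::readDNAStringSet(config$inputs$transcripts_fasta)
        seqs <- stats::setNames(as.character(ss),
                                sub("\\s.*$", "", names(ss)))
      }
      supp <- NULL
      if (!is.null(config$inputs$support_expr))
        supp <- read_expression(config$inputs$support_expr,
                                config$inputs$support_samples)
      cls <- classify_transcripts(annot, seqs, NULL, NULL, supp, th)
      tx <- annot$tx
      coords <- tx[match(cls$id, tx$id),
                   c("chrom", "start", "end", "strand")]
      stage_out$classify <- cbind(cls, coords)
    }
    write_stage_tsv(stage_out$classify, file.path(out_dir, "classification.tsv"))
  }

  if ("expression" %in% stages) {
    if (!is.null(fx)) {
      atlas <- fx$expr$atlas
      de <- fx$expr$de
      recs <- fx$expr$expr_records
      cmap <- fx$expr$category_map
    } else if (!is.null(config$inputs$atlas)) {
      atlas <- read_expression(config$inputs$atlas,
                               config$inputs$atlas_samples)
      de <- if (!is.null(config$inputs$de))
        utils::read.delim(config$inputs$de, stringsAsFactors = FALSE)
      else NULL
      recs <- NULL
      cmap <- NULL
    } else {
      atlas <- NULL
    }
    if (!is.null(atlas)) {
      tau <- compute_tau(atlas)
      names(tau)[names(tau) == "gene"] <- "id"
      cs <- detect_context_specific(rownames(atlas$values), atlas)
      tau$cs_flag <- tau$id %in% cs
      if (!is.null(recs)) {
        cs_with_records <- intersect(cs, recs$gene)
        cs_cat <- vapply(tau$id, function(g) {
          if (!g %in% cs_with_records) return(NA_character_)
          r <- recs[recs$gene == g, , drop = FALSE]
          bp <- r$bioproject[which.max(r$value)]
          if (bp %in% names(cmap)) cmap[[bp]] else "Other"
        }, character(1))
        tau$cs_category <- unname(cs_cat)
      }
      if (!is.null(de)) {
        sc <- build_stress_sets(de)
        names(sc)[names(sc) == "gene"] <- "id"
        tau <- merge(tau, sc, by = "id", all.x = TRUE)
      }
      stage_out$expression <- tau
      write_stage_tsv(tau, file.path(out_dir, "expression.tsv"))
    } else skipped <- c(skipped, "expression:no_atlas")
  }

  if ("conservation" %in% stages) {
    if (!is.null(fx)) {
      tree <- fx$phy$tree
      hits <- fx$phy$hits
    } else if (!is.null(config$inputs$tree) &&
                 !is.null(config$inputs$hits)) {
      tree <- species_tree(config$inputs$tree, config$query %||% "query")
      hits <- utils::read.delim(config$inputs$hits,
                                stringsAsFactors = FALSE)
    } else {
      tree <- NULL
      skipped <- c(skipped, "conservation:no_tree")
    }
    if (!is.null(tree)) {
      ids <- unique(hits$query_linc)
      all_ids <- if (!is.null(fx)) fx$phy$truth$id else ids
      cons <- data.frame(
        id = all_ids,
        conservation_node = vapply(all_ids, function(l)
          assign_conservation_node(
            hits$target_species[hits$query_linc == l], tree),
          integer(1)),
        stringsAsFactors = FALSE)
      if (!is.null(fx)) {
        syn <- fx$syn
        sb <- vapply(syn$lincs, function(l) {
          linc <- syn$annot_a$tx[syn$annot_a$tx$id == l, , drop = FALSE]
          res <- detect_sbsd(linc, syn$blocks, syn$annot_b, 0L, syn$tree)
          any(res$sbsd)
        }, logical(1))
        cons <- merge(cons,
                      data.frame(id = syn$lincs, sbsd = unname(sb),
                                 stringsAsFactors = FALSE),
                      by = "id", all = TRUE)
      }
      stage_out$conservation <- cons
      write_stage_tsv(cons, file.path(out_dir, "conservation.tsv"))
    }
  }

  if ("motifs" %in% stages && !is.null(fx)) {
    specs <- fx$phy$motif_specs
    tree <- fx$phy$tree
    mot <- lapply(names(fx$phy$msas), function(id) {
      msa <- fx$phy$msas[[id]]
      data.frame(
        id = id,
        sorf_node = assign_motif_node(
          check_sorf_conservation(msa, specs$sorf), tree),
        mirna_site_node = assign_motif_node(
          check_mirna_conservation(msa, specs$mirna), tree),
        structure_node = assign_motif_node(
          check_structure_conservation(msa, specs$structure), tree),
        stringsAsFactors = FALSE)
    })
    mot <- do.call(rbind, mot)
    if (!is.null(mot)) {
      stage_out$motifs <- mot
      write_stage_tsv(mot, file.path(out_dir, "motifs.tsv"))
    }
  }

  if ("neighbors" %in% stages && !is.null(fx)) {
    annot <- fx$ann$annot
    lincs <- annot$tx[annot$tx$biotype == "lincRNA_candidate", ]
    mrnas <- annot$tx[annot$tx$biotype == "mRNA", ]
    pairs <- build_adjacent_pairs(lincs, mrnas)
    if (nrow(pairs) > 0) {
      nb <- stats::aggregate(
        partner ~ linc, data = pairs,
        FUN = function(p) paste(sort(p), collapse = ","))
      names(nb) <- c("id", "neighbor_ids")
      stage_out$neighbors <- nb
      write_stage_tsv(nb, file.path(out_dir, "neighbors.tsv"))
      write_stage_tsv(pairs, file.path(out_dir, "neighbor_pairs.tsv"))
    }
  }

  records <- build_records(stage_out)
  if ("report" %in% stages) {
    if (!is.null(records$chrom)) {
      records$chrom[is.na(records$chrom)] <- "unplaced"
      records$start[is.na(records$start)] <- -1L
      records$start <- as.integer(records$start)
      write_linc_table(
        transform(records, start = ifelse(start < 0, 0L, start)),
        file.path(out_dir, "records.tsv"))
      export_confidence_gff3(records, file.path(out_dir, "lincs.gff3"))
    }
    if (!is.null(records$label))
      write_stage_tsv(rollup(records[!is.na(records$label), ], "label"),
                      file.path(out_dir, "confidence_rollup.tsv"))
  }

  prov <- c(
    "# provenance",
    paste0("seed: ", seed),
    paste0("stages: ", paste(stages, collapse = ",")),
    paste0("skipped: ", if (length(skipped)) paste(skipped, collapse = ",")
           else "none"),
    paste0("thresholds: ", paste(names(th), vapply(th, function(v)
      paste(v, collapse = "-"), character(1)), sep = "=", collapse = " ")),
    input_checksums(config)
  )
  writeLines(prov, file.path(out_dir, "provenance.txt"))
  invisible(records)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

input_checksums <- function(config) {
  if (is.null(config$inputs)) return("inputs: simulated")
  files <- unlist(config$inputs)
  files <- files[file.exists(files)]
  if (length(files) == 0) return("inputs: none")
  sums <- tools::md5sum(files)
  paste0("input ", names(sums), ": ", unname(sums))
}

write_stage_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

export_confidence_gff3 <- function(records, path) {
  r <- records[!is.na(records$start) & records$start >= 0 &
                 !is.na(records$label), , drop = FALSE]
  gff <- to_gff_coords(r$start, r$end)
  lines <- c("##gff-version 3", sprintf(
    "%s\tlinctk\tlincRNA\t%d\t%d\t.\t%s\t.\tID=%s;confidence=%s;rule=%s",
    r$chrom, gff$start, gff$end,
    ifelse(is.na(r$strand), ".", r$strand), r$id, r$label,
    ifelse(is.na(r$rule_fired), "NA", r$rule_fired)))
  writeLines(lines, path)
  invisible(path)
}
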