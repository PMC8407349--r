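#' Summed expression per KEGG functional category
#'
#' Sums (normalized) RPKM over all genes sharing the same annotation at the
#' requested KEGG level (`"level2"` category, `"level3"` pathway, or
#' `"ko"`). Genes lacking the annotation are excluded from every category;
#' their summed mass is reported separately so that category sums plus
#' unannotated mass reconstruct the per-sample total.
#'
#' @param expr A normalized [expr_matrix()].
#' @param annotations Gene annotation data.frame with `ko_id`,
#'   `kegg_level2`, `kegg_level3` columns (`NA`/empty = unannotated).
#' @param level `"level2"`, `"level3"` or `"ko"`.
#' @return A list of class `"functional_profile"`: `values`
#'   (category-by-sample matrix), `unannotated` (named per-sample totals of
#'   genes without the annotation), `level`.
#' @export
kegg_category_expression <- function(expr, annotations,
                                     level = c("level2", "level3", "ko")) {
  level <- match.arg(level)
  if (!inherits(expr, "expr_matrix")) stop("expr must be an expr_matrix")
  if (!is_normalized(expr)) {
    stop("expression must be spike-normalized before functional aggregation")
  }
  col <- switch(level, level2 = "kegg_level2", level3 = "kegg_level3",
                ko = "ko_id")
  if (!col %in% names(annotations)) {
    stop("annotations lack column ", col)
  }
  check_annotations(annotations, rownames(expr))
  lab <- annotations[[col]][match(rownames(expr), annotations$gene_id)]
  lab[!is.na(lab) & lab == ""] <- NA_character_
  vals <- unclass_profile(expr)
  annotated <- !is.na(lab)
  sums <- if (any(annotated)) {
    as.matrix(rowsum(vals[annotated, , drop = FALSE],
                     group = lab[annotated], reorder = TRUE))
  } else {
    matrix(0, nrow = 0, ncol = ncol(vals), dimnames = list(NULL, colnames(vals)))
  }
  structure(
    list(
      values = sums,
      unannotated = colSums(vals[!annotated, , drop = FALSE]),
      level = level
    ),
    class = "functional_profile"
  )
}

#' @export
print.functional_profile <- function(x, ...) {
  cat(sprintf("<functional_profile> %d %s categories x %d samples\n",
              nrow(x$values), x$level, ncol(x$values)))
  invisible(x)
}

#' Attribute each KO's expression to taxa
#'
#' For every KEGG ortholog in `ko_set` and every sample, computes the
#' fraction of the KO's total (normalized) expression contributed by each
#' genome — the per-reaction pie-chart quantity:
#' `fraction(G) = sum_{genes of G with KO} expr / sum_{all genes with KO} expr`.
#' Fractions sum to 1 where the KO's total is positive; where the total is
#' zero the attribution is marked undefined (`defined = FALSE`) with zero
#' fractions rather than NaN.
#'
#' @param expr A normalized [expr_matrix()].
#' @param annotations Gene annotation data.frame with `ko_id` and
#'   `genome_id`.
#' @param ko_set Non-empty character vector of KO ids to attribute.
#' @return Long-format data.frame: `ko_id`, `sample_id`, `genome_id`,
#'   `fraction`, `total_rpkm`, `defined`.
#' @export
taxon_pathway_attribution <- function(expr, annotations, ko_set) {
  if (!inherits(expr, "expr_matrix")) stop("expr must be an expr_matrix")
  if (!is_normalized(expr)) {
    stop("expression must be spike-normalized before attribution")
  }
  if (!length(ko_set)) stop("ko_set must be non-empty")
  if (!"ko_id" %in% names(annotations)) stop("annotations lack ko_id")
  check_annotations(annotations, rownames(expr))
  idx <- match(rownames(expr), annotations$gene_id)
  ko <- annotations$ko_id[idx]
  genome <- annotations$genome_id[idx]
  vals <- unclass_profile(expr)
  out <- vector("list", length(ko_set))
  for (k in seq_along(ko_set)) {
    kid <- ko_set[k]
    sel <- !is.na(ko) & ko == kid
    genomes_k <- sort(unique(genome[sel]))
    rows <- expand.grid(sample_id = colnames(vals), genome_id = genomes_k,
                        stringsAsFactors = FALSE)
    if (!nrow(rows)) {
      out[[k]] <- data.frame(ko_id = character(), sample_id = character(),
                             genome_id = character(), fraction = numeric(),
                             total_rpkm = numeric(), defined = logical(),
                             stringsAsFactors = FALSE)
      next
    }
    by_genome <- as.matrix(rowsum(vals[sel, , drop = FALSE],
                                  group = genome[sel], reorder = TRUE))
    by_genome <- by_genome[genomes_k, , drop = FALSE]
    totals <- colSums(by_genome)
    pos <- totals > 0
    frac <- by_genome
    frac[, pos] <- sweep(by_genome[, pos, drop = FALSE], 2, totals[pos], "/")
    frac[, !pos] <- 0
    out[[k]] <- data.frame(
      ko_id = kid,
      sample_id = rep(colnames(vals), each = length(genomes_k)),
      genome_id = rep(genomes_k, times = ncol(vals)),
      fraction = as.vector(frac),  # column-major: genome within sample
      total_rpkm = rep(totals, each = length(genomes_k)),
      defined = rep(pos, each = length(genomes_k)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Presence/absence of KOs per genome, with curation overrides
#'
#' A KO is present in a genome if any gene of that genome carries it in the
#' annotation table. Manually curated overrides flip individual cells
#' (adding KOs missed by automatic annotation or removing false positives);
#' provenance records whether each present/absent call came from the
#' annotation or from curation.
#'
#' @param annotations Gene annotation data.frame with `genome_id`, `ko_id`.
#' @param genomes Genome registry data.frame (defines the genome universe).
#' @param overrides Optional data.frame with `genome_id`, `ko_id`, `present`
#'   (logical): each row forces that cell to `present`.
#' @return A list of class `"pathway_presence"`: `present` (logical
#'   KO-by-genome matrix) and `provenance` (character matrix,
#'   `"annotated"` or `"curated_override"`).
#' @export
pathway_presence <- function(annotations, genomes, overrides = NULL) {
  if (!all(c("genome_id", "ko_id") %in% names(annotations))) {
    stop("annotations need genome_id and ko_id")
  }
  genome_ids <- genomes$genome_id
  kos <- c(annotations$ko_id, if (!is.null(overrides)) overrides$ko_id)
  kos <- sort(unique(kos[!is.na(kos) & kos != ""]))
  present <- matrix(FALSE, nrow = length(kos), ncol = length(genome_ids),
                    dimnames = list(kos, genome_ids))
  prov <- matrix("annotated", nrow = length(kos), ncol = length(genome_ids),
                 dimnames = list(kos, genome_ids))
  ann <- annotations[!is.na(annotations$ko_id) & annotations$ko_id != "", ]
  bad_g <- setdiff(ann$genome_id, genome_ids)
  if (length(bad_g)) {
    stop("annotation references unknown genome(s): ",
         paste(bad_g, collapse = ", "))
  }
  present[cbind(match(ann$ko_id, kos), match(ann$genome_id, genome_ids))] <- TRUE
  if (!is.null(overrides)) {
    if (!all(c("genome_id", "ko_id", "present") %in% names(overrides))) {
      stop("overrides need genome_id, ko_id, present")
    }
    bad <- setdiff(overrides$genome_id, genome_ids)
    if (length(bad)) {
      stop("override references unknown genome(s): ", paste(bad, collapse = ", "))
    }
    for (i in seq_len(nrow(overrides))) {
      r <- match(overrides$ko_id[i], kos)
      c <- match(overrides$genome_id[i], genome_ids)
      present[r, c] <- isTRUE(overrides$present[i])
      prov[r, c] <- "curated_override"
    }
  }
  structure(list(present = present, provenance = prov),
            class = "pathway_presence")
}

#' @export
print.pathway_presence <- function(x, ...) {
  cat(sprintf("<pathway_presence> %d KOs x %d genomes (%d curated cells)\n",
              nrow(x$present), ncol(x$present),
              sum(x$provenance == "curated_override")))
  invisible(x)
}
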