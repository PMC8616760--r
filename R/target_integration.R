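# ---------------------------------------------------------------------------
# Core procedure: a gene is called a candidate direct target of the TF iff
# (a) at least one ChIP-seq peak lies within `window` bp of its TSS and
# (b) it passed the differential-expression selection, with the direction of
# change read through the perturbation design to label the gene
# transactivated or repressed.
# ---------------------------------------------------------------------------

#' Regulation class from fold-change sign and perturbation design
#'
#' Under TF knockdown a gene that goes down was activated by the TF
#' (transactivated) and a gene that goes up was repressed; under TF
#' overexpression the mapping is mirrored.
#'
#' @param lfc_sign `"+"` or `"-"` (sign of log2 fold change,
#'   perturbed vs control), vectorised.
#' @param mode `"knockdown"` or `"overexpression"`.
#' @return Character vector, `"transactivated"` or `"repressed"`.
#' @examples
#' regulation_class("-", "knockdown")      # transactivated
#' regulation_class("+", "overexpression") # transactivated
#' @export
regulation_class <- function(lfc_sign, mode = c("knockdown",
                                                "overexpression")) {
  mode <- match.arg(mode)
  if (!all(lfc_sign %in% c("+", "-"))) stop("lfc_sign must be '+' or '-'")
  if (mode == "knockdown") {
    ifelse(lfc_sign == "-", "transactivated", "repressed")
  } else {
    ifelse(lfc_sign == "+", "transactivated", "repressed")
  }
}

#' Call candidate direct targets by binding-expression integration
#'
#' For every gene, all peaks whose anchor lies within `window` bp of the
#' gene's TSS are counted (a peak may support several neighbouring genes;
#' candidacy is per gene, not a unique peak assignment).  Genes with at
#' least one such peak that are also in the `up` or `down` set of the DEG
#' partition become candidates, labelled via [regulation_class()].
#'
#' @param pk Peak table.
#' @param gm Gene-model table.
#' @param part A `deg_partition` from [select_degs()], built on the same
#'   gene universe.
#' @param mode Perturbation design, `"knockdown"` (default) or
#'   `"overexpression"`.
#' @param window TSS window in bp (default 5000); boundary inclusive
#'   (`|distance| <= window`).
#' @param anchor Peak anchor for the distance (see [tss_distance()]).
#' @param keep `"both"` (default), `"transactivated"` or `"repressed"`;
#'   `"transactivated"` reproduces the usual final filter of an activation
#'   screen.
#' @return An object of class `candidate_targets`: a `data.frame` with
#'   columns `gene_id`, `regulation`, `n_peaks`, `min_abs_tss_distance`,
#'   `log2fc`, `padj`, sorted by (regulation, min_abs_tss_distance,
#'   gene_id).  Attributes carry the funnel counts (`funnel`), the DE genes
#'   absent from the gene models (`dropped_de_genes`), the bound-but-not-
#'   assayed gene list (`bound_not_assayed`) and the parameters used.
#' @export
integrate_targets <- function(pk, gm, part,
                              mode = c("knockdown", "overexpression"),
                              window = 5000,
                              anchor = c("summit", "midpoint",
                                         "nearest_edge"),
                              keep = c("both", "transactivated",
                                       "repressed")) {
  mode <- match.arg(mode)
  anchor <- match.arg(anchor)
  keep <- match.arg(keep)
  stopifnot(inherits(part, "deg_partition"), window >= 0)
  gm <- validate_gene_models(gm)
  pk <- validate_peaks(pk)

  deg <- part$table
  known <- deg$gene_id %in% gm$gene_id
  dropped <- deg$gene_id[!known]
  if (length(dropped)) {
    message(length(dropped),
            " DE gene(s) absent from the gene models were dropped")
  }

  prox <- proximal_pairs(pk, gm, window, anchor)
  bound_genes <- unique(prox$gene_id)

  de_status <- setNames(deg$status, deg$gene_id)
  bound_not_assayed <- setdiff(bound_genes, deg$gene_id)

  cand_ids <- intersect(bound_genes, deg$gene_id[known & deg$status != "unchanged"])
  if (length(cand_ids)) {
    per_gene <- prox[prox$gene_id %in% cand_ids, , drop = FALSE]
    agg_n <- tapply(per_gene$peak_index, per_gene$gene_id, length)
    agg_d <- tapply(abs(per_gene$tss_distance), per_gene$gene_id, min)
    idx <- match(cand_ids, deg$gene_id)
    res <- data.frame(
      gene_id = cand_ids,
      regulation = regulation_class(ifelse(deg$log2fc[idx] > 0, "+", "-"),
                                    mode),
      n_peaks = as.integer(agg_n[cand_ids]),
      min_abs_tss_distance = as.numeric(agg_d[cand_ids]),
      log2fc = deg$log2fc[idx],
      padj = deg$padj[idx],
      stringsAsFactors = FALSE
    )
  } else {
    res <- data.frame(gene_id = character(0), regulation = character(0),
                      n_peaks = integer(0),
                      min_abs_tss_distance = numeric(0),
                      log2fc = numeric(0), padj = numeric(0),
                      stringsAsFactors = FALSE)
  }
  n_both <- nrow(res)
  if (keep != "both") res <- res[res$regulation == keep, , drop = FALSE]
  res <- res[order(res$regulation, res$min_abs_tss_distance, res$gene_id), ,
             drop = FALSE]
  rownames(res) <- NULL

  funnel <- c(
    peaks_in = nrow(pk),
    peaks_tss_proximal = length(unique(prox$peak_index)),
    genes_bound = length(bound_genes),
    degs_up = length(part$up),
    degs_down = length(part$down),
    candidates = n_both,
    candidates_kept = nrow(res)
  )
  structure(res, class = c("candidate_targets", "data.frame"),
            funnel = funnel,
            dropped_de_genes = dropped,
            bound_not_assayed = sort(bound_not_assayed),
            params = list(mode = mode, window = window, anchor = anchor,
                          keep = keep,
                          lfc_threshold = part$lfc_threshold,
                          padj_threshold = part$padj_threshold))
}

# All (peak, gene) pairs with |anchor - TSS| <= window, via an IRanges
# overlap join of TSS windows with peak anchor positions.
proximal_pairs <- function(pk, gm, window, anchor) {
  empty <- data.frame(peak_index = integer(0), gene_id = character(0),
                      tss_distance = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(pk) || !nrow(gm)) return(empty)
  tss <- unname(tss_of(gm))
  apos <- peak_anchor(pk, if (anchor == "nearest_edge") "midpoint" else anchor)
  # 1-based closed coordinates for GRanges
  win <- GenomicRanges::GRanges(
    gm$chrom,
    IRanges::IRanges(start = pmax(tss - window, 0) + 1, end = tss + window + 1))
  pts <- if (anchor == "nearest_edge") {
    GenomicRanges::GRanges(pk$chrom,
                           IRanges::IRanges(start = pk$start + 1, end = pk$end))
  } else {
    GenomicRanges::GRanges(pk$chrom,
                           IRanges::IRanges(start = apos + 1, width = 1))
  }
  hits <- GenomicRanges::findOverlaps(pts, win, ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  pi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  pos <- if (anchor == "nearest_edge") {
    pmin(pmax(tss[gi], pk$start[pi]), pk$end[pi] - 1)
  } else {
    apos[pi]
  }
  d <- (pos - tss[gi]) * ifelse(gm$strand[gi] == "-", -1, 1)
  keep <- abs(d) <= window  # boundary-inclusive, trims the +1 edge padding
  data.frame(peak_index = pi[keep], gene_id = gm$gene_id[gi[keep]],
             tss_distance = d[keep], stringsAsFactors = FALSE)
}

#' @export
print.candidate_targets <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "Candidate direct targets (%s design, window %d bp, anchor %s, keep %s)\n",
    p$mode, p$window, p$anchor, p$keep))
  f <- attr(x, "funnel")
  cat(sprintf(
    "  funnel: %d peaks -> %d TSS-proximal -> %d bound genes; DEGs %d up / %d down -> %d candidates\n",
    f["peaks_in"], f["peaks_tss_proximal"], f["genes_bound"],
    f["degs_up"], f["degs_down"], f["candidates"]))
  print.data.frame(x, ...)
  invisible(x)
}

#' @method summary candidate_targets
#' @export
summary.candidate_targets <- function(object, ...) {
  list(funnel = attr(object, "funnel"),
       params = attr(object, "params"),
       n_transactivated = sum(object$regulation == "transactivated"),
       n_repressed = sum(object$regulation == "repressed"),
       dropped_de_genes = attr(object, "dropped_de_genes"),
       bound_not_assayed = attr(object, "bound_not_assayed"))
}

#' Write candidate targets and run summary
#'
#' @param ct A `candidate_targets` object.
#' @param tsv,summary_json Output paths (either may be `NULL`).
#' @export
write_candidates <- function(ct, tsv = NULL, summary_json = NULL) {
  stopifnot(inherits(ct, "candidate_targets"))
  if (!is.null(tsv)) {
    write.table(as.data.frame(ct), tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(summary_json)) {
    s <- summary(ct)
    jsonlite::write_json(
      list(params = s$params, funnel = as.list(s$funnel),
           n_transactivated = s$n_transactivated,
           n_repressed = s$n_repressed,
           dropped_de_genes = s$dropped_de_genes,
           bound_not_assayed = s$bound_not_assayed),
      summary_json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(ct)
}
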