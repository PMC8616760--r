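# ---------------------------------------------------------------------------
# Strand-aware annotation of peaks against gene models: TSS position, signed
# TSS distance, and promoter/exon/intron/intergenic classification.
# ---------------------------------------------------------------------------

#' Transcription start sites of gene models
#'
#' The TSS is the first transcribed base: `start` for `+` genes and
#' `end - 1` for `-` genes (0-based).  It depends only on the gene body and
#' strand, never on exon structure.
#'
#' @param gm Gene-model table.
#' @return Numeric vector of 0-based TSS positions, named by `gene_id`.
#' @examples
#' gm <- gene_models(c("a", "b"), "chr1", c(100, 100), c(500, 500), c("+", "-"))
#' tss_of(gm)  # a: 100, b: 499
#' @export
tss_of <- function(gm) {
  gm <- validate_gene_models(gm)
  setNames(ifelse(gm$strand == "+", gm$start, gm$end - 1), gm$gene_id)
}

#' Anchor positions of peaks
#'
#' The anchor is the single position used for TSS-distance computation:
#' the recorded summit (midpoint `floor((start + end)/2)` imputed when no
#' summit was called), the midpoint itself, or — for `nearest_edge` — it is
#' resolved per gene inside [tss_distance()].
#'
#' @param pk Peak table.
#' @param anchor `"summit"` or `"midpoint"`.
#' @return Numeric vector of 0-based anchor positions.
#' @export
peak_anchor <- function(pk, anchor = c("summit", "midpoint")) {
  anchor <- match.arg(anchor)
  pk <- validate_peaks(pk)
  mid <- (pk$start + pk$end) %/% 2
  if (anchor == "midpoint") return(mid)
  ifelse(is.na(pk$summit_offset), mid, pk$start + pk$summit_offset)
}

#' Signed distance from peaks to a gene's TSS
#'
#' Distances are reported in the gene's own orientation: negative means
#' upstream of the TSS, positive downstream, for both strands.  With
#' `anchor = "nearest_edge"` the closest position of the peak interval to
#' the TSS is used, so a peak overlapping the TSS is at distance 0.
#'
#' @param pk Peak table (all on the gene's chromosome).
#' @param gene One-row gene-model table (or a row index into `gm`).
#' @param anchor `"summit"`, `"midpoint"` or `"nearest_edge"`.
#' @return Signed numeric vector, one value per peak.
#' @export
tss_distance <- function(pk, gene, anchor = c("summit", "midpoint",
                                              "nearest_edge")) {
  anchor <- match.arg(anchor)
  gene <- validate_gene_models(gene)
  if (nrow(gene) != 1) stop("tss_distance expects a single gene")
  pk <- validate_peaks(pk)
  if (any(pk$chrom != gene$chrom)) {
    stop("peak(s) on a different chromosome than gene ", gene$gene_id,
         "; prefilter by chromosome")
  }
  tss <- unname(tss_of(gene))
  pos <- if (anchor == "nearest_edge") {
    # closest base of [start, end) to the TSS; 0 if the interval covers it
    pmin(pmax(tss, pk$start), pk$end - 1)
  } else {
    peak_anchor(pk, anchor)
  }
  d <- pos - tss
  if (gene$strand == "-") d <- -d
  d
}

#' Classify peaks against gene regulatory features
#'
#' Each peak receives exactly one class with priority
#' promoter > exon > intron > intergenic:
#' \describe{
#'   \item{promoter}{some gene's TSS lies within `promoter_halfwidth` bp of
#'     the peak anchor (`|tss_distance| <= promoter_halfwidth`, boundary
#'     inclusive; upstream-only mode available);}
#'   \item{exon / intron}{the anchor falls inside a gene body, inside /
#'     outside an annotated exon;}
#'   \item{intergenic}{none of the above; no gene is assigned.}
#' }
#' Among several qualifying genes the one with the smallest
#' `|tss_distance|` wins, ties broken by lexicographic `gene_id`.
#'
#' @param pk Peak table.
#' @param gm Gene-model table (may be empty: everything is intergenic).
#' @param promoter_halfwidth Promoter window half-width in bp (default
#'   5000, i.e. "within 5 kb of the TSS").
#' @param anchor Distance anchor, as in [tss_distance()].
#' @param upstream_only If `TRUE`, only peaks upstream of the TSS
#'   (`-halfwidth <= d <= 0`) count as promoter; default is symmetric.
#' @return A `data.frame` with one row per peak: `peak_index`, `chrom`,
#'   `start`, `end`, `name`, `gene_id` (`NA` for intergenic),
#'   `tss_distance` (`NA` for intergenic), `feature_class`.
#' @export
classify_peaks <- function(pk, gm, promoter_halfwidth = 5000,
                           anchor = c("summit", "midpoint", "nearest_edge"),
                           upstream_only = FALSE) {
  anchor <- match.arg(anchor)
  pk <- validate_peaks(pk)
  n <- nrow(pk)
  out <- data.frame(
    peak_index = seq_len(n),
    chrom = pk$chrom, start = pk$start, end = pk$end, name = pk$name,
    gene_id = rep(NA_character_, n), tss_distance = rep(NA_real_, n),
    feature_class = rep("intergenic", n),
    stringsAsFactors = FALSE
  )
  if (is.null(gm) || nrow(gm) == 0 || n == 0) return(out)
  gm <- validate_gene_models(gm)
  tss <- unname(tss_of(gm))
  sign <- ifelse(gm$strand == "-", -1, 1)
  apos <- peak_anchor(pk, if (anchor == "nearest_edge") "midpoint" else anchor)
  for (i in seq_len(n)) {
    on_chrom <- which(gm$chrom == pk$chrom[i])  # exact string match
    if (!length(on_chrom)) next
    pos <- if (anchor == "nearest_edge") {
      # closest base of the interval to each gene's TSS
      pmin(pmax(tss[on_chrom], pk$start[i]), pk$end[i] - 1)
    } else {
      rep(apos[i], length(on_chrom))
    }
    d <- (pos - tss[on_chrom]) * sign[on_chrom]
    in_prom <- if (upstream_only) d >= -promoter_halfwidth & d <= 0 else
      abs(d) <= promoter_halfwidth
    pick <- function(idx) idx[order(abs(d[idx]), gm$gene_id[on_chrom][idx])][1]
    if (any(in_prom)) {
      j <- pick(which(in_prom))
      out$gene_id[i] <- gm$gene_id[on_chrom][j]
      out$tss_distance[i] <- d[j]
      out$feature_class[i] <- "promoter"
      next
    }
    in_body <- apos[i] >= gm$start[on_chrom] & apos[i] < gm$end[on_chrom]
    if (any(in_body)) {
      j <- pick(which(in_body))
      g <- on_chrom[j]
      ex <- gm$exons[[g]]
      in_exon <- nrow(ex) > 0 && any(apos[i] >= ex$start & apos[i] < ex$end)
      out$gene_id[i] <- gm$gene_id[g]
      out$tss_distance[i] <- d[j]
      out$feature_class[i] <- if (in_exon) "exon" else "intron"
    }
  }
  out
}

#' Summarise feature classes
#'
#' @param ann Output of [classify_peaks()].
#' @return Named integer vector of counts over
#'   promoter/exon/intron/intergenic (always all four names; counts sum to
#'   the number of peaks).
#' @export
feature_class_counts <- function(ann) {
  lv <- c("promoter", "exon", "intron", "intergenic")
  tab <- table(factor(ann$feature_class, levels = lv))
  setNames(as.integer(tab), lv)
}

#' Annotate peaks and write TSV + JSON summary
#'
#' Convenience wrapper around [classify_peaks()] that also writes the
#' per-peak annotation table and a feature-class count summary.
#'
#' @inheritParams classify_peaks
#' @param out_tsv,out_json Optional output paths.
#' @return The annotation `data.frame`, invisibly when writing.
#' @export
annotate_peaks <- function(pk, gm, promoter_halfwidth = 5000,
                           anchor = "summit", upstream_only = FALSE,
                           out_tsv = NULL, out_json = NULL) {
  ann <- classify_peaks(pk, gm, promoter_halfwidth, anchor, upstream_only)
  if (!is.null(out_tsv)) {
    write.table(ann, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(anchor = anchor, promoter_halfwidth = promoter_halfwidth,
           upstream_only = upstream_only,
           feature_class_counts = as.list(feature_class_counts(ann))),
      out_json, auto_unbox = TRUE, pretty = TRUE)
  }
  if (is.null(out_tsv) && is.null(out_json)) ann else invisible(ann)
}
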