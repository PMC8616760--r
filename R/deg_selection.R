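# ---------------------------------------------------------------------------
# Differential-expression gene selection: strict fold-change and adjusted-P
# cutoffs partition the DE table into up / down / unchanged.
# ---------------------------------------------------------------------------

#' log2 fold-change cutoff for a linear fold change
#'
#' A ">1.5-fold" differential-expression criterion corresponds to a log2
#' fold-change cutoff of `log2(1.5) = 0.585` (3 dp), the package default.
#'
#' @param fold Linear fold change, `> 1`.
#' @return `log2(fold)`.
#' @examples
#' lfc_for_fold(1.5)  # 0.585 at 3 decimals
#' lfc_for_fold(2)    # 1
#' @export
lfc_for_fold <- function(fold) {
  if (!is.numeric(fold) || any(fold <= 1)) {
    stop("fold must be > 1 (a fold change of 1 means no change)")
  }
  log2(fold)
}

#' Select differentially expressed genes
#'
#' Partitions a DE table into `up`, `down` and `unchanged` using strict
#' inequalities: up means `log2fc > lfc_threshold` and
#' `padj < padj_threshold`; down means `log2fc < -lfc_threshold` and
#' `padj < padj_threshold`; everything else is unchanged.  Genes exactly on
#' a threshold are excluded.  Defaults are the 1.5-fold (`log2fc` beyond
#' ±0.585) and adjusted-P < 0.05 criteria.
#'
#' @param deg DE table (`gene_id`, `log2fc`, `padj`).
#' @param lfc_threshold Positive log2 fold-change cutoff (default 0.585).
#' @param padj_threshold Adjusted-P cutoff in (0, 1] (default 0.05).
#' @return An object of class `deg_partition`: a list with character
#'   vectors `up`, `down`, `unchanged`, the annotated `table` (extra column
#'   `status`), and the thresholds used.
#' @examples
#' deg <- data.frame(gene_id = c("a", "b", "c"),
#'                   log2fc = c(0.9, -1.2, 0.585), padj = c(0.01, 0.2, 0.001))
#' select_degs(deg)
#' @export
select_degs <- function(deg, lfc_threshold = 0.585, padj_threshold = 0.05) {
  deg <- validate_deg_table(deg)
  if (!nrow(deg)) stop("empty DE table")
  stopifnot(length(lfc_threshold) == 1, lfc_threshold > 0,
            length(padj_threshold) == 1, padj_threshold > 0,
            padj_threshold <= 1)
  sig <- deg$padj < padj_threshold
  up <- sig & deg$log2fc > lfc_threshold
  down <- sig & deg$log2fc < -lfc_threshold
  deg$status <- ifelse(up, "up", ifelse(down, "down", "unchanged"))
  structure(list(
    up = deg$gene_id[up],
    down = deg$gene_id[down],
    unchanged = deg$gene_id[!up & !down],
    table = deg,
    lfc_threshold = lfc_threshold,
    padj_threshold = padj_threshold
  ), class = "deg_partition")
}

#' @export
print.deg_partition <- function(x, ...) {
  cat("DEG selection (|log2FC| >", format(x$lfc_threshold),
      ", padj <", format(x$padj_threshold), ", strict)\n")
  cat(sprintf("  up: %d   down: %d   unchanged: %d   (total %d)\n",
              length(x$up), length(x$down), length(x$unchanged),
              nrow(x$table)))
  invisible(x)
}

#' Write DEG selection results
#'
#' Writes up/down gene lists (one id per line) and a JSON summary with the
#' thresholds and counts.
#'
#' @param part A `deg_partition`.
#' @param up_file,down_file,summary_json Output paths (any may be `NULL`).
#' @export
write_deg_selection <- function(part, up_file = NULL, down_file = NULL,
                                summary_json = NULL) {
  stopifnot(inherits(part, "deg_partition"))
  if (!is.null(up_file)) writeLines(part$up, up_file)
  if (!is.null(down_file)) writeLines(part$down, down_file)
  if (!is.null(summary_json)) {
    jsonlite::write_json(list(
      lfc_threshold = part$lfc_threshold,
      padj_threshold = part$padj_threshold,
      n_up = length(part$up), n_down = length(part$down),
      n_unchanged = length(part$unchanged), n_total = nrow(part$table)
    ), summary_json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(part)
}
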