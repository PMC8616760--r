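# ---------------------------------------------------------------------------
# Orchestration: one entry point that runs annotate -> select-degs ->
# integrate from a single parameter source and emits a machine-readable run
# report mirroring the screen's filter funnel.
# ---------------------------------------------------------------------------

pipeline_defaults <- function() {
  list(mode = "knockdown", window = 5000, lfc_threshold = 0.585,
       padj_threshold = 0.05, anchor = "summit", keep = "both",
       promoter_halfwidth = 5000, upstream_only = FALSE)
}

#' Run the full target-calling pipeline
#'
#' Reads gene models, peaks and a DE table (or takes the in-memory
#' objects), runs peak annotation, DEG selection and binding-expression
#' integration under one parameter source, and returns a run report.
#' Parameter precedence: arguments in `...` > `config` (a named list or a
#' YAML file path) > package defaults (0.585 / 0.05 / 5000 bp /
#' knockdown).
#'
#' @param genes Gene-model table or path to GFF3/BED12.
#' @param peaks Peak table or path to BED.
#' @param deg DE table or path to TSV.
#' @param config Named list or YAML file of parameters (see
#'   [run_pipeline()] details); `NULL` for defaults.
#' @param out_dir Optional output directory: writes `annotation.tsv`,
#'   `candidates.tsv` and `report.json`.
#' @param ... Individual parameter overrides: `mode`, `window`,
#'   `lfc_threshold`, `padj_threshold`, `anchor`, `keep`,
#'   `promoter_halfwidth`, `upstream_only`.
#' @return An object of class `run_report`: a list with `params`,
#'   `funnel` (stage-by-stage counts), `feature_class_counts`,
#'   `candidates` (the `candidate_targets` table), `dropped_de_genes`,
#'   `bound_not_assayed`, `inputs` (paths and md5 digests where file-backed)
#'   and `version`.
#' @export
run_pipeline <- function(genes, peaks, deg, config = NULL, out_dir = NULL,
                         ...) {
  cfg <- pipeline_defaults()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown)) {
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    }
    cfg <- utils::modifyList(cfg, config)
  }
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    cfg <- utils::modifyList(cfg, overrides)
  }
  cfg$mode <- match.arg(cfg$mode, c("knockdown", "overexpression"))
  cfg$keep <- match.arg(cfg$keep, c("both", "transactivated", "repressed"))
  cfg$anchor <- match.arg(cfg$anchor, c("summit", "midpoint", "nearest_edge"))
  stopifnot(cfg$window >= 0, cfg$lfc_threshold > 0,
            cfg$padj_threshold > 0, cfg$padj_threshold <= 1)

  inputs <- list()
  load_input <- function(x, reader, label) {
    if (is.character(x)) {
      inputs[[label]] <<- list(path = x,
                               md5 = unname(tools::md5sum(x)))
      reader(x)
    } else {
      inputs[[label]] <<- list(path = NA, md5 = NA)
      x
    }
  }
  gm <- load_input(genes, read_gene_models, "genes")
  pk <- load_input(peaks, read_peaks, "peaks")
  dg <- load_input(deg, read_deg_table, "deg")

  ann <- classify_peaks(pk, gm, cfg$promoter_halfwidth, cfg$anchor,
                        cfg$upstream_only)
  part <- select_degs(dg, cfg$lfc_threshold, cfg$padj_threshold)
  ct <- integrate_targets(pk, gm, part, mode = cfg$mode,
                          window = cfg$window, anchor = cfg$anchor,
                          keep = cfg$keep)

  report <- structure(list(
    params = cfg,
    funnel = attr(ct, "funnel"),
    feature_class_counts = feature_class_counts(ann),
    candidates = ct,
    annotation = ann,
    dropped_de_genes = attr(ct, "dropped_de_genes"),
    bound_not_assayed = attr(ct, "bound_not_assayed"),
    inputs = inputs,
    version = as.character(packageVersion("tfscreen"))
  ), class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(ann, file.path(out_dir, "annotation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_candidates(ct, tsv = file.path(out_dir, "candidates.tsv"))
    write_run_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Write a run report as JSON
#'
#' The report body is deterministic for identical inputs and parameters;
#' the wall-clock timestamp is the only run-specific field.
#'
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @param timestamp Include a timestamp field (default `TRUE`).
#' @export
write_run_report <- function(report, path, timestamp = TRUE) {
  stopifnot(inherits(report, "run_report"))
  body <- list(
    version = report$version,
    params = report$params,
    inputs = report$inputs,
    funnel = as.list(report$funnel),
    feature_class_counts = as.list(report$feature_class_counts),
    n_candidates = nrow(report$candidates),
    candidates = as.data.frame(report$candidates),
    dropped_de_genes = report$dropped_de_genes,
    bound_not_assayed = report$bound_not_assayed
  )
  if (timestamp) body$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(body, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("tfscreen run report (v", x$version, ")\n", sep = "")
  cat(sprintf("  mode=%s window=%d lfc>%g padj<%g anchor=%s keep=%s\n",
              x$params$mode, x$params$window, x$params$lfc_threshold,
              x$params$padj_threshold, x$params$anchor, x$params$keep))
  f <- x$funnel
  cat(sprintf("  funnel: %d peaks -> %d TSS-proximal -> %d bound genes\n",
              f["peaks_in"], f["peaks_tss_proximal"], f["genes_bound"]))
  cat(sprintf("          DEGs: %d up, %d down -> %d candidates (%d kept)\n",
              f["degs_up"], f["degs_down"], f["candidates"],
              f["candidates_kept"]))
  cc <- x$feature_class_counts
  cat("  peak features:", paste(names(cc), cc, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}
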