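#' @importFrom utils read.table write.table packageVersion head
#' @importFrom stats cor lm coef predict rnorm runif setNames
NULL

# ---------------------------------------------------------------------------
# Internal containers.
#
# All coordinates inside the package are 0-based half-open on the forward
# strand ([start, end), end exclusive).  GFF3 (1-based inclusive) is
# converted at the boundary; BED passes through unchanged.  A single
# convention internally removes any chance of off-by-one drift between the
# annotation, integration and simulation stages.
# ---------------------------------------------------------------------------

#' Construct a gene-model table
#'
#' A gene model records a gene's body interval, strand and (optionally) its
#' exons.  The transcription start site (TSS) is derived from body and
#' strand: `start` on `+`, `end - 1` on `-`.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Chromosome name per gene.
#' @param start,end Integer body coordinates, 0-based half-open.
#' @param strand `"+"` or `"-"` per gene; unstranded genes are not allowed
#'   because the TSS would be undefined.
#' @param name Display symbol; defaults to `gene_id`.
#' @param exons Optional list, one element per gene, each a data frame with
#'   `start`/`end` columns (0-based half-open) lying within the body and
#'   mutually non-overlapping.  `NULL` means no exon structure.
#' @return A `data.frame` with columns `gene_id`, `name`, `chrom`, `start`,
#'   `end`, `strand` and a list column `exons`.
#' @examples
#' gene_models("g1", "chr1", 100, 500, "+")
#' @export
gene_models <- function(gene_id, chrom, start, end, strand,
                        name = gene_id, exons = NULL) {
  n <- length(gene_id)
  if (is.null(exons)) {
    exons <- rep(list(empty_exons()), n)
  }
  gm <- data.frame(
    gene_id = as.character(gene_id),
    name = as.character(name),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  gm$exons <- exons
  validate_gene_models(gm)
}

empty_exons <- function() {
  data.frame(start = numeric(0), end = numeric(0))
}

validate_gene_models <- function(gm) {
  stopifnot(is.data.frame(gm))
  required <- c("gene_id", "name", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(gm))
  if (length(missing)) {
    stop("gene model table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(gm$exons)) gm$exons <- rep(list(empty_exons()), nrow(gm))
  if (anyNA(gm$start) || anyNA(gm$end)) stop("gene coordinates contain NA")
  bad <- which(!(gm$start >= 0 & gm$start < gm$end))
  if (length(bad)) {
    stop("invalid gene interval (need 0 <= start < end) for gene(s): ",
         paste(gm$gene_id[bad], collapse = ", "))
  }
  if (any(!nzchar(gm$chrom))) stop("empty chromosome name in gene models")
  bad <- which(!gm$strand %in% c("+", "-"))
  if (length(bad)) {
    stop("strandless or invalid strand for gene(s): ",
         paste(gm$gene_id[bad], collapse = ", "),
         " (gene models must be stranded so the TSS is defined)")
  }
  dup <- unique(gm$gene_id[duplicated(gm$gene_id)])
  if (length(dup)) {
    stop("duplicated gene_id in gene models: ", paste(dup, collapse = ", "))
  }
  for (i in seq_len(nrow(gm))) {
    ex <- gm$exons[[i]]
    if (!nrow(ex)) next
    ex <- ex[order(ex$start), , drop = FALSE]
    if (any(ex$start < gm$start[i]) || any(ex$end > gm$end[i]) ||
        any(ex$start >= ex$end)) {
      stop("exons outside body (or empty) for gene ", gm$gene_id[i])
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("overlapping exons for gene ", gm$gene_id[i])
    }
    gm$exons[[i]] <- ex
  }
  gm
}

#' Construct a ChIP-seq peak table
#'
#' @param chrom,start,end Peak interval, 0-based half-open.
#' @param name Optional peak name (defaults to `peak_<i>`).
#' @param score Optional non-negative score (`NA` allowed).
#' @param summit_offset Optional offset (bp) of the peak summit from
#'   `start`; `NA` means no summit was reported, in which case downstream
#'   code imputes the interval midpoint `floor((start + end) / 2)`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `summit_offset`, input order preserved.
#' @examples
#' peak_table("chr1", 1000, 1400)
#' @export
peak_table <- function(chrom, start, end, name = NULL, score = NA_real_,
                       summit_offset = NA_real_) {
  n <- max(length(chrom), length(start), length(end))
  if (!length(start)) n <- 0
  if (is.null(name)) name <- if (n) paste0("peak_", seq_len(n)) else character(0)
  pk <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    name = as.character(name),
    score = rep_len(as.numeric(score), n),
    summit_offset = rep_len(as.numeric(summit_offset), n),
    stringsAsFactors = FALSE
  )
  validate_peaks(pk)
}

validate_peaks <- function(pk) {
  stopifnot(is.data.frame(pk))
  required <- c("chrom", "start", "end")
  missing <- setdiff(required, names(pk))
  if (length(missing)) {
    stop("peak table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"name" %in% names(pk)) pk$name <- paste0("peak_", seq_len(nrow(pk)))
  if (!"score" %in% names(pk)) pk$score <- NA_real_
  if (!"summit_offset" %in% names(pk)) pk$summit_offset <- NA_real_
  if (any(pk$start < 0)) {
    stop("negative peak coordinate at row(s): ",
         paste(which(pk$start < 0), collapse = ", "))
  }
  bad <- which(!(pk$start < pk$end))
  if (length(bad)) {
    stop("peak start >= end at row(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.na(pk$score) & pk$score < 0)) stop("negative peak score")
  so <- pk$summit_offset
  bad <- which(!is.na(so) & (so < 0 | so >= pk$end - pk$start))
  if (length(bad)) {
    stop("summit outside peak interval at row(s): ",
         paste(bad, collapse = ", "))
  }
  pk
}

validate_deg_table <- function(deg) {
  stopifnot(is.data.frame(deg))
  required <- c("gene_id", "log2fc", "padj")
  missing <- setdiff(required, names(deg))
  if (length(missing)) {
    stop("DE table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!nzchar(deg$gene_id))) stop("empty gene_id in DE table")
  dup <- unique(deg$gene_id[duplicated(deg$gene_id)])
  if (length(dup)) {
    stop("duplicated gene_id in DE table: ", paste(dup, collapse = ", "))
  }
  if (anyNA(deg$log2fc) || anyNA(deg$padj)) {
    stop("NA log2fc/padj in DE table (non-numeric input?)")
  }
  bad <- which(deg$padj < 0 | deg$padj > 1)
  if (length(bad)) {
    stop("padj outside [0, 1] at row(s): ", paste(bad, collapse = ", "))
  }
  deg
}

# ---------------------------------------------------------------------------
# Readers / writers.  GFF3 and BED12 go through rtracklayer; the peak BED3+
# dialect (free-position summit column) and header-named TSV tables are read
# directly.
# ---------------------------------------------------------------------------

#' Read gene models from GFF3 or BED12
#'
#' GFF3 input uses `gene`-type records for bodies (attribute `ID` as
#' `gene_id`, `Name` as display symbol when present) and `exon` records tied
#' to their gene via `Parent`.  BED12 input takes the whole line as the body
#' and the block structure as exons.  Coordinates are normalised to the
#' package's 0-based half-open convention (GFF3 converted, BED passed
#' through).  Strandless genes are rejected.
#'
#' @param path File path.
#' @param format `"gff3"` or `"bed12"`; default guessed from the extension.
#' @return A validated gene-model `data.frame` (see [gene_models()]).
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gff3"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    meta <- S4Vectors::mcols(gr)
    is_gene <- meta$type == "gene"
    genes <- gr[is_gene]
    gmeta <- S4Vectors::mcols(genes)
    if (!length(genes)) stop("no gene-type records in ", path)
    strand_chr <- as.character(BiocGenerics::strand(genes))
    ids <- as.character(gmeta$ID)
    nm <- if (!is.null(gmeta$Name)) as.character(gmeta$Name) else ids
    nm[is.na(nm)] <- ids[is.na(nm)]
    exons <- rep(list(empty_exons()), length(genes))
    ex_gr <- gr[meta$type == "exon"]
    if (length(ex_gr)) {
      parent <- as.character(unlist(S4Vectors::mcols(ex_gr)$Parent))
      for (i in seq_along(genes)) {
        sel <- parent == ids[i]
        if (any(sel)) {
          exons[[i]] <- data.frame(
            start = BiocGenerics::start(ex_gr)[sel] - 1,
            end = BiocGenerics::end(ex_gr)[sel]
          )
        }
      }
    }
    gene_models(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(genes)),
      start = BiocGenerics::start(genes) - 1,  # GFF3 1-based inclusive
      end = BiocGenerics::end(genes),
      strand = strand_chr,
      name = nm,
      exons = exons
    )
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (!length(gr)) stop("no records in ", path)
    meta <- S4Vectors::mcols(gr)
    ids <- if (!is.null(meta$name)) as.character(meta$name) else
      paste0("gene_", seq_along(gr))
    exons <- rep(list(empty_exons()), length(gr))
    if (!is.null(meta$blocks)) {
      for (i in seq_along(gr)) {
        bl <- meta$blocks[[i]]
        if (length(bl)) {
          # blocks are relative 1-based within the BED line
          exons[[i]] <- data.frame(
            start = BiocGenerics::start(gr)[i] - 1 + BiocGenerics::start(bl) - 1,
            end = BiocGenerics::start(gr)[i] - 1 + BiocGenerics::end(bl)
          )
        }
      }
    }
    gene_models(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr) - 1,
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      name = ids,
      exons = exons
    )
  }
}

#' Write gene models to GFF3 or BED12
#'
#' Inverse of [read_gene_models()]; a write/read round trip reproduces
#' coordinates, strand, identifiers and exon structure exactly.
#'
#' @param gm Gene-model table.
#' @param path Output path.
#' @param format `"gff3"` or `"bed12"`.
#' @export
write_gene_models <- function(gm, path, format = c("gff3", "bed12")) {
  format <- match.arg(format)
  gm <- validate_gene_models(gm)
  if (format == "gff3") {
    lines <- c("##gff-version 3")
    for (i in seq_len(nrow(gm))) {
      lines <- c(lines, paste(
        gm$chrom[i], "tfscreen", "gene",
        format(gm$start[i] + 1, scientific = FALSE),
        format(gm$end[i], scientific = FALSE),
        ".", gm$strand[i], ".",
        sprintf("ID=%s;Name=%s", gm$gene_id[i], gm$name[i]),
        sep = "\t"))
      ex <- gm$exons[[i]]
      if (nrow(ex)) {
        lines <- c(lines, paste(
          gm$chrom[i], "tfscreen", "exon",
          format(ex$start + 1, scientific = FALSE),
          format(ex$end, scientific = FALSE),
          ".", gm$strand[i], ".",
          sprintf("ID=%s.exon%d;Parent=%s", gm$gene_id[i],
                  seq_len(nrow(ex)), gm$gene_id[i]),
          sep = "\t"))
      }
    }
    writeLines(lines, path)
  } else {
    lines <- vapply(seq_len(nrow(gm)), function(i) {
      ex <- gm$exons[[i]]
      if (!nrow(ex)) ex <- data.frame(start = gm$start[i], end = gm$end[i])
      paste(gm$chrom[i],
            format(gm$start[i], scientific = FALSE),
            format(gm$end[i], scientific = FALSE),
            gm$gene_id[i], 0, gm$strand[i],
            format(gm$start[i], scientific = FALSE),
            format(gm$start[i], scientific = FALSE),
            "0", nrow(ex),
            paste0(format(ex$end - ex$start, scientific = FALSE,
                          trim = TRUE), collapse = ","),
            paste0(format(ex$start - gm$start[i], scientific = FALSE,
                          trim = TRUE), collapse = ","),
            sep = "\t")
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read ChIP-seq peaks from BED3+
#'
#' Accepts plain BED3, BED with name/score columns, and peak-caller outputs
#' carrying an absolute summit position in an extra column (`summit_col`).
#' Input order is preserved; records violating the peak invariants
#' (`start >= end`, negative coordinates, summit outside the interval) are
#' rejected, never repaired.
#'
#' @param path File path.
#' @param summit_col Optional 1-based column index holding the absolute
#'   summit position; stored as an offset from `start`.
#' @param score_col Column index of the score (default 5 when present).
#' @return A validated peak `data.frame` (see [peak_table()]).
#' @export
read_peaks <- function(path, summit_col = NULL, score_col = 5L) {
  raw <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", comment.char = "#",
                    quote = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("peak BED needs at least 3 columns: ", path)
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      stop("non-numeric ", what, " at line(s): ",
           paste(which(is.na(v)), collapse = ", "))
    }
    v
  }
  start <- num(raw[[2]], "start")
  end <- num(raw[[3]], "end")
  name <- if (ncol(raw) >= 4) raw[[4]] else paste0("peak_", seq_len(nrow(raw)))
  score <- if (!is.null(score_col) && ncol(raw) >= score_col) {
    suppressWarnings(as.numeric(raw[[score_col]]))
  } else NA_real_
  summit <- NA_real_
  if (!is.null(summit_col)) {
    if (ncol(raw) < summit_col) stop("summit column ", summit_col, " absent")
    summit <- num(raw[[summit_col]], "summit") - start
  }
  peak_table(raw[[1]], start, end, name = name, score = score,
             summit_offset = summit)
}

#' Write peaks as BED
#'
#' Emits `chrom start end name score strand` plus, when any summit is
#' recorded, a seventh column with the absolute summit position so that
#' `read_peaks(..., summit_col = 7)` round-trips losslessly.
#'
#' @param pk Peak table.
#' @param path Output path.
#' @export
write_peaks <- function(pk, path) {
  pk <- validate_peaks(pk)
  score <- ifelse(is.na(pk$score), 0, pk$score)
  cols <- list(pk$chrom,
               format(pk$start, scientific = FALSE, trim = TRUE),
               format(pk$end, scientific = FALSE, trim = TRUE),
               pk$name, format(score, trim = TRUE), ".")
  if (any(!is.na(pk$summit_offset))) {
    mid <- (pk$start + pk$end) %/% 2
    abs_summit <- ifelse(is.na(pk$summit_offset), mid,
                         pk$start + pk$summit_offset)
    cols <- c(cols, list(format(abs_summit, scientific = FALSE, trim = TRUE)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Tab-separated with a header; column names are configurable so the output
#' of any DE engine can be consumed directly (the pipeline never refits the
#' DE model, it only filters the reported effect sizes and adjusted P
#' values).
#'
#' @param path File path.
#' @param gene_col,lfc_col,padj_col Header names of the identifier, log2
#'   fold-change (perturbed vs control) and adjusted-P columns.
#' @return A validated `data.frame` with columns `gene_id`, `log2fc`, `padj`.
#' @export
read_deg_table <- function(path, gene_col = "gene_id", lfc_col = "log2fc",
                           padj_col = "padj") {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (cn in c(gene_col, lfc_col, padj_col)) {
    if (!cn %in% names(tab)) stop("DE table lacks column '", cn, "'")
  }
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      stop("non-numeric ", what, " at row(s): ",
           paste(which(is.na(v)), collapse = ", "))
    }
    v
  }
  validate_deg_table(data.frame(
    gene_id = tab[[gene_col]],
    log2fc = num(tab[[lfc_col]], lfc_col),
    padj = num(tab[[padj_col]], padj_col),
    stringsAsFactors = FALSE
  ))
}

#' Write a differential-expression table
#' @param deg DE table with `gene_id`, `log2fc`, `padj`.
#' @param path Output path.
#' @export
write_deg_table <- function(deg, path) {
  deg <- validate_deg_table(deg)
  write.table(deg[c("gene_id", "log2fc", "padj")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' Sequences are upper-cased on ingestion and checked against the
#' `{A,C,G,T,N}` alphabet.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  if (any(!nchar(seqs))) stop("empty sequence in ", path)
  seqs
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
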