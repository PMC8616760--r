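# Independent oracles, deliberately written with none of the package's
# internals: naive per-base scanners and double loops against which the
# vectorised / overlap-join implementations are checked.

# -- IUPAC motif scan: O(n * m) position-by-position comparison ------------
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

naive_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

naive_scan <- function(seq, motif, both_strands = TRUE) {
  seq_chars <- strsplit(toupper(seq), "")[[1]]
  scan_one <- function(pat, strand) {
    pat_chars <- strsplit(toupper(pat), "")[[1]]
    m <- length(pat_chars)
    n <- length(seq_chars)
    hits <- list()
    for (i in seq_len(max(0, n - m + 1))) {
      window <- seq_chars[i:(i + m - 1)]
      ok <- TRUE
      for (j in seq_len(m)) {
        # subject N never matches anything
        if (window[j] == "N" || !(window[j] %in% iupac_sets[[pat_chars[j]]])) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        hits[[length(hits) + 1]] <- data.frame(
          position = i - 1, strand = strand,
          matched = paste(window, collapse = ""), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(list(data.frame(position = integer(0),
                                     strand = character(0),
                                     matched = character(0),
                                     stringsAsFactors = FALSE)), hits))
  }
  out <- scan_one(motif, "+")
  if (both_strands) {
    rc <- naive_revcomp(toupper(motif))
    if (rc != toupper(motif)) out <- rbind(out, scan_one(rc, "-"))
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# -- per-pair TSS distance and classification ------------------------------
brute_tss <- function(gene_row) {
  if (gene_row$strand == "+") gene_row$start else gene_row$end - 1
}

brute_anchor <- function(peak_row, anchor, tss = NULL) {
  if (anchor == "nearest_edge") {
    return(min(max(tss, peak_row$start), peak_row$end - 1))
  }
  if (anchor == "summit" && !is.na(peak_row$summit_offset)) {
    return(peak_row$start + peak_row$summit_offset)
  }
  (peak_row$start + peak_row$end) %/% 2
}

brute_tss_distance <- function(peak_row, gene_row, anchor = "summit") {
  tss <- brute_tss(gene_row)
  pos <- brute_anchor(peak_row, anchor, tss)
  d <- pos - tss
  if (gene_row$strand == "-") d <- -d
  d
}

brute_classify_one <- function(peak_row, gm, halfwidth, anchor = "summit",
                               upstream_only = FALSE) {
  best <- list(gene_id = NA_character_, d = NA_real_, class = "intergenic")
  cand <- list()
  for (g in seq_len(nrow(gm))) {
    if (gm$chrom[g] != peak_row$chrom) next
    d <- brute_tss_distance(peak_row, gm[g, , drop = FALSE], anchor)
    ok <- if (upstream_only) d >= -halfwidth && d <= 0 else abs(d) <= halfwidth
    if (ok) cand[[length(cand) + 1]] <- list(g = g, d = d)
  }
  if (length(cand)) {
    ds <- vapply(cand, `[[`, numeric(1), "d")
    ids <- gm$gene_id[vapply(cand, `[[`, numeric(1), "g")]
    j <- order(abs(ds), ids)[1]
    return(list(gene_id = ids[j], d = ds[j], class = "promoter"))
  }
  apos <- brute_anchor(peak_row, if (anchor == "nearest_edge") "midpoint" else anchor)
  for (g in seq_len(nrow(gm))) {
    if (gm$chrom[g] != peak_row$chrom) next
    if (apos >= gm$start[g] && apos < gm$end[g]) {
      d <- brute_tss_distance(peak_row, gm[g, , drop = FALSE], anchor)
      cand[[length(cand) + 1]] <- list(g = g, d = d)
    }
  }
  if (!length(cand)) return(best)
  ds <- vapply(cand, `[[`, numeric(1), "d")
  gs <- vapply(cand, `[[`, numeric(1), "g")
  ids <- gm$gene_id[gs]
  j <- order(abs(ds), ids)[1]
  ex <- gm$exons[[gs[j]]]
  in_exon <- nrow(ex) > 0 && any(apos >= ex$start & apos < ex$end)
  list(gene_id = ids[j], d = ds[j],
       class = if (in_exon) "exon" else "intron")
}

# -- double-loop target integration ----------------------------------------
brute_integrate <- function(pk, gm, deg, mode = "knockdown", window = 5000,
                            anchor = "summit", lfc_threshold = 0.585,
                            padj_threshold = 0.05) {
  rows <- list()
  for (g in seq_len(nrow(gm))) {
    gene <- gm[g, , drop = FALSE]
    n_peaks <- 0
    min_d <- Inf
    for (p in seq_len(nrow(pk))) {
      if (pk$chrom[p] != gene$chrom) next
      d <- brute_tss_distance(pk[p, , drop = FALSE], gene, anchor)
      if (abs(d) <= window) {
        n_peaks <- n_peaks + 1
        min_d <- min(min_d, abs(d))
      }
    }
    if (n_peaks == 0) next
    i <- match(gene$gene_id, deg$gene_id)
    if (is.na(i)) next
    up <- deg$log2fc[i] > lfc_threshold && deg$padj[i] < padj_threshold
    down <- deg$log2fc[i] < -lfc_threshold && deg$padj[i] < padj_threshold
    if (!up && !down) next
    reg <- if (mode == "knockdown") {
      if (down) "transactivated" else "repressed"
    } else {
      if (up) "transactivated" else "repressed"
    }
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = gene$gene_id, regulation = reg, n_peaks = n_peaks,
      min_abs_tss_distance = min_d, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), regulation = character(0),
                      n_peaks = integer(0),
                      min_abs_tss_distance = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$gene_id), , drop = FALSE]
}

# -- Fisher 2x2 via raw choose() over all tables with the same margins -----
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  tab_prob <- function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }
  xs <- max(0, c1 - r2):min(c1, r1)
  probs <- vapply(xs, tab_prob, numeric(1))
  p_obs <- probs[match(a, xs)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# -- random small instances -------------------------------------------------
random_gene_models <- function(n, chrom = "chr1", span = 1e6, seed) {
  set.seed(seed)
  lens <- sample(500:5000, n, replace = TRUE)
  starts <- sort(sample.int(span - max(lens), n))
  gene_models(sprintf("rg%03d", seq_len(n)), chrom, starts, starts + lens,
              sample(c("+", "-"), n, replace = TRUE))
}

random_peaks <- function(n, chrom = "chr1", span = 1e6, seed) {
  set.seed(seed)
  w <- sample(100:1000, n, replace = TRUE)
  s <- sample.int(span, n)
  peak_table(chrom, s, s + w,
             summit_offset = ifelse(runif(n) < 0.5, NA,
                                    floor(runif(n) * w)))
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
}
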