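# ---------------------------------------------------------------------------
# Synthetic inputs with planted ground truth: a genome with non-overlapping
# annotated genes, ChIP-seq peaks planted near target TSSs (background peaks
# kept out of a TSS exclusion zone), a DE table whose planted targets carry
# design-concordant effects, and median-effect dose-response curves with
# known (m, Dm).  One study seed fans out to fixed per-component substreams
# so regenerating one file never perturbs another.
# ---------------------------------------------------------------------------

# Deterministic substream seed below 2^31, derived from the study seed and a
# fixed component label.
sub_seed <- function(seed, label) {
  stopifnot(length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(as.numeric(seed)) * 32749 + h * 611953) %% 2147483647)
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic genome with annotated genes
#'
#' Genes of random length are placed without overlap (uniformly over the
#' feasible arrangements, by partitioning the slack between them), each with
#' a Bernoulli(0.5) strand and a small number of non-overlapping exons.
#' The genome sequence is i.i.d. uniform over A/C/G/T.  Fully deterministic
#' given `seed`.
#'
#' @param n_genes Number of genes (0 allowed: empty gene list, genome still
#'   emitted).
#' @param chrom_length_bp Chromosome length (default 5 Mb, comfortably
#'   holding 100 genes plus intergenic background space).
#' @param min_gene_len,max_gene_len Gene-length range in bp.
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @param with_sequence Emit the genome sequence (default `TRUE`; turn off
#'   to save memory when only coordinates are needed).
#' @return A list with `genes` (gene-model table) and `genome` (named
#'   character vector of length 1, or `NULL`).
#' @export
generate_genome <- function(n_genes = 100, chrom_length_bp = 5e6,
                            min_gene_len = 2000, max_gene_len = 10000,
                            seed = 1, chrom = "chr1", with_sequence = TRUE) {
  stopifnot(n_genes >= 0, chrom_length_bp > 0,
            min_gene_len > 0, max_gene_len >= min_gene_len)
  with_seed(sub_seed(seed, "genome"), {
    genes <- if (n_genes == 0) {
      gene_models(character(0), character(0), numeric(0), numeric(0),
                  character(0))
    } else {
      lens <- round(runif(n_genes, min_gene_len, max_gene_len))
      slack <- chrom_length_bp - sum(lens)
      if (slack < 0) {
        stop("genes do not fit on the chromosome; increase chrom_length_bp")
      }
      # uniform non-overlapping arrangement: split the slack at n random
      # breakpoints into n+1 gaps
      cuts <- sort(runif(n_genes))
      gaps <- floor(diff(c(0, cuts, 1)) * slack)  # floor: total never exceeds slack
      starts <- cumsum(gaps[seq_len(n_genes)]) +
        cumsum(c(0, lens[-n_genes]))
      ids <- sprintf("gene_%03d", seq_len(n_genes))
      strand <- ifelse(runif(n_genes) < 0.5, "+", "-")
      exons <- lapply(seq_len(n_genes), function(i) {
        k <- sample(1:3, 1)
        # k exons spread over the body, each in its own third
        bounds <- round(seq(starts[i], starts[i] + lens[i], length.out = k + 1))
        do.call(rbind, lapply(seq_len(k), function(j) {
          lo <- bounds[j]
          hi <- bounds[j + 1]
          w <- max(50, round((hi - lo) * runif(1, 0.2, 0.6)))
          s <- lo + round(runif(1, 0, max(0, hi - lo - w)))
          data.frame(start = s, end = min(s + w, hi))
        }))
      })
      gene_models(ids, chrom, starts, starts + lens, strand, exons = exons)
    }
    genome <- NULL
    if (with_sequence) {
      genome <- setNames(paste(sample(c("A", "C", "G", "T"),
                                      chrom_length_bp, replace = TRUE),
                               collapse = ""), chrom)
    }
    list(genes = genes, genome = genome)
  })
}

#' Choose planted target genes
#'
#' @param genes Gene-model table.
#' @param n_transactivated,n_repressed Numbers of planted targets of each
#'   regulation class.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `gene_id`, `regulation`.
#' @export
plant_targets <- function(genes, n_transactivated = 5, n_repressed = 3,
                          seed = 1) {
  n <- n_transactivated + n_repressed
  if (n > nrow(genes)) stop("more targets than genes")
  with_seed(sub_seed(seed, "truth"), {
    ids <- sample(genes$gene_id, n)
    data.frame(
      gene_id = ids,
      regulation = rep(c("transactivated", "repressed"),
                       c(n_transactivated, n_repressed)),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate ChIP-seq peaks with planted TSS-proximal binding
#'
#' Each planted target receives exactly one peak whose summit is uniform
#' within `planting_halfwidth` bp of its TSS.  Background peaks are placed
#' uniformly, with summits at least `tss_exclusion` bp from every TSS, so
#' that a zero-noise run has unambiguous ground truth.  With `embed_motif`
#' the core motif `TTTCCT` is written into the genome sequence at each
#' planted summit.
#'
#' @param genes Gene-model table.
#' @param truth Planted-target table from [plant_targets()] (may have 0
#'   rows).
#' @param planting_halfwidth Planting half-width in bp (default 2000; keep
#'   it at or below the integration window you intend to test).
#' @param n_background Number of background peaks.
#' @param peak_width_range Two-element range of peak widths in bp.
#' @param embed_motif Write `TTTCCT` at planted summits (needs `genome`).
#' @param genome Named character genome from [generate_genome()] (required
#'   when `embed_motif`; also used to bound coordinates).
#' @param chrom_length_bp Chromosome length when no genome is supplied.
#' @param tss_exclusion Minimum distance of background summits from any TSS
#'   (default 10000).
#' @param seed Integer seed.
#' @return A list with `peaks` (peak table; planted peaks first, named
#'   `planted_<gene_id>`), `truth_map` (peak name to planted gene), and
#'   `genome` (possibly edited copy, or `NULL`).
#' @export
generate_peaks <- function(genes, truth, planting_halfwidth = 2000,
                           n_background = 200,
                           peak_width_range = c(200, 800),
                           embed_motif = FALSE, genome = NULL,
                           chrom_length_bp = NULL, tss_exclusion = 10000,
                           seed = 1) {
  stopifnot(planting_halfwidth >= 0, n_background >= 0,
            length(peak_width_range) == 2)
  if (embed_motif && is.null(genome)) {
    stop("embed_motif requires the genome sequence")
  }
  L <- if (!is.null(genome)) nchar(genome[[1]]) else chrom_length_bp
  if (is.null(L)) stop("supply genome or chrom_length_bp")
  chrom <- if (!is.null(genome)) names(genome)[1] else
    unique(genes$chrom)[1]
  tss <- if (nrow(genes)) unname(tss_of(genes)) else numeric(0)
  with_seed(sub_seed(seed, "peaks"), {
    mk_peak <- function(summit, width, name) {
      start <- max(0, summit - width %/% 2)
      end <- min(L, start + width)
      data.frame(chrom = chrom, start = start, end = end, name = name,
                 score = round(runif(1, 50, 1000), 1),
                 summit_offset = summit - start, stringsAsFactors = FALSE)
    }
    planted <- list()
    if (nrow(truth)) {
      t_tss <- tss[match(truth$gene_id, genes$gene_id)]
      if (anyNA(t_tss)) stop("truth targets absent from gene models")
      for (i in seq_len(nrow(truth))) {
        s <- t_tss[i] + round(runif(1, -planting_halfwidth,
                                    planting_halfwidth))
        s <- min(max(s, 1), L - 7)  # leave room for a motif write at the summit
        w <- round(runif(1, peak_width_range[1], peak_width_range[2]))
        planted[[i]] <- mk_peak(s, w, paste0("planted_", truth$gene_id[i]))
      }
    }
    bg <- list()
    if (n_background > 0) {
      tries <- 0
      while (length(bg) < n_background) {
        tries <- tries + 1
        if (tries > n_background * 1000) {
          stop("could not place background peaks outside the TSS ",
               "exclusion zone; enlarge the chromosome")
        }
        s <- round(runif(1, 1, L - 2))
        if (length(tss) && min(abs(s - tss)) < tss_exclusion) next
        w <- round(runif(1, peak_width_range[1], peak_width_range[2]))
        bg[[length(bg) + 1]] <- mk_peak(s, w, paste0("bg_",
                                                     length(bg) + 1))
      }
    }
    pk <- do.call(rbind, c(planted, bg))
    if (is.null(pk)) {
      pk <- peak_table(character(0), numeric(0), numeric(0))
    }
    pk <- validate_peaks(pk)
    if (embed_motif && nrow(truth)) {
      for (i in seq_len(nrow(truth))) {
        s <- pk$start[i] + pk$summit_offset[i]
        substr(genome[[1]], s + 1, s + 6) <- "TTTCCT"
      }
    }
    truth_map <- if (nrow(truth)) {
      data.frame(peak_name = paste0("planted_", truth$gene_id),
                 gene_id = truth$gene_id, stringsAsFactors = FALSE)
    } else {
      data.frame(peak_name = character(0), gene_id = character(0))
    }
    list(peaks = pk, truth_map = truth_map, genome = genome)
  })
}

#' Generate a DE table with planted concordant effects
#'
#' Planted targets receive `log2fc = s * (effect_lfc + N(0, effect_sd))`
#' where the sign `s` encodes the regulation label through the perturbation
#' design (a transactivated gene goes down under knockdown, up under
#' overexpression) and a significant `padj` uniform in `sig_padj_range`;
#' null genes receive `log2fc ~ N(0, null_sd)` and `padj` uniform in
#' `null_padj_range`.  With `effect_sd = 0` and `null_sd = 0` the planted
#' truth is recoverable exactly.
#'
#' @param genes Gene-model table.
#' @param truth Planted-target table.
#' @param mode `"knockdown"` (default) or `"overexpression"`.
#' @param effect_lfc Planted absolute log2 fold change (default 1.0; keep
#'   it above `lfc_threshold + 3 * effect_sd` for guaranteed-recovery
#'   tests).
#' @param effect_sd,null_sd Gaussian spread of target / null effects.
#' @param sig_padj_range,null_padj_range Uniform padj ranges for targets /
#'   nulls.
#' @param seed Integer seed.
#' @return A validated DE table (`gene_id`, `log2fc`, `padj`).
#' @export
generate_de_table <- function(genes, truth,
                              mode = c("knockdown", "overexpression"),
                              effect_lfc = 1.0, effect_sd = 0.1,
                              null_sd = 0.2,
                              sig_padj_range = c(1e-6, 0.01),
                              null_padj_range = c(0.05, 1.0),
                              seed = 1) {
  mode <- match.arg(mode)
  stopifnot(effect_lfc > 0, effect_sd >= 0, null_sd >= 0)
  with_seed(sub_seed(seed, "de"), {
    n <- nrow(genes)
    lfc <- rnorm(n, 0, null_sd)
    padj <- runif(n, null_padj_range[1], null_padj_range[2])
    ti <- match(truth$gene_id, genes$gene_id)
    if (anyNA(ti)) stop("truth targets absent from gene models")
    if (length(ti)) {
      s <- ifelse(truth$regulation == "transactivated", -1, 1)
      if (mode == "overexpression") s <- -s
      lfc[ti] <- s * (effect_lfc + rnorm(length(ti), 0, effect_sd))
      padj[ti] <- runif(length(ti), sig_padj_range[1], sig_padj_range[2])
    }
    validate_deg_table(data.frame(gene_id = genes$gene_id, log2fc = lfc,
                                  padj = padj, stringsAsFactors = FALSE))
  })
}

#' Fixture DE table with exact up/down counts
#'
#' Builds a DE table in which exactly `n_up` genes pass the "up" criteria
#' and `n_down` pass "down" at the default thresholds, plus `n_null`
#' non-passing genes — for exercising selection-stage count summaries at
#' the scale a genome-wide screen reports (e.g. 1004 up / 355 down).
#'
#' @param n_up,n_down,n_null Counts.
#' @param lfc_threshold,padj_threshold Thresholds the fixture is built
#'   against (defaults 0.585, 0.05).
#' @param seed Integer seed.
#' @return A validated DE table.
#' @export
generate_deg_counts_fixture <- function(n_up = 1004, n_down = 355,
                                        n_null = 2000,
                                        lfc_threshold = 0.585,
                                        padj_threshold = 0.05, seed = 1) {
  with_seed(sub_seed(seed, "degfix"), {
    n <- n_up + n_down + n_null
    ids <- sprintf("gene_%05d", seq_len(n))
    lfc <- c(runif(n_up, lfc_threshold + 0.05, 5),
             -runif(n_down, lfc_threshold + 0.05, 5),
             runif(n_null, -lfc_threshold + 0.01, lfc_threshold - 0.01))
    padj <- c(runif(n_up + n_down, 1e-6, padj_threshold * 0.9),
              runif(n_null, padj_threshold, 1))
    validate_deg_table(data.frame(gene_id = ids, log2fc = lfc, padj = padj,
                                  stringsAsFactors = FALSE))
  })
}

#' Generate a median-effect dose-response curve
#'
#' Fractions affected follow the median-effect equation
#' `fa = (D/Dm)^m / (1 + (D/Dm)^m)`, with optional Gaussian noise on the
#' linearised (log10-odds) scale; results always stay strictly inside
#' (0, 1).
#'
#' @param m,dm True sigmoidicity and median-effect dose, `> 0`.
#' @param doses Positive dose vector.
#' @param logit_noise_sd Noise SD on the log10-odds scale (default 0).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `dose`, `fa`.
#' @export
generate_dose_response <- function(m, dm, doses, logit_noise_sd = 0,
                                   seed = 1) {
  stopifnot(m > 0, dm > 0, all(doses > 0))
  with_seed(sub_seed(seed, "dose"), {
    y <- m * (log10(doses) - log10(dm))
    if (logit_noise_sd > 0) y <- y + rnorm(length(doses), 0, logit_noise_sd)
    fa <- 10^y / (1 + 10^y)
    data.frame(dose = doses, fa = fa)
  })
}

#' Construct exactly Loewe-additive combination measurements
#'
#' For each effect level, the combination dose pair is taken on the
#' additivity isobole: `d1 = lambda * Dx1(fa)`, `d2 = (1 - lambda) *
#' Dx2(fa)`, so the combination index is 1 by construction at every level.
#'
#' @param fit1,fit2 Single-agent `median_effect` fits.
#' @param fa_levels Effect levels in (0, 1).
#' @param lambda Position along the isobole in (0, 1) (default 0.5).
#' @return A `data.frame` with columns `d1`, `d2`, `fa`.
#' @export
generate_additive_combos <- function(fit1, fit2,
                                     fa_levels = seq(0.1, 0.9, by = 0.1),
                                     lambda = 0.5) {
  stopifnot(lambda > 0, lambda < 1)
  d1 <- lambda * dose_for_effect(fit1, fa_levels)
  d2 <- (1 - lambda) * dose_for_effect(fit2, fa_levels)
  data.frame(d1 = d1, d2 = d2, fa = fa_levels)
}

#' Simulate a full study and write every pipeline input
#'
#' Generates the genome, gene models, planted targets, peaks, DE table and
#' dose-response curves under one study seed and writes them in standard
#' formats (`genes.gff3`, `genome.fa`, `peaks.bed`, `deg.tsv`,
#' `drug1.tsv`, `drug2.tsv`, `combos.tsv`) plus a `truth.json` recording
#' the planted ground truth, the seed, and all generator parameters.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Study seed; fans out to fixed per-component substreams.
#' @param config Named list overriding generator defaults; recognised keys
#'   are `n_genes`, `chrom_length_bp`, `n_transactivated`, `n_repressed`,
#'   `planting_halfwidth`, `n_background`, `mode`, `effect_lfc`,
#'   `effect_sd`, `null_sd`, `embed_motif`, `m1`, `dm1`, `m2`, `dm2`,
#'   `doses1`, `doses2`, `logit_noise_sd`.
#' @return Invisibly, a list with the file paths, the in-memory objects and
#'   the truth table.
#' @export
simulate_study <- function(out_dir, seed = 1, config = list()) {
  cfg <- utils::modifyList(list(
    n_genes = 100, chrom_length_bp = 5e6,
    n_transactivated = 5, n_repressed = 3,
    planting_halfwidth = 2000, n_background = 200,
    mode = "knockdown", effect_lfc = 1.0, effect_sd = 0.1, null_sd = 0.2,
    embed_motif = TRUE,
    m1 = 1.5, dm1 = 10, m2 = 2, dm2 = 5,
    doses1 = c(1.25, 2.5, 5, 10, 20, 40, 80),
    doses2 = c(0.625, 1.25, 2.5, 5, 10, 20, 40),
    logit_noise_sd = 0.1
  ), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(cfg$n_genes, cfg$chrom_length_bp, seed = seed)
  truth <- plant_targets(gen$genes, cfg$n_transactivated, cfg$n_repressed,
                         seed = seed)
  pk <- generate_peaks(gen$genes, truth,
                       planting_halfwidth = cfg$planting_halfwidth,
                       n_background = cfg$n_background,
                       embed_motif = cfg$embed_motif, genome = gen$genome,
                       seed = seed)
  deg <- generate_de_table(gen$genes, truth, mode = cfg$mode,
                           effect_lfc = cfg$effect_lfc,
                           effect_sd = cfg$effect_sd,
                           null_sd = cfg$null_sd, seed = seed)
  dr1 <- generate_dose_response(cfg$m1, cfg$dm1, cfg$doses1,
                                cfg$logit_noise_sd, seed = sub_seed(seed, "d1"))
  dr2 <- generate_dose_response(cfg$m2, cfg$dm2, cfg$doses2,
                                cfg$logit_noise_sd, seed = sub_seed(seed, "d2"))
  fit1 <- median_effect(dose = dr1$dose, fa = dr1$fa)
  fit2 <- median_effect(dose = dr2$dose, fa = dr2$fa)
  combos <- generate_additive_combos(fit1, fit2)

  paths <- list(
    genes = file.path(out_dir, "genes.gff3"),
    genome = file.path(out_dir, "genome.fa"),
    peaks = file.path(out_dir, "peaks.bed"),
    deg = file.path(out_dir, "deg.tsv"),
    drug1 = file.path(out_dir, "drug1.tsv"),
    drug2 = file.path(out_dir, "drug2.tsv"),
    combos = file.path(out_dir, "combos.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_gene_models(gen$genes, paths$genes, "gff3")
  write_fasta(pk$genome, paths$genome)
  write_peaks(pk$peaks, paths$peaks)
  write_deg_table(deg, paths$deg)
  write.table(dr1, paths$drug1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dr2, paths$drug2, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(combos, paths$combos, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(
    seed = seed, config = cfg,
    targets = truth,
    peak_truth_map = pk$truth_map,
    dose_response_truth = list(drug1 = list(m = cfg$m1, dm = cfg$dm1),
                               drug2 = list(m = cfg$m2, dm = cfg$dm2))
  ), paths$truth, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(paths = paths, genes = gen$genes, genome = pk$genome,
                 peaks = pk$peaks, deg = deg, truth = truth,
                 dose_response = list(drug1 = dr1, drug2 = dr2,
                                      combos = combos)))
}
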