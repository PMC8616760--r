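# The core binding + expression integration, checked against planted truth
# and a brute-force gene x peak double loop.

test_that("regulation class maps sign through the perturbation design", {
  expect_equal(regulation_class("-", "knockdown"), "transactivated")
  expect_equal(regulation_class("+", "knockdown"), "repressed")
  expect_equal(regulation_class("+", "overexpression"), "transactivated")
  expect_equal(regulation_class("-", "overexpression"), "repressed")
  expect_error(regulation_class("0", "knockdown"))
})

test_that("a TSS-proximal peak plus concordant DE makes a candidate", {
  gm <- gene_models("target", "chr1", 50000, 60000, "+")
  pk <- peak_table("chr1", 48700, 48900, summit_offset = 100)  # -1200
  deg <- data.frame(gene_id = "target", log2fc = -0.9, padj = 0.001)
  ct <- integrate_targets(pk, gm, select_degs(deg))
  expect_equal(nrow(ct), 1)
  expect_equal(ct$gene_id, "target")
  expect_equal(ct$regulation, "transactivated")
  expect_equal(ct$min_abs_tss_distance, 1200)
})

test_that("the 5000 bp window boundary is inclusive at 5000, not 5001", {
  gm <- gene_models("g", "chr1", 50000, 60000, "+")
  deg <- select_degs(data.frame(gene_id = "g", log2fc = -2, padj = 1e-5))
  at <- peak_table("chr1", 44900, 45100, summit_offset = 100)   # -5000
  beyond <- peak_table("chr1", 44899, 45099, summit_offset = 100) # -5001
  expect_equal(nrow(integrate_targets(at, gm, deg)), 1)
  expect_equal(nrow(integrate_targets(beyond, gm, deg)), 0)
})

test_that("zero-noise planted truth is recovered exactly", {
  gen <- generate_genome(n_genes = 100, seed = 31, with_sequence = FALSE)
  truth <- plant_targets(gen$genes, 5, 3, seed = 31)
  pk <- generate_peaks(gen$genes, truth, n_background = 200,
                       chrom_length_bp = 5e6, seed = 31)$peaks
  deg <- generate_de_table(gen$genes, truth, effect_sd = 0, null_sd = 0,
                           seed = 31)
  ct <- integrate_targets(pk, gen$genes, select_degs(deg))
  expect_setequal(ct$gene_id, truth$gene_id)
  expect_equal(
    ct$regulation[match(truth$gene_id, ct$gene_id)], truth$regulation)
  ta <- integrate_targets(pk, gen$genes, select_degs(deg),
                          keep = "transactivated")
  expect_setequal(ta$gene_id,
                  truth$gene_id[truth$regulation == "transactivated"])
})

test_that("candidates are monotone in the window and labels disjoint", {
  gen <- generate_genome(n_genes = 60, chrom_length_bp = 2e6, seed = 33,
                         with_sequence = FALSE)
  truth <- plant_targets(gen$genes, 4, 4, seed = 33)
  pk <- generate_peaks(gen$genes, truth, planting_halfwidth = 4000,
                       n_background = 100, chrom_length_bp = 2e6,
                       seed = 33)$peaks
  deg <- generate_de_table(gen$genes, truth, seed = 33)
  part <- select_degs(deg)
  prev <- character(0)
  for (w in c(1000, 2000, 4000, 8000)) {
    ct <- integrate_targets(pk, gen$genes, part, window = w)
    expect_true(all(prev %in% ct$gene_id), info = paste("window", w))
    expect_equal(anyDuplicated(ct$gene_id), 0)
    expect_true(all(ct$min_abs_tss_distance <= w))
    prev <- ct$gene_id
  }
})

test_that("integration equals the brute-force double loop", {
  for (seed in c(501, 502, 503)) {
    gm <- random_gene_models(50, seed = seed)
    pk <- random_peaks(200, seed = seed + 1000)
    set.seed(seed + 2000)
    deg <- data.frame(gene_id = gm$gene_id,
                      log2fc = rnorm(nrow(gm), 0, 1),
                      padj = runif(nrow(gm)))
    for (mode in c("knockdown", "overexpression")) {
      got <- integrate_targets(pk, gm, select_degs(deg), mode = mode)
      got <- as.data.frame(got)[order(got$gene_id),
                                c("gene_id", "regulation", "n_peaks",
                                  "min_abs_tss_distance")]
      rownames(got) <- NULL
      want <- brute_integrate(pk, gm, deg, mode = mode)
      rownames(want) <- NULL
      expect_equal(got, want, info = paste(seed, mode))
    }
  }
})

test_that("empty peak list gives an empty result, not an error", {
  gm <- random_gene_models(5, seed = 7)
  deg <- data.frame(gene_id = gm$gene_id, log2fc = -2,
                    padj = rep(1e-4, 5))
  ct <- integrate_targets(peak_table(character(0), numeric(0), numeric(0)),
                          gm, select_degs(deg))
  expect_equal(nrow(ct), 0)
})

test_that("DE genes missing from the models are dropped with a message; bound genes without DE records are side-listed", {
  gm <- gene_models(c("a", "b"), "chr1", c(10000, 100000),
                    c(20000, 110000), c("+", "+"))
  pk <- peak_table("chr1", c(9000, 99000), c(9200, 99200),
                   summit_offset = c(100, 100))
  deg <- data.frame(gene_id = c("a", "ghost"), log2fc = c(-2, -2),
                    padj = c(1e-4, 1e-4))
  expect_message(
    ct <- integrate_targets(pk, gm, select_degs(deg)),
    "dropped")
  expect_equal(ct$gene_id, "a")
  expect_equal(attr(ct, "dropped_de_genes"), "ghost")
  expect_equal(attr(ct, "bound_not_assayed"), "b")
})

test_that("output ordering is (regulation, min distance, gene_id)", {
  gm <- gene_models(c("g1", "g2", "g3"), "chr1",
                    c(10000, 50000, 90000), c(20000, 60000, 100000),
                    c("+", "+", "+"))
  pk <- peak_table("chr1", c(9900, 48500, 89000),
                   c(10100, 48700, 89200),
                   summit_offset = c(100, 100, 100))
  deg <- data.frame(gene_id = c("g1", "g2", "g3"),
                    log2fc = c(-1, -1, 1), padj = rep(1e-4, 3))
  ct <- integrate_targets(pk, gm, select_degs(deg))
  # regulation sorts first (repressed g3), then |TSS distance|: g1 at 0 bp,
  # g2 at 1400 bp
  expect_equal(ct$gene_id, c("g3", "g1", "g2"))
})
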