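test_that("assemble_reference_mix dilutes to the 20% ceiling, seeded", {
  tumor <- sprintf("t%03d", 1:100)
  pool <- sprintf("n%04d", 1:1000)
  mix <- assemble_reference_mix(tumor, pool, seed = 5)
  n_norm <- sum(mix$spike_in)
  expect_gte(n_norm, 400)  # 100 / 500 = 0.20
  expect_lte(100 / length(mix$cells), 0.20)
  expect_identical(mix$cells[1:100], tumor)

  mix2 <- assemble_reference_mix(tumor, pool, seed = 5)
  expect_identical(mix, mix2)
  mix3 <- assemble_reference_mix(tumor, pool, seed = 6)
  expect_false(identical(mix, mix3))

  expect_warning(out <- assemble_reference_mix(sprintf("t%02d", 1:10),
                                               sprintf("n%02d", 1:20)),
                 "pool")
  expect_identical(sum(out$spike_in), 20L)
  expect_error(assemble_reference_mix(character(), pool), "empty")
  expect_error(assemble_reference_mix(tumor, c(tumor[1], pool)), "overlap")
})

test_that("cnv_gene_filter keeps genes at both inclusive boundaries", {
  # 20 cells; craft per-gene expressing counts and means on the lognorm
  # layer directly
  # values picked so the boundary mean is exact in binary: 10 * 0.25 / 25
  ln <- matrix(0, 25, 4, dimnames = list(sprintf("c%02d", 1:25),
                                         c("few", "low", "at_bound", "rich")))
  ln[1:9, "few"] <- 2           # 9 cells < 10 -> out
  ln[1:12, "low"] <- 0.15       # mean 0.072 < 0.1 -> out
  ln[1:10, "at_bound"] <- 0.25  # 10 cells, mean exactly 0.1 -> in
  ln[, "rich"] <- 1
  m <- cnv_gene_filter(em_with_lognorm(ln))
  expect_setequal(gene_ids(m), c("at_bound", "rich"))
})

test_that("zscore_clip matches the population-sd closed form and clips", {
  ln <- matrix(c(0, 0, 0, 10,
                 1, 1, 1, 1), 4, 2,
               dimnames = list(paste0("c", 1:4), c("g1", "const")))
  expect_warning(z <- zscore_clip(em_with_lognorm(ln)), "zero-variance")
  expect_identical(colnames(z), "g1")   # constant gene dropped
  expect_equal(z[4, 1], 7.5 / 4.330127, tolerance = 1e-6)
  expect_equal(z[4, 1], 1.732051, tolerance = 1e-6)

  # values beyond the cap are clipped to +/- 3
  ln2 <- matrix(c(rep(0, 15), 10), 16, 1,
                dimnames = list(paste0("c", 1:16), "g"))
  z2 <- zscore_clip(em_with_lognorm(ln2))
  expect_equal(max(z2), 3)  # raw Z would be sqrt(15) = 3.87
})

test_that("windowed_smooth window geometry and arithmetic", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:101),
                      chromosome = "chr01", start = (1:101) * 10)
  z <- matrix(rep(1:101, each = 2), 2, 101,
              dimnames = list(c("a", "b"), genes$gene_id))
  out <- windowed_smooth(z, genes, cnv_params(window_size = 100))
  expect_identical(ncol(out$windows), 2L)          # 101 - 100 + 1
  expect_equal(out$windows[1, 1], mean(1:100))     # 50.5
  expect_equal(out$windows[1, 2], mean(2:101))

  # constant Z gives constant windows; short chromosome collapses
  genes2 <- data.frame(gene_id = c(genes$gene_id, "s1", "s2"),
                       chromosome = c(genes$chromosome, "chr02", "chr02"),
                       start = c(genes$start, 10, 20))
  z2 <- cbind(z, s1 = c(7, 7), s2 = c(9, 9))
  out2 <- windowed_smooth(z2, genes2, cnv_params(window_size = 100))
  expect_identical(ncol(out2$windows), 3L)
  expect_equal(out2$windows[, 3], c(a = 8, b = 8))
  expect_true(out2$info$short[out2$info$chromosome == "chr02"])

  expect_error(windowed_smooth(cbind(z, missing_gene = c(1, 1)), genes,
                               cnv_params()), "missing_gene")
})

test_that("center_cells is exact and idempotent", {
  w <- rbind(c(1, 2, 3), c(5, 5, 5))
  ctr <- center_cells(w)
  expect_equal(ctr[1, ], c(-1, 0, 1))
  expect_equal(ctr[2, ], c(0, 0, 0))
  expect_equal(center_cells(ctr), ctr)
  expect_equal(max(abs(rowMeans(ctr))), 0, tolerance = 1e-8)
})

test_that("score_cells statistics and classification boundaries", {
  set.seed(9)
  w <- matrix(rnorm(25 * 12), 25, 12,
              dimnames = list(sprintf("c%02d", 1:25), NULL))
  w <- center_cells(w)
  sc <- score_cells(w)
  expect_equal(sc$ms, unname(rowMeans(w^2)), tolerance = 1e-12)
  expect_true(all(sc$corr >= -1 & sc$corr <= 1, na.rm = TRUE))
  # two identical dominant cells form the top-2 reference (ceil(.05*25)=2),
  # so the reference equals their profile and their correlation is 1
  v <- center_cells(matrix(seq_len(12) * 5, 1))
  w2 <- w
  w2[1, ] <- v; w2[2, ] <- v
  sc2 <- score_cells(w2)
  expect_identical(order(sc2$ms, decreasing = TRUE)[1:2] %in% 1:2,
                   c(TRUE, TRUE))
  expect_equal(sc2$corr[1:2], c(1, 1), tolerance = 1e-12)

  # all-zero windows: ms 0, corr undefined
  sc0 <- score_cells(matrix(0, 20, 5,
                            dimnames = list(sprintf("c%02d", 1:20), NULL)))
  expect_equal(sc0$ms, rep(0, 20))
  expect_true(all(is.na(sc0$corr)))
  # undefined corr never classifies malignant through the corr arm
  cls0 <- classify_malignant(sc0)
  expect_false(any(cls0$malignant))

  expect_error(score_cells(w[1:10, ]), "20 cells")

  # strictness of the decision rule
  sc_b <- data.frame(cell_id = c("x", "y", "z"),
                     ms = c(0.025, 0.010, 0.020),
                     corr = c(0.10, 0.25, 0.20), n_windows = 5)
  cls <- classify_malignant(sc_b)
  expect_identical(cls$malignant, c(TRUE, TRUE, FALSE))
})

test_that("ms is invariant under sign flip; sorting is internal", {
  set.seed(21)
  n_cells <- 30; n_genes <- 120
  ln <- matrix(rpois(n_cells * n_genes, 4) + rnorm(n_cells * n_genes, 0, .1),
               n_cells, n_genes,
               dimnames = list(sprintf("c%02d", 1:n_cells),
                               sprintf("g%03d", 1:n_genes)))
  ln[ln < 0] <- 0
  genes <- data.frame(gene_id = colnames(ln),
                      chromosome = rep(c("chr01", "chr02"), each = 60),
                      start = rep(1:60 * 100, 2))
  p <- cnv_params(window_size = 20)
  run <- function(mat) {
    z <- zscore_clip(em_with_lognorm(mat), p)
    ctr <- center_cells(windowed_smooth(z, genes, p)$windows)
    score_cells(ctr, p)
  }
  base <- run(ln)
  # gene-order permutation of the input changes nothing
  perm <- sample(n_genes)
  expect_equal(run(ln[, perm])$ms, base$ms, tolerance = 1e-12)
  expect_equal(run(ln[, perm])$corr, base$corr, tolerance = 1e-12)
  # ms invariant when all window values flip sign
  w <- center_cells(windowed_smooth(zscore_clip(em_with_lognorm(ln), p),
                                    genes, p)$windows)
  expect_equal(score_cells(-w, p)$ms, score_cells(w, p)$ms,
               tolerance = 1e-12)
})

test_that("full scoring chain matches the brute-force oracle", {
  set.seed(33)
  n_cells <- 50; n_genes <- 300
  ln <- matrix(round(rgamma(n_cells * n_genes, 2, 1), 3), n_cells, n_genes,
               dimnames = list(sprintf("c%02d", 1:n_cells),
                               sprintf("g%03d", 1:n_genes)))
  # plant a gain so the top-5% set is non-trivial
  ln[1:5, 1:100] <- ln[1:5, 1:100] + 1.5
  genes <- data.frame(gene_id = colnames(ln),
                      chromosome = rep(sprintf("chr%02d", 1:3), each = 100),
                      start = rep(1:100 * 50, 3))
  p <- cnv_params(window_size = 100)
  z <- zscore_clip(em_with_lognorm(ln), p)
  ctr <- center_cells(windowed_smooth(z, genes, p)$windows)
  got <- score_cells(ctr, p)
  ora <- oracle_cnv_chain(ln, genes, window = 100, clip = 3,
                          top_frac = 0.05)
  expect_equal(unname(ctr), unname(ora$windows), tolerance = 1e-10)
  expect_equal(got$ms, ora$ms, tolerance = 1e-10)
  expect_equal(got$corr, ora$corr, tolerance = 1e-10)
})

test_that("infer_cnv recovers planted malignant cells on a small cohort", {
  sim <- simulate_counts(small_sim_config(seed = 12))
  m <- normalize_log2_tpm(filter_genes(qc_filter_cells(sim$matrix), 0.001))
  ann <- sim$annotation[sim$annotation$cell_id %in% cell_ids(m), ]
  tumor <- ann$cell_id[ann$lineage == "Epithelial" &
                         ann$tissue_origin == "tLung"]
  pool <- ann$cell_id[ann$lineage == "Epithelial" &
                        ann$tissue_origin == "nLung"]
  # pool (about 120) cannot reach 20%: expect the exhaustion warning
  expect_warning(sc <- infer_cnv(m, sim$genes, tumor, pool, seed = 2),
                 "pool")
  truth <- sim$truth$cells
  mal <- truth$malignant[match(sc$cell_id, truth$cell_id)]
  expect_gte(mean(sc$malignant[mal]), 0.9)
  expect_true(all(c("ms", "corr", "malignant", "is_spike_in") %in%
                    names(sc)))
  expect_identical(attr(sc, "seed"), 2)
})
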