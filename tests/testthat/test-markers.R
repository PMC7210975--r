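test_that("percent_expressing and the strict PCT gate", {
  ln <- matrix(0, 12, 3, dimnames = list(sprintf("c%02d", 1:12),
                                         c("zero", "quarter", "third")))
  ln[1:3, "quarter"] <- 2   # 3/12 = 0.25 exactly
  ln[1:4, "third"] <- 2     # 4/12
  pct <- percent_expressing(em_with_lognorm(ln), sprintf("c%02d", 1:12))
  expect_equal(unname(pct), c(0, 0.25, 1 / 3))
  expect_false(pct[["quarter"]] > 0.25)  # fails the strict gate
  expect_error(percent_expressing(em_with_lognorm(ln), character()),
               "empty")
})

test_that("log2_fold_change is a difference of log2 means", {
  ln <- matrix(c(3, 3, 3, 1, 1, 1), 6, 1,
               dimnames = list(sprintf("c%d", 1:6), "g"))
  m <- em_with_lognorm(ln)
  a <- sprintf("c%d", 1:3); b <- sprintf("c%d", 4:6)
  expect_equal(unname(log2_fold_change(m, a, b)), 2)
  expect_equal(log2_fold_change(m, a, b), -log2_fold_change(m, b, a))
  # groups with identical distributions: zero fold change
  expect_equal(unname(log2_fold_change(m, a[1:2], a[3])), 0)
  expect_error(log2_fold_change(m, a, c(b, a[1])), "overlap")
})

test_that("differential_markers agrees with a per-gene t-test oracle", {
  set.seed(14)
  n <- 12; ng <- 20
  base <- matrix(abs(rnorm(2 * n * ng, 3, 0.3)), 2 * n, ng,
                 dimnames = list(sprintf("c%02d", 1:(2 * n)),
                                 sprintf("g%02d", 1:ng)))
  base[1:n, 5] <- base[1:n, 5] + 2   # planted +2 log2 shift
  m <- em_with_lognorm(base)
  a <- sprintf("c%02d", 1:n); b <- sprintf("c%02d", (n + 1):(2 * n))
  res <- differential_markers(m, a, b)
  ora <- oracle_t_table(base[a, ], base[b, ])
  idx <- match(res$gene_id, ora$gene)
  expect_equal(res$p_value, ora$p[idx], tolerance = 1e-10)
  expect_equal(res$log2fc,
               unname(colMeans(base[a, ])[res$gene_id] -
                        colMeans(base[b, ])[res$gene_id]),
               tolerance = 1e-10)
  expect_true(res$passed[res$gene_id == "g05"])
  expect_identical(sum(res$passed), 1L)
  # sorted by log2FC descending
  expect_identical(res$gene_id[1], "g05")
  expect_false(is.unsorted(rev(res$log2fc)))
  # Bonferroni over the tested set, capped at 1, monotone in p
  expect_equal(res$adj_p, pmin(1, res$p_value * nrow(res)))

  # below the fold-change threshold never passes, whatever the p
  shifted <- base
  shifted[1:n, 7] <- shifted[1:n, 7] + 0.9
  r2 <- differential_markers(em_with_lognorm(shifted), a, b)
  g7 <- r2[r2$gene_id == "g07", ]
  expect_lt(g7$p_value, 0.01)
  expect_false(g7$passed)
})

test_that("stage_comparison_markers accepts both directions at 0.585", {
  expect_equal(log2(1.5), 0.5849625, tolerance = 1e-7)
  set.seed(8)
  n <- 15
  base <- matrix(abs(rnorm(2 * n * 3, 3, 0.2)), 2 * n, 3,
                 dimnames = list(sprintf("c%02d", 1:(2 * n)),
                                 c("down", "weak", "flat")))
  base[1:n, "down"] <- base[1:n, "down"] - 0.7   # down-regulated in A
  base[1:n, "weak"] <- base[1:n, "weak"] + 0.5   # below 0.585
  m <- em_with_lognorm(base)
  res <- stage_comparison_markers(m, sprintf("c%02d", 1:n),
                                  sprintf("c%02d", (n + 1):(2 * n)))
  expect_true(res$passed[res$gene_id == "down"])
  expect_false(res$passed[res$gene_id == "weak"])
})

test_that("signature_score is a mean over the intersected set", {
  ln <- matrix(c(2, 4, 0), 1, 3,
               dimnames = list("c1", c("a", "b", "zero")))
  m <- em_with_lognorm(ln)
  expect_equal(unname(signature_score(m, c("a", "b"))$cell_scores), 3)
  expect_equal(unname(signature_score(m, "a")$cell_scores), 2)
  # adding an all-zero gene lowers the score
  expect_lt(signature_score(m, c("a", "b", "zero"))$cell_scores[[1]], 3)
  out <- signature_score(m, c("a", "nothere"))
  expect_identical(out$missing_genes, "nothere")
  expect_error(signature_score(m, "nothere"), "nothere")
})

test_that("stratify_percentiles uses type-7 quartiles and excludes the middle", {
  s <- setNames(1:8, paste0("s", 1:8))
  cls <- stratify_percentiles(s)
  expect_identical(names(cls)[cls == "low"], c("s1", "s2"))
  expect_identical(names(cls)[cls == "high"], c("s7", "s8"))
  expect_identical(sum(cls == "low"), sum(cls == "high"))
  expect_false(any(cls == "low" & cls == "high"))
  expect_error(stratify_percentiles(setNames(rep(1, 8), paste0("s", 1:8))),
               "identical")
  expect_error(stratify_percentiles(s[1:5]), "8 samples")
})

test_that("survival_stratified censors deaths beyond the 10-year horizon", {
  set.seed(2)
  n <- 12
  surv <- data.frame(sample_id = paste0("p", 1:n),
                     time_days = c(seq(400, 3000, length.out = 10),
                                   12 * 365.25, 13 * 365.25),
                     event = 1, score = 1:n)
  out <- survival_stratified(surv, censor_years = 10)
  late <- out$data[out$data$time_days == 10 * 365.25, ]
  expect_identical(nrow(late), 2L)        # the 12- and 13-year deaths
  expect_true(all(late$event == 0))
  expect_true(out$p_value >= 0 && out$p_value <= 1)
  # exclusion variant drops them instead
  out2 <- survival_stratified(surv, censor_years = 10,
                              exclude_beyond = TRUE)
  expect_false(any(out2$data$time_days > 10 * 365.25))
})

test_that("select_variable_genes window and dispersion standardization", {
  set.seed(6)
  n <- 200
  high_mean <- rep(4, n) + rnorm(n, 0, 0.01)     # mean > 3 -> excluded
  constant <- rep(1, n)                          # zero dispersion
  noisy <- rpois(n, 1) * 2                       # dispersed, mean in window
  tame <- pmin(rpois(n, 1), 1) * 0.8             # low dispersion companion
  ln <- cbind(high = high_mean, const = constant, noisy = noisy,
              tame1 = tame, tame2 = rev(tame), tame3 = tame * 0.9)
  rownames(ln) <- sprintf("c%03d", 1:n)
  sel <- select_variable_genes(em_with_lognorm(ln), n_bins = 2)
  expect_false("high" %in% sel)
  expect_false("const" %in% sel)
  expect_true("noisy" %in% sel)

  # toy dispersion z-scores match a hand computation with one bin
  ln2 <- cbind(a = c(0, 2, 0, 2), b = c(1, 1, 1, 3), d = c(0, 0, 2, 2))
  rownames(ln2) <- paste0("c", 1:4)
  mu <- colMeans(ln2)
  v <- apply(ln2, 2, var)
  disp <- v / mu
  z <- (disp - mean(disp)) / sd(disp)
  sel2 <- select_variable_genes(em_with_lognorm(ln2), n_bins = 1,
                                mean_low = 0, mean_high = 10,
                                min_dispersion = 0.5)
  expect_identical(sel2, names(z)[z > 0.5])
})

test_that("pc1_partition separates planted populations and gates on markers", {
  set.seed(31)
  n <- 100  # 50 cells per population
  mk_a <- paste0("ma", 1:5); mk_b <- paste0("mb", 1:5)
  other <- paste0("g", 1:30)
  ln <- matrix(abs(rnorm(n * 40, 1, 0.3)), n, 40,
               dimnames = list(sprintf("c%03d", 1:n),
                               c(mk_a, mk_b, other)))
  ln[1:50, mk_a] <- ln[1:50, mk_a] + 3
  ln[51:100, mk_b] <- ln[51:100, mk_b] + 3
  m <- em_with_lognorm(ln)
  out <- pc1_partition(m, mk_a, mk_b,
                       variable_genes = c(mk_a, mk_b, other[1:10]))
  truth <- rep(c("A", "B"), each = 50)
  expect_gte(mean(out$label == truth), 0.99)

  # a cell with weak markers is undetermined (avg <= 1)
  ln2 <- ln
  ln2[1, ] <- 0.1
  out2 <- pc1_partition(em_with_lognorm(ln2), mk_a, mk_b,
                        variable_genes = c(mk_a, mk_b, other[1:10]))
  expect_identical(as.character(out2$label[[1]]), "undetermined")

  # orientation is fixed by the markers: flipping the data's sign
  # structure (swap the populations' rows) does not swap label meaning
  flip <- ln[c(51:100, 1:50), ]
  rownames(flip) <- rownames(ln)
  out3 <- pc1_partition(em_with_lognorm(flip), mk_a, mk_b,
                        variable_genes = c(mk_a, mk_b, other[1:10]))
  expect_gte(mean(out3$label == rep(c("B", "A"), each = 50)), 0.99)
})
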