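test_that("weighted t-test is null on identical groups and Welch at equal weights", {
  cm <- depth_cm(ng = 30, nc = 20, seed = 31)
  g <- cell_group(cm)
  pa <- gene_profiles(g)
  wt <- weighted_t_test(pa, pa)
  expect_equal(wt$t, rep(0, nrow(pa)))
  expect_equal(wt$p, rep(1, nrow(pa)))

  # equal weights in both groups -> textbook Welch t, p agreement to 1e-10
  set.seed(32)
  for (r in 1:200) {
    na <- sample(5:40, 1); nb <- sample(5:40, 1)
    xa <- rnorm(na); xb <- rnorm(nb, sd = runif(1, 0.5, 2))
    prof <- function(x) {
      v <- weighted_mean_variance(x, rep(1 / length(x), length(x)))
      list(mean_w = mean(x), var_mean = v$var_mean, n_eff = v$n_eff)
    }
    ours <- weighted_t_test(prof(xa), prof(xb))
    ref <- t.test(xa, xb, var.equal = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  }
})

test_that("degenerate zero-variance inputs are flagged, not propagated as NaN", {
  pr <- function(m, v, n) list(mean_w = m, var_mean = v, n_eff = n)
  expect_equal(weighted_t_test(pr(0.3, 0, 10), pr(0.3, 0, 10))$p, 1)
  deg <- weighted_t_test(pr(0.4, 0, 10), pr(0.3, 0, 10))
  expect_equal(deg$p, 0)
  expect_true(is.infinite(deg$t))
})

test_that("chi-squared aggregate test matches the textbook Pearson oracle", {
  # exactly equal proportions -> chi2 = 0, p = 1
  expect_equal(chi2_aggregate_test(30, 1000, 60, 2000), 1)
  # hand/oracle comparison, no continuity correction
  p_ours <- chi2_aggregate_test(30, 1000, 60, 1000)
  tab <- matrix(c(30, 970, 60, 940), 2, byrow = TRUE)
  expect_equal(p_ours, chisq.test(tab, correct = FALSE)$p.value, tolerance = 1e-12)
  # vectorised and symmetric under group swap
  set.seed(33)
  xa <- rpois(50, 40); xb <- rpois(50, 60)
  p1 <- chi2_aggregate_test(xa, rep(5000, 50), xb, rep(7000, 50))
  p2 <- chi2_aggregate_test(xb, rep(7000, 50), xa, rep(5000, 50))
  expect_equal(p1, p2)
  for (i in c(3, 27)) {
    tab <- matrix(c(xa[i], 5000 - xa[i], xb[i], 7000 - xb[i]), 2, byrow = TRUE)
    expect_equal(p1[i], chisq.test(tab, correct = FALSE)$p.value, tolerance = 1e-12)
  }
  # gene absent from both groups -> undefined
  expect_true(is.na(chi2_aggregate_test(0, 100, 0, 100)))
  expect_error(chi2_aggregate_test(10, 5, 1, 10), "exceeds")
})

test_that("combination rules implement proxy and max semantics", {
  proxy <- combination_policy("proxy", 0.05)
  expect_equal(combine_pvalues(1e-6, 0.4, proxy), 0.4)
  expect_equal(combine_pvalues(1e-6, 1e-3, proxy), 1e-6)
  expect_equal(combine_pvalues(0.2, 0.01, combination_policy("max")), 0.2)
  # max dominates both inputs; proxy is monotone in p_wt at fixed p_chi2
  set.seed(34)
  pw <- runif(100); pc <- runif(100)
  pm <- combine_pvalues(pw, pc, combination_policy("max"))
  expect_true(all(pm >= pw & pm >= pc))
  pw_sorted <- sort(pw)
  out_max <- combine_pvalues(pw_sorted, rep(0.3, 100), combination_policy("max"))
  expect_true(all(diff(out_max) >= 0))
  # proxy substitutes p_chi2 only below the significance floor, so it is
  # monotone on either side of alpha_min
  out <- combine_pvalues(pw_sorted, rep(0.3, 100), proxy)
  expect_true(all(diff(out[pw_sorted < 0.05]) >= 0))
  expect_true(all(diff(out[pw_sorted >= 0.05]) >= 0))
  # undefined chi2 falls back to the weighted-t p
  expect_equal(combine_pvalues(0.01, NA, proxy), 0.01)
})

test_that("log2 fold change handles zeros as documented", {
  expect_equal(log2_fold_change(0.2, 0.1), 1)
  expect_equal(log2_fold_change(0.3, 0.3), 0)
  expect_equal(log2_fold_change(0.5, 0), Inf)
  expect_equal(log2_fold_change(0, 0.5), -Inf)
  expect_true(is.na(log2_fold_change(0, 0)))
})

test_that("rank-sum p-values match exact enumeration and wilcox.test", {
  cm <- count_matrix(rbind(g1 = c(1, 2, 3, 4, 5, 6)) +
                       matrix(0, 1, 6, dimnames = list("g1", paste0("c", 1:6))))
  # exhaustive permutation oracle for [1,2,3] vs [4,5,6] on relative counts
  enum_p <- function(xa, xb) {
    pooled <- c(xa, xb); na <- length(xa)
    combs <- combn(length(pooled), na)
    w_obs <- sum(rank(pooled)[seq_len(na)]) - na * (na + 1) / 2
    ws <- apply(combs, 2, function(ix)
      sum(rank(pooled)[ix]) - na * (na + 1) / 2)
    mean_w <- length(xb) * na / 2
    mean(abs(ws - mean_w) >= abs(w_obs - mean_w))
  }
  # build groups over one matrix: equal totals so relative = counts/const
  m <- rbind(gene = c(1, 2, 3, 4, 5, 6), other = c(9, 8, 7, 6, 5, 4))
  colnames(m) <- paste0("c", 1:6)
  cmx <- count_matrix(m)
  ga <- cell_group(cmx, 1:3); gb <- cell_group(cmx, 4:6)
  res <- comparator_tests(ga, gb, genes = "gene")
  expect_equal(res$p_wilcoxon, enum_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$p_wilcoxon,
               wilcox.test(c(.1, .2, .3), c(.4, .5, .6), exact = TRUE)$p.value)

  # tie-corrected normal approximation path agrees with wilcox.test
  set.seed(35)
  big <- matrix(rpois(40 * 120, 1.5), 40, 120)
  big[1, ] <- big[2, ]  # ensure heavy ties
  cmb <- count_matrix(big)
  totals_equal <- all(cmb$cell_totals > 0)
  ga <- cell_group(cmb, 1:60); gb <- cell_group(cmb, 61:120)
  res <- comparator_tests(ga, gb)
  rel <- as.matrix(cmb$counts) %*% diag(1 / cmb$cell_totals)
  for (i in c(1, 5, 22)) {
    ref <- suppressWarnings(wilcox.test(rel[i, 1:60], rel[i, 61:120],
                                        exact = FALSE, correct = TRUE))
    expect_equal(res$p_wilcoxon[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("comparator Welch tests agree with t.test on relative and log scales", {
  set.seed(36)
  m <- matrix(rpois(30 * 80, 2), 30, 80)
  m[cbind(1:30, sample(80, 30, TRUE))] <- 5  # avoid constant rows
  cmb <- count_matrix(m)
  ga <- cell_group(cmb, 1:40); gb <- cell_group(cmb, 41:80)
  res <- comparator_tests(ga, gb)
  rel <- as.matrix(cmb$counts) %*% diag(1 / cmb$cell_totals)
  lg <- log1p(rel * 1e4)
  for (i in c(2, 11, 29)) {
    expect_equal(res$p_t_rc[i],
                 t.test(rel[i, 1:40], rel[i, 41:80])$p.value, tolerance = 1e-10)
    expect_equal(res$p_t_log[i],
                 t.test(lg[i, 1:40], lg[i, 41:80])$p.value, tolerance = 1e-10)
  }
  # identical groups -> all comparator p = 1
  same <- comparator_tests(ga, ga)
  expect_true(all(same$p_t_rc == 1))
  expect_true(all(same$p_wilcoxon == 1))
})

test_that("run_dge composes the stages and respects its symmetries", {
  cm <- depth_cm(ng = 60, nc = 50, seed = 37)
  ga <- cell_group(cm, 1:25, "A")
  gb <- cell_group(cm, 26:50, "B")
  cfg <- dge_config(min_total = 5)
  res <- run_dge(ga, gb, cfg)
  expect_equal(res$gene, sort(names(filter_genes_min_total(cm, list(ga, gb), 5))))
  # composition: stage-by-stage equals pipeline
  gi <- match(res$gene, cm$gene_ids)
  pa <- gene_profiles(ga, genes = gi)
  pb <- gene_profiles(gb, genes = gi)
  expect_equal(res$p_wt, weighted_t_test(pa, pb)$p)
  expect_equal(res$p_chi2, chi2_aggregate_test(pa$agg, pa$tot, pb$agg, pb$tot))
  expect_equal(res$log2fc_w, log2_fold_change(pa$mean_w, pb$mean_w))
  # swapping groups negates log2fc and leaves chi2 unchanged
  swp <- run_dge(gb, ga, cfg)
  expect_equal(swp$log2fc_w, -res$log2fc_w)
  expect_equal(swp$p_chi2, res$p_chi2)
  # identical groups -> p_wt 1, log2fc 0
  same <- run_dge(ga, ga, dge_config(min_total = 5, comparators = FALSE))
  expect_true(all(same$p_wt == 1))
  expect_true(all(same$log2fc_w == 0))
  # empty universe warns and returns an empty table
  expect_warning(empty <- run_dge(ga, gb, dge_config(min_total = 1e9)),
                 "zero surviving")
  expect_equal(nrow(empty), 0)
})

test_that("null p-values are uniform where the tests' assumptions hold", {
  # pure transcript-sampling noise: weighted t, RC t and chi2 all uniform
  syn <- generate_synthetic(synth_config(n_cells = 400, n_genes = 2000,
                                         n_groups = 2, seed = 109,
                                         dispersion_meanlog = -Inf,
                                         dispersion_sdlog = 0))
  res <- run_dge(syn$groups[[1]], syn$groups[[2]], dge_config())
  for (col in c("p_wt", "p_t_rc", "p_chi2")) {
    p <- res[[col]][!is.na(res[[col]])]
    expect_lt(suppressWarnings(ks.test(p, "punif")$statistic), 0.05)
  }
  # with real cell-to-cell variance the chi2 test underestimates the total
  # variance and is anticonservative - the reason it is never used alone,
  # while the weighted t stays calibrated
  syn2 <- generate_synthetic(synth_config(n_cells = 400, n_genes = 2000,
                                          n_groups = 2, seed = 110))
  res2 <- run_dge(syn2$groups[[1]], syn2$groups[[2]],
                  dge_config(comparators = FALSE))
  expect_gt(mean(res2$p_chi2 < 0.05, na.rm = TRUE), 0.10)
  expect_lt(suppressWarnings(ks.test(res2$p_wt, "punif")$statistic), 0.05)
})

test_that("the DGE TSV contract round-trips with header metadata", {
  cm <- depth_cm(ng = 25, nc = 30, seed = 38)
  res <- run_dge(cell_group(cm, 1:15), cell_group(cm, 16:30),
                 dge_config(min_total = 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dge_tsv(res, f, seed = 99, config_hash = "abc")
  lines <- readLines(f)
  expect_match(lines[1], "^# weightedDGE")
  expect_match(lines[3], "seed: 99")
  tab <- read.delim(f, comment.char = "#")
  expect_equal(names(tab)[1:4], c("gene", "mean_w_A", "mean_w_B", "log2fc_w"))
  expect_equal(nrow(tab), nrow(res))
})
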