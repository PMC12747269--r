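test_that("thinning respects its exact limits and never increases counts", {
  cm <- depth_cm(ng = 40, nc = 25, seed = 61)
  expect_identical(as.matrix(subsample_umis(cm, 1, seed = 1)$counts),
                   as.matrix(cm$counts))
  expect_equal(sum(subsample_umis(cm, 0, seed = 1)$counts), 0)
  for (mode in c("binomial", "per_gene")) {
    th <- subsample_umis(cm, 0.4, seed = 7, mode = mode)
    d0 <- as.matrix(cm$counts); d1 <- as.matrix(th$counts)
    expect_true(all(d1 <= d0))          # zeros preserved, nothing increases
    expect_true(all(d1 >= 0))
  }
  # per-gene mode retains exactly round(0.4 * total) per gene
  th <- subsample_umis(cm, 0.4, seed = 7, mode = "per_gene")
  expect_equal(unname(Matrix::rowSums(th$counts)),
               unname(round(0.4 * Matrix::rowSums(cm$counts))))
  # reproducible under the same seed
  expect_identical(as.matrix(subsample_umis(cm, 0.4, seed = 7)$counts),
                   as.matrix(subsample_umis(cm, 0.4, seed = 7)$counts))
})

test_that("noise function obeys its printed constraints", {
  set.seed(62)
  expect_true(all(noise_fn(5, rep(0, 1000)) == 0))
  draws <- noise_fn(5, rep(1e4, 1e5))
  expect_lt(abs(mean(draws)), 2)                 # zero mean (sd ~ 0.7)
  expect_lt(abs(var(draws) / 1e4 / 5 - 1), 0.03) # Var -> alpha N within 3%
  # bounded by the amplitude; roughly symmetric
  amp <- (sqrt(15) - (sqrt(15) - 1) / (1 + 0.1 * 1e4)) * sqrt(1e4)
  expect_true(all(abs(draws) <= ceiling(amp)))
  expect_lt(abs(mean(draws > 0) - mean(draws < 0)), 0.01)
  # counts stay non-negative after noise for small N at alpha = 5
  for (N in 1:6) {
    fn <- noise_fn(5, rep(N, 2000))
    expect_true(all(N + fn >= 0))
  }
  expect_error(noise_fn(12, 5), "alpha")
})

test_that("apply_noise perturbs only its targets and conserves totals on average", {
  cm <- depth_cm(ng = 50, nc = 40, seed = 63, depth_range = c(2000, 20000))
  same <- apply_noise(cm, noise_spec(5, integer(0), seed = 1))
  expect_identical(as.matrix(same$counts), as.matrix(cm$counts))
  targets <- 1:25
  noisy <- apply_noise(cm, noise_spec(5, targets, seed = 2))
  d0 <- as.matrix(cm$counts); d1 <- as.matrix(noisy$counts)
  expect_identical(d1[-targets, ], d0[-targets, ])
  expect_true(all(d1 >= 0))
  # zero-mean noise conserves totals to within the amplitude-law prediction:
  # per-gene drift sd ~ sqrt(sum A(alpha, N)^2 / 3)
  set.seed(631)
  m2 <- matrix(rpois(10 * 4000, 5), 10, 4000)
  cm2 <- count_matrix(m2)
  noisy2 <- apply_noise(cm2, noise_spec(5, 1:10, seed = 3))
  t0 <- Matrix::rowSums(cm2$counts); t1 <- Matrix::rowSums(noisy2$counts)
  amp <- function(x) (sqrt(15) - (sqrt(15) - 1) / (1 + 0.1 * x)) * sqrt(x)
  sd_pred <- apply(m2, 1, function(x) sqrt(sum(amp(x)^2 / 3)))
  expect_true(all(abs(t1 - t0) < 4 * sd_pred))
  expect_lt(abs(mean((t1 - t0) / t0)), 0.005)
})

test_that("upregulation is multiplicative with round-half-even rounding", {
  cm <- count_matrix(matrix(c(2, 4, 10, 3, 5, 7), 2, 3, byrow = TRUE,
                            dimnames = list(c("even", "odd"), paste0("c", 1:3))))
  expect_identical(as.matrix(apply_upregulation(cm, 1:2, 1)$counts),
                   as.matrix(cm$counts))
  up <- apply_upregulation(cm, "even", 1.5)
  expect_equal(as.numeric(up$counts["even", ]), c(3, 6, 15))  # exact +50%
  expect_equal(as.numeric(up$counts["odd", ]), c(3, 5, 7))
  # beta 1.3 on moderate counts: rounding-loss window from brute enumeration
  set.seed(64)
  counts <- rpois(5000, 1.2)
  realized <- sum(counts + round(0.3 * counts)) / sum(counts)
  expect_gte(realized, 1.25)
  expect_lte(realized, 1.30)
})

test_that("synthetic generator is reproducible with exact multinomial depths", {
  cfg <- synth_config(n_cells = 50, n_genes = 300, seed = 65)
  a <- generate_synthetic(cfg)
  b <- generate_synthetic(cfg)
  expect_identical(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  # column sums equal the drawn depths by construction (multinomial)
  expect_true(all(a$matrix$cell_totals >= 1))
  # zero dispersion -> pure sampling noise -> estimated rho ~ 0
  cfg0 <- synth_config(n_cells = 300, n_genes = 150, seed = 66,
                       dispersion_meanlog = -Inf, dispersion_sdlog = 0)
  s0 <- generate_synthetic(cfg0)
  pr <- gene_profiles(s0$groups[[1]],
                      genes = which(Matrix::rowSums(s0$matrix$counts) > 100))
  expect_lt(mean(pr$rho), 1e-3)
  expect_lt(max(pr$rho), 0.05)
})

test_that("planted dispersion spread reproduces a wide WDC range", {
  syn <- generate_synthetic(synth_config(n_cells = 400, n_genes = 2000,
                                         seed = 67))
  sel <- which(Matrix::rowSums(syn$matrix$counts) > 30)
  pr <- gene_profiles(syn$groups[[1]], genes = sel)
  expect_lt(quantile(pr$wdc, 0.05), 0.2)
  expect_gt(quantile(pr$wdc, 0.95), 0.9)
  # the most dispersed genes get low WDC (weights decoupled from depth)
  disp <- syn$truth$dispersion[sel]
  expect_lt(median(pr$wdc[disp > quantile(disp, 0.9)]),
            median(pr$wdc[disp < quantile(disp, 0.1)]))
})

test_that("two-group generator plants recoverable fold changes", {
  syn <- generate_synthetic(synth_config(n_cells = 400, n_genes = 800,
                                         n_groups = 2, upreg_genes = 50,
                                         upreg_beta = 1.5,
                                         dispersion_meanlog = -Inf,
                                         dispersion_sdlog = 0, seed = 68))
  up <- which(syn$truth$status == "upregulated")
  res <- run_dge(syn$groups[[2]], syn$groups[[1]],
                 dge_config(min_total = 200, comparators = FALSE))
  hit <- res$gene %in% syn$truth$gene[up]
  expect_gt(sum(hit), 10)
  # multinomial sampling is compositional: boosting the planted set deflates
  # every proportion by the renormalization factor f
  f <- 1 + (1.5 - 1) * sum(syn$truth$abundance[up])
  expect_lt(abs(median(res$log2fc_w[hit]) - log2(1.5 / f)), 0.02)
  expect_lt(abs(median(res$log2fc_w[!hit]) - log2(1 / f)), 0.02)
})

test_that("beta-binomial generator matches its nominal moments", {
  set.seed(69)
  tot <- rep(500, 4000)
  x <- simulate_beta_binomial(tot, p = 0.1, rho = 0.2, seed = 70)
  expect_lt(abs(mean(x / tot) - 0.1), 0.01)
  # Var(p_hat) = p(1-p)(rho + (1-rho)/N)
  expect_lt(abs(var(x / tot) / (0.09 * (0.2 + 0.8 / 500)) - 1), 0.10)
})

test_that("benchmark tallies match a hand-counted fixture", {
  truth <- data.frame(gene = paste0("g", 1:10),
                      status = c(rep("noise_only", 6), rep("upregulated", 4)))
  res <- data.frame(gene = paste0("g", 1:10),
                    p_wt = c(0.01, 0.2, 0.3, 0.001, 0.5, 0.9,
                             0.01, 0.04, 0.2, 0.001),
                    log2fc_w = c(0.5, 0.05, 0.3, 0.05, 0.2, 0.01,
                                 0.6, 0.05, 0.3, 0.15))
  tal <- tally_benchmark(res, truth, tests = c(wt = "p_wt"),
                         p_thresholds = 0.05)$per_replicate
  # hand count, p_only: null sig = g1,g4 -> FP 2/6; planted sig = g7,g8,g10
  p_only <- subset(tal, mode == "p_only")
  expect_equal(p_only$fp, 2 / 6)
  expect_equal(p_only$fn, 1 / 4)
  # p_fc: null sig needs |fc|>0.1 -> g1 only; planted: g7,g10 -> FN 2/4
  p_fc <- subset(tal, mode == "p_fc")
  expect_equal(p_fc$fp, 1 / 6)
  expect_equal(p_fc$fn, 2 / 4)
  # degenerate corners
  all_null <- tally_benchmark(data.frame(gene = "g1", p_wt = 1, log2fc_w = 0),
                              data.frame(gene = "g1", status = "unmodified"),
                              tests = c(wt = "p_wt"),
                              p_thresholds = 0.05)$per_replicate
  expect_true(all(all_null$fp == 0))
})
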