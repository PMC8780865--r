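test_that("noise-free plates hit the control-anchored 4PL limits", {
  tr <- plate_truth("x", b = 2, c = 0, d = 100, e = 50, noise_sd = 0,
                    nc_abs = 0.2, pc_abs = 0.8)
  p <- generate_plate(tr, c(0, 50, 1e9), replicates = 1, seed = 1)
  smp <- p[p$role == "sample", ]
  expect_equal(smp$absorbance[smp$concentration_uM == 0], 0.2)
  # inflection dose: 50% cytotoxicity, absorbance midway between controls
  expect_equal(smp$absorbance[smp$concentration_uM == 50], 0.5)
  expect_equal(smp$absorbance[smp$concentration_uM == 1e9], 0.8,
               tolerance = 1e-6)
  expect_setequal(unique(p$role), c("sample", "NC", "PC"))
})

test_that("plate generation is deterministic under a fixed seed and validates inputs", {
  tr <- plate_truth("x", noise_sd = 0.05)
  expect_identical(generate_plate(tr, c(0, 10, 100), 3, seed = 5),
                   generate_plate(tr, c(0, 10, 100), 3, seed = 5))
  expect_false(identical(generate_plate(tr, c(0, 10), 2, seed = 5),
                         generate_plate(tr, c(0, 10), 2, seed = 6)))
  expect_error(generate_plate(tr, c(0, 10), replicates = 0), "replicates")
  expect_error(plate_truth("x", nc_abs = 0.9, pc_abs = 0.2), "nc_abs")
  expect_error(plate_truth("x", e = -1), "positive")
  expect_error(plate_truth("x", noise_sd = -1), "noise_sd")
})

make_truth <- function(n_genes, modules, alpha, mu, eff = NULL,
                       sdlog = 0) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  eff <- eff %||% data.frame(gene = character(), chemical = character(),
                             log2fc_per_uM = numeric())
  count_truth(setNames(rep_len(modules, n_genes), genes), list(), eff,
              setNames(rep(alpha, n_genes), genes),
              setNames(rep(mu, n_genes), genes), module_sdlog = sdlog)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("null generator yields Poisson counts around the baseline", {
  tr <- make_truth(200, "m1", alpha = 0, mu = 80)
  des <- data.frame(sample_id = sprintf("s%d", 1:30), chemical = "x",
                    concentration_uM = 0, time_h = 48, replicate = 1:30)
  cts <- generate_counts(tr, des, seed = 3)
  m <- rowMeans(cts)
  se <- sqrt(80 / 30)
  expect_true(mean(abs(m - 80) <= 3 * se) > 0.99)
  v <- apply(cts, 1, var)
  # Poisson limit: variance tracks the mean, no quadratic term
  expect_lt(abs(mean(v) / 80 - 1), 0.15)
})

test_that("shared latent factors induce within-module correlation", {
  tr <- make_truth(60, rep(c("mA", "mB"), each = 30), alpha = 0.05,
                   mu = 200, sdlog = 0.3)
  des <- data.frame(sample_id = sprintf("s%d", 1:200), chemical = "x",
                    concentration_uM = 0, time_h = 48, replicate = 1:200)
  cts <- generate_counts(tr, des, seed = 9)
  cc <- cor(t(log1p(cts)))
  within <- c(cc[1:30, 1:30][upper.tri(diag(30))],
              cc[31:60, 31:60][upper.tri(diag(30))])
  between <- cc[1:30, 31:60]
  expect_gt(mean(within), mean(between) + 0.2)
})

test_that("a +1 log2FC/uM effect doubles the mean at concentration 1", {
  eff <- data.frame(gene = "g001", chemical = "x", log2fc_per_uM = 1)
  tr <- make_truth(1, "m1", alpha = 0, mu = 100, eff = eff)
  n <- 2e4
  des <- data.frame(sample_id = sprintf("s%d", 1:n), chemical = "x",
                    concentration_uM = rep(c(0, 1), each = n / 2),
                    time_h = 48, replicate = 1:n)
  cts <- generate_counts(tr, des, seed = 21)
  ratio <- mean(cts[1, des$concentration_uM == 1]) /
    mean(cts[1, des$concentration_uM == 0])
  expect_equal(ratio, 2, tolerance = 0.03)
})

test_that("count generation rejects invalid truths and unknown chemicals", {
  genes <- c("g1", "g2")
  expect_error(count_truth(setNames(c("m", "m"), genes), list(),
                           data.frame(gene = character(), chemical = character(),
                                      log2fc_per_uM = numeric()),
                           setNames(c(-0.1, 0.1), genes),
                           setNames(c(10, 10), genes)),
               "nonnegative")
  tr <- make_truth(2, "m1", 0.1, 10,
                   eff = data.frame(gene = "g001", chemical = "a",
                                    log2fc_per_uM = 1))
  des <- data.frame(sample_id = "s1", chemical = "zzz",
                    concentration_uM = 5, time_h = 48, replicate = 1)
  expect_error(generate_counts(tr, des, 1), "not in effect profile")
})

test_that("benchmark generator gives controlled similarity by construction", {
  fc <- setNames(c(2, -1.5, 0.8, 3, -0.2), sprintf("b%d", 1:5))
  bt <- benchmark_truth(fc, names(fc)[abs(fc) > 0.5],
                        concordance = list(
                          perfect = list(scale = 1, noise_sd = 0),
                          half = list(scale = 0.5, noise_sd = 0)))
  out <- generate_benchmark(bt, seed = 2)
  h <- harmonize_tables(out$models, out$gold)
  si_perfect <- similarity(h$models$perfect$log2fc, h$gold$log2fc)
  si_half <- similarity(h$models$half$log2fc, h$gold$log2fc)
  expect_equal(si_perfect, rep(1, 4))
  expect_equal(si_half, rep(0.5, 4))
})

test_that("higher concordance scale yields larger recovery at threshold 1", {
  set.seed(4)
  fc <- setNames(rnorm(100, 0, 1.5), sprintf("b%03d", 1:100))
  bt <- benchmark_truth(fc, names(fc)[abs(fc) > 0.5],
                        concordance = list(
                          good = list(scale = 1.0, noise_sd = 0.1),
                          poor = list(scale = 0.3, noise_sd = 0.1)))
  out <- generate_benchmark(bt, seed = 7)
  h <- harmonize_tables(out$models, out$gold)
  r_good <- recovered_at_one(similarity(h$models$good$log2fc, h$gold$log2fc))
  r_poor <- recovered_at_one(similarity(h$models$poor$log2fc, h$gold$log2fc))
  expect_gt(r_good, r_poor)
})

test_that("benchmark truth validates its gold DE set and gene universe", {
  expect_error(benchmark_truth(setNames(numeric(0), character(0)),
                               character(0), list()), "empty")
  expect_error(benchmark_truth(setNames(c(1, 0), c("a", "b")), c("b"),
                               list()), "nonzero")
})
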