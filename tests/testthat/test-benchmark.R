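test_that("the similarity ratio reproduces its worked values", {
  expect_equal(similarity(2, 2), 1)
  expect_equal(similarity(1.0, 2.0), 0.5)
  expect_equal(similarity(-1.0, 2.0), -0.5)
  expect_true(is.na(similarity(1, 0)))
  # scale equivariance: scaling the model fold changes scales Si
  fc_gold <- c(1.2, -0.8, 2.5)
  fc_model <- c(0.6, -1.0, 2.0)
  expect_equal(similarity(3 * fc_model, fc_gold),
               3 * similarity(fc_model, fc_gold))
})

test_that("harmonization restricts to the common gold-DE universe", {
  genes <- sprintf("g%02d", 1:10)
  gold <- data.frame(gene = genes, log2fc = c(2, -1, 1.5, 3, 0.2, 0.1,
                                              -2, 0.3, 1, 0.5),
                     de_flag = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6)))
  m1 <- data.frame(gene = genes, log2fc = rnorm(10))
  m2 <- data.frame(gene = genes, log2fc = rnorm(10))
  h <- harmonize_tables(list(a = m1, b = m2), gold)
  expect_equal(h$universe, genes[1:4])
  expect_equal(nrow(h$gold), 4)
  expect_equal(h$models$a$gene, genes[1:4])
  # genes missing from one table drop out of the universe
  h2 <- harmonize_tables(list(a = m1[-1, ], b = m2), gold)
  expect_equal(h2$universe, genes[2:4])
  # gold DE from p_adj when flags are absent
  gold_p <- data.frame(gene = genes, log2fc = gold$log2fc,
                       p_adj = c(0.01, 0.2, 0.01, 0.01, rep(0.9, 6)))
  h3 <- harmonize_tables(list(a = m1), gold_p)
  expect_equal(h3$universe, genes[c(1, 3, 4)])
  expect_error(harmonize_tables(list(a = m1[0, ]), gold), "empty")
})

test_that("ortholog mapping drops ambiguous and unmapped symbols", {
  gold <- data.frame(gene = c("TP53", "GDF15", "ATF4"),
                     log2fc = c(2, 1.5, 1), de_flag = TRUE)
  rat <- data.frame(gene = c("Tp53", "Gdf15", "Atf4", "Weird"),
                    log2fc = c(1, 1, 1, 1))
  map <- data.frame(
    source_symbol = c("Tp53", "Gdf15", "Atf4", "Dup", "Dup"),
    human_symbol = c("TP53", "GDF15", "ATF4", "A", "B"))
  expect_warning(
    expect_warning(h <- harmonize_tables(list(rat = rat), gold,
                                         ortholog_map = map,
                                         map_tables = "rat"),
                   "ambiguous"),
    "unmapped")
  expect_setequal(h$universe, c("TP53", "GDF15", "ATF4"))
  # identity mapping is a no-op
  idmap <- data.frame(source_symbol = gold$gene, human_symbol = gold$gene)
  hum <- data.frame(gene = gold$gene, log2fc = c(2, 1, 0.5))
  h_id <- harmonize_tables(list(m = hum), gold, ortholog_map = idmap,
                           map_tables = "m")
  h_no <- harmonize_tables(list(m = hum), gold)
  expect_equal(h_id, h_no)
})

test_that("recovery curves count thresholded similarities exactly", {
  si <- c(1.2, 0.9, -0.3, 1.0, 0.4)
  rc <- recovery_curve(si, thresholds = c(0.5, 1.0))
  expect_equal(rc$count, c(3L, 2L))
  expect_equal(recovered_at_one(si), 2L)
  expect_equal(attr(rc, "universe_size"), 5L)
  # below the minimum every gene is recovered
  expect_equal(recovery_curve(si, thresholds = -1)$count, 5L)
  # a perfect model is all-or-nothing around 1
  rc1 <- recovery_curve(rep(1, 7), thresholds = seq(0, 2, 0.5))
  expect_equal(rc1$count, c(7L, 7L, 7L, 0L, 0L))
  expect_equal(recovered_at_one(rep(1, 7)), 7L)
  # curve is nonincreasing and equals brute-force enumeration
  set.seed(20)
  si2 <- rnorm(50)
  grid <- seq(0, 2, by = 0.05)
  rc2 <- recovery_curve(si2, grid)
  expect_true(all(diff(rc2$count) <= 0))
  expect_equal(rc2$count,
               vapply(grid, function(t) sum(si2 >= t), integer(1)))
  expect_equal(recovered_at_one(si2), rc2$count[rc2$threshold == 1])
  expect_error(recovery_curve(numeric(0)), "empty")
  expect_error(recovery_curve(si, thresholds = c(1, 0.5)), "ascending")
})

test_that("noise-free scale-s truth gives all-or-nothing recovery at threshold s", {
  set.seed(30)
  fc <- setNames(rnorm(40, 0, 2), sprintf("g%02d", 1:40))
  for (s in c(0.5, 1, 1.5)) {
    bt <- benchmark_truth(fc, names(fc)[fc != 0],
                          concordance = list(m = list(scale = s,
                                                      noise_sd = 0)))
    out <- generate_benchmark(bt, seed = 1)
    # thresholds bracket s rather than hitting it exactly: si = (s * fc) / fc
    # reproduces s only to floating-point rounding
    bm <- benchmark_models(out$models, out$gold,
                           thresholds = c(s - 0.01, s + 0.01))
    expect_equal(bm$curves$count, c(bm$universe_size, 0L))
  }
})

test_that("the full benchmark ranks models by planted concordance", {
  set.seed(31)
  fc <- setNames(rnorm(150, 0, 1.5), sprintf("g%03d", 1:150))
  bt <- benchmark_truth(fc, names(fc)[abs(fc) > 0.8],
                        concordance = list(
                          good = list(scale = 1, noise_sd = 0.1),
                          mid = list(scale = 0.6, noise_sd = 0.1),
                          poor = list(scale = 0.2, noise_sd = 0.1)))
  out <- generate_benchmark(bt, seed = 3)
  bm <- benchmark_models(out$models, out$gold)
  # recovered_at_one sits on a knife edge for scale 1 (si = 1 + noise), so
  # rank the models at threshold 0.5 where the planted scales separate
  cv <- bm$curves[abs(bm$curves$threshold - 0.5) < 1e-12, ]
  n05 <- setNames(cv$count, cv$model)
  expect_true(n05["good"] > n05["mid"] && n05["mid"] > n05["poor"])
  r <- bm$recovered_at_one
  expect_true(r["good"] >= r["mid"] && r["mid"] >= r["poor"])
  expect_true(all(bm$similarity$si[bm$similarity$model == "good"] > 0.5))
})
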