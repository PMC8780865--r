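test_that("signed adjacency maps correlation extremes as a signed network should", {
  n <- 10
  base <- sin(seq_len(n))
  expr <- rbind(g1 = base, g2 = 2 * base + 5, g3 = -base,
                g4 = rep(1, n) + c(1e-8 * seq_len(n)))
  a <- signed_adjacency(expr[1:3, ], power = 6)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(a["g1", "g3"], 0)
  expect_equal(unname(diag(a)), rep(1, 3))
  # orthogonal profiles: correlation 0 gives 0.5^power
  x <- c(1, -1, 1, -1, 1, -1)
  y <- c(1, 1, -1, -1, 1, 1) - mean(c(1, 1, -1, -1, 1, 1))
  a2 <- signed_adjacency(rbind(x = x, y = y), power = 3)
  expect_equal(a2["x", "y"], 0.5^3)
  const <- rbind(g1 = base, flat = rep(2, n))
  expect_warning(a3 <- signed_adjacency(const, 2), "zero-variance")
  # zero-variance correlations are set to 0, giving adjacency 0.5^power
  expect_equal(a3["g1", "flat"], 0.5^2)
})

test_that("TOM matches the brute-force triple loop and its fixed points", {
  a <- matrix(c(1, .5, .2,
                .5, 1, .4,
                .2, .4, 1), 3, 3)
  tom <- tom_similarity(a)
  # hand expansion for the (1,2) entry
  k <- c(.5 + .2, .5 + .4, .2 + .4)
  expect_equal(tom[1, 2], (.2 * .4 + .5) / (min(k[1], k[2]) + 1 - .5))
  expect_equal(tom, tom_bruteforce(a))
  expect_true(isSymmetric(tom))
  expect_equal(unname(diag(tom)), rep(1, 3))
  # two genes with identical full-strength neighbourhoods overlap completely
  b <- matrix(c(1, 1, 1, 1,
                1, 1, 1, 1,
                1, 1, 1, .2,
                1, 1, .2, 1), 4, 4)
  tomb <- tom_similarity(b)
  expect_equal(tomb[1, 2], 1)
  expect_error(tom_similarity(matrix(c(1, .2, .5, 1), 2, 2)), "symmetric")
  set.seed(77)
  for (i in 1:20) {
    g <- sample(3:6, 1)
    m <- matrix(runif(g * g), g, g)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    t1 <- tom_similarity(m)
    expect_equal(t1, tom_bruteforce(m), tolerance = 1e-12)
    expect_true(all(t1 >= 0 & t1 <= 1 + 1e-12))
  }
})

test_that("planted blocks are recovered as modules, invariant to gene order", {
  expr <- two_block_expr(block = 50, n = 40, seed = 3)
  ms <- find_modules(expr, power = 6, min_size = 20)
  truth <- rep(1:2, each = 50)
  expect_gte(ari(ms$modules, truth), 0.9)
  expect_equal(length(setdiff(unique(ms$modules), "unassigned")), 2)
  set.seed(5)
  perm <- sample(nrow(expr))
  ms_perm <- find_modules(expr[perm, ], power = 6, min_size = 20)
  expect_equal(ari(ms_perm$modules[rownames(expr)], ms$modules), 1)
})

test_that("independent genes yield no modules and the fallback power", {
  set.seed(6)
  expr <- matrix(rnorm(120 * 30), 120, 30,
                 dimnames = list(sprintf("g%03d", 1:120), NULL))
  ms <- find_modules(expr, power = 6, min_size = 20)
  expect_true(all(ms$modules == "unassigned") ||
                max(table(ms$modules[ms$modules != "unassigned"])) < 40)
  pk <- pick_soft_threshold(expr, powers = c(2, 4, 6))
  expect_true(pk$power %in% c(2, 4, 6, 12))
  expect_equal(pick_soft_threshold(expr, powers = 5)$power %in% c(5, 12), TRUE)
  expect_warning(pick_soft_threshold(expr[1:10, ], powers = c(2, 4)),
                 "fallback")
})

test_that("soft-threshold choice is stable across adjacent seeds on planted data", {
  p1 <- pick_soft_threshold(two_block_expr(seed = 11), powers = c(2, 4, 6, 8))
  p2 <- pick_soft_threshold(two_block_expr(seed = 12), powers = c(2, 4, 6, 8))
  expect_equal(p1$power, p2$power)
})

test_that("eigengenes and kME capture module structure", {
  n <- 12
  base <- rnorm(n)
  expr <- rbind(g1 = base, g2 = 2 * base + 1, g3 = base / 3)
  eg <- module_eigengene(expr, rownames(expr))
  expect_equal(sum(eg^2), 1)
  expect_equal(unname(kme(expr, eg)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(kme(rbind(neg = -base), eg)), -1, tolerance = 1e-9)
  # eigengene captures at least as much variance as any single gene profile
  xs <- t(scale(t(expr)))
  v_eg <- sum((xs %*% eg)^2)
  v_single <- max(apply(xs, 1, function(g) {
    d <- g / sqrt(sum(g^2)); sum((xs %*% d)^2)
  }))
  expect_gte(v_eg, v_single - 1e-9)
  expect_error(module_eigengene(expr, character(0)), "empty")
})

test_that("kME ordering follows the planted signal-to-noise ordering", {
  set.seed(9)
  n <- 60
  base <- rnorm(n)
  noise <- seq(0.1, 2, length.out = 20)
  expr <- t(sapply(noise, function(s) base + rnorm(n, sd = s)))
  rownames(expr) <- sprintf("g%02d", 1:20)
  eg <- module_eigengene(expr, rownames(expr))
  k <- kme(expr, eg)
  expect_gte(cor(rank(-k), rank(noise), method = "spearman"), 0.9)
})

test_that("module activity is a bounded, monotone-invariant rank score", {
  set.seed(10)
  expr <- matrix(rnorm(200), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:10)))
  modules <- setNames(rep(c("M1", "unassigned"), c(5, 15)), rownames(expr))
  act <- module_activity(expr, modules)
  expect_true(all(act >= -1 & act <= 1))
  # maximal case: module genes occupy the top ranks in a sample
  expr2 <- expr
  expr2[1:5, 1] <- 100 + 1:5
  expect_equal(unname(module_activity(expr2, modules)["M1", 1]), 1)
  # invariant under a monotone transform of a sample's values
  expr3 <- expr
  expr3[, 2] <- exp(expr3[, 2])
  expect_equal(module_activity(expr3, modules), act)
  expect_error(module_activity(expr, setNames(rep("M1", 20), rownames(expr))),
               "covers all")
})

test_that("a planted dose-dependent module shows monotone median activity", {
  st <- simulate_study(n_genes = 120, n_modules = 4, chemicals = "diclofenac",
                       responsive = list(diclofenac = list(
                         pathways = "ATF4", effect = 1.0)),
                       seed = 55)
  expr <- log2cpm(st$counts)
  modules <- setNames(ifelse(names(st$truth$module_assignment) %in%
                               st$gene_sets$ATF4, "UPR", "unassigned"),
                      names(st$truth$module_assignment))
  act <- module_activity(expr, modules)
  conc <- st$design$concentration_uM[match(colnames(act), st$design$sample_id)]
  med <- tapply(act["UPR", ], conc, median)
  expect_true(all(diff(med) > -0.02))
  expect_gt(med[length(med)], med[1])
})
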