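# Independent oracles and small fixture builders shared by the suite.

# brute-force Benjamini-Hochberg step-up: adjusted p_i = min over j with
# p_(j) >= p_(i) of m * p_(j) / j, capped at 1
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[ord[i]] / i)
    adj_sorted[i] <- min(1, running)
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# triple-loop topological overlap oracle
tom_bruteforce <- function(a) {
  g <- nrow(a)
  ad <- a
  diag(ad) <- 0
  k <- rowSums(ad)
  tom <- diag(g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(g)) {
      if (u != i && u != j) s <- s + ad[i, u] * ad[u, j]
    }
    tom[i, j] <- (s + ad[i, j]) / (min(k[i], k[j]) + 1 - ad[i, j])
  }
  tom
}

# hypergeometric z oracle: standardise r by the mean and variance of
# X ~ Hypergeometric(N, R, n) computed numerically from dhyper
hyper_z_oracle <- function(N, R, r, n) {
  x <- 0:n
  pmf <- dhyper(x, R, N - R, n)
  mu <- sum(x * pmf)
  v <- sum((x - mu)^2 * pmf)
  if (v <= 0) return(NA_real_)
  (r - mu) / sqrt(v)
}

# Poisson log-linear GLM by direct likelihood maximisation (generic optim),
# independent of the IRLS path used by the package
poisson_glm_oracle <- function(y, x, offset = rep(0, length(y))) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x + offset
    sum(exp(eta) - y * eta)
  }
  grad <- function(b) {
    eta <- b[1] + b[2] * x + offset
    d <- exp(eta) - y
    c(sum(d), sum(d * x))
  }
  fit <- optim(c(log(mean(y) + 0.5), 0), nll, grad, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 2000))
  fit$par
}

# expression matrix with two planted correlated blocks of `block` genes each
two_block_expr <- function(block = 50, n = 40, noise_sd = 0.35, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(2 * n), 2, n)
  expr <- rbind(
    base[rep(1, block), ] + matrix(rnorm(block * n, sd = noise_sd), block, n),
    base[rep(2, block), ] + matrix(rnorm(block * n, sd = noise_sd), block, n))
  rownames(expr) <- sprintf("g%03d", seq_len(2 * block))
  colnames(expr) <- sprintf("s%02d", seq_len(n))
  expr
}

# pure-null NB count fixture: no effects, no module latent factor
null_count_fixture <- function(n_genes = 2000, alpha = 0.1, mu = 100,
                               concentrations = rep(c(0, 1, 2), each = 2),
                               seed = 11) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  truth <- count_truth(
    setNames(rep("m1", n_genes), genes),
    list(),
    data.frame(gene = character(), chemical = character(),
               log2fc_per_uM = numeric()),
    setNames(rep(alpha, n_genes), genes),
    setNames(rep(mu, n_genes), genes),
    module_sdlog = 0)
  design <- data.frame(
    sample_id = sprintf("s%d", seq_along(concentrations)),
    chemical = "x", concentration_uM = concentrations, time_h = 48,
    replicate = seq_along(concentrations))
  list(truth = truth, design = design,
       counts = generate_counts(truth, design, seed = seed))
}

# adjusted Rand index with "unassigned" treated as its own class
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
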