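# independent recomputation of prevalence/heritability/marginals used to
# check the simulator against its own stored values
hwe <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)
recompute_model_stats <- function(m) {
  p <- apply(m$genotype, 1, function(g)
    prod(mapply(function(v, q) hwe(q)[v + 1], g, m$maf)))
  K <- sum(p * m$penetrance)
  h2 <- sum(p * (m$penetrance - K)^2) / (K * (1 - K))
  marg <- max(unlist(lapply(seq_len(ncol(m$genotype)), function(i)
    sapply(0:2, function(v) {
      sel <- m$genotype[, i] == v
      abs(sum(p[sel] * m$penetrance[sel]) / sum(p[sel]) - K)
    }))))
  list(K = K, h2 = h2, marginal_dev = marg)
}

test_that("a constant penetrance table has zero heritability", {
  grid <- fmdr:::.model_grid(c(0.2, 0.2))
  expect_equal(fmdr:::.heritability(grid$p, rep(0.3, 9)), 0)
})

test_that("sampled penetrance models satisfy their own invariants", {
  for (cfg in list(list(n = 2, maf = 0.2, h2 = 0.2),
                   list(n = 2, maf = 0.4, h2 = 0.4),
                   list(n = 3, maf = 0.4, h2 = 0.2),
                   list(n = 2, maf = 0.1, h2 = 0.2))) {
    m <- sample_penetrance_model(cfg$n, cfg$maf, cfg$h2, seed = 17)
    stats <- recompute_model_stats(m)
    expect_equal(stats$K, m$prevalence, tolerance = 1e-10)
    expect_equal(stats$h2, m$h2, tolerance = 1e-10)
    expect_lte(abs(stats$h2 - cfg$h2) / cfg$h2, 0.1)
    expect_lt(stats$marginal_dev, 0.01)
    expect_true(all(m$penetrance >= 0 & m$penetrance <= 1))
  }
})

test_that("infeasible targets fail with the best-achieved heritability", {
  expect_error(
    sample_penetrance_model(2, 0.02, 0.9, seed = 1, max_tries = 5),
    "best achieved h2")
})

test_that("generated data sets fill quotas exactly and record the truth", {
  m <- sample_penetrance_model(2, 0.2, 0.2, seed = 5)
  sim <- generate_dataset(m, 400, 400, n_noise_snps = 48, seed = 9)
  expect_equal(sum(sim$data$phenotype == 1L), 400L)
  expect_equal(sum(sim$data$phenotype == 0L), 400L)
  expect_equal(ncol(sim$data$genotypes), 50L)
  expect_length(sim$causal_loci, 2L)
  expect_false(is.unsorted(sim$causal_loci, strictly = TRUE))

  # determinism
  sim2 <- generate_dataset(m, 400, 400, n_noise_snps = 48, seed = 9)
  expect_identical(sim$data$genotypes, sim2$data$genotypes)
  expect_identical(sim$causal_loci, sim2$causal_loci)
})

test_that("noise SNPs sit at their nominal allele frequency", {
  m <- sample_penetrance_model(2, 0.2, 0.2, seed = 5)
  sim <- generate_dataset(m, 2000, 2000, n_noise_snps = 30,
                          noise_maf = 0.3, seed = 21)
  noise <- setdiff(seq_len(32), sim$causal_loci)
  mafs <- colMeans(sim$data$genotypes[, noise]) / 2
  expect_true(all(abs(mafs - 0.3) < 0.02))
})

test_that("the planted signal is pure epistasis: joint but not marginal", {
  m <- sample_penetrance_model(2, 0.3, 0.2, seed = 31)
  sim <- generate_dataset(m, 10000, 10000, n_noise_snps = 2, seed = 33)
  cl <- sim$causal_loci
  g <- sim$data$genotypes
  ph <- sim$data$phenotype
  # joint 9-cell association is overwhelming at this sample size
  joint <- suppressWarnings(
    stats::chisq.test(table(g[, cl[1]] * 3 + g[, cl[2]], ph)))
  expect_lt(joint$p.value, 0.01)
  # single-locus margins are flat by construction
  for (l in cl) {
    single <- suppressWarnings(stats::chisq.test(table(g[, l], ph)))
    expect_gt(single$p.value, 0.01)
  }
})

test_that("shuffled phenotypes break the planted association", {
  sim <- simulate_epistasis(seed = 41, maf = 0.2, h2 = 0.4,
                            n_cases = 300, n_controls = 300, n_snps = 15)
  sr <- exhaustive_search(sim$data, 2)
  expect_equal(unname(sr$combos[1, ]), sim$causal_loci)
  shuffled <- sim$data
  set.seed(42)
  shuffled$phenotype <- sample(shuffled$phenotype)
  sr2 <- exhaustive_search(shuffled, 2)
  expect_false(identical(unname(sr2$combos[1, ]), sim$causal_loci))
  expect_gt(sr2$training_error[1], sr$training_error[1])
})

test_that("the six benchmark designs carry the documented settings", {
  d <- simulation_designs()
  expect_equal(nrow(d), 6L)
  expect_equal(d$maf, rep(c(0.1, 0.2, 0.4), each = 2))
  expect_equal(d$n_cases + d$n_controls, rep(c(800L, 1600L), 3))
  expect_true(all(d$n_cases == d$n_controls))
  expect_true(all(d$h2 == 0.2))
  expect_true(all(d$n_snps == 50L))
  # model 6: MAF 0.4, 800 cases and 800 controls
  expect_equal(d[d$model == 6, c("maf", "n_cases", "n_controls")],
               data.frame(maf = 0.4, n_cases = 800L, n_controls = 800L,
                          row.names = 6L))
  sim <- simulate_design(2, seed = 3)
  expect_equal(dim(sim$data), c(1600L, 50L))
  expect_identical(simulate_design(2, seed = 3)$data$genotypes,
                   sim$data$genotypes)
})
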