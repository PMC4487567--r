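test_that("retention sizes follow the ceil-percentage rule with floor and cap", {
  cfg <- retention_config(2)
  expect_equal(fmdr:::.retained_size(cfg, 2L, 1225L), 25L)   # ceil(.02*1225)
  expect_equal(fmdr:::.retained_size(retention_config(100), 2L, 1225L), 1225L)
  expect_equal(fmdr:::.retained_size(retention_config(0.01), 3L, 50L), 1L)
  expect_equal(fmdr:::.retained_size(
    retention_config(10, min_retained = 8), 3L, 50L), 8L)
  expect_equal(fmdr:::.retained_size(
    retention_config(10, per_order = c("3" = 50)), 3L, 50L), 25L)
  expect_error(retention_config(0), "in \\(0, 100\\]")
  expect_error(retention_config(120), "in \\(0, 100\\]")
})

test_that("order-2 seeding is the truncated exhaustive search", {
  data <- random_gm(120, 12, 31)
  sr <- exhaustive_search(data, 2)
  mem <- seed_order2(data, config = retention_config(10))
  expect_equal(nrow(mem$combos), ceiling(0.1 * choose(12, 2)))
  expect_equal(mem$evaluated, choose(12, 2))
  expect_equal(mem$combos[1, ], sr$combos[1, ])
  expect_equal(mem$training_error, sr$training_error[seq_len(nrow(mem$combos))])

  mem_all <- seed_order2(data, config = retention_config(100))
  expect_equal(mem_all$combos, sr$combos)
})

test_that("candidate extension unions, deduplicates and canonicalises", {
  mem <- structure(list(fold_index = 1L, order = 2L,
                        combos = rbind(c(1L, 2L), c(1L, 3L)),
                        training_error = c(0.1, 0.2), evaluated = 6L),
                   class = "fold_memory")
  cand <- extend_candidates(mem, 4L)
  expect_equal(cand, rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L)))

  # one retained combination extends to exactly N - m candidates
  mem1 <- structure(list(fold_index = 1L, order = 3L,
                         combos = rbind(c(2L, 5L, 7L)),
                         training_error = 0.1, evaluated = 10L),
                    class = "fold_memory")
  expect_equal(nrow(extend_candidates(mem1, 9L)), 6L)

  # retaining all C(N, m) combinations regenerates all C(N, m+1)
  for (N in c(6L, 8L)) {
    all_m <- t(utils::combn(N, 2L))
    memf <- structure(list(fold_index = 1L, order = 2L, combos = all_m,
                           training_error = numeric(nrow(all_m)),
                           evaluated = nrow(all_m)),
                      class = "fold_memory")
    expect_equal(extend_candidates(memf, N), t(utils::combn(N, 3L)))
  }
  expect_error(extend_candidates(mem1, 3L), "cannot extend")
})

test_that("advancing with full retention reproduces the exhaustive ranking", {
  data <- random_gm(100, 8, 41)
  cfg <- retention_config(100)
  mem <- seed_order2(data, config = cfg)
  for (target in 3:4) {
    mem <- advance_order(data, NULL, mem, cfg)
    sr <- exhaustive_search(data, target)
    expect_equal(mem$combos, sr$combos)
    expect_equal(mem$training_error, sr$training_error)
    expect_equal(mem$evaluated, choose(8, target))
  }
})

test_that("candidate counts respect the greedy construction bound", {
  data <- random_gm(150, 20, 51)
  cfg <- retention_config(10)
  mem <- seed_order2(data, config = cfg)
  for (i in 1:2) {
    retained <- nrow(mem$combos)
    m <- mem$order
    mem <- advance_order(data, NULL, mem, cfg)
    expect_lte(mem$evaluated, retained * (20L - m))
    expect_lt(mem$evaluated, choose(20, mem$order))
  }
})

test_that("retained sub-signals guarantee the causal superset is generated", {
  # joint-effect property: whenever a 2-subset of a causal triple survives
  # in memory, the triple itself must appear among the order-3 candidates
  sim <- simulate_epistasis(seed = 61, order = 3, maf = 0.4, h2 = 0.3,
                            n_cases = 300, n_controls = 300, n_snps = 12)
  mem <- seed_order2(sim$data, config = retention_config(25))
  pairs_of_causal <- t(utils::combn(sim$causal_loci, 2L))
  retained_keys <- apply(mem$combos, 1, paste, collapse = ",")
  if (any(apply(pairs_of_causal, 1, paste, collapse = ",") %in%
          retained_keys)) {
    cand <- extend_candidates(mem, 12L)
    expect_true(paste(sim$causal_loci, collapse = ",") %in%
                  apply(cand, 1, paste, collapse = ","))
  }
  # unconditionally: every extension of every retained combo is present
  cand <- extend_candidates(mem, 12L)
  keys <- apply(cand, 1, paste, collapse = ",")
  for (i in seq_len(nrow(mem$combos))) {
    for (s in setdiff(1:12, mem$combos[i, ])) {
      expect_true(paste(sort(c(mem$combos[i, ], s)), collapse = ",") %in%
                    keys)
    }
  }
})
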