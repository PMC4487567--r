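test_that("cell ratio reproduces the worked example and forced values", {
  # 88 cases / 90 controls in a cell, 300 cases and 300 controls in training
  expect_equal(round(cell_ratio(88, 90, 300, 300), 3), 0.978)
  # balanced counts give exactly 1 regardless of scale
  for (k in c(1, 7, 50)) expect_equal(cell_ratio(k, k, 123, 123), 1)
  expect_equal(cell_ratio(10, 5, 100, 200), 4)
  expect_identical(cell_ratio(3, 0, 10, 10), Inf)
  expect_true(is.na(cell_ratio(0, 0, 10, 10)))
  expect_error(cell_ratio(-1, 2, 10, 10), "non-negative")
  expect_error(cell_ratio(1, 2, 0, 10), ">= 1")
})

test_that("imbalance correction reduces to the plain ratio on balanced data", {
  set.seed(3)
  cc <- sample(0:30, 20, replace = TRUE)
  nn <- sample(1:30, 20, replace = TRUE)
  expect_equal(cell_ratio(cc, nn, 250, 250), cc / nn)
  # and in general equals (cases/controls) * (N*/P*)
  expect_equal(cell_ratio(cc, nn, 193, 704), (cc / nn) * (704 / 193))
})

test_that("cell tables count exactly the subset, matching a brute recount", {
  gm <- genotype_matrix(matrix(c(0L, 0L, 0L, 0L), 2, 2), c(1, 0))
  tab <- build_cell_table(gm, c(1L, 2L))
  expect_equal(nrow(tab$genotype), 1L)
  expect_equal(tab$case_count, 1L)
  expect_equal(tab$control_count, 1L)

  for (seed in 1:4) {
    data <- random_gm(200, 8, seed)
    combo <- sort(sample(8, sample(2:3, 1)))
    subset <- sample(200, 150)
    tab <- build_cell_table(data, combo, subset)
    oracle <- brute_cell_counts(data, combo, subset)
    expect_equal(nrow(tab$genotype), length(oracle))
    for (i in seq_along(tab$case_count)) {
      key <- paste(tab$genotype[i, ], collapse = "-")
      expect_equal(unname(oracle[[key]]),
                   c(tab$case_count[i], tab$control_count[i]))
    }
    expect_equal(sum(tab$case_count), tab$case_total)
    expect_equal(sum(tab$control_count), tab$control_total)
    expect_lte(nrow(tab$genotype), 3^length(combo))
  }
})

test_that("all-case subsets yield zero control counts and empty subsets error", {
  data <- random_gm(60, 4, 9)
  cases <- which(data$phenotype == 1L)
  tab <- build_cell_table(data, c(1L, 3L), cases)
  expect_true(all(tab$control_count == 0L))
  expect_equal(tab$control_total, 0L)
  expect_error(build_cell_table(data, c(1L, 3L), integer(0)), "empty")
  expect_error(build_cell_table(data, c(1L, 9L)), "out of range")
  expect_error(build_cell_table(data, c(3L, 1L)), "strictly increasing")
})

test_that("H/L labelling follows the threshold rule with its boundary", {
  # 88 cases / 90 controls in the AA cell of a 300-case/300-control
  # training set: corrected ratio 0.978 < 1 -> L
  gm88 <- genotype_matrix(
    matrix(c(rep(0L, 88), rep(1L, 212), rep(0L, 90), rep(1L, 210))),
    c(rep(1L, 300), rep(0L, 300)))
  tab <- build_cell_table(gm88, 1L)
  expect_equal(unname(label_cells(tab, T = 1)$labels[tab$genotype[, 1] == 0L]),
               "L")
  # ratio exactly 1 -> H ("equal to or greater")
  gm1 <- genotype_matrix(matrix(0L, 10, 1), rep(c(1L, 0L), 5))
  expect_equal(label_cells(build_cell_table(gm1, 1L))$labels, "H")
  # cases with no controls -> infinite ratio -> H at any threshold
  gm2 <- genotype_matrix(matrix(rep(c(0L, 1L), each = 5), 10, 1),
                         rep(c(1L, 0L), each = 5))
  lab <- label_cells(build_cell_table(gm2, 1L), T = 50)
  expect_equal(unname(lab$labels[lab$genotype[, 1] == 0L]), "H")
  expect_equal(unname(lab$labels[lab$genotype[, 1] == 1L]), "L")
  expect_error(label_cells(build_cell_table(gm2, 1L), T = 0), "T must be")
})

test_that("confusion pooling matches a per-sample recount and conserves totals", {
  for (seed in 5:8) {
    data <- random_gm(100, 10, seed, case_frac = 0.4)
    combo <- sort(sample(10, 2))
    train <- sample(100, 70)
    test <- setdiff(seq_len(100), train)
    lab <- label_cells(build_cell_table(data, combo, train))
    for (subset in list(train, test)) {
      ct <- confusion_from_labels(data, combo, lab, subset)
      oracle <- brute_confusion(data, combo, lab, subset)
      expect_equal(ct[c("TP", "FP", "TN", "FN")],
                   oracle[c("TP", "FP", "TN", "FN")],
                   ignore_attr = TRUE)
      expect_equal(ct$TP + ct$FN, sum(data$phenotype[subset] == 1L))
      expect_equal(ct$FP + ct$TN, sum(data$phenotype[subset] == 0L))
      expect_equal(ct$TP + ct$FP + ct$TN + ct$FN, length(subset))
    }
  }
})

test_that("an all-H labelling leaves no negatives", {
  data <- random_gm(50, 3, 2, case_frac = 0.9)  # cases dominate every cell?
  combo <- c(1L, 2L)
  tab <- build_cell_table(data, combo)
  lab <- label_cells(tab)
  lab$labels[] <- "H"
  ct <- confusion_from_labels(data, combo, lab)
  expect_equal(ct$FN, 0L)
  expect_equal(ct$TN, 0L)
})

test_that("balanced error has its forced values and scale invariance", {
  expect_equal(balanced_error(list(TP = 80, FN = 20, FP = 30, TN = 70)), 0.25)
  expect_equal(balanced_error(list(TP = 5, FN = 0, FP = 0, TN = 9)), 0)
  expect_equal(balanced_error(list(TP = 4, FN = 4, FP = 7, TN = 7)), 0.5)
  expect_error(balanced_error(list(TP = 0, FN = 0, FP = 3, TN = 3)),
               "zero denominator|lacks one class")
  # duplicating every sample leaves the error unchanged
  set.seed(1)
  for (i in 1:5) {
    ct <- as.list(setNames(sample(1:50, 4), c("TP", "FP", "TN", "FN")))
    ct2 <- lapply(ct, `*`, 2L)
    expect_equal(balanced_error(ct), balanced_error(ct2))
  }
})

test_that("evaluate_combination composes train and test scoring correctly", {
  gm <- separable_gm()
  sc <- evaluate_combination(gm, c(1L, 3L), seq_len(nrow(gm$genotypes)))
  expect_equal(sc$training_error, 0)

  # phenotype-independent genotypes: training error near chance
  data <- random_gm(2000, 4, 77)
  sc2 <- evaluate_combination(data, c(1L, 2L), seq_len(2000))
  expect_lt(abs(sc2$training_error - 0.5), 0.05)

  # composed route agrees with the fast search path, train and test
  for (seed in 1:5) {
    data <- random_gm(120, 6, seed)
    train <- sample(120, 90)
    test <- setdiff(seq_len(120), train)
    ctx <- fmdr:::.fold_context(data, train, test)
    combo <- sort(sample(6, 2))
    fast <- fmdr:::.score_combo(ctx, combo)
    slow <- evaluate_combination(data, combo, train, test)
    expect_equal(slow$training_error, fast[1])
    expect_equal(slow$testing_error, fast[2])
  }
})

test_that("exhaustive search enumerates C(N,n) models, ranked with stable ties", {
  data <- random_gm(100, 50, 11)
  sr <- exhaustive_search(data, 2)
  expect_equal(sr$evaluated, 1225L)
  expect_equal(nrow(sr$combos), choose(50, 2))
  expect_false(is.unsorted(sr$training_error))

  small <- random_gm(40, 5, 12)
  expect_equal(exhaustive_search(small, 5)$evaluated, 1L)
  expect_error(exhaustive_search(small, 6), "between 1 and")

  # ties broken by lexicographically smallest loci tuple
  tied <- which(sr$training_error == sr$training_error[1])
  if (length(tied) > 1) {
    first_two <- sr$combos[tied[1:2], ]
    expect_true(first_two[1, 1] < first_two[2, 1] ||
                  (first_two[1, 1] == first_two[2, 1] &&
                     first_two[1, 2] < first_two[2, 2]))
  }
})

test_that("a strongly planted pair ranks first in the exhaustive search", {
  for (seed in c(21, 22, 23)) {
    sim <- simulate_epistasis(seed = seed, maf = 0.2, h2 = 0.4,
                              n_cases = 400, n_controls = 400, n_snps = 12)
    sr <- exhaustive_search(sim$data, 2)
    expect_equal(unname(sr$combos[1, ]), sim$causal_loci)
  }
})
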