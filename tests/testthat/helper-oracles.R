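# Independent brute-force oracles and small fixture builders.  These
# deliberately avoid the package's vectorised code paths: counting is done
# with per-sample loops so the fast implementations are checked against a
# different route.

random_gm <- function(n_samples, n_snps, seed, case_frac = 0.5) {
  set.seed(seed)
  n_cases <- max(1L, round(n_samples * case_frac))
  pheno <- sample(c(rep(1L, n_cases), rep(0L, n_samples - n_cases)))
  genotype_matrix(matrix(sample(0:2, n_samples * n_snps, replace = TRUE),
                         nrow = n_samples),
                  pheno)
}

# per-sample nested-loop recount of a cell table
brute_cell_counts <- function(data, combo, subset) {
  counts <- list()
  for (s in subset) {
    key <- paste(data$genotypes[s, combo], collapse = "-")
    if (is.null(counts[[key]])) counts[[key]] <- c(case = 0L, control = 0L)
    slot <- if (data$phenotype[s] == 1L) "case" else "control"
    counts[[key]][slot] <- counts[[key]][slot] + 1L
  }
  counts
}

# per-sample recount of the pooled confusion table given an H/L labelling
brute_confusion <- function(data, combo, labeling, subset) {
  lab_of <- setNames(labeling$labels,
                     apply(labeling$genotype, 1L, paste, collapse = "-"))
  TP <- FP <- TN <- FN <- 0L
  for (s in subset) {
    key <- paste(data$genotypes[s, combo], collapse = "-")
    lab <- lab_of[key]
    if (is.na(lab)) lab <- "L"   # unseen cell rule
    case <- data$phenotype[s] == 1L
    if (lab == "H" && case) TP <- TP + 1L
    else if (lab == "H") FP <- FP + 1L
    else if (case) FN <- FN + 1L
    else TN <- TN + 1L
  }
  list(TP = TP, FP = FP, TN = TN, FN = FN)
}

# a data set where one SNP pair separates cases from controls perfectly:
# case iff (g1, g2) is in a fixed set of cells
separable_gm <- function(n = 120, seed = 42) {
  set.seed(seed)
  g1 <- sample(0:2, n, replace = TRUE)
  g2 <- sample(0:2, n, replace = TRUE)
  risk <- (g1 + g2) %% 2 == 0
  if (all(risk) || !any(risk)) stop("degenerate fixture")
  noise <- matrix(sample(0:2, n * 3, replace = TRUE), nrow = n)
  geno <- unname(cbind(g1, noise[, 1], g2, noise[, 2:3]))
  genotype_matrix(geno, as.integer(risk))
}
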