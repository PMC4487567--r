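## Core MDR machinery: multi-locus cell tables, imbalance-corrected
## case:control ratios, H/L risk labelling, confusion pooling, balanced
## classification error, and the exhaustive order-n search.

.check_combo <- function(combo, n_snps) {
  combo <- as.integer(combo)
  if (length(combo) < 1L) stop("locus combination must have order >= 1",
                               call. = FALSE)
  if (anyNA(combo) || any(combo < 1L) || any(combo > n_snps))
    stop("locus index out of range 1..", n_snps, call. = FALSE)
  if (is.unsorted(combo, strictly = TRUE))
    stop("locus combination must be strictly increasing with no duplicates",
         call. = FALSE)
  combo
}

## base-3 cell code in 0..3^n-1 for each sample row; first locus varies fastest
.cell_codes <- function(geno, combo) {
  code <- geno[, combo[1L]]
  if (length(combo) > 1L)
    for (k in 2L:length(combo)) code <- code + 3L^(k - 1L) * geno[, combo[k]]
  as.integer(code)
}

## decode 0..3^n-1 back to genotype tuples (rows), same locus order
.decode_codes <- function(codes, n) {
  out <- matrix(0L, nrow = length(codes), ncol = n)
  for (k in seq_len(n)) out[, k] <- (codes %/% 3L^(k - 1L)) %% 3L
  out
}

#' Tabulate multi-locus genotype cells
#'
#' Counts, for one locus combination and a subset of samples, how many cases
#' and how many controls fall in each observed multi-locus genotype cell.
#' A 2-locus model has up to nine cells (AA-AA ... aa-aa); an order-n model
#' up to 3^n, but only cells actually observed in the subset are returned.
#'
#' @param data a [genotype_matrix].
#' @param combo strictly increasing vector of SNP column indices (the locus
#'   combination).
#' @param subset integer vector of sample row indices to count (e.g. a
#'   training fold); defaults to all samples.
#' @return an object of class \code{cell_table}: list with \code{order},
#'   \code{genotype} (observed cells x order matrix of codes 0/1/2),
#'   \code{case_count}, \code{control_count} (per observed cell),
#'   \code{case_total} (P*), \code{control_total} (N*).
#' @export
build_cell_table <- function(data, combo, subset = seq_along(data$phenotype)) {
  combo <- .check_combo(combo, ncol(data$genotypes))
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("sample subset is empty", call. = FALSE)
  if (any(subset < 1L) || any(subset > nrow(data$genotypes)))
    stop("sample subset index out of range", call. = FALSE)
  n <- length(combo)
  codes <- .cell_codes(data$genotypes[subset, , drop = FALSE], combo)
  pheno <- data$phenotype[subset]
  nb <- 3L^n
  cnt_case <- tabulate(codes[pheno == 1L] + 1L, nbins = nb)
  cnt_ctrl <- tabulate(codes[pheno == 0L] + 1L, nbins = nb)
  observed <- which(cnt_case + cnt_ctrl > 0L)
  structure(list(
    order = n,
    combo = combo,
    genotype = .decode_codes(observed - 1L, n),
    codes = observed - 1L,
    case_count = cnt_case[observed],
    control_count = cnt_ctrl[observed],
    case_total = sum(cnt_case),
    control_total = sum(cnt_ctrl)),
    class = "cell_table")
}

#' Imbalance-corrected case:control cell ratio
#'
#' The ratio used to classify a multi-locus genotype cell as high or low
#' risk, corrected for the overall case:control imbalance of the training
#' set: \deqn{f = (case\_count \times N^*) / (control\_count \times P^*)}
#' where P* and N* are the training-set case and control totals.  On
#' balanced data (P* = N*) this reduces to the plain cell ratio.  A cell
#' with cases but no controls has ratio \code{Inf}; an empty cell returns
#' \code{NA}.
#'
#' @param case_count,control_count per-cell counts (vectorised).
#' @param P_star,N_star training-set case and control totals (>= 1).
#' @return numeric ratio(s).
#' @examples
#' cell_ratio(88, 90, 300, 300)  # 0.9777...
#' @export
cell_ratio <- function(case_count, control_count, P_star, N_star) {
  if (P_star < 1L || N_star < 1L)
    stop("P_star and N_star must be >= 1", call. = FALSE)
  if (any(case_count < 0) || any(control_count < 0))
    stop("cell counts must be non-negative", call. = FALSE)
  r <- (case_count * N_star) / (control_count * P_star)
  r[control_count == 0 & case_count > 0] <- Inf
  r[control_count == 0 & case_count == 0] <- NA_real_
  r
}

#' Label cells high (H) or low (L) risk
#'
#' A cell is labelled "H" when its imbalance-corrected ratio ([cell_ratio])
#' is greater than or equal to the threshold \code{T} (default 1), "L"
#' otherwise.  Cells with cases but no controls (infinite ratio) are "H";
#' cells with controls but no cases are "L".  Only observed cells carry a
#' label.
#'
#' @param table a [build_cell_table()] result.
#' @param T positive risk threshold (default 1).
#' @return an object of class \code{risk_labeling}: list with
#'   \code{labels} (character "H"/"L" per observed cell), \code{codes},
#'   \code{genotype}, \code{order}, \code{threshold}.
#' @export
label_cells <- function(table, T = 1) {
  stopifnot(inherits(table, "cell_table"))
  if (!is.numeric(T) || T <= 0) stop("threshold T must be > 0", call. = FALSE)
  r <- cell_ratio(table$case_count, table$control_count,
                  table$case_total, table$control_total)
  structure(list(
    labels = ifelse(r >= T, "H", "L"),
    codes = table$codes,
    genotype = table$genotype,
    order = table$order,
    combo = table$combo,
    threshold = T),
    class = "risk_labeling")
}

#' Pool labelled cells into a confusion table
#'
#' Looks up each subset sample's multi-locus genotype cell in a risk
#' labelling (built on a training set) and pools: cases in H cells are true
#' positives, controls in H cells false positives, controls in L cells true
#' negatives, cases in L cells false negatives.  Samples falling in cells
#' never observed during training are conservatively assigned L.
#'
#' @param data a [genotype_matrix].
#' @param combo the locus combination the labelling was built on.
#' @param labeling a [label_cells()] result.
#' @param subset sample indices to score (training or held-out test set).
#' @return object of class \code{confusion_table}: list with TP, FP, TN, FN.
#' @export
confusion_from_labels <- function(data, combo, labeling,
                                  subset = seq_along(data$phenotype)) {
  stopifnot(inherits(labeling, "risk_labeling"))
  combo <- .check_combo(combo, ncol(data$genotypes))
  if (length(combo) != labeling$order)
    stop("combo order does not match labeling order", call. = FALSE)
  subset <- as.integer(subset)
  codes <- .cell_codes(data$genotypes[subset, , drop = FALSE], combo)
  pheno <- data$phenotype[subset]
  is_h <- logical(3L^labeling$order)      # unseen cells default to L
  is_h[labeling$codes + 1L] <- labeling$labels == "H"
  h <- is_h[codes + 1L]
  structure(list(
    TP = sum(h & pheno == 1L), FP = sum(h & pheno == 0L),
    TN = sum(!h & pheno == 0L), FN = sum(!h & pheno == 1L)),
    class = "confusion_table")
}

#' Balanced classification error
#'
#' \deqn{0.5 (FN/(TP+FN) + FP/(FP+TN))} — the mean of the false-negative
#' and false-positive rates, robust to case:control imbalance.  0 is a
#' perfect classifier, 0.5 is chance.
#'
#' @param ct a [confusion_from_labels()] result, or any list with elements
#'   TP, FP, TN, FN.
#' @return error in [0, 1].
#' @export
balanced_error <- function(ct) {
  with(ct, {
    if (TP + FN < 1L || FP + TN < 1L)
      stop("evaluation subset lacks one class (zero denominator)",
           call. = FALSE)
    0.5 * (FN / (TP + FN) + FP / (FP + TN))
  })
}

#' Evaluate one locus combination on a train/test split
#'
#' Composes the full MDR evaluation of a candidate model: build the cell
#' table on the training subset, label cells H/L, pool into a confusion
#' table, and compute the balanced classification error — then, if a test
#' subset is given, score it against the *training* labelling.
#'
#' @inheritParams build_cell_table
#' @param train_subset training sample indices (must contain both classes).
#' @param test_subset held-out sample indices, or NULL.
#' @param threshold risk threshold T.
#' @return object of class \code{model_score}: list with \code{combination},
#'   \code{training_error}, \code{testing_error} (NA if no test subset),
#'   \code{labeling}, \code{confusion_train}, \code{confusion_test}.
#' @export
evaluate_combination <- function(data, combo, train_subset,
                                 test_subset = NULL, threshold = 1) {
  tab <- build_cell_table(data, combo, train_subset)
  if (tab$case_total < 1L || tab$control_total < 1L)
    stop("training subset must contain both cases and controls",
         call. = FALSE)
  lab <- label_cells(tab, threshold)
  ct_train <- confusion_from_labels(data, combo, lab, train_subset)
  score <- structure(list(
    combination = tab$combo,
    training_error = balanced_error(ct_train),
    testing_error = NA_real_,
    labeling = lab,
    confusion_train = ct_train,
    confusion_test = NULL),
    class = "model_score")
  if (!is.null(test_subset)) {
    ct_test <- confusion_from_labels(data, combo, lab, test_subset)
    score$testing_error <- balanced_error(ct_test)
    score$confusion_test <- ct_test
  }
  score
}

#' @export
print.model_score <- function(x, ...) {
  cat("model_score:", paste(x$combination, collapse = ","),
      sprintf("| train error %.4f", x$training_error))
  if (!is.na(x$testing_error)) cat(sprintf(" | test error %.4f", x$testing_error))
  cat("\n")
  invisible(x)
}

## -------------------------------------------------------------------------
## Fast internal scorer used by the searches.  Operates on a precomputed
## fold context so the per-combination cost is a handful of vector ops.

.fold_context <- function(data, train_subset, test_subset = NULL,
                          threshold = 1) {
  g <- data$genotypes
  ph <- data$phenotype
  train_subset <- as.integer(train_subset)
  ctx <- list(
    gP = g[train_subset[ph[train_subset] == 1L], , drop = FALSE],
    gN = g[train_subset[ph[train_subset] == 0L], , drop = FALSE],
    threshold = threshold)
  ctx$P_star <- nrow(ctx$gP); ctx$N_star <- nrow(ctx$gN)
  if (ctx$P_star < 1L || ctx$N_star < 1L)
    stop("training subset must contain both cases and controls",
         call. = FALSE)
  if (!is.null(test_subset)) {
    test_subset <- as.integer(test_subset)
    ctx$tP <- g[test_subset[ph[test_subset] == 1L], , drop = FALSE]
    ctx$tN <- g[test_subset[ph[test_subset] == 0L], , drop = FALSE]
    if (nrow(ctx$tP) < 1L || nrow(ctx$tN) < 1L)
      stop("test subset lacks one class", call. = FALSE)
  }
  ctx
}

.codes_of <- function(g, combo) {
  code <- g[, combo[1L]]
  if (length(combo) > 1L)
    for (k in 2L:length(combo)) code <- code + 3L^(k - 1L) * g[, combo[k]]
  code + 1L
}

## returns c(train_error, test_error); test_error NA when no test set
.score_combo <- function(ctx, combo) {
  nb <- 3L^length(combo)
  cP <- tabulate(.codes_of(ctx$gP, combo), nbins = nb)
  cN <- tabulate(.codes_of(ctx$gN, combo), nbins = nb)
  ## H iff ratio >= T, i.e. cP*N* >= T*cN*P*; covers the cN==0, cP>0 case
  h <- (cP * ctx$N_star >= ctx$threshold * cN * ctx$P_star) & (cP + cN > 0L)
  TP <- sum(cP[h]); FP <- sum(cN[h])
  train_err <- 0.5 * ((ctx$P_star - TP) / ctx$P_star + FP / ctx$N_star)
  test_err <- NA_real_
  if (!is.null(ctx$tP)) {
    TPt <- sum(h[.codes_of(ctx$tP, combo)])
    FPt <- sum(h[.codes_of(ctx$tN, combo)])
    test_err <- 0.5 * ((nrow(ctx$tP) - TPt) / nrow(ctx$tP) +
                         FPt / nrow(ctx$tN))
  }
  c(train_err, test_err)
}

## score a combos matrix (n_combos x order); returns train-error vector
.score_combos_train <- function(ctx, combos) {
  apply(combos, 1L, function(cmb) .score_combo(ctx, cmb)[1L])
}

## order rows by training error, ties by lexicographic loci tuple
.rank_combos <- function(combos, errors) {
  do.call(order, c(list(errors), lapply(seq_len(ncol(combos)),
                                        function(j) combos[, j])))
}

#' Exhaustive MDR search at one interaction order
#'
#' Evaluates every one of the C(N, n) locus combinations of a given order on
#' a training subset and ranks them by training balanced error (ties broken
#' by lexicographically smallest loci tuple).
#'
#' @inheritParams evaluate_combination
#' @param order interaction order n (number of loci per model).
#' @param train_subset training sample indices; defaults to all samples.
#' @return object of class \code{search_result}: list with \code{order},
#'   \code{combos} (ranked matrix, one combination per row),
#'   \code{training_error} (sorted ascending), \code{evaluated} (the number
#'   of combinations scored, exactly choose(N, n)).
#' @examples
#' set.seed(1)
#' gm <- genotype_matrix(matrix(sample(0:2, 200, TRUE), 50), rep(0:1, 25))
#' exhaustive_search(gm, order = 2)
#' @export
exhaustive_search <- function(data, order, train_subset = NULL,
                              threshold = 1) {
  N <- ncol(data$genotypes)
  order <- as.integer(order)
  if (order < 1L || order > N)
    stop("order must be between 1 and the number of SNPs (", N, ")",
         call. = FALSE)
  if (is.null(train_subset)) train_subset <- seq_along(data$phenotype)
  ctx <- .fold_context(data, train_subset, threshold = threshold)
  combos <- t(utils::combn(N, order))
  err <- .score_combos_train(ctx, combos)
  o <- .rank_combos(combos, err)
  structure(list(order = order,
                 combos = combos[o, , drop = FALSE],
                 training_error = err[o],
                 evaluated = nrow(combos)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, n = 5L, ...) {
  cat(sprintf("search_result: order %d, %d combinations evaluated\n",
              x$order, x$evaluated))
  k <- min(n, nrow(x$combos))
  for (i in seq_len(k))
    cat(sprintf("  %d. [%s]  train error %.4f\n", i,
                paste(x$combos[i, ], collapse = ","), x$training_error[i]))
  invisible(x)
}
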