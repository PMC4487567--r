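## Ten-fold cross-validation bookkeeping: random-sort fold assignment,
## per-fold search, cross-validation consistency (CVC), and final model
## selection.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Assign samples to cross-validation folds by random sort
#'
#' Samples are shuffled with a seeded RNG and dealt into V contiguous
#' blocks whose sizes differ by at most one.  The split is deliberately
#' *not* stratified by class: with imbalanced data the training-set
#' control:case ratio therefore varies from fold to fold around the overall
#' ratio, as it does when whole data sets are randomly sorted before
#' splitting.
#'
#' @param data a [genotype_matrix], or an integer sample count.
#' @param V number of folds (default 10).
#' @param seed RNG seed for the shuffle; NULL uses the current RNG state.
#' @return object of class \code{fold_assignment}: list with \code{V},
#'   \code{fold_of_sample} (integer in 1..V per sample), \code{seed}.
#' @export
assign_folds <- function(data, V = 10L, seed = NULL) {
  n <- if (inherits(data, "genotype_matrix")) nrow(data$genotypes)
       else as.integer(data)
  V <- as.integer(V)
  if (V < 2L) stop("V must be >= 2", call. = FALSE)
  if (V > n) stop("more folds than samples", call. = FALSE)
  perm <- .with_seed(seed, sample.int(n))
  sizes <- rep(n %/% V, V)
  r <- n %% V
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  fold <- integer(n)
  fold[perm] <- rep.int(seq_len(V), sizes)
  structure(list(V = V, fold_of_sample = fold, seed = seed),
            class = "fold_assignment")
}

## CVC summary for one interaction order from the V fold-best models
.summarize_order <- function(order, fold_best, V) {
  keys <- vapply(fold_best, function(b) paste(b$combo, collapse = ","), "")
  counts <- sort(table(keys), decreasing = TRUE)
  test_err <- vapply(fold_best, function(b) b$test_error, 0)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) {
    ## ties: lower mean testing error among the folds each model won,
    ## then lexicographically smallest combination
    mte <- vapply(top, function(k) mean(test_err[keys == k]), 0)
    top <- top[mte == min(mte)]
    if (length(top) > 1L) {
      mats <- do.call(rbind, lapply(strsplit(top, ","), as.integer))
      top <- top[do.call("order", lapply(seq_len(ncol(mats)),
                                         function(j) mats[, j]))[1L]]
    } else top <- top[1L]
  } else top <- top[1L]
  mean_err <- mean(test_err)
  structure(list(
    order = order,
    per_fold_best = fold_best,
    cvc_counts = counts,
    final_model = as.integer(strsplit(top, ",")[[1L]]),
    consistency_k = as.integer(counts[[top]]),
    consistency = sprintf("%d / %d", counts[[top]], V),
    mean_test_error = mean_err,
    sd_test_error = stats::sd(test_err),
    accuracy = 1 - mean_err),
    class = "cvc_result")
}

#' @export
print.cvc_result <- function(x, ...) {
  cat(sprintf("cvc_result: order %d | final model [%s] | CVC %s | accuracy %.4f\n",
              x$order, paste(x$final_model, collapse = ","),
              x$consistency, x$accuracy))
  invisible(x)
}

#' Run a cross-validated MDR or FMDR search
#'
#' For each fold, runs the chosen search on the nine-tenths training set,
#' scores the fold-best model of every order on the held-out tenth (using
#' the training labelling), and accumulates cross-validation consistency
#' (CVC): how often each combination is the fold-best.  The final model per
#' order is the combination with the highest CVC, ties broken by lower mean
#' testing error, then lexicographically.  Reported accuracy is 1 minus the
#' unweighted mean of the V fold-best testing balanced errors.
#'
#' @param data a [genotype_matrix].
#' @param search "mdr" (exhaustive at every order) or "fmdr" (greedy
#'   retention search).
#' @param max_order largest interaction order analysed; results are
#'   reported for every order 2..max_order.
#' @param V number of cross-validation folds.
#' @param seed RNG seed for the fold shuffle; the search itself is
#'   deterministic.
#' @param config a [retention_config()] (FMDR only).
#' @param threshold risk threshold T.
#' @param fold_assignment optional precomputed [assign_folds()] result
#'   (overrides \code{V} and \code{seed}).
#' @return list with \code{per_order} (list of \code{cvc_result}, one per
#'   order), \code{accounting} (per order: combinations evaluated and
#'   retained per fold), \code{folds} (the \code{fold_assignment}),
#'   \code{search}.
#' @export
run_cv <- function(data, search = c("mdr", "fmdr"), max_order = 2L,
                   V = 10L, seed = NULL, config = retention_config(),
                   threshold = 1, fold_assignment = NULL) {
  search <- match.arg(search)
  validate_genotype_matrix(data)
  max_order <- as.integer(max_order)
  N <- ncol(data$genotypes)
  if (max_order < 2L) stop("max_order must be >= 2", call. = FALSE)
  if (max_order > N) stop("max_order exceeds the number of SNPs",
                          call. = FALSE)
  fa <- if (is.null(fold_assignment)) assign_folds(data, V, seed)
        else fold_assignment
  V <- fa$V
  orders <- 2L:max_order
  fold_best <- lapply(orders, function(o) vector("list", V))
  evaluated <- retained <- matrix(0L, nrow = length(orders), ncol = V,
                                  dimnames = list(orders, NULL))

  for (i in seq_len(V)) {
    train <- which(fa$fold_of_sample != i)
    test <- which(fa$fold_of_sample == i)
    if (length(unique(data$phenotype[train])) < 2L ||
        length(unique(data$phenotype[test])) < 2L)
      stop("fold ", i, " lacks one class; reshuffle with a different seed",
           call. = FALSE)
    ctx_test <- .fold_context(data, train, test, threshold)

    record <- function(o, combo, train_err) {
      te <- .score_combo(ctx_test, combo)[2L]
      fold_best[[match(o, orders)]][[i]] <<- list(
        fold = i, combo = combo, train_error = train_err, test_error = te)
    }

    if (search == "mdr") {
      for (o in orders) {
        sr <- exhaustive_search(data, o, train, threshold)
        evaluated[match(o, orders), i] <- sr$evaluated
        retained[match(o, orders), i] <- sr$evaluated
        record(o, sr$combos[1L, ], sr$training_error[1L])
      }
    } else {
      mem <- seed_order2(data, train, config, threshold, fold_index = i)
      evaluated[1L, i] <- mem$evaluated
      retained[1L, i] <- nrow(mem$combos)
      record(2L, mem$combos[1L, ], mem$training_error[1L])
      for (o in orders[-1L]) {
        mem <- advance_order(data, train, mem, config, threshold)
        evaluated[match(o, orders), i] <- mem$evaluated
        retained[match(o, orders), i] <- nrow(mem$combos)
        record(o, mem$combos[1L, ], mem$training_error[1L])
      }
    }
  }

  per_order <- lapply(seq_along(orders), function(k)
    .summarize_order(orders[k], fold_best[[k]], V))
  names(per_order) <- paste0("order", orders)
  list(per_order = per_order,
       accounting = list(orders = orders, evaluated = evaluated,
                         retained = retained),
       folds = fa, search = search)
}
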