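#' Fit an MDR or FMDR gene-gene interaction model
#'
#' The main fitting function.  Runs a V-fold cross-validated multifactor
#' dimensionality reduction analysis of a case-control genotype data set,
#' either exhaustively at every interaction order ("mdr") or with the fast
#' greedy retention search ("fmdr"), and selects a final locus-combination
#' model per order by cross-validation consistency (CVC).
#'
#' MDR reduces an n-SNP predictor to one binary attribute by pooling
#' multi-locus genotype cells into high- and low-risk groups: a cell is
#' high-risk when its imbalance-corrected case:control ratio reaches the
#' threshold \code{T}.  Models are scored by the balanced classification
#' error, 0.5 (FN/(TP+FN) + FP/(FP+TN)).  FMDR prunes the combinatorial
#' search by keeping, per fold, only the best \code{retain}\% of
#' combinations at each order and extending those with one further SNP to
#' form the next order's candidates; with \code{retain = 100} it reproduces
#' the exhaustive search exactly.
#'
#' @param data a [genotype_matrix], or a path to an MDR-format text file
#'   (read with [read_genotype_table()]).
#' @param method "mdr" or "fmdr".
#' @param max_order largest interaction order to analyse (>= 2); results
#'   are kept for every order from 2 up.
#' @param folds number of cross-validation folds (default 10).
#' @param retain FMDR retention percentage in (0, 100] (default 10).
#' @param threshold high/low-risk ratio threshold T (default 1).
#' @param seed RNG seed for the fold shuffle; everything else is
#'   deterministic.
#' @param per_order_retain optional named vector of per-order retention
#'   percentages, e.g. \code{c("2" = 2, "3" = 3)}.
#' @param min_retained floor on the number of combinations each fold memory
#'   keeps (default 1).
#' @return an object of class \code{mdr_fit}; see [print.mdr_fit()],
#'   [summary.mdr_fit()], [coef.mdr_fit()], [predict.mdr_fit()],
#'   [plot.mdr_fit()].
#' @examples
#' sim <- simulate_epistasis(seed = 7, n_snps = 10, n_cases = 150,
#'                           n_controls = 150, h2 = 0.3)
#' fit <- mdr(sim$data, method = "fmdr", max_order = 3, seed = 1)
#' fit
#' coef(fit)
#' @export
mdr <- function(data, method = c("mdr", "fmdr"), max_order = 2L,
                folds = 10L, retain = 10, threshold = 1, seed = NULL,
                per_order_retain = NULL, min_retained = 1L) {
  method <- match.arg(method)
  if (is.character(data)) data <- read_genotype_table(data)
  config <- retention_config(retain, per_order_retain, min_retained)
  cv <- run_cv(data, search = method, max_order = max_order, V = folds,
               seed = seed, config = config, threshold = threshold)
  structure(list(call = match.call(),
                 method = method,
                 data = data,
                 snp_names = data$snp_names,
                 per_order = cv$per_order,
                 accounting = cv$accounting,
                 folds = cv$folds,
                 threshold = threshold,
                 config = config,
                 seed = seed),
            class = "mdr_fit")
}

.order_table <- function(x) {
  rows <- lapply(x$per_order, function(r) data.frame(
    order = r$order,
    model = paste(x$snp_names[r$final_model], collapse = ","),
    cvc = r$consistency,
    accuracy = r$accuracy,
    mean_test_error = r$mean_test_error,
    evaluated = sum(x$accounting$evaluated[as.character(r$order), ]),
    stringsAsFactors = FALSE))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' @describeIn mdr print the per-order final models, CVC and accuracy.
#' @param x,object an \code{mdr_fit}.
#' @param ... unused.
#' @export
print.mdr_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d samples (%d cases, %d controls), %d SNPs, %d-fold CV\n",
              toupper(x$method), nrow(x$data$genotypes), n_cases(x$data),
              n_controls(x$data), length(x$snp_names), x$folds$V))
  if (x$method == "fmdr")
    cat(sprintf("retention: %g%% per order (min %d)\n",
                x$config$retain_percent, x$config$min_retained))
  tab <- .order_table(x)
  tab$accuracy <- sprintf("%.4f", tab$accuracy)
  tab$mean_test_error <- sprintf("%.4f", tab$mean_test_error)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @describeIn mdr final model loci (SNP names) per order, as a named list.
#' @export
coef.mdr_fit <- function(object, ...) {
  stats::setNames(
    lapply(object$per_order,
           function(r) object$snp_names[r$final_model]),
    names(object$per_order))
}

#' @describeIn mdr adds, per order, the whole-data odds ratio (with 95\%
#'   Woolf CI) of the final model's high/low-risk classification.
#' @export
summary.mdr_fit <- function(object, ...) {
  tab <- .order_table(object)
  ors <- lapply(object$per_order, function(r) {
    sc <- evaluate_combination(object$data, r$final_model,
                               seq_along(object$data$phenotype),
                               threshold = object$threshold)
    odds_ratio(sc$confusion_train, correct = TRUE)
  })
  tab$or <- vapply(ors, function(o) o$odds_ratio, 0)
  tab$or_ci_low <- vapply(ors, function(o) o$ci_low, 0)
  tab$or_ci_high <- vapply(ors, function(o) o$ci_high, 0)
  structure(list(fit = object, table = tab), class = "summary.mdr_fit")
}

#' @export
print.summary.mdr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nWhole-data odds ratios of the final models:\n")
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  order %d: OR %.2f (95%% CI %.2f-%.2f)\n", tab$order[i],
                tab$or[i], tab$or_ci_low[i], tab$or_ci_high[i]))
  invisible(x)
}

#' @describeIn mdr classify new samples as case (high-risk cell) or control
#'   using the final model of the given order, with the risk labelling
#'   refit on the full training data.
#' @param newdata a [genotype_matrix] or genotype matrix/data.frame with the
#'   same SNP columns; defaults to the training data.
#' @param order which interaction order's final model to use (default: the
#'   largest fitted).
#' @export
predict.mdr_fit <- function(object, newdata = NULL,
                            order = max(object$accounting$orders), ...) {
  key <- paste0("order", order)
  if (!key %in% names(object$per_order))
    stop("no fitted model at order ", order, call. = FALSE)
  combo <- object$per_order[[key]]$final_model
  tab <- build_cell_table(object$data, combo)
  lab <- label_cells(tab, object$threshold)
  g <- if (is.null(newdata)) object$data$genotypes
       else if (inherits(newdata, "genotype_matrix")) newdata$genotypes
       else as.matrix(newdata)
  storage.mode(g) <- "integer"
  if (!all(g %in% c(0L, 1L, 2L)))
    stop("newdata genotypes must be coded 0/1/2", call. = FALSE)
  is_h <- logical(3L^length(combo))
  is_h[lab$codes + 1L] <- lab$labels == "H"
  codes <- .cell_codes(g, combo)
  factor(ifelse(is_h[codes + 1L], "case", "control"),
         levels = c("control", "case"))
}

#' @describeIn mdr plot cross-validated accuracy against interaction order.
#' @export
plot.mdr_fit <- function(x, ...) {
  tab <- .order_table(x)
  graphics::plot(tab$order, tab$accuracy, type = "b", pch = 19,
                 xlab = "interaction order",
                 ylab = "CV balanced accuracy",
                 main = sprintf("%s: accuracy by order", toupper(x$method)),
                 ...)
  invisible(x)
}
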