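## FMDR: greedy order-by-order search.  Per cross-validation fold, the best
## n% of combinations at order m are kept in a fold memory; order-(m+1)
## candidates are generated only by extending the retained combinations with
## one further SNP.  With 100% retention the search is exactly the
## exhaustive MDR search at every order.

#' Retention configuration for the FMDR greedy search
#'
#' Controls how many combinations each fold memory keeps after ranking an
#' order: \code{max(min_retained, ceiling(retain_percent/100 x evaluated))},
#' capped at the number evaluated.  A per-order override map supports
#' retention-by-count readings (e.g. keep the top 2 at order 2, top 3 at
#' order 3) via percentages or via \code{min_retained}.
#'
#' @param retain_percent percentage of evaluated combinations retained per
#'   order, in (0, 100]; default 10.
#' @param per_order optional named numeric vector overriding
#'   \code{retain_percent} for specific orders, e.g. \code{c("2" = 5)}.
#' @param min_retained floor on the number retained (default 1).
#' @return object of class \code{retention_config}.
#' @export
retention_config <- function(retain_percent = 10, per_order = NULL,
                             min_retained = 1L) {
  if (!is.numeric(retain_percent) || retain_percent <= 0 ||
      retain_percent > 100)
    stop("retain_percent must be in (0, 100]", call. = FALSE)
  if (!is.null(per_order) &&
      (is.null(names(per_order)) || any(per_order <= 0 | per_order > 100)))
    stop("per_order must be a named vector of percentages in (0, 100]",
         call. = FALSE)
  structure(list(retain_percent = retain_percent, per_order = per_order,
                 min_retained = max(1L, as.integer(min_retained))),
            class = "retention_config")
}

.retained_size <- function(config, order, evaluated) {
  pct <- config$retain_percent
  ov <- config$per_order[as.character(order)]
  if (length(ov) == 1L && !is.na(ov)) pct <- ov
  min(evaluated, max(config$min_retained, ceiling(pct / 100 * evaluated)))
}

.new_memory <- function(fold_index, search, retained_n) {
  keep <- seq_len(retained_n)
  structure(list(fold_index = fold_index,
                 order = search$order,
                 combos = search$combos[keep, , drop = FALSE],
                 training_error = search$training_error[keep],
                 evaluated = search$evaluated),
            class = "fold_memory")
}

#' Seed a fold memory with the exhaustive order-2 search
#'
#' The first FMDR step: all C(N, 2) locus pairs are evaluated on the fold's
#' training subset, ranked by training balanced error, and the best n%
#' saved into the fold's memory.
#'
#' @inheritParams exhaustive_search
#' @param config a [retention_config()].
#' @param fold_index index of the cross-validation fold this memory belongs
#'   to (bookkeeping only).
#' @return object of class \code{fold_memory}: list with
#'   \code{fold_index}, \code{order}, \code{combos} (retained, ranked),
#'   \code{training_error}, \code{evaluated} (candidates scored at this
#'   order).
#' @export
seed_order2 <- function(data, train_subset = NULL,
                        config = retention_config(), threshold = 1,
                        fold_index = 1L) {
  if (ncol(data$genotypes) < 2L) stop("need at least 2 SNPs", call. = FALSE)
  sr <- exhaustive_search(data, 2L, train_subset, threshold)
  .new_memory(fold_index, sr, .retained_size(config, 2L, sr$evaluated))
}

#' Generate order-(m+1) candidates from a fold memory
#'
#' Each retained order-m combination is extended with every SNP not already
#' in it; duplicates (the same set reached through different parents) are
#' collapsed to their canonical sorted form.
#'
#' @param memory a \code{fold_memory}.
#' @param N total number of SNPs.
#' @return matrix of candidate combinations (one per row, order m + 1),
#'   in lexicographic order.
#' @export
extend_candidates <- function(memory, N) {
  stopifnot(inherits(memory, "fold_memory"))
  m <- memory$order
  R <- nrow(memory$combos)
  if (R == 0L) stop("fold memory is empty", call. = FALSE)
  if (m >= N) stop("cannot extend: order already equals the number of SNPs",
                   call. = FALSE)
  ext <- matrix(0L, nrow = R * (N - m), ncol = m + 1L)
  row <- 0L
  for (i in seq_len(R)) {
    base <- memory$combos[i, ]
    for (s in setdiff(seq_len(N), base)) {
      row <- row + 1L
      ext[row, ] <- sort(c(base, s))
    }
  }
  ext <- unique(ext)
  ext[do.call(order, lapply(seq_len(ncol(ext)), function(j) ext[, j])), ,
      drop = FALSE]
}

#' Advance a fold memory to the next interaction order
#'
#' Scores exactly the [extend_candidates()] set on the fold's training
#' subset, ranks by training error, and truncates to the retained size —
#' one greedy step of the FMDR search.
#'
#' @inheritParams seed_order2
#' @param memory the fold's current \code{fold_memory} (order m >= 2).
#' @return a \code{fold_memory} at order m + 1; its \code{evaluated} field
#'   records the candidate count for complexity accounting.
#' @export
advance_order <- function(data, train_subset, memory,
                          config = retention_config(), threshold = 1) {
  stopifnot(inherits(memory, "fold_memory"))
  N <- ncol(data$genotypes)
  cand <- extend_candidates(memory, N)
  if (is.null(train_subset)) train_subset <- seq_along(data$phenotype)
  ctx <- .fold_context(data, train_subset, threshold = threshold)
  err <- .score_combos_train(ctx, cand)
  o <- .rank_combos(cand, err)
  sr <- list(order = memory$order + 1L, combos = cand[o, , drop = FALSE],
             training_error = err[o], evaluated = nrow(cand))
  .new_memory(memory$fold_index, sr,
              .retained_size(config, sr$order, sr$evaluated))
}

#' @export
print.fold_memory <- function(x, ...) {
  cat(sprintf(
    "fold_memory (fold %d): order %d, %d retained of %d evaluated; best [%s] err %.4f\n",
    x$fold_index, x$order, nrow(x$combos), x$evaluated,
    paste(x$combos[1L, ], collapse = ","), x$training_error[1L]))
  invisible(x)
}
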