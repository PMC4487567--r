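## Post-hoc statistics: odds ratio with Woolf CI for a 2x2 risk table,
## paired t-tests between methods, and power summaries over simulation
## replicates.

#' Odds ratio with Woolf (log-normal) confidence interval
#'
#' OR = (TP x TN) / (FP x FN) for the 2x2 table pooling high-risk against
#' low-risk classification, with the log-scale interval
#' exp(ln OR +/- z sqrt(1/TP + 1/FP + 1/TN + 1/FN)).
#'
#' @param ct a \code{confusion_table} (or list with TP, FP, TN, FN).
#' @param confidence confidence level (default 0.95).
#' @param correct apply the Haldane-Anscombe +0.5 correction to every cell;
#'   required when any cell is zero, harmless otherwise.
#' @return object of class \code{or_result}: list with \code{odds_ratio},
#'   \code{ci_low}, \code{ci_high}, \code{confidence}, \code{table}.
#' @examples
#' odds_ratio(list(TP = 50, FN = 50, FP = 25, TN = 75))  # OR 3
#' @export
odds_ratio <- function(ct, confidence = 0.95, correct = FALSE) {
  cells <- c(ct$TP, ct$FP, ct$TN, ct$FN)
  if (any(cells < 0)) stop("confusion counts must be non-negative",
                           call. = FALSE)
  if (any(cells == 0) && !correct)
    stop("zero cell in the 2x2 table: rerun with correct = TRUE ",
         "(Haldane-Anscombe +0.5 correction)", call. = FALSE)
  if (correct) cells <- cells + 0.5
  tp <- cells[1L]; fp <- cells[2L]; tn <- cells[3L]; fn <- cells[4L]
  or <- (tp * tn) / (fp * fn)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  se <- sqrt(1 / tp + 1 / fp + 1 / tn + 1 / fn)
  structure(list(odds_ratio = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 confidence = confidence,
                 table = ct),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.2f (%.0f%% CI %.2f-%.2f)\n", x$odds_ratio,
              100 * x$confidence, x$ci_low, x$ci_high))
  invisible(x)
}

#' Paired t-test between two matched result vectors
#'
#' Classical paired t-test on the elementwise differences, used to compare
#' two methods' per-replicate results (e.g. power or accuracy across
#' simulated data sets).  When the differences have zero variance — the two
#' vectors are identical up to a constant shift of zero — the comparison is
#' flagged degenerate (conventionally printed "-").
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return object of class \code{paired_comparison}: list with
#'   \code{t_statistic}, \code{degrees_of_freedom}, \code{p_value},
#'   \code{mean_difference}, \code{sd_difference}, \code{degenerate}.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length",
                                   call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    return(structure(list(t_statistic = NA_real_,
                          degrees_of_freedom = length(a) - 1L,
                          p_value = NA_real_,
                          mean_difference = mean(d),
                          sd_difference = 0,
                          degenerate = TRUE),
                     class = "paired_comparison"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  structure(list(t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_difference = mean(d),
                 sd_difference = stats::sd(d),
                 degenerate = FALSE),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  if (x$degenerate) cat("paired t-test: - (identical results)\n")
  else cat(sprintf("paired t-test: t = %.3f, df = %d, p = %.4g, mean diff = %.4f\n",
                   x$t_statistic, x$degrees_of_freedom, x$p_value,
                   x$mean_difference))
  invisible(x)
}

#' Power over simulation replicates
#'
#' Power is the fraction of replicates in which the search's final selected
#' model is exactly the planted causal locus set.  The SD reported is the
#' sample SD of the per-replicate 0/1 recovery indicator.
#'
#' @param final_models list of integer vectors: the final model (locus
#'   indices) selected in each replicate.
#' @param causal either one integer vector (the same planted set for all
#'   replicates) or a list of per-replicate planted sets.
#' @return object of class \code{power_summary}: list with \code{power},
#'   \code{sd}, \code{n_replicates}, \code{recovered} (logical per
#'   replicate).
#' @export
power_analysis <- function(final_models, causal) {
  if (length(final_models) < 1L) stop("need at least one replicate",
                                      call. = FALSE)
  if (!is.list(causal)) causal <- rep(list(causal), length(final_models))
  if (length(causal) != length(final_models))
    stop("causal list length must match replicates", call. = FALSE)
  hit <- mapply(function(m, c) identical(sort(as.integer(m)),
                                         sort(as.integer(c))),
                final_models, causal)
  structure(list(power = mean(hit),
                 sd = if (length(hit) > 1L) stats::sd(hit) else 0,
                 n_replicates = length(hit),
                 recovered = hit),
            class = "power_summary")
}

#' @export
print.power_summary <- function(x, ...) {
  cat(sprintf("power %.2f (+/-%.2f) over %d replicates\n",
              x$power, x$sd, x$n_replicates))
  invisible(x)
}
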