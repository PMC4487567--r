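## Workflow entry points behind the command-line script: search a data set,
## simulate benchmark data, and run a power comparison.  Each is a thin
## orchestration over the fitting and simulation functions, writing JSON
## and TSV result files.

RESULT_SCHEMA_VERSION <- "1.0"

#' Search a genotype file for gene-gene interactions
#'
#' Reads an MDR-format genotype table, fits [mdr()] with the requested
#' method, and (optionally) writes per-order results as JSON plus a
#' human-readable TSV table.  Evaluated-combination counts per order are
#' included so the search cost is auditable.
#'
#' @param input path to an MDR-format genotype file.
#' @param method "mdr" or "fmdr".
#' @param max_order,folds,retain,threshold,seed passed to [mdr()].
#' @param out_dir output directory, or NULL to skip writing.
#' @return the \code{mdr_fit}, invisibly; results written to
#'   \code{<out_dir>/search_<method>.json} and \code{.tsv}.
#' @export
run_search <- function(input, method = c("mdr", "fmdr"), max_order = 2L,
                       folds = 10L, retain = 10, threshold = 1,
                       seed = NULL, out_dir = NULL) {
  method <- match.arg(method)
  fit <- mdr(input, method = method, max_order = max_order, folds = folds,
             retain = retain, threshold = threshold, seed = seed)
  smry <- summary(fit)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    per_order <- lapply(fit$per_order, function(r) list(
      order = r$order,
      final_model = fit$snp_names[r$final_model],
      consistency = r$consistency,
      accuracy = r$accuracy,
      mean_test_error = r$mean_test_error,
      or = smry$table$or[smry$table$order == r$order],
      or_ci = c(smry$table$or_ci_low[smry$table$order == r$order],
                smry$table$or_ci_high[smry$table$order == r$order]),
      evaluated = sum(fit$accounting$evaluated[as.character(r$order), ]),
      per_fold = lapply(r$per_fold_best, function(b) list(
        fold = b$fold, model = fit$snp_names[b$combo],
        train_error = b$train_error, test_error = b$test_error))))
    jsonlite::write_json(
      list(schema_version = RESULT_SCHEMA_VERSION, method = method,
           seed = seed, threshold = threshold, retain = retain,
           results = per_order),
      file.path(out_dir, paste0("search_", method, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(smry$table,
                       file.path(out_dir, paste0("search_", method, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fit)
}

#' Simulate benchmark data sets to files
#'
#' Writes one or more pure-epistasis replicates in MDR format, each with a
#' JSON truth sidecar recording the planted causal loci (as column names),
#' the penetrance table, the realised heritability and the seed.
#'
#' @param out_dir output directory.
#' @param model standard design number 1..6, or NULL to use the explicit
#'   parameters.
#' @param replicates number of data sets (distinct derived seeds).
#' @param seed base seed.
#' @param order,maf,h2,n_cases,n_controls,n_snps explicit simulation
#'   parameters, used when \code{model} is NULL.
#' @return character vector of the data file paths, invisibly.
#' @export
run_simulate <- function(out_dir, model = NULL, replicates = 1L, seed = 1L,
                         order = 2L, maf = 0.2, h2 = 0.2, n_cases = 400L,
                         n_controls = 400L, n_snps = 50L) {
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(replicates)
  for (r in seq_len(replicates)) {
    rep_seed <- seed + 1000L * (r - 1L)
    sim <- if (is.null(model))
      simulate_epistasis(seed = rep_seed, order = order, maf = maf, h2 = h2,
                         n_cases = n_cases, n_controls = n_controls,
                         n_snps = n_snps)
    else simulate_design(model, seed = rep_seed, order = order)
    stem <- file.path(out_dir, sprintf("sim_rep%03d", r))
    paths[r] <- paste0(stem, ".txt")
    write_genotype_table(sim$data, paths[r])
    jsonlite::write_json(
      list(schema_version = RESULT_SCHEMA_VERSION,
           causal_loci = sim$data$snp_names[sim$causal_loci],
           causal_columns = sim$causal_loci,
           penetrance = sim$model$penetrance,
           maf = sim$model$maf, h2 = sim$model$h2,
           prevalence = sim$model$prevalence, seed = rep_seed),
      paste0(stem, ".truth.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(paths)
}

#' Power comparison between MDR and FMDR on simulated replicates
#'
#' Simulates \code{replicates} pure-epistasis data sets, runs both the
#' exhaustive and the greedy search on each (same folds per replicate), and
#' summarises the power — the fraction of replicates whose final selected
#' model at the causal order is exactly the planted locus set — together
#' with a paired t-test between the two methods' recovery indicators.
#'
#' @inheritParams run_simulate
#' @param retain FMDR retention percentage.
#' @param folds cross-validation folds.
#' @param max_order search depth (default: the causal order).
#' @param out_dir optional output directory for a JSON/TSV report.
#' @return list with \code{power_mdr}, \code{power_fmdr} (each a
#'   \code{power_summary}), \code{comparison} (a \code{paired_comparison},
#'   degenerate when the two recovery vectors are identical), and
#'   \code{table} (one row per replicate).
#' @export
run_power <- function(replicates = 10L, seed = 1L, order = 2L, maf = 0.2,
                      h2 = 0.2, n_cases = 400L, n_controls = 400L,
                      n_snps = 50L, retain = 10, folds = 10L,
                      max_order = order, out_dir = NULL) {
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  key <- paste0("order", order)
  rows <- vector("list", replicates)
  mdr_models <- fmdr_models <- vector("list", replicates)
  causal <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rep_seed <- seed + 1000L * (r - 1L)
    sim <- simulate_epistasis(seed = rep_seed, order = order, maf = maf,
                              h2 = h2, n_cases = n_cases,
                              n_controls = n_controls, n_snps = n_snps)
    causal[[r]] <- sim$causal_loci
    fit_m <- mdr(sim$data, "mdr", max_order = max_order, folds = folds,
                 seed = rep_seed + 1L)
    fit_f <- mdr(sim$data, "fmdr", max_order = max_order, folds = folds,
                 retain = retain, seed = rep_seed + 1L)
    mdr_models[[r]] <- fit_m$per_order[[key]]$final_model
    fmdr_models[[r]] <- fit_f$per_order[[key]]$final_model
    rows[[r]] <- data.frame(
      replicate = r, seed = rep_seed,
      causal = paste(sim$causal_loci, collapse = ","),
      mdr_model = paste(mdr_models[[r]], collapse = ","),
      fmdr_model = paste(fmdr_models[[r]], collapse = ","),
      mdr_accuracy = fit_m$per_order[[key]]$accuracy,
      fmdr_accuracy = fit_f$per_order[[key]]$accuracy,
      stringsAsFactors = FALSE)
  }
  pm <- power_analysis(mdr_models, causal)
  pf <- power_analysis(fmdr_models, causal)
  cmp <- paired_t_test(as.numeric(pm$recovered), as.numeric(pf$recovered))
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  out <- list(power_mdr = pm, power_fmdr = pf, comparison = cmp,
              table = tab)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(schema_version = RESULT_SCHEMA_VERSION,
           power_mdr = pm$power, sd_mdr = pm$sd,
           power_fmdr = pf$power, sd_fmdr = pf$sd,
           p_value = if (cmp$degenerate) "-" else cmp$p_value,
           replicates = replicates, seed = seed),
      file.path(out_dir, "power.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    utils::write.table(tab, file.path(out_dir, "power.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
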