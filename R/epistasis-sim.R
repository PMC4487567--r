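## Pure-epistasis penetrance-model simulator.  Random n-locus penetrance
## architectures are drawn at a target broad-sense heritability and MAF,
## with per-locus marginal penetrances projected flat so the planted signal
## is a pure interaction (no main effects), then embedded among
## phenotype-independent Hardy-Weinberg noise SNPs.

## per-locus HWE genotype frequencies for minor allele frequency q
.hwe_freq <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

## joint genotype probabilities and per-locus genotype index (cells x n)
.model_grid <- function(maf) {
  n <- length(maf)
  geno <- .decode_codes(0:(3L^n - 1L), n)
  p <- rep(1, 3L^n)
  for (i in seq_len(n)) p <- p * .hwe_freq(maf[i])[geno[, i] + 1L]
  list(geno = geno, p = p)
}

.prevalence <- function(p, f) sum(p * f)

.heritability <- function(p, f) {
  K <- .prevalence(p, f)
  sum(p * (f - K)^2) / (K * (1 - K))
}

## largest |marginal penetrance - K| over loci and genotype values
.marginal_deviation <- function(grid, f) {
  K <- .prevalence(grid$p, f)
  dev <- 0
  for (i in seq_len(ncol(grid$geno))) {
    for (v in 0:2) {
      sel <- grid$geno[, i] == v
      m <- sum(grid$p[sel] * f[sel]) / sum(grid$p[sel])
      dev <- max(dev, abs(m - K))
    }
  }
  dev
}

#' Sample a pure-epistasis penetrance model
#'
#' Draws a random n-locus penetrance table f(g) at a target broad-sense
#' heritability h2 = sum p_g (f_g - K)^2 / (K(1-K)) under per-locus
#' Hardy-Weinberg genotype frequencies, with all per-locus marginal
#' penetrances projected flat (pure epistasis: no main effects).  The
#' sampler alternates a marginal-flattening projection with a rescale of
#' the table about its prevalence K to hit the target h2, clipping to
#' [0, 1]; draws that fail to satisfy the invariants (realised h2 within
#' 10\% relative of target, marginal deviation below \code{epsilon}) are
#' rejected and redrawn.
#'
#' @param order number of interacting loci n (default 2).
#' @param maf minor allele frequency, scalar or per-locus vector, in
#'   (0, 0.5].
#' @param h2 target heritability in (0, 1).
#' @param K_target optional target prevalence; by default K is left where
#'   the accepted random architecture lands.
#' @param seed RNG seed.
#' @param max_tries rejection budget (default 500).
#' @param epsilon marginal-purity tolerance on the penetrance scale
#'   (default 0.01).
#' @return object of class \code{penetrance_model}: list with \code{order},
#'   \code{maf}, \code{penetrance} (vector of length 3^n, cell code order),
#'   \code{genotype} (cells x n genotype codes), \code{cell_prob} (HWE joint
#'   probabilities), \code{prevalence}, \code{h2}, \code{target_h2}.
#' @export
sample_penetrance_model <- function(order = 2L, maf = 0.2, h2 = 0.2,
                                    K_target = NULL, seed = NULL,
                                    max_tries = 500L, epsilon = 0.01) {
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)", call. = FALSE)
  maf <- rep_len(maf, order)
  if (any(maf <= 0 | maf > 0.5)) stop("maf must be in (0, 0.5]",
                                      call. = FALSE)
  grid <- .model_grid(maf)
  .with_seed(seed, {
    best_h2 <- NA_real_
    for (try in seq_len(max_tries)) {
      f <- stats::runif(length(grid$p))
      for (it in 1:60) {
        K <- .prevalence(grid$p, f)
        if (!is.null(K_target)) { f <- f + (K_target - K); K <- K_target }
        ## flatten main effects: subtract each locus's marginal deviation
        adj <- numeric(length(f))
        for (i in seq_len(order)) {
          for (v in 0:2) {
            sel <- grid$geno[, i] == v
            adj[sel] <- adj[sel] +
              sum(grid$p[sel] * f[sel]) / sum(grid$p[sel]) - K
          }
        }
        f <- f - adj
        ## rescale about K to the target heritability, then clip
        K <- .prevalence(grid$p, f)
        if (K <= 0 || K >= 1) break
        v_now <- sum(grid$p * (f - K)^2)
        if (v_now <= 0) break
        f <- K + sqrt(h2 * K * (1 - K) / v_now) * (f - K)
        f <- pmin(1, pmax(0, f))
        got <- .heritability(grid$p, f)
        if (abs(got - h2) / h2 <= 0.1 &&
            .marginal_deviation(grid, f) < epsilon) {
          return(structure(list(order = order, maf = maf, penetrance = f,
                                genotype = grid$geno, cell_prob = grid$p,
                                prevalence = .prevalence(grid$p, f),
                                h2 = got, target_h2 = h2),
                           class = "penetrance_model"))
        }
      }
      got <- tryCatch(.heritability(grid$p, f), error = function(e) NA_real_)
      if (is.na(best_h2) || (!is.na(got) && abs(got - h2) < abs(best_h2 - h2)))
        best_h2 <- got
    }
    stop(sprintf(
      "no admissible penetrance model in %d tries (best achieved h2 %.3f; high h2 with low MAF can be infeasible)",
      max_tries, best_h2), call. = FALSE)
  })
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf(
    "penetrance_model: %d loci, MAF %s, h2 %.3f (target %.3f), prevalence %.3f\n",
    x$order, paste(format(x$maf), collapse = "/"), x$h2, x$target_h2,
    x$prevalence))
  invisible(x)
}

#' Generate a case-control data set from a penetrance model
#'
#' Draws multi-locus genotypes for the causal loci from their Hardy-Weinberg
#' joint distribution, assigns case status with probability equal to the
#' cell penetrance, and keeps drawing until the case and control quotas are
#' both filled.  Noise SNP columns are phenotype-independent HWE draws; the
#' causal columns are placed at seeded random positions among them.
#'
#' @param model a [sample_penetrance_model()] result.
#' @param n_cases,n_controls sample quotas (>= 1).
#' @param n_noise_snps number of non-causal SNP columns (default 48).
#' @param noise_maf minor allele frequency of noise SNPs (default: the
#'   model's first-locus MAF).
#' @param seed RNG seed.
#' @param max_batches safety bound on quota-filling draws (default 10000
#'   batches of the total sample size).
#' @return object of class \code{sim_dataset}: list with \code{data} (a
#'   [genotype_matrix]), \code{causal_loci} (sorted column indices of the
#'   planted loci), \code{model}, \code{seed}.
#' @export
generate_dataset <- function(model, n_cases, n_controls,
                             n_noise_snps = 48L, noise_maf = model$maf[1L],
                             seed = NULL, max_batches = 10000L) {
  stopifnot(inherits(model, "penetrance_model"))
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  if (n_cases < 1L || n_controls < 1L) stop("quotas must be >= 1",
                                            call. = FALSE)
  total <- n_cases + n_controls
  .with_seed(seed, {
    case_codes <- integer(0); ctrl_codes <- integer(0)
    batches <- 0L
    while (length(case_codes) < n_cases || length(ctrl_codes) < n_controls) {
      batches <- batches + 1L
      if (batches > max_batches)
        stop("case/control quota unreachable: model prevalence too extreme",
             call. = FALSE)
      codes <- sample.int(length(model$cell_prob), total, replace = TRUE,
                          prob = model$cell_prob)
      is_case <- stats::runif(total) < model$penetrance[codes]
      case_codes <- c(case_codes, codes[is_case])
      ctrl_codes <- c(ctrl_codes, codes[!is_case])
    }
    case_codes <- case_codes[seq_len(n_cases)]
    ctrl_codes <- ctrl_codes[seq_len(n_controls)]
    causal_geno <- rbind(model$genotype[case_codes, , drop = FALSE],
                         model$genotype[ctrl_codes, , drop = FALSE])
    pheno <- c(rep(1L, n_cases), rep(0L, n_controls))
    n_snps <- model$order + as.integer(n_noise_snps)
    geno <- matrix(0L, nrow = total, ncol = n_snps)
    causal_pos <- sort(sample.int(n_snps, model$order))
    geno[, causal_pos] <- causal_geno
    noise_pos <- setdiff(seq_len(n_snps), causal_pos)
    if (length(noise_pos) > 0L)
      geno[, noise_pos] <- stats::rbinom(total * length(noise_pos), 2L,
                                         noise_maf)
    ## random sample order so class blocks are not contiguous
    perm <- sample.int(total)
    gm <- genotype_matrix(geno[perm, , drop = FALSE], pheno[perm],
                          paste0("SNP", seq_len(n_snps)))
    structure(list(data = gm, causal_loci = causal_pos, model = model,
                   seed = seed),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: causal loci [%s] of %d SNPs, h2 %.3f\n",
              paste(x$causal_loci, collapse = ","),
              ncol(x$data$genotypes), x$model$h2))
  print(x$data)
  invisible(x)
}

#' One-call pure-epistasis simulation
#'
#' Convenience wrapper: samples a penetrance model and generates one
#' case-control data set from it.
#'
#' @inheritParams sample_penetrance_model
#' @param n_cases,n_controls sample quotas.
#' @param n_snps total SNP columns including the causal loci (default 50).
#' @param noise_maf MAF of the noise SNPs (default: same as \code{maf}).
#' @param seed RNG seed (drives both the architecture draw and sampling).
#' @return a \code{sim_dataset}; see [generate_dataset()].
#' @export
simulate_epistasis <- function(seed = NULL, order = 2L, maf = 0.2,
                               h2 = 0.2, n_cases = 400L, n_controls = 400L,
                               n_snps = 50L, noise_maf = maf,
                               K_target = NULL) {
  model <- sample_penetrance_model(order, maf, h2, K_target, seed = seed)
  generate_dataset(model, n_cases, n_controls,
                   n_noise_snps = n_snps - as.integer(order),
                   noise_maf = noise_maf,
                   seed = if (is.null(seed)) NULL else seed + 1L)
}

#' The six standard simulation designs
#'
#' The benchmark grid for the power study: 50 attributes, heritability 0.2,
#' two causal loci, MAF 0.1/0.2/0.4 crossed with balanced sample sizes 800
#' and 1600.
#'
#' @return data.frame with columns \code{model}, \code{maf},
#'   \code{n_cases}, \code{n_controls}, \code{n_snps}, \code{h2}.
#' @export
simulation_designs <- function() {
  data.frame(model = 1:6,
             maf = rep(c(0.1, 0.2, 0.4), each = 2),
             n_cases = rep(c(400L, 800L), 3),
             n_controls = rep(c(400L, 800L), 3),
             n_snps = 50L,
             h2 = 0.2)
}

#' Simulate one replicate of a standard design
#'
#' @param model design number 1..6 (see [simulation_designs()]).
#' @param seed RNG seed.
#' @param order number of causal loci (default 2).
#' @return a \code{sim_dataset}.
#' @export
simulate_design <- function(model, seed = NULL, order = 2L) {
  d <- simulation_designs()
  if (!model %in% d$model) stop("model must be 1..6", call. = FALSE)
  d <- d[d$model == model, ]
  simulate_epistasis(seed = seed, order = order, maf = d$maf, h2 = d$h2,
                     n_cases = d$n_cases, n_controls = d$n_controls,
                     n_snps = d$n_snps)
}
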