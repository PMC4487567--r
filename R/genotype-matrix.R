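#' Construct a case-control genotype matrix
#'
#' The universal input container for MDR/FMDR analysis: an integer matrix of
#' genotype codes (rows = samples, columns = SNPs) together with a binary
#' case/control phenotype.  Genotypes are coded 0/1/2 for the homozygous
#' reference (AA), heterozygous (Aa) and homozygous variant (aa) genotypes.
#'
#' Missing genotypes are rejected: the methods here assume complete data, and
#' failing loudly is preferred over silent imputation.
#'
#' @param genotypes integer matrix (samples x SNPs) with values in
#'   \{0, 1, 2\}.
#' @param phenotype per-sample class labels: integer/numeric 0 (control) and
#'   1 (case), logical, or a character/factor with levels "control"/"case".
#' @param snp_names optional character vector of unique SNP identifiers;
#'   defaults to the column names of \code{genotypes}, or "SNP1", "SNP2", ...
#' @return an object of class \code{genotype_matrix}: a list with elements
#'   \code{genotypes} (integer matrix with SNP column names),
#'   \code{phenotype} (integer vector, 1 = case, 0 = control) and
#'   \code{snp_names}.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, 0L, 1L, 1L), nrow = 3)
#' gm <- genotype_matrix(g, c(1, 1, 0), c("rs1", "rs2"))
#' gm
#' @export
genotype_matrix <- function(genotypes, phenotype, snp_names = NULL) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(snp_names)) snp_names <- colnames(genotypes)
  if (is.null(snp_names)) snp_names <- paste0("SNP", seq_len(ncol(genotypes)))
  phenotype <- .coerce_phenotype(phenotype)
  colnames(genotypes) <- snp_names
  x <- structure(
    list(genotypes = genotypes, phenotype = phenotype,
         snp_names = as.character(snp_names)),
    class = "genotype_matrix")
  validate_genotype_matrix(x)
}

.coerce_phenotype <- function(phenotype) {
  if (is.factor(phenotype)) phenotype <- as.character(phenotype)
  if (is.character(phenotype)) {
    low <- tolower(phenotype)
    bad <- !low %in% c("case", "control", "0", "1")
    if (any(bad))
      stop("phenotype labels must be case/control or 0/1; found: ",
           paste(unique(phenotype[bad]), collapse = ", "), call. = FALSE)
    phenotype <- ifelse(low %in% c("case", "1"), 1L, 0L)
  }
  if (is.logical(phenotype)) phenotype <- as.integer(phenotype)
  if (anyNA(phenotype)) stop("phenotype contains missing values", call. = FALSE)
  if (!all(phenotype %in% c(0, 1)))
    stop("phenotype must be coded 0 (control) / 1 (case)", call. = FALSE)
  as.integer(phenotype)
}

#' Validate a genotype_matrix
#'
#' Checks the class invariants: all genotype values in \{0,1,2\} with no
#' missing entries, matching dimensions, unique SNP names, and at least one
#' case and one control.
#'
#' @param x a \code{genotype_matrix}.
#' @return \code{x}, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_genotype_matrix <- function(x) {
  g <- x$genotypes
  if (anyNA(g)) {
    idx <- which(is.na(g), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing genotype at row %d, column '%s'",
                 idx[1L], colnames(g)[idx[2L]]), call. = FALSE)
  }
  bad <- !(g %in% c(0L, 1L, 2L))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow = nrow(g)), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype value %s at row %d, column '%s' (must be 0/1/2)",
                 g[idx[1L], idx[2L]], idx[1L], colnames(g)[idx[2L]]),
         call. = FALSE)
  }
  if (length(x$phenotype) != nrow(g))
    stop("phenotype length does not match number of samples", call. = FALSE)
  if (length(x$snp_names) != ncol(g))
    stop("snp_names length does not match number of SNP columns", call. = FALSE)
  if (anyDuplicated(x$snp_names))
    stop("SNP names must be unique", call. = FALSE)
  if (sum(x$phenotype == 1L) < 1L || sum(x$phenotype == 0L) < 1L)
    stop("data must contain at least one case and one control", call. = FALSE)
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples (%d cases, %d controls) x %d SNPs\n",
              nrow(x$genotypes), sum(x$phenotype == 1L),
              sum(x$phenotype == 0L), ncol(x$genotypes)))
  cat("SNPs:", paste(utils::head(x$snp_names, 8L), collapse = ", "),
      if (length(x$snp_names) > 8L) "...", "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

n_cases <- function(x) sum(x$phenotype == 1L)
n_controls <- function(x) sum(x$phenotype == 0L)
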