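#' Read a case-control genotype table
#'
#' Reads the plain-text convention used by MDR software: a header line, one
#' row per sample, SNP genotypes coded 0/1/2, and a final class column coded
#' 1 = case, 0 = control.  Tab- and comma-delimited files are both accepted;
#' by default the delimiter is auto-detected (tab preferred, then comma).
#'
#' The class column is identified by the name "Class" (case-insensitive);
#' if no column has that name the last column is used and a warning is
#' issued.  Any token that is not an integer 0/1/2 in a genotype column, or
#' not 0/1 in the class column, is an error naming the offending cell —
#' nothing is silently coerced.
#'
#' @param path path to the file.
#' @param delimiter field delimiter, "\\t" or ","; \code{NULL} (default)
#'   auto-detects from the header line.
#' @return a [genotype_matrix].
#' @seealso [write_genotype_table()]
#' @export
read_genotype_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("format error: file needs a header line and at least one sample row",
         call. = FALSE)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", lines[1L])) "\t" else ","
  }
  header <- trimws(strsplit(lines[1L], delimiter, fixed = TRUE)[[1L]])
  if (length(header) < 2L)
    stop("format error: need at least one SNP column and a class column",
         call. = FALSE)
  class_col <- which(tolower(header) == "class")
  if (length(class_col) == 0L) {
    class_col <- length(header)
    warning("no 'Class' column found; using last column '",
            header[class_col], "' as the class column", call. = FALSE)
  } else if (length(class_col) > 1L) {
    stop("format error: multiple 'Class' columns", call. = FALSE)
  }
  snp_cols <- setdiff(seq_along(header), class_col)

  body <- strsplit(lines[-1L], delimiter, fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != length(header)))
    stop(sprintf("format error: row %d has %d fields, expected %d",
                 which(nfield != length(header))[1L] + 1L,
                 nfield[nfield != length(header)][1L], length(header)),
         call. = FALSE)
  tab <- matrix(trimws(unlist(body)), nrow = length(body), byrow = TRUE)

  parse_int <- function(tokens, allowed, what, cols) {
    ok <- tokens %in% as.character(allowed)
    if (!all(ok)) {
      bad <- which(matrix(!ok, nrow = nrow(tab)), arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "format error: invalid %s value '%s' at data row %d, column '%s'",
        what, tokens[!ok][1L], bad[1L], header[cols[bad[2L]]]), call. = FALSE)
    }
    as.integer(tokens)
  }
  geno <- matrix(parse_int(tab[, snp_cols, drop = FALSE], 0:2,
                           "genotype", snp_cols),
                 nrow = nrow(tab))
  cls <- parse_int(tab[, class_col], 0:1, "class", class_col)
  genotype_matrix(geno, cls, snp_names = header[snp_cols])
}

#' Write a case-control genotype table
#'
#' Writes a [genotype_matrix] in the plain-text MDR convention read by
#' [read_genotype_table()]: header "snp1<d>snp2<d>...<d>Class", one row per
#' sample, genotypes 0/1/2, cases as 1 and controls as 0.
#'
#' @param data a [genotype_matrix].
#' @param path output file path.
#' @param delimiter field delimiter (default tab).
#' @return \code{path}, invisibly.
#' @export
write_genotype_table <- function(data, path, delimiter = "\t") {
  validate_genotype_matrix(data)
  if (ncol(data$genotypes) < 1L)
    stop("format error: genotype matrix has no SNP columns", call. = FALSE)
  out <- cbind(data$genotypes, Class = data$phenotype)
  lines <- c(paste(colnames(out), collapse = delimiter),
             apply(out, 1L, paste, collapse = delimiter))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write to ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}
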