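## Tissue-specificity statistic on protein x tissue TPM tables: per protein,
## mean mu and population standard deviation s over tissues; a tissue is
## specific when its TPM strictly exceeds mu + 1.65 s (the 1.65 factor marks
## the upper bound of the 90% confidence band).

#' Flag matrix of tissue-specific expression
#'
#' Vectorized core of the specificity statistic: for each protein row,
#' `mu = mean(x)`, `s = population SD(x)` (divisor n), and a cell is flagged
#' when `x > mu + 1.65 s` (strict).
#'
#' @param table numeric matrix, proteins x tissues, TPM >= 0
#' @param factor confidence factor (default 1.65)
#' @return logical matrix of the same shape
#' @export
specificityFlags <- function(table, factor = 1.65) {
  if (ncol(table) < 2L) stop("need at least 2 tissues per protein")
  if (any(table < 0)) stop("TPM values must be non-negative")
  if (anyNA(table)) {
    warning("missing TPM cells set to 0")
    table[is.na(table)] <- 0
  }
  mu <- rowMeans(table)
  s <- sqrt(rowMeans((table - mu)^2))
  table > mu + factor * s
}

#' Tissue-specificity calls
#'
#' Per (protein, tissue) cell: TPM, the protein's mean and population SD
#' over tissues, the threshold `mu + 1.65 s`, and the specificity flag
#' (1 when TPM strictly exceeds the threshold).
#'
#' @param table numeric matrix, proteins x tissues (row/column names
#'   required)
#' @param factor confidence factor (default 1.65)
#' @param flaggedOnly if `TRUE`, return only flagged cells
#' @return data.frame with columns `protein`, `tissue`, `tpm`, `mu`, `s`,
#'   `threshold`, `flag`
#' @export
specificityCalls <- function(table, factor = 1.65, flaggedOnly = FALSE) {
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop("expression table needs protein row names and tissue column names")
  flags <- specificityFlags(table, factor)
  mu <- rowMeans(table)
  s <- sqrt(rowMeans((table - mu)^2))
  df <- data.frame(
    protein = rep(rownames(table), times = ncol(table)),
    tissue = rep(colnames(table), each = nrow(table)),
    tpm = as.vector(table),
    mu = rep(unname(mu), times = ncol(table)),
    s = rep(unname(s), times = ncol(table)),
    threshold = rep(unname(mu + factor * s), times = ncol(table)),
    flag = as.integer(as.vector(flags)))
  if (flaggedOnly) df <- df[df$flag == 1L, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Proteins specifically expressed in one tissue
#'
#' @param calls data.frame from [specificityCalls()]
#' @param tissue tissue name
#' @return data.frame of flagged proteins in that tissue, sorted by protein,
#'   with TPM values
#' @export
summarizeByTissue <- function(calls, tissue) {
  if (!(tissue %in% calls$tissue)) stop("unknown tissue: ", tissue)
  out <- calls[calls$tissue == tissue & calls$flag == 1L,
               c("protein", "tissue", "tpm", "threshold")]
  out <- out[order(out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a protein x tissue TPM table
#'
#' TSV with a header row of tissue names and first column `protein`.
#' Missing cells become 0 with a warning.
#'
#' @param path TSV path
#' @return numeric matrix with protein row names
#' @export
readExpressionTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "protein")
    stop("first column of expression table must be 'protein'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$protein
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    warning("missing TPM cells set to 0")
    m[is.na(m)] <- 0
  }
  if (any(m < 0)) stop("TPM values must be non-negative")
  m
}

#' Write a protein x tissue TPM table
#'
#' @param table numeric matrix with dimnames
#' @param path output TSV path
#' @export
writeExpressionTable <- function(table, path) {
  df <- data.frame(protein = rownames(table), table, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.commentHeader(c(format = "expression_tpm")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
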