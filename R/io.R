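## Readers/writers for the external formats the pipeline touches, plus
## alignment-coordinate bookkeeping. Residue and column coordinates are
## 1-based everywhere (mutation nomenclature such as Ser346Arg is 1-based).

.commentHeader <- function(params = character()) {
  sprintf("# evoscape %s%s",
          as.character(utils::packageVersion("evoscape")),
          if (length(params)) paste0(" | ", paste(names(params), params,
                                                  sep = "=", collapse = " "))
          else "")
}

#' Construct a MultipleAlignment from sequences in memory
#'
#' @param seqs named character vector of equal-length aligned sequences
#' @param referenceId taxon id of the reference sequence
#' @return a [MultipleAlignment-class]
#' @export
multipleAlignment <- function(seqs, referenceId) {
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  new("MultipleAlignment", seqs = seqs, referenceId = referenceId)
}

#' Read an aligned FASTA file
#'
#' Parses an aligned amino-acid FASTA file (via Biostrings), uppercases
#' residues, normalizes `.` to `-`, and validates that all rows have equal
#' length and that the reference is present.
#'
#' @param path FASTA file path
#' @param referenceId taxon id of the reference (e.g. human) sequence
#' @return a [MultipleAlignment-class]
#' @export
readAlignment <- function(path, referenceId) {
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("could not parse FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  v <- as.character(seqs)
  names(v) <- sub("\\s.*$", "", names(seqs))
  if (length(unique(nchar(v))) != 1L)
    stop("ragged alignment: sequences in '", path, "' differ in length")
  if (!(referenceId %in% names(v)))
    stop("reference sequence '", referenceId, "' not found in '", path, "'")
  multipleAlignment(v, referenceId)
}

#' Write an alignment as FASTA
#'
#' @param alignment a [MultipleAlignment-class]
#' @param path output path
#' @export
writeAlignment <- function(alignment, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(sequences(alignment)), path, width = 80L)
  invisible(path)
}

#' Read a Newick tree
#'
#' Single-tree Newick parsing via ape. Missing branch lengths default to 0
#' with a warning; duplicate leaf labels are an error. Unrooted trees with a
#' basal trifurcation are accepted as-is: under the reversible models used
#' here the likelihood is root-invariant, so any rooting is equivalent.
#'
#' @param path Newick file path
#' @return an ape `phylo` object
#' @export
readNewickTree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) NULL)
  if (is.null(tr))
    stop("could not parse Newick file '", path, "'", call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in tree: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("tree has missing branch lengths; defaulting them to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  tr
}

#' Map alignment columns to reference residues and back
#'
#' Numbers the non-gap columns of the reference row 1..n left-to-right;
#' columns where the reference is gapped map to `NA`.
#'
#' @param alignment a [MultipleAlignment-class]
#' @return a [ColumnMap-class]
#' @export
buildColumnMap <- function(alignment) {
  ref <- strsplit(sequences(alignment)[[referenceId(alignment)]], "")[[1L]]
  nongap <- ref != "-"
  c2r <- rep(NA_integer_, length(ref))
  c2r[nongap] <- seq_len(sum(nongap))
  new("ColumnMap", columnToResidue = c2r, residueToColumn = which(nongap))
}

#' @rdname buildColumnMap
#' @param map a [ColumnMap-class]
#' @param column alignment column indices
#' @export
columnToResidue <- function(map, column) map@columnToResidue[column]

#' @rdname buildColumnMap
#' @param residue 1-based reference residue indices
#' @export
residueToColumn <- function(map, residue) map@residueToColumn[residue]

.ungapped <- function(alignment, id) {
  gsub("-", "", sequences(alignment)[[id]], fixed = TRUE)
}

## per-taxon map: residue index -> alignment column
.taxonResidueColumns <- function(alignment, id) {
  chars <- strsplit(sequences(alignment)[[id]], "")[[1L]]
  which(chars != "-")
}

#' Read a per-residue score track
#'
#' TSV with header `seq_id<TAB>pos<TAB>score` (comment lines starting with
#' `#` ignored). Positions must cover 1..n for the ungapped length n of the
#' named sequence, without gaps or duplicates; scores must lie in `[0, 1]`.
#'
#' @param path TSV path
#' @param alignment a [MultipleAlignment-class] used for length validation
#' @param kind `"disorder"` or `"phospho"`
#' @return an [AnnotationTrack-class]; if the file holds several sequence
#'   ids, a named list of tracks
#' @export
readTrack <- function(path, alignment, kind = c("disorder", "phospho")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("seq_id", "pos", "score") %in% names(df)))
    stop("track file must have columns seq_id, pos, score: ", path)
  out <- lapply(split(df, df$seq_id), function(d) {
    id <- d$seq_id[[1L]]
    if (!(id %in% taxa(alignment)))
      stop("track sequence '", id, "' absent from alignment")
    n <- nchar(.ungapped(alignment, id))
    if (any(d$score < 0 | d$score > 1))
      stop("track scores outside [0, 1] for sequence '", id, "'")
    if (anyDuplicated(d$pos))
      stop("duplicate residue positions in track for '", id, "'")
    if (nrow(d) != n || !setequal(d$pos, seq_len(n)))
      stop(sprintf(
        "track for '%s' must cover residues 1..%d exactly (got %d rows)",
        id, n, nrow(d)))
    new("AnnotationTrack", sequenceId = id, kind = kind,
        scores = d$score[order(d$pos)])
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Write per-residue score tracks
#'
#' @param tracks an [AnnotationTrack-class] or list of them
#' @param path output TSV path
#' @export
writeTrack <- function(tracks, path) {
  if (is(tracks, "AnnotationTrack")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(seq_id = tr@sequenceId, pos = seq_along(tr@scores),
               score = tr@scores)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.commentHeader(c(format = "track",
                              kind = tracks[[1L]]@kind)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and filter a variant table
#'
#' TSV with header `protein<TAB>pos<TAB>ref<TAB>alt<TAB>n_cases<TAB>label`.
#' Keeps rows whose label is in `allowedLabels` and whose reference amino
#' acid matches the alignment's reference sequence at that position; rejected
#' rows are returned in the `"rejected"` attribute with a reason.
#'
#' @param path TSV path
#' @param alignment a [MultipleAlignment-class] providing the reference
#' @param allowedLabels pathogenicity labels to keep (default `"pathogenic"`)
#' @return data.frame of accepted variants (protein, pos, ref, alt, n_cases,
#'   label) with attribute `rejected`
#' @export
readVariants <- function(path, alignment, allowedLabels = "pathogenic") {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("protein", "pos", "ref", "alt", "n_cases", "label")
  if (!all(need %in% names(df)))
    stop("variant file must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) {
    out <- df
    attr(out, "rejected") <- cbind(df, reason = character(0))
    return(out)
  }
  refseq <- strsplit(.ungapped(alignment, referenceId(alignment)), "")[[1L]]
  reason <- rep(NA_character_, nrow(df))
  reason[!(df$label %in% allowedLabels)] <- "label not in allow-list"
  oob <- is.na(reason) & (df$pos < 1L | df$pos > length(refseq))
  reason[oob] <- "position out of range"
  mism <- is.na(reason) & toupper(df$ref) != refseq[pmin(pmax(df$pos, 1L),
                                                         length(refseq))]
  reason[mism] <- "ref residue mismatch"
  out <- df[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  rej <- df[!is.na(reason), , drop = FALSE]
  rej$reason <- reason[!is.na(reason)]
  rownames(rej) <- NULL
  attr(out, "rejected") <- rej
  out
}

#' Write a variant table
#'
#' @param variants data.frame with the standard variant columns
#' @param path output TSV path
#' @export
writeVariants <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.commentHeader(c(format = "variants")), con)
  utils::write.table(
    variants[, c("protein", "pos", "ref", "alt", "n_cases", "label")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a domain interval file (`name<TAB>start<TAB>end`, 1-based
#' inclusive)
#'
#' @param path TSV path
#' @return data.frame with columns name, start, end
#' @export
readDomains <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("name", "start", "end") %in% names(df)))
    stop("domain file must have columns name, start, end")
  if (anyDuplicated(df$name)) stop("domain names must be unique")
  if (any(df$start < 1L | df$end < df$start))
    stop("domain intervals must satisfy 1 <= start <= end")
  df
}

#' Generic TSV writer with pipeline header comment
#'
#' @param df data.frame
#' @param path output path
#' @param params named character vector recorded in the header comment
#' @export
writeTsv <- function(df, path, params = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.commentHeader(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
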