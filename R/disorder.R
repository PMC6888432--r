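## Order-disorder track integration: tree-ordered heat-map matrix over the
## alignment, binary disorder calls at the 0.5 cutoff, per-column consensus,
## constrained/flexible disorder classification, and the ordered-vs-
## disordered rate comparison.

## tip labels in the row order a ladderized plot would use (deterministic)
.ladderOrder <- function(tree) {
  tr <- ape::ladderize(tree)
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr$tip.label[tr$edge[tr$edge[, 2L] <= length(tr$tip.label), 2L]]
}

#' Build the tree-ordered disorder heat-map matrix
#'
#' Spreads each taxon's per-residue disorder scores across the non-gap cells
#' of its alignment row, in sequence order; gap cells are `NA`. Rows are
#' ordered by the ladderized order of the input tree, so the matrix lines up
#' with taxonomic position as in an alignment/tree heat map.
#'
#' @param alignment a [MultipleAlignment-class]
#' @param tracks named list of disorder [AnnotationTrack-class] objects (one
#'   per taxon; names or `sequenceId`s must cover all taxa)
#' @param tree ape `phylo` over the alignment taxa
#' @return a [DisorderMatrix-class]
#' @export
buildDisorderMatrix <- function(alignment, tracks, tree) {
  .checkTreeAlignment(tree, alignment)
  if (is(tracks, "AnnotationTrack")) tracks <- list(tracks)
  ids <- vapply(tracks, function(t) t@sequenceId, character(1))
  names(tracks) <- ids
  missing <- setdiff(taxa(alignment), ids)
  if (length(missing))
    stop("missing disorder track(s) for: ", paste(missing, collapse = ", "))
  ord <- .ladderOrder(tree)
  L <- alignmentWidth(alignment)
  m <- matrix(NA_real_, nrow = length(ord), ncol = L,
              dimnames = list(ord, NULL))
  for (id in ord) {
    cols <- .taxonResidueColumns(alignment, id)
    sc <- scores(tracks[[id]])
    if (length(sc) != length(cols))
      stop("track length for '", id, "' does not match its ungapped length")
    m[id, cols] <- sc
  }
  new("DisorderMatrix", scores = m, leafOrder = ord)
}

#' Binary order/disorder call at the 0.5 cutoff
#'
#' A residue is called disordered when its disorder propensity is at or
#' above the cutoff (boundary inclusive); 0.5 is the conventional divide
#' between order and disorder propensity for IUPred-style scores.
#'
#' @param scores numeric vector in `[0, 1]`
#' @param cutoff disorder cutoff (default 0.5)
#' @return logical vector, `TRUE` = disordered
#' @export
callDisorder <- function(scores, cutoff = 0.5) {
  if (any(scores < 0 | scores > 1, na.rm = TRUE))
    stop("disorder scores must lie in [0, 1]")
  scores >= cutoff
}

#' Per-column consensus structure call
#'
#' A column is called disordered when at least `majority` (default 50%,
#' inclusive) of its non-gap cells are at or above the disorder cutoff;
#' columns with no non-gap cells are `no_data`.
#'
#' @param matrix a [DisorderMatrix-class]
#' @param column column index or vector of indices; default all columns
#' @param cutoff disorder cutoff (default 0.5)
#' @param majority consensus fraction (default 0.5, inclusive)
#' @return character vector in `{"ordered", "disordered", "no_data"}`
#' @export
consensusStructure <- function(matrix, column = NULL, cutoff = 0.5,
                               majority = 0.5) {
  m <- scores(matrix)
  if (is.null(column)) column <- seq_len(ncol(m))
  vapply(column, function(j) {
    v <- m[, j]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return("no_data")
    if (mean(v >= cutoff) >= majority) "disordered" else "ordered"
  }, character(1))
}

#' Classify reference residues by structure and evolutionary rate
#'
#' Combines per-residue structure calls with rate Z scores: residues are
#' `slow` when `Z < 0` and `fast` otherwise; disordered residues are then
#' `constrained_disorder` (slow) or `flexible_disorder` (fast), ordered
#' residues are `ordered`. Residues with structure `no_data` or missing Z
#' stay `no_data`.
#'
#' @param structure character vector per reference residue
#'   (`"ordered"`/`"disordered"`/`"no_data"`)
#' @param z numeric Z score per reference residue
#' @return data.frame with columns `pos`, `structure`, `evolution`, `z`,
#'   `category`
#' @export
classifyResidues <- function(structure, z) {
  if (length(structure) != length(z))
    stop("structure and z must have equal length")
  evolution <- ifelse(is.na(z), NA_character_,
                      ifelse(z < 0, "slow", "fast"))
  category <- rep("no_data", length(z))
  ok <- !is.na(z) & structure != "no_data"
  category[ok & structure == "ordered"] <- "ordered"
  category[ok & structure == "disordered" & evolution == "slow"] <-
    "constrained_disorder"
  category[ok & structure == "disordered" & evolution == "fast"] <-
    "flexible_disorder"
  data.frame(pos = seq_along(z), structure = structure,
             evolution = evolution, z = z, category = category)
}

#' Compare rate distributions of ordered vs disordered residues
#'
#' Two-sided Mann-Whitney U test of the rate Z scores grouped by structure
#' call (see [mannWhitneyU()]).
#'
#' @param z numeric Z scores
#' @param structure matching character vector of structure calls
#' @return list with `U`, `p`, `method`, `medianDisordered`,
#'   `medianOrdered`, and group sizes
#' @export
compareRateDistributions <- function(z, structure) {
  keep <- !is.na(z) & structure %in% c("ordered", "disordered")
  zd <- z[keep & structure == "disordered"]
  zo <- z[keep & structure == "ordered"]
  if (length(zd) == 0L || length(zo) == 0L)
    stop("both structure groups must be non-empty")
  res <- mannWhitneyU(zd, zo)
  list(U = res$U, p = res$p, method = res$method,
       medianDisordered = res$medianA, medianOrdered = res$medianB,
       nDisordered = length(zd), nOrdered = length(zo))
}

#' Export a disorder matrix as TSV (masked cells empty)
#'
#' @param matrix a [DisorderMatrix-class]
#' @param path output path
#' @export
writeDisorderMatrix <- function(matrix, path) {
  m <- scores(matrix)
  df <- as.data.frame(m)
  names(df) <- paste0("col", seq_len(ncol(m)))
  df <- cbind(taxon = rownames(m), df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.commentHeader(c(format = "disorder_matrix")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
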