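## Phosphosite calling at the 0.75 propensity cutoff (S/T/Y residues only)
## and majority-rule conservation across the alignment.

#' Call phosphosites for one sequence
#'
#' Positions whose phosphorylation propensity is at or above `cutoff`
#' (inclusive) and whose residue is S, T or Y (the phospho-acceptor amino
#' acids) are called positive.
#'
#' @param track a phospho [AnnotationTrack-class]
#' @param alignment a [MultipleAlignment-class] providing the residues
#' @param cutoff propensity cutoff (default 0.75)
#' @return integer vector of 1-based residue positions
#' @export
callSites <- function(track, alignment, cutoff = 0.75) {
  id <- track@sequenceId
  res <- strsplit(.ungapped(alignment, id), "")[[1L]]
  sc <- scores(track)
  if (length(sc) != length(res))
    stop("track length for '", id, "' does not match its ungapped length")
  which(sc >= cutoff & res %in% c("S", "T", "Y"))
}

#' Majority-rule conserved phosphosite columns
#'
#' A column is conserved when the number of sequences with a positive call
#' at that column, divided by the denominator, is at least `majority`
#' (inclusive at exactly 50%). The default denominator is the total number
#' of sequences in the alignment, so gapped sequences count as negative
#' ("the amount of sequence in the alignment"); `denominator = "nongap"`
#' divides by the non-gap count instead.
#'
#' @param alignment a [MultipleAlignment-class]
#' @param callsets named list (by taxon) of positive residue positions, as
#'   returned by [callSites()]
#' @param majority conservation threshold (default 0.5)
#' @param denominator `"all"` (default) or `"nongap"`
#' @param tracks optional named list of phospho tracks used to report the
#'   reference score per position
#' @param requireReference if `TRUE` (default), the reference-coordinate
#'   report keeps only columns where the reference itself is positive
#'   ("conserved human sites")
#' @return list with `columns` (data.frame: column, n_positive, denominator,
#'   fraction, conserved) and `referenceSites` (data.frame: ref_pos,
#'   residue, reference_positive, fraction_positive, conserved)
#' @export
conservedColumns <- function(alignment, callsets, majority = 0.5,
                             denominator = c("all", "nongap"),
                             tracks = NULL, requireReference = TRUE) {
  denominator <- match.arg(denominator)
  L <- alignmentWidth(alignment)
  ids <- taxa(alignment)
  if (!all(names(callsets) %in% ids))
    stop("callset names must be alignment taxa")
  pos <- matrix(FALSE, nrow = length(ids), ncol = L,
                dimnames = list(ids, NULL))
  gap <- matrix(TRUE, nrow = length(ids), ncol = L,
                dimnames = list(ids, NULL))
  for (id in ids) {
    cols <- .taxonResidueColumns(alignment, id)
    gap[id, cols] <- FALSE
    cs <- callsets[[id]]
    if (length(cs)) pos[id, cols[cs]] <- TRUE
  }
  nPos <- colSums(pos)
  den <- if (denominator == "all") rep(length(ids), L) else colSums(!gap)
  frac <- ifelse(den > 0, nPos / den, 0)
  conserved <- frac >= majority & den > 0
  columns <- data.frame(column = seq_len(L), n_positive = nPos,
                        denominator = den, fraction = frac,
                        conserved = conserved)
  map <- buildColumnMap(alignment)
  refId <- referenceId(alignment)
  refCols <- map@residueToColumn
  refRes <- strsplit(.ungapped(alignment, refId), "")[[1L]]
  refPositive <- pos[refId, refCols]
  refScore <- if (!is.null(tracks) && refId %in% names(tracks))
    scores(tracks[[refId]]) else rep(NA_real_, length(refCols))
  refSites <- data.frame(ref_pos = seq_along(refCols), residue = refRes,
                         human_score = refScore,
                         reference_positive = refPositive,
                         fraction_positive = frac[refCols],
                         conserved = conserved[refCols])
  if (requireReference)
    refSites$conserved <- refSites$conserved & refSites$reference_positive
  list(columns = columns, referenceSites = refSites)
}
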