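#' @import methods
NULL

AA_ALPHABET20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' MultipleAlignment: a gapped amino-acid alignment with a reference sequence
#'
#' Container for an aligned set of ortholog protein sequences. Rows are
#' equal-length strings over the 20 amino acids plus `X` (unknown residue) and
#' `-` (gap). One taxon is designated the reference (typically the human
#' sequence); all per-residue outputs of the pipeline are reported in the
#' 1-based coordinates of that sequence.
#'
#' @slot seqs named character vector of aligned sequences (names are taxon ids)
#' @slot referenceId id of the reference taxon; must be one of `names(seqs)`
#' @exportClass MultipleAlignment
setClass("MultipleAlignment",
  representation(seqs = "character", referenceId = "character"))

setValidity("MultipleAlignment", function(object) {
  s <- object@seqs
  if (length(s) < 1L) return("alignment must contain at least one sequence")
  if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
    return("all sequences must be named by taxon id")
  if (anyDuplicated(names(s))) return("taxon ids must be unique")
  w <- unique(nchar(s))
  if (length(w) != 1L) return("ragged alignment: rows differ in length")
  if (w < 1L) return("alignment width must be >= 1")
  if (length(object@referenceId) != 1L || !(object@referenceId %in% names(s)))
    return("referenceId must name exactly one sequence in the alignment")
  bad <- grepl(sprintf("[^%sX-]", paste(AA_ALPHABET20, collapse = "")), s)
  if (any(bad))
    return(sprintf("invalid characters in sequence(s): %s",
                   paste(names(s)[bad], collapse = ", ")))
  if (any(vapply(s, function(x) !grepl(sprintf("[%sX]", paste(AA_ALPHABET20, collapse = "")), x), logical(1))))
    return("every row must contain at least one non-gap character")
  TRUE
})

#' AnnotationTrack: per-residue scores for one ungapped sequence
#'
#' A dense score vector (one value per ungapped residue of the named
#' sequence), with all scores in `[0, 1]`. `kind` distinguishes disorder
#' propensity (IUPred-style) from phosphorylation propensity (NetPhos-style).
#'
#' @slot sequenceId taxon id the track belongs to
#' @slot kind one of `"disorder"`, `"phospho"`
#' @slot scores numeric vector in `[0, 1]`, one value per residue
#' @exportClass AnnotationTrack
setClass("AnnotationTrack",
  representation(sequenceId = "character", kind = "character",
                 scores = "numeric"))

setValidity("AnnotationTrack", function(object) {
  if (length(object@sequenceId) != 1L) return("sequenceId must be length 1")
  if (!(object@kind %in% c("disorder", "phospho")))
    return("kind must be 'disorder' or 'phospho'")
  if (length(object@scores) < 1L) return("empty track")
  if (anyNA(object@scores)) return("scores must not contain NA")
  if (any(object@scores < 0 | object@scores > 1))
    return("scores must lie in [0, 1]")
  TRUE
})

#' ColumnMap: alignment-column / reference-residue coordinate bookkeeping
#'
#' Maps every alignment column to the 1-based residue index it occupies in the
#' reference sequence (`NA` for columns where the reference is gapped) and
#' back. The two maps are inverse bijections over the non-gap columns.
#'
#' @slot columnToResidue integer vector of length L; `NA` at reference gaps
#' @slot residueToColumn integer vector of length (ungapped reference length)
#' @exportClass ColumnMap
setClass("ColumnMap",
  representation(columnToResidue = "integer", residueToColumn = "integer"))

setValidity("ColumnMap", function(object) {
  c2r <- object@columnToResidue; r2c <- object@residueToColumn
  nres <- sum(!is.na(c2r))
  if (length(r2c) != nres) return("residueToColumn length mismatch")
  if (nres > 0) {
    if (!identical(c2r[!is.na(c2r)], seq_len(nres)))
      return("non-gap columns must be numbered 1..n left-to-right")
    if (!identical(c2r[r2c], seq_len(nres)))
      return("round-trip identity violated")
  }
  TRUE
})

#' SiteRateResult: per-column posterior-mean evolutionary rates
#'
#' Result of empirical-Bayes site-rate estimation: posterior mean rate and Z
#' score per alignment column, a no-data flag for columns in which every taxon
#' is gap/`X`, the gamma shape used, and the marginal log-likelihood.
#'
#' @slot rate numeric, posterior mean rate per column
#' @slot z numeric, standardized rate per column (`NA` where no data)
#' @slot noData logical per column
#' @slot alpha gamma shape parameter used
#' @slot nCategories number of discrete gamma categories
#' @slot logLik marginal log-likelihood at `alpha`
#' @exportClass SiteRateResult
setClass("SiteRateResult",
  representation(rate = "numeric", z = "numeric", noData = "logical",
                 alpha = "numeric", nCategories = "integer",
                 logLik = "numeric"))

setValidity("SiteRateResult", function(object) {
  L <- length(object@rate)
  if (length(object@z) != L || length(object@noData) != L)
    return("rate, z and noData must have equal length")
  if (any(object@noData & !is.na(object@z)))
    return("no-data columns must carry NA Z scores")
  if (object@alpha <= 0) return("alpha must be positive")
  TRUE
})

#' DisorderMatrix: tree-ordered order-disorder heat-map matrix
#'
#' Disorder scores spread over the alignment: rows are taxa in ladderized tree
#' order, columns are alignment columns, cells are scores in `[0, 1]` with
#' `NA` exactly where the alignment has a gap.
#'
#' @slot scores numeric matrix (taxa x columns) with NA at gaps
#' @slot leafOrder taxon ids in the row order used (ladderized tree order)
#' @exportClass DisorderMatrix
setClass("DisorderMatrix",
  representation(scores = "matrix", leafOrder = "character"))

setValidity("DisorderMatrix", function(object) {
  if (!identical(rownames(object@scores), object@leafOrder))
    return("row names must equal leafOrder")
  v <- object@scores[!is.na(object@scores)]
  if (length(v) && (any(v < 0) || any(v > 1)))
    return("scores must lie in [0, 1]")
  TRUE
})

#' PhyloProfile: binary protein-by-species presence/absence matrix
#'
#' Phylogenetic profiles: rows are proteins, columns species, cells 0/1
#' (ortholog detected or not). `groups` is a strictly nested family of species
#' sets (e.g. chordates within metazoans within multicellular within
#' eukaryotes), ordered from narrowest to broadest, used to label clusters by
#' conservation depth.
#'
#' @slot mat binary integer matrix, proteins x species
#' @slot groups named list of species-id character vectors, narrowest first
#' @exportClass PhyloProfile
setClass("PhyloProfile",
  representation(mat = "matrix", groups = "list"))

setValidity("PhyloProfile", function(object) {
  m <- object@mat
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("profile matrix needs protein row names and species column names")
  if (!all(m %in% c(0L, 1L))) return("profile matrix must be binary")
  g <- object@groups
  if (length(g)) {
    if (is.null(names(g))) return("groups must be named")
    sp <- colnames(m)
    for (i in seq_along(g)) {
      if (!all(g[[i]] %in% sp)) return("group species absent from matrix")
      if (i > 1 && !all(g[[i - 1]] %in% g[[i]]))
        return("groups must be nested, narrowest first")
      if (i > 1 && length(g[[i]]) <= length(g[[i - 1]]))
        return("groups must be strictly nested")
    }
    if (!all(sp %in% g[[length(g)]]))
      return("every species must belong to the broadest group")
  }
  TRUE
})

#' ProfileClusters: Ward clustering of phylogenetic profiles
#'
#' Agglomerative (Ward) clustering result: an `hclust`-compatible merge tree,
#' a flat assignment at `k` clusters, and per-cluster evolutionary class
#' labels.
#'
#' @slot hclust an object of S3 class `hclust` (merge, height, order, labels)
#' @slot assignment named integer vector, cluster id per protein
#' @slot classLabels character vector, one label per cluster id
#' @slot k number of flat clusters
#' @exportClass ProfileClusters
setClass("ProfileClusters",
  representation(hclust = "ANY", assignment = "integer",
                 classLabels = "character", k = "integer"))

setValidity("ProfileClusters", function(object) {
  if (!inherits(object@hclust, "hclust")) return("hclust slot must be hclust")
  if (length(object@classLabels) != object@k)
    return("one class label per cluster required")
  if (!all(object@assignment %in% seq_len(object@k)))
    return("assignment must use cluster ids 1..k")
  TRUE
})
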