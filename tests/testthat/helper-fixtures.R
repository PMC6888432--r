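## Small fixtures built in code, shared across test files.

tinyAlignment <- function() {
  multipleAlignment(
    c(human = "MKT-AS", mouse = "MKTQAS", frog = "M-TQAT"),
    referenceId = "human")
}

## a random gapped alignment for property-style checks
randomAlignment <- function(nTaxa, L, gapRate = 0.15, seed = 1L) {
  set.seed(seed)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  rows <- replicate(nTaxa, {
    r <- sample(aa, L, replace = TRUE)
    r[stats::runif(L) < gapRate] <- "-"
    if (all(r == "-")) r[1] <- "A"
    paste(r, collapse = "")
  })
  names(rows) <- sprintf("t%02d", seq_len(nTaxa))
  ## reference must have at least one residue
  multipleAlignment(rows, referenceId = names(rows)[1])
}

writeTempFasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}

writeTempLines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

## small deterministic tree over given labels
balancedTree <- function(labels, edgeLength = 0.2) {
  build <- function(lab) {
    if (length(lab) == 1) return(lab)
    h <- length(lab) %/% 2
    sprintf("(%s,%s)", build(lab[1:h]), build(lab[-(1:h)]))
  }
  tr <- ape::read.tree(text = paste0(build(labels), ";"))
  tr$edge.length <- rep(edgeLength, nrow(tr$edge))
  tr
}

smallBundleConfig <- function(dir, seed = 1L) {
  paths <- simulateBundle(dir, seed = seed, nTaxa = 12L, nSites = 100L,
                          blockLength = 25L, nPtmSites = 4L,
                          nVariants = 10L)
  list(alignment = paths$alignment, tree = paths$tree,
       disorder = paths$disorder, phospho = paths$phospho,
       domains = paths$domains, variants = paths$variants,
       orthologs = paths$orthologs, taxonomy = paths$taxonomy,
       expression = paths$expression, referenceId = "s01",
       outDir = file.path(dir, "out"))
}
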