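## Synthetic-data generators: every input the pipeline consumes, with known
## ground truth. All generators are deterministic for a fixed seed and leave
## the caller's RNG state untouched.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## per-stage substreams derived from one bundle seed (kept below 2^31)
.substream <- function(seed, k) (as.integer(seed) %% 2000000L) * 1000L + k

#' Simulate a Yule-topology tree
#'
#' Topology grows by repeatedly splitting a uniformly chosen extant tip (the
#' Yule process); branch lengths are i.i.d. exponential with the given mean
#' (substitutions/site).
#'
#' @param nTaxa number of leaves (>= 2)
#' @param meanBranchLength mean branch length (default 0.1)
#' @param seed RNG seed
#' @return an ape `phylo` with tip labels `s01`, `s02`, ...
#' @export
simulateTree <- function(nTaxa, meanBranchLength = 0.1, seed = 1L) {
  if (nTaxa < 2L) stop("need at least 2 taxa")
  labels <- sprintf("s%02d", seq_len(nTaxa))
  .withSeed(seed, {
    tips <- c(labels[1L], labels[2L])
    if (nTaxa > 2L) for (i in 3:nTaxa) {
      j <- sample.int(length(tips), 1L)
      tips[j] <- sprintf("(%s,%s)", tips[j], labels[i])
    }
    nwk <- sprintf("(%s,%s);", tips[1L],
                   paste(tips[-1L], collapse = ","))
    tr <- ape::read.tree(text = nwk)
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / meanBranchLength)
    tr
  })
}

#' Simulate an alignment on a tree with per-site gamma rates
#'
#' Each site draws a discrete-gamma category; its true rate is the category
#' rate times an optional per-site multiplier (used to make, e.g.,
#' disordered blocks evolve faster). The root state is drawn from the model's
#' stationary frequencies and evolved along each branch with
#' `P(t * rate)`. Optionally, gap characters are inserted at random cells
#' (`gapRate`), never in the reference row and never leaving a row all-gap.
#'
#' @param tree ape `phylo`
#' @param model from [substitutionModel()]
#' @param gamma from [gammaCategories()]
#' @param nSites number of alignment columns
#' @param seed RNG seed
#' @param rateMultipliers optional numeric vector of length `nSites`
#' @param gapRate per-cell gap probability (default 0)
#' @param referenceId reference taxon (default first tip label)
#' @return list with `alignment` ([MultipleAlignment-class]), `trueRates`
#'   (per-site rate actually used), `categories` (per-site category index)
#' @export
simulateAlignment <- function(tree, model, gamma, nSites, seed = 1L,
                              rateMultipliers = NULL, gapRate = 0,
                              referenceId = NULL) {
  if (is.null(rateMultipliers)) rateMultipliers <- rep(1, nSites)
  if (length(rateMultipliers) != nSites)
    stop("rateMultipliers must have length nSites")
  ntip <- length(tree$tip.label)
  if (is.null(referenceId)) referenceId <- tree$tip.label[1L]
  .withSeed(seed, {
    cats <- sample.int(gamma$K, nSites, replace = TRUE)
    trueRates <- gamma$rates[cats] * rateMultipliers
    tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    nnode <- ntip + tr$Nnode
    states <- matrix(NA_integer_, nnode, nSites)
    root <- ntip + 1L
    states[root, ] <- sample.int(20L, nSites, replace = TRUE,
                                 prob = model$pi)
    groups <- split(seq_len(nSites), trueRates)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      t <- tr$edge.length[e]
      for (g in groups) {
        r <- trueRates[g[1L]]
        P <- transitionProbabilities(model, t * r)
        cp <- t(apply(P, 1L, cumsum))
        u <- stats::runif(length(g))
        states[child, g] <- rowSums(cp[states[par, g], , drop = FALSE] <
                                      u) + 1L
      }
    }
    chars <- matrix(AA_ALPHABET20[states[seq_len(ntip), ]], ntip, nSites)
    rownames(chars) <- tr$tip.label
    if (gapRate > 0) {
      mask <- matrix(stats::runif(ntip * nSites) < gapRate, ntip, nSites)
      mask[rownames(chars) == referenceId, ] <- FALSE
      allGap <- rowSums(!mask) == 0L
      mask[allGap, 1L] <- FALSE
      chars[mask] <- "-"
    }
    seqs <- apply(chars, 1L, paste, collapse = "")
    list(alignment = multipleAlignment(seqs, referenceId),
         trueRates = trueRates, categories = cats)
  })
}

#' Simulate per-taxon disorder tracks with block structure
#'
#' Reference residues are partitioned into blocks with regime `"ordered"` or
#' `"disordered"`; ordered residues draw scores from Beta(2, 8) (mean 0.2),
#' disordered from Beta(8, 2) (mean 0.8), independently per taxon and
#' residue. Residues of non-reference taxa inherit the regime of the
#' reference residue sharing their column (columns where the reference is
#' gapped inherit the preceding reference residue's regime).
#'
#' @param alignment a [MultipleAlignment-class]
#' @param blocks data.frame with columns `length`, `regime`; lengths must
#'   sum to the ungapped reference length
#' @param seed RNG seed
#' @param orderedShape,disorderedShape Beta shape pairs for the two regimes
#' @return list with `tracks` (named list of disorder
#'   [AnnotationTrack-class]) and `regimes` (per reference residue)
#' @export
simulateDisorderTracks <- function(alignment, blocks, seed = 1L,
                                   orderedShape = c(2, 8),
                                   disorderedShape = c(8, 2)) {
  refLen <- nchar(.ungapped(alignment, referenceId(alignment)))
  if (sum(blocks$length) != refLen)
    stop("block lengths must sum to the reference length (", refLen, ")")
  if (!all(blocks$regime %in% c("ordered", "disordered")))
    stop("block regime must be 'ordered' or 'disordered'")
  regimes <- rep(blocks$regime, blocks$length)
  map <- buildColumnMap(alignment)
  ## per-column regime: reference residue at/preceding the column
  residueAt <- cummax(ifelse(is.na(map@columnToResidue), 0L,
                             map@columnToResidue))
  residueAt[residueAt == 0L] <- 1L
  colRegime <- regimes[residueAt]
  .withSeed(seed, {
    tracks <- lapply(taxa(alignment), function(id) {
      cols <- .taxonResidueColumns(alignment, id)
      reg <- colRegime[cols]
      sc <- numeric(length(cols))
      no <- reg == "ordered"
      sc[no] <- stats::rbeta(sum(no), orderedShape[1L], orderedShape[2L])
      sc[!no] <- stats::rbeta(sum(!no), disorderedShape[1L],
                              disorderedShape[2L])
      new("AnnotationTrack", sequenceId = id, kind = "disorder",
          scores = pmin(pmax(sc, 0), 1))
    })
    names(tracks) <- taxa(alignment)
    list(tracks = tracks, regimes = regimes)
  })
}

#' Plant conserved phosphosites
#'
#' At each planted reference position, a Binomial(n_taxa, f) subset of taxa
#' is made positive: their residue at that column is set to serine and their
#' phospho score drawn from U(0.75, 1); all other scores are baseline
#' U(0, 0.5). Taxa gapped at the column cannot be positive.
#'
#' @param alignment a [MultipleAlignment-class]
#' @param positions reference residue positions to plant
#' @param f per-taxon conservation probability
#' @param seed RNG seed
#' @return list with `alignment` (serines planted), `tracks` (named list of
#'   phospho [AnnotationTrack-class]), `truth` (data.frame: position,
#'   n_positive)
#' @export
simulatePtm <- function(alignment, positions, f, seed = 1L) {
  map <- buildColumnMap(alignment)
  ids <- taxa(alignment)
  .withSeed(seed, {
    rows <- strsplit(sequences(alignment), "")
    scoreAt <- lapply(rows, function(r) {
      n <- sum(r != "-")
      stats::runif(n, 0, 0.5)
    })
    names(scoreAt) <- ids
    truth <- data.frame(position = positions, n_positive = 0L)
    for (pi in seq_along(positions)) {
      col <- residueToColumn(map, positions[pi])
      positive <- ids[stats::runif(length(ids)) < f]
      for (id in positive) {
        cols <- which(rows[[id]] != "-")
        ri <- match(col, cols)
        if (is.na(ri)) next  # gapped at this column
        rows[[id]][col] <- "S"
        scoreAt[[id]][ri] <- stats::runif(1L, 0.75, 1)
        truth$n_positive[pi] <- truth$n_positive[pi] + 1L
      }
    }
    seqs <- vapply(rows, paste, character(1), collapse = "")
    names(seqs) <- ids
    aln <- multipleAlignment(seqs, referenceId(alignment))
    tracks <- lapply(ids, function(id)
      new("AnnotationTrack", sequenceId = id, kind = "phospho",
          scores = scoreAt[[id]]))
    names(tracks) <- ids
    list(alignment = aln, tracks = tracks, truth = truth)
  })
}

#' Default nested taxonomy groups for simulated profiles
#'
#' @param sizes named integer vector of cumulative group sizes, narrowest
#'   first (defaults: 8 chordates within 20 metazoans within 45
#'   multicellular within 95 eukaryotes)
#' @return named list of species-id vectors, narrowest first
#' @export
defaultTaxonomyGroups <- function(sizes = c(chordates = 8L, metazoans = 20L,
                                            multicellular = 45L,
                                            eukaryotes = 95L)) {
  species <- sprintf("sp%03d", seq_len(sizes[[length(sizes)]]))
  stats::setNames(lapply(sizes, function(n) species[seq_len(n)]),
                  names(sizes))
}

#' Simulate phylogenetic profiles with planted classes
#'
#' Each class's pattern is presence in exactly one nested taxonomy group
#' (class i present in group i); profile rows follow their class pattern
#' with i.i.d. cell flips at rate `flipNoise`.
#'
#' @param classSizes integer vector, proteins per class (one per group)
#' @param groups nested taxonomy groups (default [defaultTaxonomyGroups()])
#' @param flipNoise per-cell flip probability (default 0.05)
#' @param seed RNG seed
#' @return list with `profile` ([PhyloProfile-class]) and `truth` (named
#'   integer vector: true class per protein)
#' @export
simulateProfiles <- function(classSizes = rep(15L, 4L),
                             groups = defaultTaxonomyGroups(),
                             flipNoise = 0.05, seed = 1L) {
  if (length(classSizes) != length(groups))
    stop("need one class size per taxonomy group")
  species <- groups[[length(groups)]]
  nProt <- sum(classSizes)
  proteins <- sprintf("prot%03d", seq_len(nProt))
  trueClass <- rep(seq_along(classSizes), classSizes)
  names(trueClass) <- proteins
  .withSeed(seed, {
    m <- matrix(0L, nProt, length(species),
                dimnames = list(proteins, species))
    for (i in seq_len(nProt))
      m[i, groups[[trueClass[i]]]] <- 1L
    flips <- matrix(stats::runif(length(m)) < flipNoise, nrow(m), ncol(m))
    m[flips] <- 1L - m[flips]
    list(profile = new("PhyloProfile", mat = m, groups = groups),
         truth = trueClass)
  })
}

DEFAULT_TISSUES <- c("cerebral_cortex",
                     sprintf("tissue%02d", 2:37))

#' Simulate a TPM expression table with spiked tissue-specific cells
#'
#' Baseline TPM values are i.i.d. log-normal; each spiked (protein, tissue)
#' cell is multiplied by its fold factor.
#'
#' @param nProteins number of proteins
#' @param tissues tissue names (default 37 including `cerebral_cortex`)
#' @param meanlog,sdlog log-normal baseline parameters
#' @param spikes data.frame with columns `protein` (index or name),
#'   `tissue`, `fold`; may be `NULL`
#' @param seed RNG seed
#' @return list with `table` (matrix) and `truth` (the spikes data.frame)
#' @export
simulateExpression <- function(nProteins = 200L, tissues = DEFAULT_TISSUES,
                               meanlog = 1, sdlog = 1, spikes = NULL,
                               seed = 1L) {
  proteins <- sprintf("gene%03d", seq_len(nProteins))
  .withSeed(seed, {
    m <- matrix(stats::rlnorm(nProteins * length(tissues), meanlog, sdlog),
                nProteins, length(tissues),
                dimnames = list(proteins, tissues))
    if (!is.null(spikes) && nrow(spikes)) {
      pid <- if (is.numeric(spikes$protein)) proteins[spikes$protein]
             else spikes$protein
      m[cbind(match(pid, proteins), match(spikes$tissue, tissues))] <-
        m[cbind(match(pid, proteins), match(spikes$tissue, tissues))] *
        spikes$fold
      spikes$protein <- pid
    }
    list(table = m, truth = spikes)
  })
}

#' Simulate a pathogenic-variant table with domain enrichment
#'
#' Variant positions are drawn over reference residues with sampling weight
#' `rho` inside domain intervals and 1 outside; the reference amino acid is
#' taken from the alignment's reference sequence, the alternate is a random
#' different residue, case counts are 1 + Poisson(1), and a fraction of rows
#' get a non-pathogenic label to exercise filtering.
#'
#' @param alignment a [MultipleAlignment-class]
#' @param domains data.frame (name, start, end) on reference coordinates
#' @param nVariants number of variant rows
#' @param rho domain enrichment factor (default 4)
#' @param pathogenicFraction fraction labeled `"pathogenic"` (default 0.8)
#' @param protein protein name recorded in the table
#' @param seed RNG seed
#' @return data.frame with the standard variant columns
#' @export
simulateVariants <- function(alignment, domains, nVariants = 20L, rho = 4,
                             pathogenicFraction = 0.8,
                             protein = "protein1", seed = 1L) {
  refseq <- strsplit(.ungapped(alignment, referenceId(alignment)), "")[[1L]]
  w <- rep(1, length(refseq))
  if (!is.null(domains) && nrow(domains))
    for (i in seq_len(nrow(domains)))
      w[domains$start[i]:domains$end[i]] <- rho
  .withSeed(seed, {
    pos <- sample.int(length(refseq), nVariants, replace = TRUE, prob = w)
    ref <- refseq[pos]
    alt <- vapply(ref, function(r)
      sample(setdiff(AA_ALPHABET20, r), 1L), character(1))
    data.frame(protein = protein, pos = pos, ref = ref, alt = unname(alt),
               n_cases = 1L + stats::rpois(nVariants, 1),
               label = ifelse(stats::runif(nVariants) < pathogenicFraction,
                              "pathogenic", "polymorphism"))
  })
}

#' Write a complete synthetic input bundle
#'
#' Generates every input the pipeline consumes under one seed (per-stage
#' substreams, so stages are independently reproducible) and writes them as
#' plain-text files: aligned FASTA, Newick tree, disorder and phospho track
#' TSVs, domain intervals, variant table, ortholog presence table + taxonomy
#' groups, TPM table, plus `truth.json` with the ground truth. The default
#' parameters are the package's reference study conditions: 24 taxa, 300
#' sites, gamma shape 0.5 with 16 categories, alternating 50-residue
#' ordered/disordered blocks with disordered sites evolving at 3x the
#' ordered rate, 10 planted phosphosites conserved in 70% of taxa, four
#' 15-protein profile classes with 5% flip noise, and a 200 x 37 TPM table
#' with five cortex-spiked genes.
#'
#' @param dir output directory (created if needed)
#' @param seed bundle seed
#' @param nTaxa,nSites,alpha,K alignment simulation parameters
#' @param disorderedRateMultiplier rate multiplier for disordered blocks
#' @param blockLength length of each alternating regime block
#' @param ptmConservation per-taxon positive probability f for planted sites
#' @param nPtmSites number of planted phosphosites
#' @param flipNoise profile flip noise
#' @param nVariants variant rows
#' @param rho variant domain enrichment
#' @return named list of file paths (invisibly, with `truth` attached)
#' @export
simulateBundle <- function(dir, seed = 1L, nTaxa = 24L, nSites = 300L,
                           alpha = 0.5, K = 16L,
                           disorderedRateMultiplier = 3,
                           blockLength = 50L, ptmConservation = 0.7,
                           nPtmSites = 10L, flipNoise = 0.05,
                           nVariants = 20L, rho = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- substitutionModel("jtt")
  gamma <- gammaCategories(alpha, K)
  nBlocks <- nSites %/% blockLength
  if (nBlocks * blockLength != nSites)
    stop("nSites must be a multiple of blockLength")
  blocks <- data.frame(
    length = rep(blockLength, nBlocks),
    regime = rep(c("ordered", "disordered"), length.out = nBlocks))
  mult <- rep(ifelse(blocks$regime == "disordered",
                     disorderedRateMultiplier, 1), blocks$length)
  tree <- simulateTree(nTaxa, seed = .substream(seed, 1L))
  sim <- simulateAlignment(tree, model, gamma, nSites,
                           seed = .substream(seed, 2L),
                           rateMultipliers = mult)
  dis <- simulateDisorderTracks(sim$alignment, blocks,
                                seed = .substream(seed, 3L))
  ptmPos <- seq(from = blockLength + 5L, by = nSites %/% nPtmSites,
                length.out = nPtmSites)
  ptm <- simulatePtm(sim$alignment, ptmPos, ptmConservation,
                     seed = .substream(seed, 4L))
  aln <- ptm$alignment
  domains <- data.frame(
    name = sprintf("D%d", seq_len(sum(blocks$regime == "ordered"))),
    start = (which(blocks$regime == "ordered") - 1L) * blockLength + 1L,
    end = which(blocks$regime == "ordered") * blockLength)
  variants <- simulateVariants(aln, domains, nVariants, rho,
                               seed = .substream(seed, 5L))
  prof <- simulateProfiles(flipNoise = flipNoise,
                           seed = .substream(seed, 6L))
  spikes <- data.frame(protein = 1:5, tissue = "cerebral_cortex", fold = 50)
  expr <- simulateExpression(spikes = spikes, seed = .substream(seed, 7L))
  paths <- list(
    alignment = file.path(dir, "alignment.fasta"),
    tree = file.path(dir, "tree.nwk"),
    disorder = file.path(dir, "disorder.tsv"),
    phospho = file.path(dir, "phospho.tsv"),
    domains = file.path(dir, "domains.tsv"),
    variants = file.path(dir, "variants.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.json"))
  writeAlignment(aln, paths$alignment)
  ape::write.tree(tree, file = paths$tree)
  writeTrack(dis$tracks, paths$disorder)
  writeTrack(ptm$tracks, paths$phospho)
  writeTsv(domains, paths$domains, c(format = "domains"))
  writeVariants(variants, paths$variants)
  m <- profileMatrix(prof$profile)
  long <- data.frame(protein = rep(rownames(m), ncol(m)),
                     species = rep(colnames(m), each = nrow(m)),
                     present = as.integer(m))
  writeTsv(long, paths$orthologs, c(format = "orthologs"))
  groups <- taxonomyGroups(prof$profile)
  narrowest <- rep(names(groups)[1L], length(groups[[length(groups)]]))
  sp <- groups[[length(groups)]]
  for (gi in seq_along(groups)[-1L])
    narrowest[!(sp %in% groups[[gi - 1L]]) & sp %in% groups[[gi]]] <-
      names(groups)[gi]
  writeTsv(data.frame(species = sp, group = narrowest), paths$taxonomy,
           c(format = "taxonomy"))
  writeExpressionTable(expr$table, paths$expression)
  truth <- list(seed = seed,
                referenceId = referenceId(aln),
                trueRates = sim$trueRates,
                categories = sim$categories,
                regimes = dis$regimes,
                ptm = ptm$truth,
                profileClasses = as.list(prof$truth),
                spikes = expr$truth,
                alpha = alpha, K = K,
                disorderedRateMultiplier = disorderedRateMultiplier)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  attr(paths, "truth") <- truth
  invisible(paths)
}
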