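model <- substitutionModel("jtt")

test_that("Yule trees have the requested leaves and are seed-stable", {
  tr <- simulateTree(2, seed = 1)
  expect_equal(sort(tr$tip.label), c("s01", "s02"))  # a single cherry
  expect_equal(length(simulateTree(24, seed = 5)$tip.label), 24L)
  expect_identical(ape::write.tree(simulateTree(10, seed = 3)),
                   ape::write.tree(simulateTree(10, seed = 3)))
  expect_false(identical(ape::write.tree(simulateTree(10, seed = 3)),
                         ape::write.tree(simulateTree(10, seed = 4))))
  expect_error(simulateTree(1), "at least 2")
})

test_that("simulated alignments respect rate structure and determinism", {
  tr <- simulateTree(8, seed = 2)
  g <- gammaCategories(0.5, 4)
  sim1 <- simulateAlignment(tr, model, g, 50, seed = 7)
  sim2 <- simulateAlignment(tr, model, g, 50, seed = 7)
  expect_identical(sequences(sim1$alignment), sequences(sim2$alignment))
  expect_identical(sim1$trueRates, sim2$trueRates)

  ## rate multiplier 0 freezes those columns
  mult <- rep(c(0, 1), each = 25)
  sim0 <- simulateAlignment(tr, model, g, 50, seed = 7,
                            rateMultipliers = mult)
  chars <- do.call(rbind, strsplit(sequences(sim0$alignment), ""))
  nDistinct <- apply(chars, 2, function(x) length(unique(x)))
  expect_true(all(nDistinct[1:25] == 1))

  ## fast sites accumulate more distinct residues than slow sites
  gx <- gammaCategories(0.3, 4)
  simx <- simulateAlignment(tr, model, gx, 400, seed = 8)
  charsx <- do.call(rbind, strsplit(sequences(simx$alignment), ""))
  nd <- apply(charsx, 2, function(x) length(unique(x)))
  hi <- simx$categories == 4; lo <- simx$categories == 1
  expect_gt(median(nd[hi]), median(nd[lo]))
})

test_that("simulated residue frequencies approach the stationary law", {
  tr <- simulateTree(6, seed = 4)
  sim <- simulateAlignment(tr, model, gammaCategories(1, 4), 10000,
                           seed = 10)
  obs <- observedFrequencies(sim$alignment)
  tv <- sum(abs(obs - model$pi)) / 2
  expect_lt(tv, 0.03)
})

test_that("gap masking never touches the reference or empties a row", {
  tr <- simulateTree(8, seed = 2)
  sim <- simulateAlignment(tr, model, gammaCategories(0.5, 4), 60,
                           seed = 3, gapRate = 0.2)
  seqs <- sequences(sim$alignment)
  expect_false(grepl("-", seqs[[referenceId(sim$alignment)]]))
  expect_true(all(vapply(seqs, function(s)
    nchar(gsub("-", "", s)) > 0, logical(1))))
})

test_that("disorder tracks recover their regimes through the callers", {
  tr <- simulateTree(12, seed = 6)
  g <- gammaCategories(0.5, 8)
  blocks <- data.frame(length = c(40, 40), regime = c("ordered",
                                                      "disordered"))
  recov <- numeric(5)
  for (s in 1:5) {
    sim <- simulateAlignment(tr, model, g, 80, seed = 100 + s)
    dis <- simulateDisorderTracks(sim$alignment, blocks, seed = 200 + s)
    dm <- buildDisorderMatrix(sim$alignment, dis$tracks, tr)
    cons <- consensusStructure(dm)
    recov[s] <- mean(cons == dis$regimes)
    expect_true(all(vapply(dis$tracks, function(t)
      all(scores(t) >= 0 & scores(t) <= 1), logical(1))))
  }
  expect_gte(median(recov), 0.95)
  expect_error(simulateDisorderTracks(sim$alignment,
                                      data.frame(length = 10,
                                                 regime = "ordered")),
               "sum")
})

test_that("planted phosphosites obey the conservation fraction", {
  tr <- simulateTree(10, seed = 3)
  sim <- simulateAlignment(tr, model, gammaCategories(1, 4), 30, seed = 4)
  ptm <- simulatePtm(sim$alignment, positions = c(5L, 15L), f = 1,
                     seed = 5)
  calls <- lapply(ptm$tracks, callSites, alignment = ptm$alignment)
  cons <- conservedColumns(ptm$alignment, calls)
  ## f = 1: every taxon positive at both planted sites
  expect_equal(ptm$truth$n_positive, c(10L, 10L))
  expect_true(all(cons$referenceSites$conserved[c(5, 15)]))
  ## determinism
  ptm2 <- simulatePtm(sim$alignment, positions = c(5L, 15L), f = 1,
                      seed = 5)
  expect_identical(sequences(ptm2$alignment), sequences(ptm$alignment))
})

test_that("noise-free profiles reproduce their class patterns exactly", {
  sim <- simulateProfiles(flipNoise = 0, seed = 1)
  m <- profileMatrix(sim$profile)
  g <- taxonomyGroups(sim$profile)
  for (p in rownames(m)) {
    klass <- sim$truth[[p]]
    expect_identical(unname(m[p, ]),
                     as.integer(colnames(m) %in% g[[klass]]))
  }
})

test_that("spiked expression cells are flagged reliably", {
  hits <- 0L
  for (s in 1:50) {
    sim <- simulateExpression(nProteins = 100, spikes = data.frame(
      protein = 1, tissue = "cerebral_cortex", fold = 50), seed = s)
    fl <- specificityFlags(sim$table)
    if (fl["gene001", "cerebral_cortex"]) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})

test_that("bundles are bit-reproducible and round-trip through readers", {
  d1 <- file.path(tempdir(), "bundle-a")
  d2 <- file.path(tempdir(), "bundle-b")
  unlink(c(d1, d2), recursive = TRUE)
  p1 <- simulateBundle(d1, seed = 17, nTaxa = 8L, nSites = 50L,
                       blockLength = 25L, nPtmSites = 2L, nVariants = 5L)
  p2 <- simulateBundle(d2, seed = 17, nTaxa = 8L, nSites = 50L,
                       blockLength = 25L, nPtmSites = 2L, nVariants = 5L)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  }
  aln <- readAlignment(p1$alignment, "s01")
  expect_equal(length(taxa(aln)), 8L)
  tr <- readNewickTree(p1$tree)
  expect_setequal(tr$tip.label, taxa(aln))
  tracks <- readTrack(p1$disorder, aln, "disorder")
  expect_equal(length(tracks), 8L)
  expect_s4_class(tracks[[1]], "AnnotationTrack")
  v <- readVariants(p1$variants, aln)
  expect_true(all(v$label == "pathogenic"))
})
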