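test_that("profiles are built from scores or member flags", {
  tab <- data.frame(protein = c("p1", "p1", "p2"),
                    species = c("s1", "s2", "s1"),
                    score = c(150, 149, 400))
  groups <- list(inner = "s1", all = c("s1", "s2"))
  prof <- buildProfile(tab, groups)
  m <- profileMatrix(prof)
  expect_equal(m["p1", "s1"], 1L)  # score 150 is present (>= threshold)
  expect_equal(m["p1", "s2"], 0L)  # 149 absent
  expect_equal(m["p2", "s2"], 0L)  # missing pair -> 0

  tabf <- data.frame(protein = "p1", species = "s1", present = 1)
  expect_equal(profileMatrix(buildProfile(tabf, groups))["p1", "s1"], 1L)

  dup <- data.frame(protein = c("p1", "p1"), species = c("s1", "s1"),
                    score = c(200, 10))
  expect_error(buildProfile(dup, groups), "conflicting")

  zero <- data.frame(protein = "p3", species = "s1", score = 0)
  expect_equal(attr(buildProfile(zero, groups), "allZero"), "p3")
})

test_that("Manhattan distance is the Hamming count with metric axioms", {
  expect_equal(manhattanDistance(c(1, 0, 1), c(0, 0, 1)), 1)
  expect_equal(manhattanDistance(c(1, 1), c(1, 1)), 0)
  expect_error(manhattanDistance(1, c(1, 2)), "equal length")
  set.seed(4)
  for (i in 1:20) {
    x <- stats::rbinom(8, 1, 0.5); y <- stats::rbinom(8, 1, 0.5)
    z <- stats::rbinom(8, 1, 0.5)
    expect_equal(manhattanDistance(x, y), manhattanDistance(y, x))
    expect_lte(manhattanDistance(x, z),
               manhattanDistance(x, y) + manhattanDistance(y, z))
  }
})

test_that("Ward merges the nearest pair first and keeps heights monotone", {
  X <- matrix(c(0, 1, 10), ncol = 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  cl <- wardCluster(X, k = 2)
  expect_equal(sort(cl@hclust$merge[1, ]), c(-2, -1))  # {0} with {1} first
  expect_true(all(diff(cl@hclust$height) >= -1e-12))
})

test_that("Ward merge sequence matches hclust on tie-free data", {
  set.seed(21)
  for (i in 1:10) {
    X <- matrix(stats::runif(7 * 4), 7,
                dimnames = list(sprintf("p%d", 1:7), NULL))
    cl <- wardCluster(X, k = 3)
    ref <- stats::hclust(stats::dist(X, method = "manhattan"),
                         method = "ward.D")
    expect_equal(cl@hclust$height, ref$height, tolerance = 1e-10)
    expect_identical(hclustMergeSets(cl@hclust), hclustMergeSets(ref))
  }
})

test_that("clustering is invariant to row permutation up to relabeling", {
  sim <- simulateProfiles(classSizes = rep(6L, 4L), seed = 3)
  m <- profileMatrix(sim$profile)
  cl1 <- wardCluster(m, k = 4)
  set.seed(8)
  perm <- sample(nrow(m))
  cl2 <- wardCluster(m[perm, ], k = 4)
  a1 <- clusterAssignment(cl1)
  a2 <- clusterAssignment(cl2)[names(a1)]
  expect_equal(mclust::adjustedRandIndex(a1, a2), 1)
})

test_that("class labels follow the depth rule with its fallback", {
  groups <- defaultTaxonomyGroups(c(chordates = 4L, metazoans = 10L,
                                    multicellular = 22L, eukaryotes = 46L))
  species <- groups$eukaryotes
  mkCluster <- function(p) {
    ## two identical rows with presence pattern p, plus two far-away rows
    ## so the k=2 cut isolates them
    m <- rbind(p, p, 1 - p, 1 - p)
    dimnames(m) <- list(c("x1", "x2", "y1", "y2"), species)
    m
  }
  labelOf <- function(present) {
    p <- as.integer(species %in% present)
    prof <- new("PhyloProfile", mat = mkCluster(p), groups = groups)
    cl <- assignClassLabels(wardCluster(prof, k = 2), prof)
    classLabels(cl)[clusterAssignment(cl)[["x1"]]]
  }
  ## present nearly everywhere -> eukaryote class
  expect_equal(labelOf(species), "Class4_eukaryote")
  ## present only in chordates -> chordate class
  expect_equal(labelOf(groups$chordates), "Class1_chordate")
  ## metazoan-wide presence -> metazoan class
  expect_equal(labelOf(groups$metazoans), "Class2_metazoan")
  ## weak presence everywhere -> unresolved
  set.seed(1)
  p40 <- as.integer(stats::runif(length(species)) < 0.4)
  prof <- new("PhyloProfile", mat = mkCluster(p40), groups = groups)
  cl <- assignClassLabels(wardCluster(prof, k = 2), prof)
  expect_equal(classLabels(cl)[clusterAssignment(cl)[["x1"]]],
               "unresolved")
})

test_that("class labels ignore duplication of a species within its group", {
  sim <- simulateProfiles(classSizes = rep(8L, 4L), seed = 12,
                          flipNoise = 0)
  prof <- sim$profile
  cl <- assignClassLabels(wardCluster(prof, k = 4), prof)
  ## duplicate one chordate species column
  m <- profileMatrix(prof)
  g <- taxonomyGroups(prof)
  dupSp <- g$chordates[1]
  m2 <- cbind(m, dup = m[, dupSp])
  colnames(m2)[ncol(m2)] <- "sp_dup"
  g2 <- lapply(g, function(s) c(s, "sp_dup"))
  prof2 <- new("PhyloProfile", mat = m2, groups = g2)
  cl2 <- assignClassLabels(wardCluster(prof2, k = 4), prof2)
  lab1 <- classLabels(cl)[clusterAssignment(cl)]
  lab2 <- classLabels(cl2)[clusterAssignment(cl2)]
  expect_identical(lab1, lab2)
})

test_that("dendrograms export as Newick with all proteins as tips", {
  sim <- simulateProfiles(classSizes = rep(5L, 4L), seed = 2)
  cl <- wardCluster(sim$profile, k = 4)
  path <- tempfile(fileext = ".nwk")
  writeDendrogram(cl, path)
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, rownames(profileMatrix(sim$profile)))
  expect_error(wardCluster(profileMatrix(sim$profile)[1:3, ], k = 4),
               "cannot cut")
})
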