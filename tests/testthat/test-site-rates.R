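model <- substitutionModel("jtt")

test_that("zero-rate likelihood is exactly pi_a for constant columns", {
  tr <- balancedTree(c("a", "b", "c", "d"))
  for (res in c("A", "W", "S")) {
    aln <- multipleAlignment(stats::setNames(rep(res, 4),
                                             c("a", "b", "c", "d")), "a")
    expect_identical(columnLikelihood(aln, tr, model, 0, 1),
                     model$pi[match(res, strsplit("ARNDCQEGHILKMFPSTWYV",
                                                  "")[[1]])])
  }
  aln2 <- multipleAlignment(c(a = "A", b = "R", c = "A", d = "A"), "a")
  expect_identical(columnLikelihood(aln2, tr, model, 0, 1), 0)
})

test_that("pruning equals ancestral-state enumeration, including gaps and X", {
  set.seed(101)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in 1:6) {
    tr <- ape::rtree(4)
    tr$tip.label <- c("a", "b", "c", "d")
    chars <- sample(aa, 4, replace = TRUE)
    if (i == 5) chars[2] <- "-"   # gap leaf: free state in the oracle
    if (i == 6) chars[3] <- "X"   # unknown residue, same treatment
    ## pad with a second all-A column so gapped rows stay valid
    aln <- multipleAlignment(stats::setNames(paste0(chars, "A"),
                                             tr$tip.label), "a")
    rate <- stats::runif(1, 0.1, 2.5)
    got <- columnLikelihood(aln, tr, model, rate, 1)
    want <- enumColumnLikelihood(tr, aaCodes(chars), model, rate)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to re-rooting (reversibility)", {
  set.seed(7)
  tr <- ape::rtree(6)
  tr$tip.label <- sprintf("t%d", 1:6)
  chars <- sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 6,
                  replace = TRUE)
  aln <- multipleAlignment(stats::setNames(chars, tr$tip.label), "t1")
  base <- columnLikelihood(aln, tr, model, 0.8, 1)
  for (og in c("t3", "t5")) {
    rerooted <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(columnLikelihood(aln, rerooted, model, 0.8, 1), base,
                 tolerance = 1e-8)
  }
})

test_that("posterior mean rates follow the empirical Bayes formula", {
  set.seed(11)
  tr <- ape::rtree(4)
  tr$tip.label <- c("a", "b", "c", "d")
  chars <- c("A", "R", "A", "N")
  aln <- multipleAlignment(stats::setNames(chars, tr$tip.label), "a")
  g <- gammaCategories(0.7, 8)
  res <- posteriorMeanRates(aln, tr, model, g)
  ## oracle: enumeration likelihood per category, then the posterior mean
  lk <- vapply(g$rates, function(r)
    enumColumnLikelihood(tr, aaCodes(chars), model, r), numeric(1))
  expect_equal(siteRates(res)[1], sum(g$rates * lk) / sum(lk),
               tolerance = 1e-10)
})

test_that("no-data columns fall back to the prior and carry no Z", {
  tr <- balancedTree(c("a", "b", "c", "d"))
  aln <- multipleAlignment(
    c(a = "A-R", b = "A-R", c = "R-A", d = "A-A"), "a")
  g <- gammaCategories(0.5, 16)
  res <- posteriorMeanRates(aln, tr, model, g)
  expect_identical(noDataColumns(res), c(FALSE, TRUE, FALSE))
  expect_equal(siteRates(res)[2], mean(g$rates), tolerance = 1e-12)
  expect_true(is.na(zScores(res)[2]))
  expect_false(anyNA(zScores(res)[c(1, 3)]))
})

test_that("variable columns get higher posterior rates than invariant ones", {
  labels <- sprintf("t%02d", 1:8)
  tr <- balancedTree(labels)
  rows <- stats::setNames(paste0("A", c("R", "N", "D", "C", "Q", "E", "G",
                                        "H")), labels)
  aln <- multipleAlignment(rows, "t01")  # col 1 invariant, col 2 saturated
  res <- posteriorMeanRates(aln, tr, model, gammaCategories(0.5, 16))
  expect_lt(siteRates(res)[1], siteRates(res)[2])
  expect_lt(zScores(res)[1], 0)
  expect_gt(zScores(res)[2], 0)
})

test_that("Z standardization has the closed form and contract", {
  expect_equal(standardizeZ(c(1, 2, 3)),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_error(standardizeZ(c(2, 2, 2)), "zero spread")
  expect_error(standardizeZ(3), "at least 2")
  set.seed(3)
  for (i in 1:5) {
    z <- standardizeZ(stats::rlnorm(50))
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-9)
  }
})

test_that("rates project onto reference coordinates by dropping ref gaps", {
  aln <- multipleAlignment(c(r = "M-K", o = "MAK"), "r")
  map <- buildColumnMap(aln)
  res <- new("SiteRateResult", rate = c(0.5, 1.2, 2.0),
             z = c(-1, 0.1, 1), noData = rep(FALSE, 3),
             alpha = 1, nCategories = 4L, logLik = -10)
  proj <- projectRates(res, map)
  expect_equal(proj$pos, 1:2)
  expect_equal(proj$rate, c(0.5, 2.0))
  expect_equal(proj$z, c(-1, 1))
  ## dropped columns are exactly the reference-gap columns
  expect_equal(nrow(proj), nchar(gsub("-", "", "M-K")))
})

test_that("alpha estimation is pinned to the boundary without rate signal", {
  tr <- balancedTree(c("a", "b", "c", "d"))
  aln <- multipleAlignment(stats::setNames(rep("A", 4),
                                           c("a", "b", "c", "d")), "a")
  expect_warning(est <- estimateAlpha(aln, tr, model, K = 8), "boundary")
  expect_equal(est$alpha, 0.02)
  ## optimizer contract: returned value beats both endpoints
  f <- function(a) {
    g <- gammaCategories(a, 8)
    lk <- vapply(g$rates, function(r) columnLikelihood(aln, tr, model, r, 1),
                 numeric(1))
    log(mean(lk))
  }
  expect_gte(est$logLik, f(0.02) - 1e-9)
  expect_gte(est$logLik, f(20) - 1e-9)
})
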