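## Empirical-Bayes per-site evolutionary rates on a fixed tree: Felsenstein
## pruning under a reversible amino-acid model with a discrete-gamma prior
## over rate multipliers, posterior-mean rates, Z standardization, and
## projection onto reference coordinates.

## integer codes 1..20 (AA_ALPHABET20 order); NA for gap or X (missing data)
.encodeAlignment <- function(alignment) {
  m <- do.call(rbind, strsplit(sequences(alignment), ""))
  codes <- match(m, AA_ALPHABET20)
  dim(codes) <- dim(m)
  rownames(codes) <- taxa(alignment)
  codes
}

.checkTreeAlignment <- function(tree, alignment) {
  if (!setequal(tree$tip.label, taxa(alignment)))
    stop("tree leaves and alignment taxa must coincide")
}

## Felsenstein pruning at a single rate multiplier, vectorized over columns.
## Gap/X leaves contribute all-ones partial vectors ("missing data");
## per-node column rescaling keeps partials away from underflow. Returns the
## root-combined likelihood and the accumulated log scale separately so the
## unscaled case stays exact in linear space.
.columnPruning <- function(codes, tree, model, rate) {
  if (rate < 0) stop("rate must be non-negative")
  ntip <- length(tree$tip.label)
  L <- ncol(codes)
  tree <- ape::reorder.phylo(tree, "postorder")
  edge <- tree$edge
  elen <- tree$edge.length
  nnode <- ntip + tree$Nnode
  partials <- vector("list", nnode)
  logscale <- rep(0, L)
  tipIndex <- match(tree$tip.label, rownames(codes))
  for (i in seq_len(ntip)) {
    p <- matrix(0, 20L, L)
    cd <- codes[tipIndex[i], ]
    miss <- is.na(cd)
    if (any(!miss)) p[cbind(cd[!miss], which(!miss))] <- 1
    if (any(miss)) p[, miss] <- 1
    partials[[i]] <- p
  }
  parents <- unique(edge[, 1L])  # postorder: children resolved before parents
  for (node in parents) {
    rows <- which(edge[, 1L] == node)
    acc <- matrix(1, 20L, L)
    for (r in rows) {
      child <- edge[r, 2L]
      P <- transitionProbabilities(model, elen[r] * rate)
      acc <- acc * (P %*% partials[[child]])
    }
    mx <- apply(acc, 2L, max)
    pos <- mx > 0
    if (any(pos)) acc[, pos] <- acc[, pos, drop = FALSE] /
        rep(mx[pos], each = 20L)
    logscale <- logscale + ifelse(pos, log(mx), -Inf)
    partials[[node]] <- acc
  }
  root <- parents[length(parents)]
  list(root = colSums(model$pi * partials[[root]]), logscale = logscale)
}

.columnLogLik <- function(codes, tree, model, rate) {
  pr <- .columnPruning(codes, tree, model, rate)
  log(pr$root) + pr$logscale
}

#' Likelihood of one alignment column at a fixed rate
#'
#' Felsenstein pruning over the tree with transition probabilities
#' `P(t * rate) = exp(Q t rate)`; gap and `X` leaves contribute all-ones
#' partial likelihood vectors (missing data) and the root is combined with
#' the stationary frequencies.
#'
#' @param alignment a [MultipleAlignment-class]
#' @param tree ape `phylo` whose leaves match the alignment taxa
#' @param model from [substitutionModel()]
#' @param rate non-negative rate multiplier
#' @param column alignment column index
#' @return the column likelihood (a probability in `(0, 1]`, or 0 when the
#'   column is impossible at the given rate)
#' @export
columnLikelihood <- function(alignment, tree, model, rate, column) {
  .checkTreeAlignment(tree, alignment)
  codes <- .encodeAlignment(alignment)[, column, drop = FALSE]
  pr <- .columnPruning(codes, tree, model, rate)
  unname(pr$root * exp(pr$logscale))
}

## K x L matrix of per-category column log-likelihoods
.categoryLogLik <- function(codes, tree, model, gamma) {
  L <- ncol(codes)
  ll <- vapply(gamma$rates,
               function(r) .columnLogLik(codes, tree, model, r),
               numeric(L))
  ## vapply drops to a length-K vector when L == 1
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1L)
  t(ll)
}

## marginal log-likelihood per column: log mean_k L_c(r_k)
.marginalLogLik <- function(ll) {
  mx <- apply(ll, 2L, max)
  mx + log(colMeans(exp(sweep(ll, 2L, mx))))
}

#' Estimate the gamma shape parameter by maximum marginal likelihood
#'
#' Maximizes the discrete-gamma marginal log-likelihood
#' `sum_c log[(1/K) sum_k L_c(r_k)]` over a bracketed scalar search for the
#' shape `alpha` in `[0.02, 20]`. Deterministic given its inputs. If the
#' optimum lies at a bracket endpoint the endpoint is returned with a
#' warning (typical for alignments with no rate signal, e.g. a single
#' invariant column).
#'
#' @inheritParams columnLikelihood
#' @param K number of discrete gamma categories (default 16)
#' @param interval search bracket for alpha
#' @return list with `alpha` and `logLik`
#' @export
estimateAlpha <- function(alignment, tree, model, K = 16L,
                          interval = c(0.02, 20)) {
  .checkTreeAlignment(tree, alignment)
  codes <- .encodeAlignment(alignment)
  if (all(is.na(codes)))
    stop("cannot estimate alpha: every column is gap/X only")
  f <- function(a)
    sum(.marginalLogLik(.categoryLogLik(codes, tree, model,
                                        gammaCategories(a, K))))
  opt <- stats::optimize(f, interval = interval, maximum = TRUE,
                         tol = 1e-4)
  cand <- c(opt$maximum, interval)
  vals <- c(opt$objective, f(interval[1L]), f(interval[2L]))
  best <- which.max(vals)
  if (best != 1L)
    warning(sprintf(
      "alpha pinned to search boundary %.3g (no interior optimum)",
      cand[best]))
  list(alpha = cand[best], logLik = vals[best])
}

#' Empirical-Bayes posterior-mean site rates
#'
#' For each alignment column computes the posterior mean of the rate
#' multiplier under the discrete-gamma prior,
#' `rhat_c = sum_k r_k L_c(r_k) / sum_k L_c(r_k)` (uniform prior weights).
#' Columns in which every taxon is gap/`X` carry no signal: they are flagged
#' `noData`, assigned the prior mean rate, and excluded from Z
#' standardization.
#'
#' @inheritParams columnLikelihood
#' @param gamma categories from [gammaCategories()]
#' @return a [SiteRateResult-class]
#' @export
posteriorMeanRates <- function(alignment, tree, model, gamma) {
  .checkTreeAlignment(tree, alignment)
  codes <- .encodeAlignment(alignment)
  noData <- apply(codes, 2L, function(x) all(is.na(x)))
  ll <- .categoryLogLik(codes, tree, model, gamma)
  mx <- apply(ll, 2L, max)
  w <- exp(sweep(ll, 2L, mx))           # K x L, unnormalized posterior
  rhat <- colSums(gamma$rates * w) / colSums(w)
  if (anyNA(rhat)) stop("internal error: NaN posterior mean rate")
  rhat[noData] <- mean(gamma$rates)
  z <- rep(NA_real_, length(rhat))
  if (sum(!noData) >= 2L && stats::sd(rhat[!noData]) > 0)
    z[!noData] <- standardizeZ(rhat[!noData])
  new("SiteRateResult", rate = rhat, z = z, noData = noData,
      alpha = gamma$alpha, nCategories = as.integer(gamma$K),
      logLik = sum(.marginalLogLik(ll)))
}

#' Standardize rates as Z scores
#'
#' `Z = (r - mean) / SD` with the population (divisor n) standard deviation,
#' over the supplied values. Values greater/less than zero mark faster/slower
#' than average evolution.
#'
#' @param rates numeric vector (non-flagged columns only)
#' @return numeric vector with mean 0 and population SD 1
#' @export
standardizeZ <- function(rates) {
  if (length(rates) < 2L)
    stop("need at least 2 values to standardize")
  m <- mean(rates)
  s <- sqrt(mean((rates - m)^2))
  if (s == 0) stop("cannot standardize: zero spread")
  (rates - m) / s
}

#' Project per-column rates onto reference residues
#'
#' Drops alignment columns where the reference is gapped and reports one row
#' per reference residue.
#'
#' @param result a [SiteRateResult-class]
#' @param map a [ColumnMap-class] for the same alignment
#' @return data.frame with columns `pos`, `rate`, `z`, `no_data`
#' @export
projectRates <- function(result, map) {
  cols <- map@residueToColumn
  data.frame(pos = seq_along(cols),
             rate = siteRates(result)[cols],
             z = zScores(result)[cols],
             no_data = noDataColumns(result)[cols])
}
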