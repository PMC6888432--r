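## Independent oracles used by the tests. These re-derive quantities by
## brute force or closed form and must stay independent of the package
## implementation paths they check.

## Column likelihood by explicit summation over all ancestral-state
## assignments (and over the states of gap/X tips, which are free).
enumColumnLikelihood <- function(tree, tipCodes, model, rate) {
  ntip <- length(tree$tip.label)
  interior <- ntip + seq_len(tree$Nnode)
  freeTips <- which(is.na(tipCodes))
  free <- c(interior, freeTips)
  grid <- as.matrix(expand.grid(rep(list(1:20), length(free))))
  stateOf <- function(n) {
    k <- match(n, free)
    if (!is.na(k)) grid[, k] else rep.int(tipCodes[[n]], nrow(grid))
  }
  p <- model$pi[stateOf(ntip + 1L)]  # root prior
  for (e in seq_len(nrow(tree$edge))) {
    P <- transitionProbabilities(model, tree$edge.length[e] * rate)
    p <- p * P[cbind(stateOf(tree$edge[e, 1L]), stateOf(tree$edge[e, 2L]))]
  }
  sum(p)
}

aaCodes <- function(chars) {
  codes <- match(chars, strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  codes
}

## Greedy Ward agglomeration recomputing every inter-cluster distance from
## the raw pairwise matrix at each step via the generalized Ward form
##   D(A,B) = nA nB / (nA + nB) * (2 mean(d[A,B]) - mean(d[A,A]) - mean(d[B,B]))
## (mean over all ordered pairs, diagonal included). Ties broken by the
## lexicographically smallest pair of smallest original member indices.
bruteForceWard <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  wardD <- function(A, B) {
    nA <- length(A); nB <- length(B)
    (nA * nB / (nA + nB)) *
      (2 * mean(d[A, B, drop = FALSE]) - sum(d[A, A]) / nA^2 -
         sum(d[B, B]) / nB^2)
  }
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; bestD <- Inf; bestKey <- c(Inf, Inf)
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in (i + 1):length(clusters)) {
        dd <- wardD(clusters[[i]], clusters[[j]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (dd < bestD - 1e-9 * max(1, abs(bestD)) ||
            (abs(dd - bestD) <= 1e-9 * max(1, abs(bestD)) &&
             (key[1] < bestKey[1] ||
              (key[1] == bestKey[1] && key[2] < bestKey[2])))) {
          best <- c(i, j); bestD <- dd; bestKey <- key
        }
      }
    merges[[length(merges) + 1L]] <-
      list(members = sort(c(clusters[[best[1]]], clusters[[best[2]]])),
           height = bestD)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}

## members of each merge step of an hclust object, as sorted index sets
hclustMergeSets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    grab <- function(x) if (x < 0) -x else sets[[x]]
    sets[[k]] <- sort(c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2])))
  }
  sets
}

## U statistic by direct pair counting (ties count one half)
pairCountU <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}
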