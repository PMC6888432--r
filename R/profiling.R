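## Phylogenetic profiling: binary presence/absence profiles, Manhattan
## distance, Ward agglomeration (Lance-Williams on the provided
## dissimilarities, deterministic tie-breaking), k=4 cut, and class labeling
## by taxonomic conservation depth.

#' Build a phylogenetic profile matrix
#'
#' From a long table of `(protein, species, score)` or
#' `(protein, species, present)` rows: presence is the member flag when
#' given, otherwise `score >= scoreThreshold` (default 150, the
#' Smith-Waterman similarity threshold used for ortholog cluster
#' membership). Pairs absent from the table are 0. All-zero profile rows are
#' allowed but reported via the `"allZero"` attribute.
#'
#' @param table data.frame with columns `protein`, `species`, and either
#'   `present` (0/1) or `score`
#' @param groups named list of nested species sets, narrowest first (see
#'   [PhyloProfile-class]); species absent from the table but present in the
#'   broadest group get 0 columns
#' @param scoreThreshold presence threshold on `score` (default 150)
#' @return a [PhyloProfile-class]
#' @export
buildProfile <- function(table, groups, scoreThreshold = 150) {
  if (!all(c("protein", "species") %in% names(table)))
    stop("table must have columns protein and species")
  if ("present" %in% names(table)) {
    pres <- as.integer(table$present != 0)
  } else if ("score" %in% names(table)) {
    pres <- as.integer(table$score >= scoreThreshold)
  } else stop("table must have a 'present' or 'score' column")
  key <- paste(table$protein, table$species, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    conflict <- vapply(dup, function(k)
      length(unique(pres[key == k])) > 1, logical(1))
    if (any(conflict))
      stop("conflicting duplicate (protein, species) entries")
    keep <- !duplicated(key)
    table <- table[keep, , drop = FALSE]
    pres <- pres[keep]
  }
  proteins <- unique(table$protein)
  species <- union(unique(table$species),
                   if (length(groups)) groups[[length(groups)]] else NULL)
  m <- matrix(0L, nrow = length(proteins), ncol = length(species),
              dimnames = list(proteins, species))
  m[cbind(match(table$protein, proteins),
          match(table$species, species))] <- pres
  pp <- new("PhyloProfile", mat = m, groups = groups)
  attr(pp, "allZero") <- rownames(m)[rowSums(m) == 0]
  pp
}

#' Manhattan distance between two profile rows
#'
#' `sum(|a_i - b_i|)`; on binary vectors this is the Hamming count.
#'
#' @param a,b equal-length numeric vectors
#' @return the distance
#' @export
manhattanDistance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  sum(abs(a - b))
}

## hclust $order: left-to-right leaf order of the merge tree
.mergeOrder <- function(merge) {
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1L]), expand(merge[k, 2L]))
  }
  expand(nrow(merge))
}

## Ward agglomeration via the Lance-Williams update
##   d(k, i+j) = ((n_i+n_k) d_ki + (n_j+n_k) d_kj - n_k d_ij) / (n_i+n_j+n_k)
## applied to the dissimilarities as provided ("ward" variant; the
## "ward.squared" variant applies it to squared dissimilarities and reports
## square-root heights, the Ward.D2 convention). Ties are broken by the
## lexicographically smallest pair of smallest-original-member indices.
.wardAgglomerate <- function(D0, variant = c("ward", "ward.squared")) {
  variant <- match.arg(variant)
  n <- nrow(D0)
  D <- if (variant == "ward.squared") D0^2 else D0
  active <- seq_len(n)          # cluster id: -row for singleton, +merge row
  rep_ <- seq_len(n)            # smallest original member per active cluster
  size <- rep(1L, n)
  id <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  diag(D) <- Inf
  for (step in seq_len(n - 1L)) {
    dmin <- min(D)
    eps <- 1e-9 * max(1, abs(dmin))
    cand <- which(D <= dmin + eps, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    reps <- cbind(pmin(rep_[cand[, 1L]], rep_[cand[, 2L]]),
                  pmax(rep_[cand[, 1L]], rep_[cand[, 2L]]))
    pick <- order(reps[, 1L], reps[, 2L])[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- if (variant == "ward.squared") sqrt(D[i, j]) else D[i, j]
    ni <- size[i]; nj <- size[j]
    others <- setdiff(seq_along(id), c(i, j))
    newd <- ((ni + size[others]) * D[i, others] +
             (nj + size[others]) * D[j, others] -
             size[others] * D[i, j]) / (ni + nj + size[others])
    ## merged cluster replaces slot i; drop slot j
    D[i, others] <- newd; D[others, i] <- newd
    D[i, i] <- Inf
    keep <- setdiff(seq_along(id), j)
    D <- D[keep, keep, drop = FALSE]
    size[i] <- ni + nj
    rep_[i] <- min(rep_[i], rep_[j])
    id[i] <- step
    size <- size[keep]; rep_ <- rep_[keep]; id <- id[keep]
  }
  list(merge = merge, height = height)
}

#' Ward clustering of phylogenetic profiles
#'
#' Agglomerative clustering of the profile rows on their Manhattan distance
#' matrix using Ward's method (Lance-Williams update on the provided
#' dissimilarities; `variant = "ward.squared"` switches to the squared-update
#' convention). Tie-breaking is deterministic (lowest pair of original row
#' indices). The merge tree is returned as a standard `hclust` object and cut
#' into `k` flat clusters, numbered in order of first appearance along the
#' row order.
#'
#' @param profile a [PhyloProfile-class] (or a numeric matrix)
#' @param k number of flat clusters (default 4)
#' @param variant `"ward"` (default) or `"ward.squared"`
#' @return a [ProfileClusters-class] with unlabeled clusters (labels
#'   `"cluster1"`..`"clusterk"`; see [assignClassLabels()])
#' @export
wardCluster <- function(profile, k = 4L, variant = c("ward", "ward.squared")) {
  variant <- match.arg(variant)
  m <- if (is(profile, "PhyloProfile")) profileMatrix(profile) else profile
  n <- nrow(m)
  if (k > n) stop("cannot cut ", n, " rows into ", k, " clusters")
  D <- as.matrix(stats::dist(m, method = "manhattan"))
  agg <- .wardAgglomerate(D, variant)
  hc <- structure(list(merge = agg$merge, height = agg$height,
                       order = .mergeOrder(agg$merge),
                       labels = rownames(m),
                       method = if (variant == "ward") "ward.D" else "ward.D2",
                       call = match.call(), dist.method = "manhattan"),
                  class = "hclust")
  raw <- stats::cutree(hc, k = k)
  ## renumber clusters by first appearance so ids are reproducible
  lev <- unique(raw)
  assignment <- match(raw, lev)
  names(assignment) <- rownames(m)
  new("ProfileClusters", hclust = hc,
      assignment = as.integer(assignment) |> stats::setNames(rownames(m)),
      classLabels = paste0("cluster", seq_len(k)), k = as.integer(k))
}

#' Label clusters by taxonomic conservation depth
#'
#' For each cluster, mean presence is computed inside every nested taxonomy
#' group and in its complement; the cluster is labeled with the broadest
#' group whose inside-presence is at least `insideMin` and whose
#' outside-presence is below `outsideMax`, or `"unresolved"` when none
#' qualifies. With the canonical four nested groups this yields the
#' Class 1 (chordate) .. Class 4 (eukaryote) naming.
#'
#' @param clusters a [ProfileClusters-class]
#' @param profile the clustered [PhyloProfile-class]
#' @param insideMin minimum mean presence inside the group (default 0.5)
#' @param outsideMax maximum mean presence outside it (default 0.25)
#' @return the [ProfileClusters-class] with `classLabels` filled in
#' @export
assignClassLabels <- function(clusters, profile, insideMin = 0.5,
                              outsideMax = 0.25) {
  groups <- taxonomyGroups(profile)
  if (!length(groups)) stop("profile has no taxonomy groups")
  m <- profileMatrix(profile)
  defaults <- c(chordates = "Class1_chordate", metazoans = "Class2_metazoan",
                multicellular = "Class3_multicellular",
                eukaryotes = "Class4_eukaryote")
  asgn <- clusterAssignment(clusters)
  labels <- character(clusters@k)
  for (cl in seq_len(clusters@k)) {
    rows <- names(asgn)[asgn == cl]
    sub <- m[rows, , drop = FALSE]
    lab <- "unresolved"
    for (gi in rev(seq_along(groups))) {  # broadest first
      g <- groups[[gi]]
      inside <- mean(sub[, g, drop = FALSE])
      comp <- setdiff(colnames(m), g)
      outside <- if (length(comp)) mean(sub[, comp, drop = FALSE]) else 0
      if (inside >= insideMin && outside < outsideMax) {
        gname <- names(groups)[gi]
        lab <- if (gname %in% names(defaults)) defaults[[gname]] else gname
        break
      }
    }
    labels[cl] <- lab
  }
  new("ProfileClusters", hclust = clusters@hclust,
      assignment = asgn, classLabels = labels, k = clusters@k)
}

#' Read a taxonomy group file
#'
#' TSV `species<TAB>group` assigning each species its narrowest group;
#' nested sets are built following `hierarchy` (narrowest first): group i
#' contains all species assigned to groups 1..i.
#'
#' @param path TSV path
#' @param hierarchy group names, narrowest first
#' @return named list of species vectors, narrowest first
#' @export
readTaxonomyGroups <- function(path,
                               hierarchy = c("chordates", "metazoans",
                                             "multicellular", "eukaryotes")) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("species", "group") %in% names(df)))
    stop("taxonomy file must have columns species, group")
  if (!all(df$group %in% hierarchy))
    stop("unknown group name(s): ",
         paste(setdiff(df$group, hierarchy), collapse = ", "))
  lev <- match(df$group, hierarchy)
  stats::setNames(lapply(seq_along(hierarchy),
                         function(i) df$species[lev <= i]),
                  hierarchy)
}

#' Export a cluster dendrogram as Newick
#'
#' @param clusters a [ProfileClusters-class]
#' @param path output path
#' @export
writeDendrogram <- function(clusters, path) {
  phy <- ape::as.phylo(clusters@hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
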