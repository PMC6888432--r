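## Pathogenic-variant context: join each missense variant to its residue's
## domain, structure/evolution category and distance to the nearest
## conserved phosphosite, and summarize the distribution.

#' Annotate variants with structural and evolutionary context
#'
#' Each variant (on reference coordinates) is joined to the domain interval
#' containing it (if any), the residue's structure/evolution category and Z
#' score, and the distance (absolute residue difference, 0 = overlap) to the
#' nearest conserved phosphosite. Variants whose position lacks a
#' classification row are flagged.
#'
#' @param variants data.frame from [readVariants()]
#' @param domains data.frame with columns name, start, end (1-based
#'   inclusive); may have zero rows
#' @param classification data.frame from [classifyResidues()]
#' @param ptmPositions integer vector of conserved phosphosite positions
#' @return data.frame: variant columns plus `in_domain`, `structure`,
#'   `category`, `z`, `dist_nearest_ptm`, `flagged`
#' @export
annotateVariants <- function(variants, domains, classification,
                             ptmPositions = integer()) {
  n <- nrow(variants)
  inDomain <- rep(NA_character_, n)
  if (!is.null(domains) && nrow(domains)) {
    for (i in seq_len(nrow(domains))) {
      hit <- variants$pos >= domains$start[i] & variants$pos <= domains$end[i]
      inDomain[hit & is.na(inDomain)] <- domains$name[i]
    }
  }
  idx <- match(variants$pos, classification$pos)
  flagged <- is.na(idx) |
    classification$category[ifelse(is.na(idx), 1L, idx)] == "no_data"
  distPtm <- if (length(ptmPositions))
    vapply(variants$pos, function(p) min(abs(p - ptmPositions)), numeric(1))
  else rep(NA_real_, n)
  data.frame(variants,
             in_domain = inDomain,
             structure = classification$structure[idx],
             evolution = classification$evolution[idx],
             category = classification$category[idx],
             z = classification$z[idx],
             dist_nearest_ptm = distPtm,
             flagged = flagged)
}

#' Summarize the variant distribution over context classes
#'
#' Contingency counts over (in domain vs not) x (ordered vs disordered) x
#' (slow vs fast), both site-weighted (each variant row counts once) and
#' case-weighted (rows count `n_cases` times). Rows with missing context are
#' tallied separately so totals are conserved.
#'
#' @param contexts data.frame from [annotateVariants()]
#' @return list with `siteCounts` and `caseCounts` (3-way tables),
#'   `unclassified` (site and case counts), and totals
#' @export
summarizeDistribution <- function(contexts) {
  if (nrow(contexts) == 0L) stop("need at least one variant context")
  domain <- factor(ifelse(is.na(contexts$in_domain), "non_domain", "domain"),
                   levels = c("domain", "non_domain"))
  structure <- factor(contexts$structure,
                      levels = c("ordered", "disordered"))
  evolution <- factor(contexts$evolution, levels = c("slow", "fast"))
  ok <- !is.na(structure) & !is.na(evolution)
  siteCounts <- table(domain = domain[ok], structure = structure[ok],
                      evolution = evolution[ok])
  caseCounts <- stats::xtabs(n_cases ~ domain + structure + evolution,
    data = data.frame(domain = domain, structure = structure,
                      evolution = evolution,
                      n_cases = contexts$n_cases)[ok, , drop = FALSE])
  ## make case table dense on the full factor grid
  full <- array(0, dim = c(2, 2, 2),
                dimnames = list(domain = levels(domain),
                                structure = levels(structure),
                                evolution = levels(evolution)))
  full[dimnames(caseCounts)$domain, dimnames(caseCounts)$structure,
       dimnames(caseCounts)$evolution] <- caseCounts
  list(siteCounts = siteCounts,
       caseCounts = as.table(full),
       unclassified = c(sites = sum(!ok),
                        cases = sum(contexts$n_cases[!ok])),
       totalSites = nrow(contexts),
       totalCases = sum(contexts$n_cases))
}
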