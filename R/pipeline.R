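## Pipeline orchestration: run every stage from a single config, write all
## result tables, and emit a consolidated summary JSON. Outputs are a pure
## function of (inputs, config); every file is stamped with the config hash.

.defaultConfig <- function() {
  list(
    referenceId = NULL,
    outDir = NULL,
    model = "jtt",            # or "jtt+f"
    K = 16L,
    alpha = "auto",           # or a positive number
    disorderCutoff = 0.5,
    consensusMajority = 0.5,
    disorderMode = "reference_only",  # or "consensus" for residue calls
    ptmCutoff = 0.75,
    ptmMajority = 0.5,
    ptmDenominator = "all",
    allowedLabels = "pathogenic",
    k = 4L,
    wardVariant = "ward",
    insideMin = 0.5,
    outsideMax = 0.25,
    specificityFactor = 1.65)
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  config$outDir <- NULL  # output location does not affect results
  ord <- config[order(names(config))]
  jsonlite::write_json(ord, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages in dependency order from a single configuration:
#' site rates (empirical Bayes, JTT + discrete gamma, Z scores), disorder
#' matrix + residue classification, conserved phosphosites, variant context,
#' phylogenetic profile clustering with class labels, and tissue-specificity
#' calls. Writes one TSV per result, a Newick dendrogram, and
#' `summary.json` (group medians, Mann-Whitney result, class sizes,
#' specificity counts), all stamped with the config hash. Any stage failure
#' aborts with a stage-named error.
#'
#' @param config a named list or the path of a YAML file. Required entries:
#'   `alignment`, `tree`, `disorder`, `phospho`, `domains`, `variants`,
#'   `orthologs`, `taxonomy`, `expression` (input paths), `referenceId`,
#'   and `outDir`. Optional entries override the defaults: `model`
#'   (`"jtt"`/`"jtt+f"`), `K`, `alpha` (`"auto"` or a number),
#'   `disorderCutoff`, `consensusMajority`, `disorderMode`
#'   (`"reference_only"`/`"consensus"`), `ptmCutoff`, `ptmMajority`,
#'   `ptmDenominator`, `allowedLabels`, `k`, `wardVariant`, `insideMin`,
#'   `outsideMax`, `specificityFactor`.
#' @return invisibly, a list with the summary and the output file paths
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.defaultConfig(), config)
  need <- c("alignment", "tree", "disorder", "phospho", "domains",
            "variants", "orthologs", "taxonomy", "expression")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("config is missing input path(s): ", paste(missing, collapse = ", "))
  for (p in need) if (!file.exists(cfg[[p]]))
    stop("input file for '", p, "' not found: ", cfg[[p]])
  if (is.null(cfg$referenceId) || is.null(cfg$outDir))
    stop("config must set referenceId and outDir")
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(cfg[order(names(cfg))])
  stamp <- c(config_hash = hash)
  outs <- list()

  ## --- site rates -------------------------------------------------------
  rates <- .stage("site_rates", {
    aln <- readAlignment(cfg$alignment, cfg$referenceId)
    tree <- readNewickTree(cfg$tree)
    model <- substitutionModel(cfg$model, alignment = aln)
    alpha <- if (identical(cfg$alpha, "auto"))
      estimateAlpha(aln, tree, model, K = cfg$K)$alpha
    else as.numeric(cfg$alpha)
    gamma <- gammaCategories(alpha, cfg$K)
    res <- posteriorMeanRates(aln, tree, model, gamma)
    map <- buildColumnMap(aln)
    proj <- projectRates(res, map)
    outs$rates <- file.path(cfg$outDir, "site_rates.tsv")
    writeTsv(proj, outs$rates,
             c(stamp, model = cfg$model, K = cfg$K,
               alpha = sprintf("%.6g", alpha)))
    list(aln = aln, tree = tree, result = res, map = map, proj = proj,
         alpha = alpha)
  })

  ## --- disorder ---------------------------------------------------------
  disorder <- .stage("structure_disorder", {
    tracks <- readTrack(cfg$disorder, rates$aln, kind = "disorder")
    if (is(tracks, "AnnotationTrack"))
      tracks <- stats::setNames(list(tracks), tracks@sequenceId)
    dm <- buildDisorderMatrix(rates$aln, tracks, rates$tree)
    outs$disorderMatrix <- file.path(cfg$outDir, "disorder_matrix.tsv")
    writeDisorderMatrix(dm, outs$disorderMatrix)
    refId <- referenceId(rates$aln)
    structure <- if (identical(cfg$disorderMode, "consensus")) {
      consensusStructure(dm, cutoff = cfg$disorderCutoff,
                         majority = cfg$consensusMajority)[
        rates$map@residueToColumn]
    } else {
      ifelse(callDisorder(scores(tracks[[refId]]), cfg$disorderCutoff),
             "disordered", "ordered")
    }
    cls <- classifyResidues(structure, rates$proj$z)
    outs$classification <- file.path(cfg$outDir, "residue_classes.tsv")
    writeTsv(cls, outs$classification, c(stamp, mode = cfg$disorderMode))
    mw <- compareRateDistributions(cls$z, cls$structure)
    list(tracks = tracks, matrix = dm, classification = cls, mw = mw)
  })

  ## --- conserved phosphosites ------------------------------------------
  ptm <- .stage("ptm_conservation", {
    ptracks <- readTrack(cfg$phospho, rates$aln, kind = "phospho")
    if (is(ptracks, "AnnotationTrack"))
      ptracks <- stats::setNames(list(ptracks), ptracks@sequenceId)
    calls <- lapply(ptracks, callSites, alignment = rates$aln,
                    cutoff = cfg$ptmCutoff)
    cons <- conservedColumns(rates$aln, calls, majority = cfg$ptmMajority,
                             denominator = cfg$ptmDenominator,
                             tracks = ptracks)
    outs$ptm <- file.path(cfg$outDir, "conserved_ptm.tsv")
    writeTsv(cons$referenceSites, outs$ptm,
             c(stamp, cutoff = cfg$ptmCutoff, majority = cfg$ptmMajority))
    cons
  })

  ## --- variant context --------------------------------------------------
  variants <- .stage("variant_annotation", {
    domains <- readDomains(cfg$domains)
    v <- readVariants(cfg$variants, rates$aln,
                      allowedLabels = cfg$allowedLabels)
    ptmPos <- ptm$referenceSites$ref_pos[ptm$referenceSites$conserved]
    ctx <- annotateVariants(v, domains, disorder$classification, ptmPos)
    outs$variants <- file.path(cfg$outDir, "variant_context.tsv")
    writeTsv(ctx, outs$variants, stamp)
    list(contexts = ctx,
         summary = if (nrow(ctx)) summarizeDistribution(ctx) else NULL)
  })

  ## --- phylogenetic profiling ------------------------------------------
  profiling <- .stage("phyloprofiling", {
    tab <- utils::read.delim(cfg$orthologs, comment.char = "#",
                             stringsAsFactors = FALSE)
    groups <- readTaxonomyGroups(cfg$taxonomy)
    prof <- buildProfile(tab, groups)
    cl <- wardCluster(prof, k = cfg$k, variant = cfg$wardVariant)
    cl <- assignClassLabels(cl, prof, insideMin = cfg$insideMin,
                            outsideMax = cfg$outsideMax)
    asgn <- clusterAssignment(cl)
    outs$clusters <- file.path(cfg$outDir, "clusters.tsv")
    writeTsv(data.frame(protein = names(asgn), cluster = unname(asgn),
                        class = classLabels(cl)[asgn]),
             outs$clusters, c(stamp, k = cfg$k, variant = cfg$wardVariant))
    outs$dendrogram <- file.path(cfg$outDir, "dendrogram.nwk")
    writeDendrogram(cl, outs$dendrogram)
    list(profile = prof, clusters = cl)
  })

  ## --- tissue specificity -----------------------------------------------
  expression <- .stage("expression_specificity", {
    tab <- readExpressionTable(cfg$expression)
    calls <- specificityCalls(tab, factor = cfg$specificityFactor)
    outs$specificity <- file.path(cfg$outDir, "specificity_calls.tsv")
    writeTsv(calls[calls$flag == 1L, , drop = FALSE], outs$specificity,
             c(stamp, factor = cfg$specificityFactor))
    calls
  })

  ## --- summary ----------------------------------------------------------
  classSizes <- table(factor(
    classLabels(profiling$clusters)[clusterAssignment(profiling$clusters)],
    levels = classLabels(profiling$clusters)))
  summary <- list(
    config_hash = hash,
    alpha = rates$alpha,
    log_likelihood = rates$result@logLik,
    n_columns = length(siteRates(rates$result)),
    n_no_data = sum(noDataColumns(rates$result)),
    mann_whitney = disorder$mw,
    n_conserved_ptm = sum(ptm$referenceSites$conserved),
    n_variants = nrow(variants$contexts),
    n_cases = sum(variants$contexts$n_cases),
    class_sizes = as.list(classSizes),
    n_specific_calls = sum(expression$flag == 1L))
  outs$summary <- file.path(cfg$outDir, "summary.json")
  jsonlite::write_json(summary, outs$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(summary = summary, paths = outs, config = cfg))
}
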