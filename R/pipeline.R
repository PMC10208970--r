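#' Assemble a run configuration
#'
#' Bundles input paths and stage settings for \code{\link{runPipeline}}.
#' Paths may be \code{NULL}: stages whose inputs are absent are skipped
#' (e.g. a variant-only run without an expression matrix). The seed is
#' propagated to every stochastic stage.
#'
#' @param variants path to the annotated variant TSV (or VCF).
#' @param pedigree path to the PED file.
#' @param panelFiles character vector of gene panel files (one symbol per
#'   line).
#' @param review path to the clinical-review TSV (family, chrom, pos, ref,
#'   alt, acmg_class, phenotype_consistent).
#' @param expression,expressionMeta paths to the expression matrix and its
#'   sample metadata TSVs.
#' @param seeds optional file of seed genes for prioritization (defaults
#'   to the high-confidence genes found by classification).
#' @param candidateGenes optional file of candidate genes to prioritize
#'   (defaults to the low-confidence genes).
#' @param regionsBed,geneCoordsBed optional BED inputs for CNV-region
#'   prioritization.
#' @param structuralVariants optional SV call TSV.
#' @param outDir output directory.
#' @param filter a \code{\link{filterConfig}}.
#' @param nIter Monte-Carlo draws for co-expression and prioritization.
#' @param seed integer seed for all stochastic stages.
#' @param thresholdQuantile genome-wide edge-threshold quantile.
#' @param minDetectedFraction expression-eligibility floor.
#' @param fdr prioritization q-value threshold.
#' @param variantDialect \code{"tsv"} or \code{"vcf"}.
#' @return a named list with class \code{"TriageRunConfig"}.
#' @export
runConfig <- function(variants = NULL, pedigree = NULL,
                      panelFiles = NULL, review = NULL,
                      expression = NULL, expressionMeta = NULL,
                      seeds = NULL, candidateGenes = NULL,
                      regionsBed = NULL, geneCoordsBed = NULL,
                      structuralVariants = NULL,
                      outDir = "triage-out", filter = filterConfig(),
                      nIter = 5000, seed = 1L, thresholdQuantile = 0.95,
                      minDetectedFraction = 0.5, fdr = 0.1,
                      variantDialect = "tsv") {
  cfg <- list(variants = variants, pedigree = pedigree,
              panelFiles = panelFiles, review = review,
              expression = expression, expressionMeta = expressionMeta,
              seeds = seeds, candidateGenes = candidateGenes,
              regionsBed = regionsBed, geneCoordsBed = geneCoordsBed,
              structuralVariants = structuralVariants, outDir = outDir,
              filter = filter, nIter = nIter, seed = as.integer(seed),
              thresholdQuantile = thresholdQuantile,
              minDetectedFraction = minDetectedFraction, fdr = fdr,
              variantDialect = variantDialect)
  for (p in c("variants", "pedigree", "review", "expression",
              "expressionMeta", "seeds", "candidateGenes", "regionsBed",
              "geneCoordsBed", "structuralVariants")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("configured ", p, " file does not exist: ", cfg[[p]])
  }
  for (p in cfg$panelFiles)
    if (!file.exists(p)) stop("panel file does not exist: ", p)
  structure(cfg, class = "TriageRunConfig")
}

#' Read a YAML run configuration
#'
#' YAML keys mirror the arguments of \code{\link{runConfig}}; the
#' \code{filter} block mirrors \code{\link{filterConfig}} field names.
#'
#' @param path YAML file.
#' @return a \code{"TriageRunConfig"}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$filter)) y$filter <- do.call(filterConfig, y$filter)
  do.call(runConfig, y)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full triage pipeline
#'
#' Orchestrates filtering, classification, co-expression and
#' prioritization over the configured inputs, writing plain TSV/JSON stage
#' outputs (pool.tsv, attrition.tsv, candidates.tsv, coexpression.json,
#' prioritization.tsv, summary.json) into the output directory so any
#' stage can be inspected independently. Every threshold actually used is
#' echoed into the summary. Re-running with an identical configuration and
#' seed reproduces byte-identical outputs.
#'
#' Stages whose inputs are not configured are skipped: with no expression
#' matrix the run is variant-only; with no variants the run is
#' expression-only.
#'
#' @param cfg a \code{"TriageRunConfig"} from \code{\link{runConfig}} or
#'   \code{\link{readRunConfig}}.
#' @return invisibly, a list with the in-memory stage results
#'   (\code{pool}, \code{attrition}, \code{candidates}, \code{summary},
#'   \code{coexpression}, \code{prioritization}, \code{sv}).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "TriageRunConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  summary <- list(settings = list(
    filter = unclass(cfg$filter), n_iter = cfg$nIter, seed = cfg$seed,
    threshold_quantile = cfg$thresholdQuantile,
    min_detected_fraction = cfg$minDetectedFraction, fdr = cfg$fdr,
    connectivity_formula = "sum over seed genes of |spearman rho|"))

  high_genes <- character(); low_genes <- character()
  if (!is.null(cfg$variants) && !is.null(cfg$pedigree)) {
    vt <- stage("read_variants",
                readAnnotatedVariants(cfg$variants, cfg$variantDialect))
    ped <- stage("read_pedigree", readPedigree(cfg$pedigree))
    filt <- stage("filter", filterVariants(vt, ped, cfg$filter))
    out$pool <- filt$pool
    out$attrition <- filt$attrition
    .writeTsv(variants(filt$pool), file.path(cfg$outDir, "pool.tsv"))
    .writeTsv(filt$attrition, file.path(cfg$outDir, "attrition.tsv"))
    summary$attrition <- as.list(table(filt$attrition$reason[
      !filt$attrition$kept]))
    summary$n_input_variants <- nrow(variants(vt))
    summary$n_pool <- nrow(variants(filt$pool))

    panelSet <- if (length(cfg$panelFiles))
      stage("read_panels", readGenePanels(cfg$panelFiles))
    else GenePanelSet(list(panel = character()))
    shortlist <- stage("classify",
                       shortlistCandidates(filt$pool, panelSet))
    if (!is.null(cfg$review)) {
      review <- read.delim(cfg$review)
      shortlist <- stage("review", applyReview(shortlist, review,
                                               filt$pool))
    } else {
      shortlist$acmg_class <- NA_integer_
      shortlist$phenotype_consistent <- NA
      shortlist$tier <- "excluded"
    }
    out$candidates <- shortlist
    .writeTsv(shortlist, file.path(cfg$outDir, "candidates.tsv"))
    n_probands <- length(probands(ped))
    out$summary <- summarizeCohort(shortlist, n_probands)
    summary$cohort <- out$summary
    high_genes <- unique(toupper(
      shortlist$gene[shortlist$tier == "high_confidence"]))
    low_genes <- unique(toupper(
      shortlist$gene[shortlist$tier == "low_confidence"]))
  }

  if (!is.null(cfg$structuralVariants)) {
    sv <- stage("sv", filterSV(readStructuralVariants(
      cfg$structuralVariants), cfg$filter))
    out$sv <- sv
    .writeTsv(sv, file.path(cfg$outDir, "sv_kept.tsv"))
  }

  if (!is.null(cfg$expression)) {
    em <- stage("read_expression",
                readExpressionMatrix(cfg$expression, cfg$expressionMeta))
    seeds <- if (!is.null(cfg$seeds))
      unique(toupper(readLines(cfg$seeds))) else high_genes
    seeds <- intersect(seeds, rownames(em))
    if (length(seeds) >= 2) {
      coex <- stage("coexpr", analyzeCoexpression(
        em, seeds, nIter = cfg$nIter, seed = cfg$seed,
        thresholdQuantile = cfg$thresholdQuantile))
      out$coexpression <- coex
      jsonlite::write_json(list(
        genes = coex@geneSet, set_statistic = coex@setStatistic,
        n_pairs = coex@nPairs, n_missing_pairs = coex@nMissing,
        mc_p = coex@mcP, n_iter = coex@nIter, seed = coex@seed,
        threshold = coex@threshold, n_edges = nrow(coex@edges),
        order = coex@order),
        file.path(cfg$outDir, "coexpression.json"), auto_unbox = TRUE,
        digits = NA)
      .writeTsv(coex@edges, file.path(cfg$outDir, "edges.tsv"))

      cands <- if (!is.null(cfg$candidateGenes))
        unique(toupper(readLines(cfg$candidateGenes))) else low_genes
      cands <- setdiff(intersect(cands, rownames(em)), seeds)
      prior <- list()
      if (length(cands))
        prior$variant_genes <- cbind(
          batch = "low_confidence",
          stage("prioritize", prioritizeGenes(
            em, cands, seeds, nIter = cfg$nIter, seed = cfg$seed,
            fdr = cfg$fdr)))
      if (!is.null(cfg$regionsBed) && !is.null(cfg$geneCoordsBed)) {
        regions <- stage("read_regions",
                         readCnvRegions(cfg$regionsBed, cfg$geneCoordsBed))
        rp <- stage("prioritize_regions", prioritizeRegions(
          em, regions, seeds, nIter = cfg$nIter, seed = cfg$seed,
          fdr = cfg$fdr))
        prior$regions <- cbind(batch = paste0("region:", rp$region),
                               rp[, setdiff(names(rp), "region")])
      }
      if (length(prior)) {
        prior_df <- do.call(rbind, prior)
        rownames(prior_df) <- NULL
        out$prioritization <- prior_df
        .writeTsv(prior_df, file.path(cfg$outDir, "prioritization.tsv"))
      }
    }
  }

  jsonlite::write_json(summary, file.path(cfg$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
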