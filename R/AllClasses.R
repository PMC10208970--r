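#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom stats cor median quantile p.adjust rnorm runif rpois setNames
#'   as.dist hclust complete.cases
#' @importFrom utils read.delim write.table read.table head
NULL

## Column layout shared by the reader, writer, simulator and validity checks.
## One row per (family, site, alt allele, transcript).
.VARIANT_COLUMNS <- c(
  "family", "chrom", "pos", "ref", "alt", "gene", "transcript",
  "consequence", "gnomad_ac", "gnomad_af", "pli", "loftool", "cadd_phred",
  "sift_call", "sift_score", "polyphen_call", "polyphen_score", "mtr_fdr",
  "ada_score", "rf_score", "qd", "fs", "sor", "mq_rank_sum",
  "read_pos_rank_sum", "excess_het_z", "filter", "variant_class", "uid"
)

.GENOTYPE_LEVELS <- c("hom_ref", "het", "hom_alt", "hemi_alt", "missing")
.SIFT_CALLS <- c("deleterious", "deleterious_low_confidence", "tolerated")
.POLYPHEN_CALLS <- c("probably_damaging", "possibly_damaging", "benign")

#' VariantTable: annotated small variants with per-sample genotypes
#'
#' A \code{VariantTable} holds one row per (family, site, alternate allele,
#' transcript) with VEP-style functional annotations, in-silico scores,
#' population frequencies and site-level quality metrics, plus a long-format
#' genotype table (sample, genotype class, read depth DP, genotype quality
#' GQ). Missing annotations are \code{NA}, never 0: an allele absent from
#' gnomAD is distinguishable from one observed zero times.
#'
#' @slot variants data.frame of variant-level fields (see
#'   \code{\link{readAnnotatedVariants}} for the column dialect).
#' @slot genotypes data.frame with columns \code{uid}, \code{sample},
#'   \code{gt}, \code{dp}, \code{gq}; \code{gt} is one of \code{hom_ref},
#'   \code{het}, \code{hom_alt}, \code{hemi_alt}, \code{missing}.
#'
#' @export
setClass("VariantTable",
  representation(variants = "data.frame", genotypes = "data.frame"))

setValidity("VariantTable", function(object) {
  v <- object@variants
  g <- object@genotypes
  msg <- character()
  missing_cols <- setdiff(.VARIANT_COLUMNS, names(v))
  if (length(missing_cols))
    msg <- c(msg, paste("missing variant columns:",
                        paste(missing_cols, collapse = ", ")))
  if (!all(c("uid", "sample", "gt", "dp", "gq") %in% names(g)))
    msg <- c(msg, "genotype table needs uid, sample, gt, dp, gq")
  if (length(msg)) return(msg)
  if (nrow(v)) {
    if (any(v$pos < 1)) msg <- c(msg, "pos must be >= 1")
    if (any(v$ref == v$alt)) msg <- c(msg, "alt must differ from ref")
    in01 <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
    for (col in c("gnomad_af", "pli", "loftool", "sift_score",
                  "polyphen_score", "mtr_fdr", "ada_score", "rf_score"))
      if (!in01(v[[col]])) msg <- c(msg, paste(col, "must lie in [0, 1]"))
    if (!all(is.na(v$cadd_phred) | v$cadd_phred >= 0))
      msg <- c(msg, "cadd_phred must be nonnegative")
    if (!all(is.na(v$gnomad_ac) | v$gnomad_ac >= 0))
      msg <- c(msg, "gnomad_ac must be nonnegative")
    if (!all(v$variant_class %in% c("snv", "indel")))
      msg <- c(msg, "variant_class must be snv or indel")
    if (anyDuplicated(v$uid)) msg <- c(msg, "uid must be unique")
  }
  if (nrow(g)) {
    if (!all(g$gt %in% .GENOTYPE_LEVELS))
      msg <- c(msg, "unknown genotype class in gt")
    ok <- is.na(g$dp) | g$dp >= 0
    if (!all(ok)) msg <- c(msg, "dp must be nonnegative")
    if (!all(is.na(g$gq) | g$gq >= 0)) msg <- c(msg, "gq must be nonnegative")
    if (!all(g$uid %in% v$uid))
      msg <- c(msg, "genotype uid not present in variant table")
  }
  if (length(msg)) msg else TRUE
})

#' Pedigree: family structure with sex and affected status
#'
#' Wraps a standard 6-column PED table (family, individual, father, mother,
#' sex, phenotype) with optional \code{twin} annotation used to collapse
#' monozygotic twin pairs to a single analysis proband. Trios, parent-child
#' duos, singletons and extended families are all representable; a missing
#' parent is the empty string.
#'
#' @slot ped data.frame with columns \code{family}, \code{id},
#'   \code{father}, \code{mother}, \code{sex} (male/female/unknown),
#'   \code{affected} (affected/unaffected/unknown), \code{twin} (character,
#'   "" when not annotated).
#'
#' @export
setClass("Pedigree", representation(ped = "data.frame"))

setValidity("Pedigree", function(object) {
  p <- object@ped
  msg <- character()
  need <- c("family", "id", "father", "mother", "sex", "affected", "twin")
  if (!all(need %in% names(p)))
    return(paste("pedigree needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(p$id))
    msg <- c(msg, "duplicate sample id in pedigree")
  dangling <- setdiff(setdiff(c(p$father, p$mother), ""), p$id)
  if (length(dangling))
    msg <- c(msg, paste("parent id not in pedigree:",
                        paste(dangling, collapse = ", ")))
  if (any(p$father == p$id & p$id != "") || any(p$mother == p$id & p$id != ""))
    msg <- c(msg, "individual listed as its own parent")
  if (!all(p$sex %in% c("male", "female", "unknown")))
    msg <- c(msg, "sex must be male/female/unknown")
  if (!all(p$affected %in% c("affected", "unaffected", "unknown")))
    msg <- c(msg, "affected must be affected/unaffected/unknown")
  ## cycle check: walking parent links must terminate
  if (!length(msg) && nrow(p)) {
    idx <- setNames(seq_len(nrow(p)), p$id)
    for (i in seq_len(nrow(p))) {
      seen <- character(); cur <- p$id[i]
      while (cur != "") {
        if (cur %in% seen) { msg <- c(msg, "pedigree contains a cycle"); break }
        seen <- c(seen, cur)
        j <- idx[[cur]]
        cur <- p$father[j]   # father chain suffices with the self-parent check
      }
      if (length(msg)) break
    }
  }
  if (length(msg)) msg else TRUE
})

#' GenePanelSet: named gene lists and their union
#'
#' Holds the "genes of interest" panels used for stage-1 shortlisting (e.g.
#' speech disorder, intellectual disability, epilepsy, ASD, cleft palate
#' panels, plus SFARI and human-accelerated-region sets). Membership is
#' case-normalized to upper case.
#'
#' @slot panels named list of character vectors of gene symbols.
#' @slot provenance named character vector of source labels, one per panel.
#'
#' @export
setClass("GenePanelSet",
  representation(panels = "list", provenance = "character"))

setValidity("GenePanelSet", function(object) {
  msg <- character()
  if (is.null(names(object@panels)) || any(!nzchar(names(object@panels))))
    msg <- c(msg, "panels must be named")
  if (!all(vapply(object@panels, is.character, logical(1))))
    msg <- c(msg, "panels must be character vectors")
  if (any(vapply(object@panels, function(p) any(p != toupper(p)), logical(1))))
    msg <- c(msg, "panel symbols must be upper-cased")
  if (any(vapply(object@panels, anyDuplicated, integer(1)) > 0))
    msg <- c(msg, "duplicate symbol within a panel")
  if (length(msg)) msg else TRUE
})

#' ExpressionMatrix: genes x developmental brain samples
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding a nonnegative
#' genes-by-samples expression matrix (assay \code{"expr"}) with per-sample
#' donor and developmental-stage metadata. This is the substrate for every
#' co-expression statistic in the package.
#'
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    return("assay 'expr' required")
  x <- SummarizedExperiment::assay(object, "expr")
  if (!is.numeric(x)) msg <- c(msg, "expression values must be numeric")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene symbols")
  if (is.numeric(x) && any(x < 0, na.rm = TRUE))
    msg <- c(msg, "expression values must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' CoexpressionResult: a gene set's co-expression statistic and null
#'
#' Container for the output of \code{\link{analyzeCoexpression}}: the
#' pairwise Spearman matrix of the gene set, the genome-wide top-quantile
#' edge threshold on |rho|, the set statistic (median |rho| over unordered
#' pairs), its Monte-Carlo empirical p-value, the supra-threshold edge list
#' and a hierarchical-clustering display order.
#'
#' @slot rho symmetric Spearman correlation matrix for the gene set.
#' @slot threshold genome-wide |rho| cutoff (e.g. the top-5\% quantile).
#' @slot setStatistic median |rho| over the set's pairs.
#' @slot nPairs number of unordered pairs entering the median.
#' @slot nMissing number of pairs excluded because rho was undefined.
#' @slot mcP empirical p-value, add-one estimator (r + 1) / (n + 1).
#' @slot nullStats null statistics from the Monte-Carlo draws.
#' @slot nIter number of Monte-Carlo draws.
#' @slot seed integer seed that fixed the draw sequence.
#' @slot edges data.frame of supra-threshold edges (gene_i, gene_j, rho,
#'   sign, above_threshold).
#' @slot order display ordering of the gene set from median-linkage
#'   clustering.
#' @slot geneSet the gene symbols analyzed.
#'
#' @export
setClass("CoexpressionResult",
  representation(rho = "matrix", threshold = "numeric",
                 setStatistic = "numeric", nPairs = "integer",
                 nMissing = "integer", mcP = "numeric",
                 nullStats = "numeric", nIter = "integer", seed = "integer",
                 edges = "data.frame", order = "character",
                 geneSet = "character"))

setValidity("CoexpressionResult", function(object) {
  msg <- character()
  r <- object@rho
  if (nrow(r) != ncol(r)) msg <- c(msg, "rho must be square")
  else if (nrow(r)) {
    if (max(abs(r - t(r)), na.rm = TRUE) > 1e-12)
      msg <- c(msg, "rho must be symmetric")
    if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "|rho| must be <= 1")
  }
  if (length(object@setStatistic) &&
      !is.na(object@setStatistic) &&
      (object@setStatistic < 0 || object@setStatistic > 1))
    msg <- c(msg, "set statistic must lie in [0, 1]")
  if (length(object@mcP) && !is.na(object@mcP) &&
      (object@mcP <= 0 || object@mcP > 1))
    msg <- c(msg, "mcP must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
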