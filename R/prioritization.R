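#' Continuous connectivity score of a gene to a seed set
#'
#' The connectivity of a candidate gene to a set of implicated (seed)
#' genes is the sum over seeds of |rho(gene, seed)|. The candidate is
#' removed from the seed set if it is a member; undefined correlations
#' contribute 0 and are counted in the \code{"n_missing"} attribute. The
#' score is bounded by the number of seeds.
#'
#' @param gene candidate gene symbol.
#' @param seedSet character vector of seed gene symbols.
#' @param rho symmetric Spearman matrix containing the candidate and the
#'   seeds.
#' @return the connectivity score (numeric scalar).
#' @export
connectivityScore <- function(gene, seedSet, rho) {
  seeds <- setdiff(seedSet, gene)
  missing_genes <- setdiff(c(gene, seeds), rownames(rho))
  if (length(missing_genes))
    stop("genes absent from correlation matrix: ",
         paste(missing_genes, collapse = ", "))
  vals <- abs(rho[gene, seeds])
  score <- sum(vals, na.rm = TRUE)
  attr(score, "n_missing") <- sum(is.na(vals))
  score
}

## connectivity of many genes against one seed set from standardized ranks
.connectivityFromZ <- function(z, gene_idx, seed_idx) {
  r <- abs(z[gene_idx, , drop = FALSE] %*% t(z[seed_idx, , drop = FALSE]))
  rowSums(r, na.rm = TRUE)
}

#' Prioritize candidate genes by co-expression connectivity
#'
#' Scores each candidate by its connectivity to the seed set, compares it
#' with the connectivity of \code{nIter} genes drawn uniformly from the
#' eligible universe (add-one empirical p-value), adjusts the candidate
#' batch by Benjamini-Hochberg, and flags genes with q below \code{fdr}.
#' The same null draw is shared by the whole batch.
#'
#' @inheritParams monteCarloCoexpression
#' @param candidates character vector of candidate gene symbols; must be
#'   disjoint from the seed set.
#' @param seedSet character vector of implicated seed genes.
#' @param fdr q-value threshold for prioritization (default 0.1).
#' @return data.frame with \code{gene}, \code{score}, \code{mc_p},
#'   \code{q}, \code{prioritized}, sorted by descending score. The
#'   connectivity formula used is recorded in the \code{"formula"}
#'   attribute.
#' @export
prioritizeGenes <- function(m, candidates, seedSet, nIter = 5000,
                            seed = 1L, eligibleUniverse = NULL,
                            fdr = 0.1) {
  if (nIter < 1) stop("nIter must be >= 1")
  overlap <- intersect(candidates, seedSet)
  if (length(overlap))
    stop("candidate genes are members of the seed set: ",
         paste(overlap, collapse = ", "))
  x <- .exprValues(m)
  missing_genes <- setdiff(c(candidates, seedSet), rownames(x))
  if (length(missing_genes))
    stop("genes absent from matrix: ",
         paste(missing_genes, collapse = ", "))
  if (is.null(eligibleUniverse)) eligibleUniverse <- eligibleGenes(m)
  z <- .rankStandardize(x)
  seed_idx <- match(seedSet, rownames(x))
  cand_idx <- match(candidates, rownames(x))
  ## a candidate never scores against itself (none are seeds here, but the
  ## null genes may be seed members; their self-pair is excluded below)
  scores <- .connectivityFromZ(z, cand_idx, seed_idx)
  univ_idx <- match(eligibleUniverse, rownames(x))
  null_scores <- withr::with_seed(as.integer(seed), {
    draw <- univ_idx[sample.int(length(univ_idx), nIter, replace = TRUE)]
    s <- .connectivityFromZ(z, draw, seed_idx)
    ## remove the self-term |rho| = 1 for null genes inside the seed set
    s - ifelse(draw %in% seed_idx, 1, 0)
  })
  mc_p <- vapply(scores, function(s)
    (1 + sum(null_scores >= s)) / (nIter + 1), numeric(1))
  q <- p.adjust(mc_p, method = "BH")
  out <- data.frame(gene = candidates, score = scores, mc_p = mc_p, q = q,
                    prioritized = q < fdr)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "formula") <- "sum over seed genes of |spearman rho|"
  out
}

#' Read CNV regions and their gene membership
#'
#' @param regionsBed BED file of regions (0-based half-open, converted to
#'   1-based inclusive internally) with the region label in the name
#'   column.
#' @param geneCoordsBed BED file of gene spans with the gene symbol in the
#'   name column.
#' @return data.frame with \code{label}, \code{chrom}, \code{start},
#'   \code{end} and a \code{member_genes} list column; genes overlapping
#'   several regions belong to each.
#' @export
readCnvRegions <- function(regionsBed, geneCoordsBed) {
  regions <- rtracklayer::import(regionsBed, format = "BED")
  genes <- rtracklayer::import(geneCoordsBed, format = "BED")
  hits <- GenomicRanges::findOverlaps(regions, genes)
  members <- split(genes$name[S4Vectors::subjectHits(hits)],
                   factor(S4Vectors::queryHits(hits),
                          levels = seq_along(regions)))
  out <- data.frame(
    label = regions$name,
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions),   # rtracklayer yields 1-based
    end = GenomicRanges::end(regions))
  out$member_genes <- lapply(members, unique)
  if (any(lengths(out$member_genes) == 0))
    warning("region(s) without member genes: ",
            paste(out$label[lengths(out$member_genes) == 0],
                  collapse = ", "))
  out
}

#' Prioritize genes within CNV regions
#'
#' Runs \code{\link{prioritizeGenes}} per region over its member genes
#' (restricted to genes present and eligible in the expression matrix);
#' null draws come from the full eligible universe, not from within the
#' region. The q-values are computed per region batch. A gene in several
#' overlapping regions is scored once per region and reported in each.
#'
#' @inheritParams prioritizeGenes
#' @param regions data.frame from \code{\link{readCnvRegions}} (or with
#'   the same columns).
#' @return data.frame with \code{region}, \code{gene}, \code{score},
#'   \code{mc_p}, \code{q}, \code{prioritized}, regions in input order and
#'   genes by descending score; regions with no scorable or no prioritized
#'   gene are flagged in the \code{n_prioritized} attribute table.
#' @export
prioritizeRegions <- function(m, regions, seedSet, nIter = 5000,
                              seed = 1L, eligibleUniverse = NULL,
                              fdr = 0.1) {
  x <- .exprValues(m)
  if (is.null(eligibleUniverse)) eligibleUniverse <- eligibleGenes(m)
  out <- list()
  summary <- data.frame(region = regions$label, n_members =
                          lengths(regions$member_genes),
                        n_scored = 0L, n_prioritized = 0L)
  for (i in seq_len(nrow(regions))) {
    members <- setdiff(intersect(regions$member_genes[[i]], rownames(x)),
                       seedSet)
    if (!length(members)) next
    res <- prioritizeGenes(m, members, seedSet, nIter = nIter,
                           seed = seed, eligibleUniverse = eligibleUniverse,
                           fdr = fdr)
    summary$n_scored[i] <- nrow(res)
    summary$n_prioritized[i] <- sum(res$prioritized)
    out[[i]] <- cbind(region = regions$label[i], res)
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(region = character(), gene = character(),
                  score = numeric(), mc_p = numeric(), q = numeric(),
                  prioritized = logical())
  rownames(res) <- NULL
  attr(res, "region_summary") <- summary
  res
}
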