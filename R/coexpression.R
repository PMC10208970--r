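.exprValues <- function(m) {
  if (is(m, "ExpressionMatrix") || is(m, "SummarizedExperiment"))
    SummarizedExperiment::assay(m, "expr")
  else as.matrix(m)
}

## Average-rank each gene across samples, then center/scale so that the
## dot product of two rows equals their Spearman rho. Constant genes get
## all-NA rows (rho undefined).
.rankStandardize <- function(x) {
  n <- ncol(x)
  r <- t(apply(x, 1L, rank))   # average ranks on ties
  r <- r - (n + 1) / 2
  ss <- sqrt(rowSums(r^2))
  out <- r / ss
  out[ss == 0, ] <- NA_real_
  out
}

#' Pairwise Spearman correlation matrix
#'
#' Computes rank correlations (average ranks on ties) between all pairs of
#' the requested genes. Pairs involving a constant expression vector are
#' undefined and returned as \code{NA}; the diagonal is 1.
#'
#' @param m an \linkS4class{ExpressionMatrix} (or numeric genes x samples
#'   matrix) with at least 3 samples.
#' @param genes optional subset of gene symbols (all genes by default).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(m, genes = NULL) {
  x <- .exprValues(m)
  if (ncol(x) < 3) stop("at least 3 samples required")
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, rownames(x))
    if (length(missing_genes))
      stop("genes absent from matrix: ",
           paste(missing_genes, collapse = ", "))
    x <- x[genes, , drop = FALSE]
  }
  z <- .rankStandardize(x)
  rho <- tcrossprod(z)
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  diag(rho)[!is.na(diag(rho))] <- 1
  const <- is.na(z[, 1])
  rho[const, ] <- NA_real_; rho[, const] <- NA_real_
  rho
}

#' Genes eligible for null draws
#'
#' The Monte-Carlo null universe is restricted to expression-eligible
#' genes: those detected (expression above \code{detectionLimit}) in at
#' least \code{minDetectedFraction} of samples, and non-constant.
#'
#' @inheritParams spearmanMatrix
#' @param minDetectedFraction minimum fraction of samples with detected
#'   expression (default 0.5).
#' @param detectionLimit expression value above which a gene counts as
#'   detected in a sample (default 0).
#' @return character vector of eligible gene symbols.
#' @export
eligibleGenes <- function(m, minDetectedFraction = 0.5,
                          detectionLimit = 0) {
  x <- .exprValues(m)
  detected <- rowMeans(x > detectionLimit) >= minDetectedFraction
  nonconst <- apply(x, 1L, function(v) length(unique(v)) > 1L)
  rownames(x)[detected & nonconst]
}

#' Genome-wide co-expression edge threshold
#'
#' The |rho| value at the requested quantile (default: top 5\%, i.e. the
#' 0.95 quantile) over gene pairs genome-wide. When the number of pairs
#' exceeds \code{maxPairs}, the quantile is estimated over \code{maxPairs}
#' pairs sampled uniformly without replacement; the method used is
#' recorded in the \code{"method"} attribute. Pairs with undefined rho are
#' excluded and counted in the \code{"n_undefined"} attribute.
#'
#' @inheritParams spearmanMatrix
#' @param quantile quantile of |rho| in (0, 1]; 0 returns the minimum.
#' @param maxPairs sampling cap on the number of pairs.
#' @param seed integer seed for pair sampling (only used above the cap).
#' @return the threshold on |rho|.
#' @export
genomeWideThreshold <- function(m, quantile = 0.95, maxPairs = 2e6,
                                seed = 1L) {
  if (quantile < 0 || quantile > 1) stop("quantile must lie in [0, 1]")
  x <- .exprValues(m)
  g <- nrow(x)
  n_pairs <- g * (g - 1) / 2
  z <- .rankStandardize(x)
  if (n_pairs <= maxPairs) {
    rho <- tcrossprod(z)
    vals <- abs(rho[upper.tri(rho)])
    method <- "exact"
  } else {
    pair_id <- withr::with_seed(as.integer(seed),
      sample(n_pairs, maxPairs))
    ## map linear pair index (column-major upper triangle) to (i, j)
    j <- ceiling((1 + sqrt(1 + 8 * pair_id)) / 2)
    i <- pair_id - (j - 1) * (j - 2) / 2
    ## chunked so the index expansion never materializes a huge matrix
    vals <- numeric(length(pair_id))
    chunk <- 100000L
    for (at in seq(1L, length(pair_id), by = chunk)) {
      idx <- at:min(at + chunk - 1L, length(pair_id))
      vals[idx] <- abs(rowSums(z[i[idx], , drop = FALSE] *
                                 z[j[idx], , drop = FALSE]))
    }
    method <- "sampled"
  }
  n_undef <- sum(is.na(vals))
  thr <- unname(stats::quantile(vals, probs = quantile, na.rm = TRUE,
                                type = 7))
  attr(thr, "method") <- method
  attr(thr, "n_undefined") <- n_undef
  thr
}

#' Gene-set co-expression statistic: median |rho| over pairs
#'
#' @param rho symmetric Spearman matrix containing the set.
#' @param geneSet gene symbols.
#' @return list with \code{statistic} (median |rho| over the C(k,2)
#'   unordered pairs), \code{n_pairs} (pairs entering the median) and
#'   \code{n_missing} (pairs excluded because rho was undefined).
#' @export
setCoexpressionStatistic <- function(rho, geneSet) {
  missing_genes <- setdiff(geneSet, rownames(rho))
  if (length(missing_genes))
    stop("genes absent from correlation matrix: ",
         paste(missing_genes, collapse = ", "))
  r <- rho[geneSet, geneSet, drop = FALSE]
  vals <- abs(r[upper.tri(r)])
  list(statistic = median(vals, na.rm = TRUE),
       n_pairs = sum(!is.na(vals)), n_missing = sum(is.na(vals)))
}

.setStatFromZ <- function(z, idx) {
  r <- tcrossprod(z[idx, , drop = FALSE])
  median(abs(r[upper.tri(r)]), na.rm = TRUE)
}

#' Monte-Carlo test of gene-set co-expression
#'
#' Draws \code{nIter} uniform same-size gene sets from the eligible
#' universe (allowing member overlap with the observed set but excluding
#' its exact identity), computes each draw's median |rho|, and reports the
#' add-one empirical p-value (r + 1) / (n + 1), which never returns 0: the
#' resolution floor at 4999 draws is 2e-4.
#'
#' @inheritParams spearmanMatrix
#' @param geneSet gene symbols to test (all must be in the matrix).
#' @param nIter number of Monte-Carlo draws (default 5000).
#' @param seed integer seed fixing the draw sequence.
#' @param eligibleUniverse optional character vector of genes for the null
#'   draws; defaults to \code{\link{eligibleGenes}} of the matrix.
#' @return list with \code{statistic}, \code{mc_p}, \code{null_stats},
#'   \code{n_pairs}, \code{n_missing}, \code{n_iter}, \code{seed}.
#' @export
monteCarloCoexpression <- function(m, geneSet, nIter = 5000, seed = 1L,
                                   eligibleUniverse = NULL) {
  x <- .exprValues(m)
  missing_genes <- setdiff(geneSet, rownames(x))
  if (length(missing_genes))
    stop("gene set members absent from matrix: ",
         paste(missing_genes, collapse = ", "))
  if (nIter < 1) stop("nIter must be >= 1")
  if (is.null(eligibleUniverse)) eligibleUniverse <- eligibleGenes(m)
  if (length(eligibleUniverse) < length(geneSet) + 1)
    stop("eligible universe must exceed the gene set size")
  z <- .rankStandardize(x)
  k <- length(geneSet)
  obs_idx <- match(geneSet, rownames(x))
  obs_r <- tcrossprod(z[obs_idx, , drop = FALSE])
  vals <- abs(obs_r[upper.tri(obs_r)])
  observed <- median(vals, na.rm = TRUE)
  univ_idx <- match(eligibleUniverse, rownames(x))
  obs_sorted <- sort(obs_idx)
  null_stats <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nIter), function(it) {
      repeat {
        idx <- univ_idx[sample.int(length(univ_idx), k)]
        if (!identical(sort(idx), obs_sorted)) break
      }
      .setStatFromZ(z, idx)
    }, numeric(1))
  })
  mc_p <- (1 + sum(null_stats >= observed, na.rm = TRUE)) / (nIter + 1)
  list(statistic = observed, mc_p = mc_p, null_stats = null_stats,
       n_pairs = sum(!is.na(vals)), n_missing = sum(is.na(vals)),
       n_iter = as.integer(nIter), seed = as.integer(seed))
}

#' Build the supra-threshold co-expression network
#'
#' @param rho symmetric Spearman matrix (typically restricted to the gene
#'   set of interest).
#' @param threshold edge threshold on |rho|; an edge exists when
#'   |rho| >= threshold.
#' @param geneSets optional named list of gene sets used to attach a
#'   study-of-origin provenance label to each node.
#' @return list with \code{edges} (data.frame gene_i, gene_j, rho, sign,
#'   above_threshold over all pairs) and \code{nodes} (data.frame gene,
#'   provenance, degree).
#' @export
buildNetwork <- function(rho, threshold, geneSets = NULL) {
  genes <- rownames(rho)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- data.frame(gene_i = genes[ut[, 1]], gene_j = genes[ut[, 2]],
                      rho = rho[ut])
  edges$sign <- ifelse(is.na(edges$rho), NA_character_,
                       ifelse(edges$rho >= 0, "positive", "negative"))
  edges$above_threshold <- !is.na(edges$rho) & abs(edges$rho) >= threshold
  kept <- edges[edges$above_threshold, , drop = FALSE]
  degree <- setNames(integer(length(genes)), genes)
  for (g in genes)
    degree[[g]] <- sum(kept$gene_i == g) + sum(kept$gene_j == g)
  provenance <- rep(NA_character_, length(genes))
  if (!is.null(geneSets))
    for (nm in rev(names(geneSets)))
      provenance[genes %in% geneSets[[nm]]] <- nm
  list(edges = edges,
       nodes = data.frame(gene = genes, provenance = provenance,
                          degree = unname(degree)))
}

#' Display ordering by median-linkage hierarchical clustering
#'
#' Agglomerative clustering of the genes on distance 1 - rho using the
#' median (WPGMC) linkage, as used for co-expression heatmap ordering;
#' returns the dendrogram leaf order.
#'
#' @param rho symmetric Spearman matrix.
#' @param geneSet optional subset to order (all rows by default).
#' @return character vector: gene symbols in display order.
#' @export
clusterOrder <- function(rho, geneSet = NULL) {
  if (is.null(geneSet)) geneSet <- rownames(rho)
  if (length(geneSet) == 1L) return(geneSet)
  d <- 1 - rho[geneSet, geneSet]
  hc <- hclust(as.dist(d), method = "median")
  geneSet[hc$order]
}

#' Full co-expression analysis of a gene set
#'
#' Computes the set's Spearman matrix, the genome-wide edge threshold, the
#' median-|rho| set statistic with its Monte-Carlo p-value, the
#' supra-threshold network and a clustering display order, bundled into a
#' \linkS4class{CoexpressionResult}.
#'
#' @inheritParams monteCarloCoexpression
#' @param thresholdQuantile genome-wide quantile for the edge threshold
#'   (default 0.95, the top 5\%).
#' @param maxPairs pair-sampling cap for the threshold.
#' @param geneSets optional named list for node provenance labels.
#' @return a \linkS4class{CoexpressionResult}.
#' @export
analyzeCoexpression <- function(m, geneSet, nIter = 5000, seed = 1L,
                                thresholdQuantile = 0.95, maxPairs = 2e6,
                                eligibleUniverse = NULL, geneSets = NULL) {
  rho_set <- spearmanMatrix(m, geneSet)
  thr <- genomeWideThreshold(m, quantile = thresholdQuantile,
                             maxPairs = maxPairs, seed = seed)
  mc <- monteCarloCoexpression(m, geneSet, nIter = nIter, seed = seed,
                               eligibleUniverse = eligibleUniverse)
  net <- buildNetwork(rho_set, as.numeric(thr), geneSets = geneSets)
  new("CoexpressionResult", rho = rho_set, threshold = as.numeric(thr),
      setStatistic = mc$statistic, nPairs = as.integer(mc$n_pairs),
      nMissing = as.integer(mc$n_missing), mcP = mc$mc_p,
      nullStats = mc$null_stats, nIter = mc$n_iter, seed = mc$seed,
      edges = net$edges[net$edges$above_threshold, , drop = FALSE],
      order = clusterOrder(rho_set), geneSet = geneSet)
}
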