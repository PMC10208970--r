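.LOF_CONSEQUENCES <- c("frameshift_variant", "stop_gained", "start_lost",
                       "stop_lost", "splice_acceptor_variant",
                       "splice_donor_variant")

.splitConsequence <- function(x) strsplit(x, ",", fixed = TRUE)

#' Classify predicted loss-of-function variants
#'
#' A variant is predicted LoF when all three clauses hold: (1) its
#' consequence includes frameshift, stop gained, start or stop lost, or a
#' splice acceptor/donor term; (2) its gene is predicted intolerant to LoF
#' variation (pLI >= 0.9 or LoFtool < 0.1); and (3) it is predicted
#' damaging (CADD Phred >= 20) or predicted to affect splicing (AdaBoost
#' >= 0.6 or random-forest >= 0.6). Frameshift variants are exempt from
#' clause 3: intolerance alone suffices. Missing annotations never satisfy
#' a clause.
#'
#' @param x a \linkS4class{VariantTable} (or its \code{variants()} frame).
#' @return data.frame with \code{uid}, \code{is_lof}, and logical columns
#'   \code{lof_consequence}, \code{lof_intolerant}, \code{lof_damaging}
#'   enumerating which clauses fired.
#' @export
classifyLoF <- function(x) {
  v <- if (is(x, "VariantTable")) variants(x) else x
  cons <- .splitConsequence(v$consequence)
  has_lof <- vapply(cons, function(cc) any(cc %in% .LOF_CONSEQUENCES),
                    logical(1))
  is_fs <- vapply(cons, function(cc) "frameshift_variant" %in% cc,
                  logical(1))
  intolerant <- (!is.na(v$pli) & v$pli >= 0.9) |
    (!is.na(v$loftool) & v$loftool < 0.1)
  damaging <- (!is.na(v$cadd_phred) & v$cadd_phred >= 20) |
    (!is.na(v$ada_score) & v$ada_score >= 0.6) |
    (!is.na(v$rf_score) & v$rf_score >= 0.6)
  data.frame(uid = v$uid,
             is_lof = has_lof & intolerant & (is_fs | damaging),
             lof_consequence = has_lof, lof_intolerant = intolerant,
             lof_damaging = damaging | is_fs)
}

#' Classify predicted damaging missense variants
#'
#' A missense variant is predicted damaging when at least three of four
#' criteria hold: (1) PolyPhen-2 probably or possibly damaging; (2) SIFT
#' deleterious or deleterious-low-confidence; (3) CADD Phred >= 20;
#' (4) missense tolerance ratio significantly different from 1
#' (FDR < 0.05). A missing annotation is a criterion not met.
#'
#' @inheritParams classifyLoF
#' @return data.frame with \code{uid}, \code{is_damaging_missense},
#'   \code{n_criteria}, and the four criterion columns.
#' @export
classifyMissense <- function(x) {
  v <- if (is(x, "VariantTable")) variants(x) else x
  cons <- .splitConsequence(v$consequence)
  is_mis <- vapply(cons, function(cc) "missense_variant" %in% cc,
                   logical(1))
  c_poly <- !is.na(v$polyphen_call) &
    v$polyphen_call %in% c("probably_damaging", "possibly_damaging")
  c_sift <- !is.na(v$sift_call) &
    v$sift_call %in% c("deleterious", "deleterious_low_confidence")
  c_cadd <- !is.na(v$cadd_phred) & v$cadd_phred >= 20
  c_mtr <- !is.na(v$mtr_fdr) & v$mtr_fdr < 0.05
  n <- c_poly + c_sift + c_cadd + c_mtr
  data.frame(uid = v$uid,
             is_damaging_missense = is_mis & n >= 3, n_criteria = n,
             mis_polyphen = c_poly, mis_sift = c_sift, mis_cadd = c_cadd,
             mis_mtr = c_mtr)
}

## collapse per-transcript records: a variant allele qualifies when ANY of
## its transcripts qualifies; the qualifying transcript is reported.
.collapseByAllele <- function(v, qualifies) {
  allele <- paste(v$family, v$chrom, v$pos, v$ref, v$alt, sep = ":")
  keep <- rep(FALSE, nrow(v))
  for (a in unique(allele[qualifies])) {
    idx <- which(allele == a & qualifies)
    keep[idx[1]] <- TRUE   # report the first qualifying transcript
  }
  keep
}

#' Two-stage candidate shortlisting
#'
#' Classifies the filtered pool into predicted LoF and predicted damaging
#' missense candidates (most-severe-transcript rule: an allele qualifies if
#' any of its transcripts does), then applies the two-stage search per
#' family: stage 1 restricts to genes of interest (the panel union); the
#' genome-wide, gene-agnostic stage 2 is evaluated only for families where
#' stage 1 yields no reviewable candidate.
#'
#' @param pool a \linkS4class{VariantTable} of filter-surviving variants.
#' @param panelSet a \linkS4class{GenePanelSet}.
#' @return data.frame with one row per shortlisted allele: \code{uid},
#'   \code{family}, \code{gene}, \code{deleterious_class} (\code{lof} or
#'   \code{damaging_missense}) and \code{stage} (\code{panel} or
#'   \code{genome_wide}).
#' @export
shortlistCandidates <- function(pool, panelSet) {
  v <- variants(pool)
  if (!nrow(v))
    return(data.frame(uid = character(), family = character(),
                      gene = character(), deleterious_class = character(),
                      stage = character()))
  lof <- classifyLoF(pool)$is_lof
  mis <- classifyMissense(pool)$is_damaging_missense
  qualifies <- lof | mis
  rep_row <- .collapseByAllele(v, qualifies)
  union <- panelUnion(panelSet)
  in_panel <- toupper(v$gene) %in% union
  out <- list()
  for (fam in unique(v$family)) {
    fam_rows <- which(v$family == fam & rep_row)
    if (!length(fam_rows)) next
    stage1 <- fam_rows[in_panel[fam_rows]]
    chosen <- if (length(stage1)) stage1 else fam_rows
    stage <- if (length(stage1)) "panel" else "genome_wide"
    out[[fam]] <- data.frame(
      uid = v$uid[chosen], family = fam, gene = v$gene[chosen],
      deleterious_class = ifelse(lof[chosen], "lof", "damaging_missense"),
      stage = stage)
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(uid = character(), family = character(),
                  gene = character(), deleterious_class = character(),
                  stage = character())
  rownames(res) <- NULL
  res
}

#' Assign confidence tiers from clinical review inputs
#'
#' ACMG class and gene-phenotype consistency come from clinical review and
#' are inputs, never computed. High confidence requires class 4 or 5
#' (likely pathogenic / pathogenic) with a consistent phenotype; low
#' confidence is class 3 (uncertain significance), or class 4 without
#' phenotype consistency; everything else is excluded.
#'
#' @param acmgClass integer vector of ACMG classes (1-5).
#' @param phenotypeConsistent logical vector.
#' @return character vector of tiers (\code{high_confidence},
#'   \code{low_confidence}, \code{excluded}).
#' @export
assignTier <- function(acmgClass, phenotypeConsistent) {
  stopifnot(all(is.na(acmgClass) | acmgClass %in% 1:5))
  pc <- !is.na(phenotypeConsistent) & phenotypeConsistent
  ifelse(!is.na(acmgClass) & acmgClass %in% 4:5 & pc, "high_confidence",
         ifelse(!is.na(acmgClass) &
                  (acmgClass == 3 | (acmgClass == 4 & !pc)),
                "low_confidence", "excluded"))
}

#' Attach review inputs and tiers to a shortlist
#'
#' @param shortlist output of \code{\link{shortlistCandidates}}.
#' @param review data.frame with columns \code{family}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{acmg_class},
#'   \code{phenotype_consistent}.
#' @param pool the \linkS4class{VariantTable} the shortlist came from.
#' @return the shortlist with \code{acmg_class},
#'   \code{phenotype_consistent} and \code{tier} columns; unreviewed
#'   candidates get \code{NA} class and tier \code{excluded}.
#' @export
applyReview <- function(shortlist, review, pool) {
  v <- variants(pool)
  idx <- match(shortlist$uid, v$uid)
  key <- paste(v$family[idx], v$chrom[idx], v$pos[idx], v$ref[idx],
               v$alt[idx], sep = ":")
  rkey <- paste(review$family, review$chrom, review$pos, review$ref,
                review$alt, sep = ":")
  m <- match(key, rkey)
  shortlist$acmg_class <- review$acmg_class[m]
  shortlist$phenotype_consistent <-
    as.logical(review$phenotype_consistent[m])
  shortlist$tier <- assignTier(shortlist$acmg_class,
                               shortlist$phenotype_consistent)
  shortlist
}

#' Summarize cohort-level diagnostic yield
#'
#' @param candidates reviewed shortlist from \code{\link{applyReview}}.
#' @param nProbands number of analysis probands in the cohort.
#' @return list with \code{n_probands}, \code{solved} (probands with at
#'   least one high-confidence variant), \code{yield_percent} (nearest
#'   integer percent), per-tier variant counts, the number of probands
#'   carrying low-confidence damaging missense variants and its percentage
#'   at one decimal.
#' @examples
#' ## 18 of 70 probands solved -> 26%
#' @export
summarizeCohort <- function(candidates, nProbands) {
  high <- candidates[candidates$tier == "high_confidence", , drop = FALSE]
  low <- candidates[candidates$tier == "low_confidence", , drop = FALSE]
  low_mis <- low[low$deleterious_class == "damaging_missense", ,
                 drop = FALSE]
  solved <- length(unique(high$family))
  list(n_probands = nProbands,
       solved = solved,
       yield_percent = round(100 * solved / nProbands),
       n_high_confidence = nrow(high),
       n_low_confidence = nrow(low),
       low_conf_missense_probands = length(unique(low_mis$family)),
       low_conf_missense_percent =
         round(100 * length(unique(low_mis$family)) / nProbands, 1))
}
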