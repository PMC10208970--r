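#' Simulate gene panels with a controlled overlap structure
#'
#' Builds named panels over a synthetic gene universe such that realized
#' panel cardinalities match \code{panelSizes} exactly and the number of
#' redundant memberships (genes counted in more than one panel, with
#' multiplicity) equals \code{nOverlap}, so that
#' union size = sum(sizes) - nOverlap.
#'
#' @param panelSizes named integer vector of panel sizes.
#' @param nOverlap total redundant memberships across panels.
#' @param universeSize number of genes in the simulated universe.
#' @param seed integer seed fixing all randomness.
#' @return a \linkS4class{GenePanelSet}.
#' @examples
#' ps <- simulatePanels(c(speech = 81, id = 1399, epilepsy = 611,
#'                        asd = 131, cleft = 156),
#'                      nOverlap = 233, universeSize = 5000, seed = 1)
#' length(panelUnion(ps))  # 2145
#' @export
simulatePanels <- function(panelSizes, nOverlap, universeSize, seed = 1L) {
  stopifnot(length(panelSizes) >= 1, all(panelSizes >= 1), nOverlap >= 0)
  union_size <- sum(panelSizes) - nOverlap
  if (union_size > universeSize)
    stop("union size ", union_size, " exceeds universe size ", universeSize)
  if (union_size < max(panelSizes))
    stop("overlap structure infeasible: union smaller than largest panel")
  universe <- sprintf("GENE%05d", seq_len(universeSize))
  withr::with_seed(as.integer(seed), {
    pool <- sample(universe, union_size)
    panels <- list()
    used <- character()
    remaining <- nOverlap
    fresh_at <- 1L
    for (nm in names(panelSizes)) {
      size <- panelSizes[[nm]]
      o <- min(remaining, size, length(used))
      overlap_genes <- if (o) sample(used, o) else character()
      n_fresh <- size - o
      if (fresh_at + n_fresh - 1L > union_size)
        stop("overlap structure infeasible for panel ", nm)
      fresh <- if (n_fresh) pool[fresh_at:(fresh_at + n_fresh - 1L)]
      else character()
      fresh_at <- fresh_at + n_fresh
      panels[[nm]] <- c(overlap_genes, fresh)
      used <- unique(c(used, panels[[nm]]))
      remaining <- remaining - o
    }
    if (remaining > 0)
      stop("could not place ", remaining, " overlap memberships")
    GenePanelSet(panels)
  })
}

#' Simulate a block-structured developmental expression matrix
#'
#' Samples are drawn from a multivariate normal with block-constant
#' correlation on the log scale, then exponentiated to RPKM-like positive
#' values; Spearman statistics are invariant to that monotone transform.
#' The requested within-block correlation is interpreted on the Spearman
#' scale and converted to the Gaussian (Pearson) scale via
#' r = 2 sin(pi rho_s / 6) so the realized Spearman matches the target.
#' Donor ids and BrainSpan-like developmental stage labels (8 weeks post
#' conception to 10 months after birth) are recorded in the sample
#' metadata; samples are generated independently of donor.
#'
#' @param nGenes number of genes.
#' @param nSamples number of samples (>= 3).
#' @param nDonors number of donors recorded in the metadata.
#' @param moduleAssignments integer vector (length \code{nGenes} or a named
#'   map gene -> block id); block 0 = unstructured background.
#' @param withinBlockCorrelation target pairwise Spearman correlation in
#'   (0, 1) within each nonzero block.
#' @param noiseSd standard deviation of additional independent log-scale
#'   noise (0 keeps the realized correlation at the target).
#' @param seed integer seed fixing all randomness.
#' @return an \linkS4class{ExpressionMatrix}.
#' @export
simulateExpression <- function(nGenes, nSamples, nDonors = 24,
                               moduleAssignments = NULL,
                               withinBlockCorrelation = 0.65,
                               noiseSd = 0, seed = 1L) {
  stopifnot(nSamples >= 3, nGenes >= 2)
  if (is.null(moduleAssignments)) moduleAssignments <- rep(0L, nGenes)
  if (length(moduleAssignments) != nGenes)
    stop("moduleAssignments must have one entry per gene")
  rho_s <- withinBlockCorrelation
  if (any(moduleAssignments != 0) && (rho_s <= 0 || rho_s >= 1))
    stop("withinBlockCorrelation must lie in (0, 1): implied block ",
         "covariance is not positive definite otherwise")
  r <- 2 * sin(pi * rho_s / 6)   # Spearman -> Pearson for a bivariate normal
  genes <- if (!is.null(names(moduleAssignments)))
    names(moduleAssignments) else sprintf("GENE%05d", seq_len(nGenes))
  withr::with_seed(as.integer(seed), {
    z <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
                dimnames = list(genes, sprintf("S%04d", seq_len(nSamples))))
    for (b in setdiff(unique(moduleAssignments), 0)) {
      idx <- which(moduleAssignments == b)
      shared <- rnorm(nSamples)
      z[idx, ] <- sqrt(r) * matrix(shared, length(idx), nSamples,
                                   byrow = TRUE) +
        sqrt(1 - r) * z[idx, , drop = FALSE]
    }
    if (noiseSd > 0)
      z <- z + matrix(rnorm(nGenes * nSamples, sd = noiseSd),
                      nGenes, nSamples)
    vals <- exp(z) * 10   # log-normal, RPKM-like scale
    stages <- c("8 pcw", "9 pcw", "12 pcw", "13 pcw", "16 pcw", "17 pcw",
                "19 pcw", "21 pcw", "24 pcw", "26 pcw", "35 pcw", "37 pcw",
                "4 mos", "10 mos")
    meta <- data.frame(
      sample_id = colnames(vals),
      donor_id = sprintf("D%03d", rep_len(seq_len(nDonors), nSamples)),
      stage_label = rep_len(stages, nSamples),
      age_value = rep_len(c(8, 9, 12, 13, 16, 17, 19, 21, 24, 26, 35, 37,
                            4, 10), nSamples),
      age_unit = rep_len(c(rep("pcw", 12), "mos", "mos"), nSamples))
    em <- ExpressionMatrix(vals, meta)
    SummarizedExperiment::rowData(em)$block <- moduleAssignments
    em
  })
}

.LOF_CHOICES <- c("stop_gained", "frameshift_variant",
                  "splice_acceptor_variant", "splice_donor_variant",
                  "start_lost", "stop_lost")

## draw annotation values guaranteeing (or guaranteeing failure of) the
## deleteriousness rules; QC metrics are clean unless a failure mode says
## otherwise
.cleanQC <- function() list(qd = runif(1, 15, 35), fs = runif(1, 0, 10),
                            sor = runif(1, 0.5, 1.5),
                            mq_rank_sum = runif(1, -2, 2),
                            read_pos_rank_sum = runif(1, -2, 2),
                            excess_het_z = runif(1, -1, 1),
                            filter = "PASS")

#' Simulate an annotated trio cohort with planted variants
#'
#' Generates a trio pedigree per family plus an annotated variant table
#' containing (i) planted causal variants that satisfy the full LoF or
#' damaging-missense rule set with clean QC, rarity and the requested
#' inheritance pattern, and (ii) benign background variants each
#' constructed to fail exactly one named filter (site QC, genotype QC,
#' frequency, cohort recurrence, inheritance consistency) or to survive
#' all filters but fail deleteriousness classification. Every generated
#' variant appears exactly once in the truth table with its expected
#' disposition.
#'
#' @param nFamilies number of trio families (>= 1).
#' @param planted list of planted-variant specs; each a list with
#'   \code{family} (index), \code{gene}, \code{category} (\code{lof},
#'   \code{damaging_missense} or \code{benign}), \code{inheritance}
#'   (\code{de_novo}, \code{maternal}, \code{paternal},
#'   \code{compound_het_pair}, \code{x_linked_de_novo}) and optional
#'   \code{chrom}.
#' @param backgroundRate expected benign background variants per family
#'   (Poisson).
#' @param probandSex optional vector of proband sexes per family.
#' @param familyDesign per-family design: \code{"trio"} (default),
#'   \code{"duo_mother"}/\code{"duo_father"} (one parent unavailable) or
#'   \code{"singleton"}; recycled to \code{nFamilies}. Compound
#'   heterozygous plants require a trio (phase comes from parental
#'   genotypes).
#' @param seed integer seed fixing all randomness.
#' @return list with \code{variants} (a \linkS4class{VariantTable}),
#'   \code{pedigree} (a \linkS4class{Pedigree}), \code{truth} (data.frame:
#'   family, chrom, pos, gene, category, inheritance, expected_tier,
#'   expected_failure_filter) and \code{review} (ACMG class and phenotype
#'   consistency for the reviewer-input file).
#' @export
simulateCohort <- function(nFamilies, planted = list(),
                           backgroundRate = 10, probandSex = NULL,
                           familyDesign = "trio", seed = 1L) {
  stopifnot(nFamilies >= 1)
  fams <- sprintf("FAM%03d", seq_len(nFamilies))
  familyDesign <- rep_len(familyDesign, nFamilies)
  stopifnot(all(familyDesign %in% c("trio", "duo_mother", "duo_father",
                                    "singleton")))
  for (pv in planted)
    if (pv$inheritance == "compound_het_pair" &&
        familyDesign[pv$family] != "trio")
      stop("compound heterozygous plants require a trio family ",
           "(family ", pv$family, " is ", familyDesign[pv$family], ")")
  withr::with_seed(as.integer(seed), {
    if (is.null(probandSex))
      probandSex <- sample(c("male", "female"), nFamilies, replace = TRUE)
    ped <- do.call(rbind, lapply(seq_len(nFamilies), function(i) {
      fam <- fams[i]
      design <- familyDesign[i]
      has_f <- design %in% c("trio", "duo_father")
      has_m <- design %in% c("trio", "duo_mother")
      rows <- data.frame(
        family = fam,
        id = paste0(fam, c("_P", if (has_f) "_F", if (has_m) "_M")),
        father = c(if (has_f) paste0(fam, "_F") else "",
                   rep("", has_f + has_m)),
        mother = c(if (has_m) paste0(fam, "_M") else "",
                   rep("", has_f + has_m)),
        sex = c(probandSex[i], if (has_f) "male", if (has_m) "female"),
        affected = c("affected", rep("unaffected", has_f + has_m)),
        twin = "")
      rows
    }))

    rows <- list(); genos <- list(); truth <- list(); review <- list()
    pos_counter <- 0L
    next_pos <- function() { pos_counter <<- pos_counter + 1000L; pos_counter }

    add_geno <- function(uid, sample, gt, dp = NULL, gq = NULL) {
      genos[[length(genos) + 1L]] <<- data.frame(
        uid = uid, sample = sample, gt = gt,
        dp = if (is.null(dp)) round(runif(1, 20, 60)) else dp,
        gq = if (is.null(gq)) round(runif(1, 30, 99)) else gq)
    }

    plant_scores <- function(category, consequence) {
      ann <- list(pli = NA_real_, loftool = NA_real_,
                  cadd_phred = NA_real_, ada_score = NA_real_,
                  rf_score = NA_real_, sift_call = NA_character_,
                  sift_score = NA_real_, polyphen_call = NA_character_,
                  polyphen_score = NA_real_, mtr_fdr = NA_real_)
      if (category == "lof") {
        if (runif(1) < 0.5) ann$pli <- runif(1, 0.9, 1)
        else ann$loftool <- runif(1, 0, 0.099)
        if (grepl("splice", consequence) && runif(1) < 0.5) {
          ann$ada_score <- runif(1, 0.6, 1)
          ann$rf_score <- runif(1, 0.6, 1)
        } else if (consequence != "frameshift_variant" || runif(1) < 0.5) {
          ann$cadd_phred <- runif(1, 20, 45)
        }
      } else if (category == "damaging_missense") {
        crit <- sample(4, sample(3:4, 1))
        if (1 %in% crit) {
          ann$polyphen_call <- sample(c("probably_damaging",
                                        "possibly_damaging"), 1)
          ann$polyphen_score <- runif(1, 0.5, 1)
        } else {
          ann$polyphen_call <- "benign"; ann$polyphen_score <- runif(1, 0, 0.1)
        }
        if (2 %in% crit) {
          ann$sift_call <- "deleterious"; ann$sift_score <- runif(1, 0, 0.04)
        } else {
          ann$sift_call <- "tolerated"; ann$sift_score <- runif(1, 0.2, 1)
        }
        ann$cadd_phred <- if (3 %in% crit) runif(1, 20, 35)
        else runif(1, 1, 15)
        if (4 %in% crit) ann$mtr_fdr <- runif(1, 0, 0.049)
      } else {   # benign scores: misses every rule
        ann$pli <- runif(1, 0, 0.5); ann$loftool <- runif(1, 0.3, 1)
        ann$cadd_phred <- runif(1, 0, 10)
        ann$sift_call <- "tolerated"; ann$sift_score <- runif(1, 0.3, 1)
        ann$polyphen_call <- "benign"; ann$polyphen_score <- runif(1, 0, 0.1)
      }
      ann
    }

    add_variant <- function(fam, gene, chrom, category, consequence,
                            inheritance, qc = .cleanQC(),
                            gnomad_ac = NA_integer_, gnomad_af = NA_real_,
                            geno_spec = NULL, expected_tier = "none",
                            expected_failure = "none", dp_override = NULL) {
      pos <- next_pos()
      ref <- sample(c("A", "C", "G", "T"), 1)
      alt <- if (consequence == "frameshift_variant")
        paste0(ref, sample(c("A", "C", "G", "T"), 1)) else
          sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      tx <- paste0("ENST", sprintf("%08d", pos))
      ann <- plant_scores(category, consequence)
      row <- data.frame(
        family = fam, chrom = chrom, pos = pos, ref = ref, alt = alt,
        gene = gene, transcript = tx, consequence = consequence,
        gnomad_ac = gnomad_ac, gnomad_af = gnomad_af,
        pli = ann$pli, loftool = ann$loftool, cadd_phred = ann$cadd_phred,
        sift_call = ann$sift_call, sift_score = ann$sift_score,
        polyphen_call = ann$polyphen_call,
        polyphen_score = ann$polyphen_score, mtr_fdr = ann$mtr_fdr,
        ada_score = ann$ada_score, rf_score = ann$rf_score,
        qd = qc$qd, fs = qc$fs, sor = qc$sor,
        mq_rank_sum = qc$mq_rank_sum,
        read_pos_rank_sum = qc$read_pos_rank_sum,
        excess_het_z = qc$excess_het_z, filter = qc$filter)
      uid <- .variantUID(fam, chrom, pos, ref, alt, tx)
      rows[[length(rows) + 1L]] <<- row
      for (gs in geno_spec)
        add_geno(uid, gs$sample, gs$gt, gs$dp, gs$gq)
      truth[[length(truth) + 1L]] <<- data.frame(
        family = fam, chrom = chrom, pos = pos, gene = gene,
        category = category, inheritance = inheritance,
        expected_tier = expected_tier,
        expected_failure_filter = expected_failure)
      uid
    }

    trio_geno <- function(fam, child_gt, father_gt, mother_gt) {
      out <- list(list(sample = paste0(fam, "_P"), gt = child_gt))
      if (paste0(fam, "_F") %in% ped$id)
        out <- c(out, list(list(sample = paste0(fam, "_F"),
                                gt = father_gt)))
      if (paste0(fam, "_M") %in% ped$id)
        out <- c(out, list(list(sample = paste0(fam, "_M"),
                                gt = mother_gt)))
      out
    }

    ## ---- planted causal variants -------------------------------------
    for (pv in planted) {
      fam <- fams[pv$family]
      sex <- probandSex[pv$family]
      category <- pv$category
      inheritance <- pv$inheritance
      chrom <- pv$chrom %||% as.character(sample(1:22, 1))
      consequence <- if (category == "lof") sample(.LOF_CHOICES, 1)
      else if (category == "damaging_missense") "missense_variant"
      else "missense_variant"
      expected_tier <- if (category == "benign") "none" else
        "high_confidence"
      if (inheritance == "compound_het_pair") {
        if (category == "benign") stop("compound het plants must be causal")
        af <- runif(1, 0, 0.0004)
        for (side in c("maternal", "paternal")) {
          gs <- if (side == "maternal")
            trio_geno(fam, "het", "hom_ref", "het")
          else trio_geno(fam, "het", "het", "hom_ref")
          add_variant(fam, pv$gene, chrom, category, consequence,
                      paste0("compound_het_", side), gnomad_ac = 5L,
                      gnomad_af = af, geno_spec = gs,
                      expected_tier = expected_tier)
          review[[length(review) + 1L]] <- .reviewRow(rows, 5L, TRUE)
        }
        next
      }
      if (inheritance == "x_linked_de_novo") {
        chrom <- "X"
        child_gt <- if (sex == "male") "hemi_alt" else "het"
        gs <- trio_geno(fam, child_gt, "hom_ref", "hom_ref")
        add_variant(fam, pv$gene, chrom, category, consequence,
                    "x_linked_de_novo", geno_spec = gs,
                    expected_tier = expected_tier)
        review[[length(review) + 1L]] <- .reviewRow(rows, 5L, TRUE)
        next
      }
      gs <- switch(inheritance,
        de_novo = trio_geno(fam, "het", "hom_ref", "hom_ref"),
        maternal = trio_geno(fam, "het", "hom_ref", "het"),
        paternal = trio_geno(fam, "het", "het", "hom_ref"),
        stop("unknown inheritance: ", inheritance))
      if (inheritance %in% c("maternal", "paternal")) {
        ## transmitting parent must be affected for the variant to remain
        parent_id <- paste0(fam, if (inheritance == "maternal") "_M"
                            else "_F")
        if (!parent_id %in% ped$id)
          stop("inherited plant needs the transmitting parent in the ",
               "family design (family ", pv$family, ")")
        ped$affected[ped$id == parent_id] <- "affected"
      }
      add_variant(fam, pv$gene, chrom, category, consequence, inheritance,
                  geno_spec = gs, expected_tier = expected_tier)
      review[[length(review) + 1L]] <- .reviewRow(
        rows, if (category == "benign") 2L else sample(4:5, 1),
        category != "benign")
    }

    ## ---- benign background variants ----------------------------------
    modes <- c("site_qc", "genotype_qc", "frequency", "recurrence",
               "inheritance", "not_deleterious")
    if (nFamilies < 2) modes <- setdiff(modes, "recurrence")
    bg_counter <- 0L
    for (i in seq_len(nFamilies)) {
      fam <- fams[i]
      n_bg <- rpois(1, backgroundRate)
      unaffected_parent <- function(fam_id) {
        ids <- intersect(paste0(fam_id, c("_F", "_M")), ped$id)
        ids[ped$affected[match(ids, ped$id)] == "unaffected"]
      }
      for (k in seq_len(n_bg)) {
        mode <- sample(modes, 1)
        ## transmission-based failure modes need an unaffected carrier
        if (mode == "inheritance" && !length(unaffected_parent(fam)))
          mode <- "frequency"
        bg_counter <- bg_counter + 1L   # unique background genes
        gene <- sprintf("BGENE%05d", bg_counter)
        chrom <- as.character(sample(1:22, 1))
        qc <- .cleanQC()
        gnomad_ac <- NA_integer_; gnomad_af <- NA_real_
        gs <- trio_geno(fam, "het", "hom_ref", "hom_ref")
        inheritance <- "de_novo"
        category <- if (mode == "not_deleterious") "benign" else
          sample(c("lof", "damaging_missense"), 1)
        consequence <- if (category == "lof") sample(.LOF_CHOICES, 1)
        else "missense_variant"
        if (mode == "site_qc") {
          bad <- sample(c("filter_flag", "excess_het", "qd", "fs", "sor",
                          "mq_rank_sum", "read_pos_rank_sum"), 1)
          switch(bad,
            filter_flag = { qc$filter <- "VQSRTrancheSNP99.70to100.00" },
            excess_het = { qc$excess_het_z <- runif(1, 4.6, 10) },
            qd = { qc$qd <- runif(1, 0, 1.9) },
            fs = { qc$fs <- runif(1, 201, 300) },
            sor = { qc$sor <- runif(1, 10.1, 20) },
            mq_rank_sum = { qc$mq_rank_sum <- runif(1, -20, -12.7) },
            read_pos_rank_sum = {
              qc$read_pos_rank_sum <- runif(1, -30, -20.1) })
          if (bad == "mq_rank_sum")  # SNV-only rule
            consequence <- if (category == "lof") "stop_gained" else
              consequence
        } else if (mode == "genotype_qc") {
          idx <- sample(length(gs), 1)
          gs[[idx]]$dp <- sample(1:10, 1)
          gs[[idx]]$gq <- sample(1:20, 1)
        } else if (mode == "frequency") {
          gnomad_ac <- sample(3:50, 1)
          gnomad_af <- runif(1, 0.001, 0.01)
        } else if (mode == "recurrence") {
          carriers <- unlist(lapply(fams[-i], unaffected_parent))
          if (!length(carriers)) { gnomad_ac <- sample(3:50, 1)
          } else gs[[length(gs) + 1L]] <- list(
            sample = sample(carriers, 1), gt = "het")
          if (!length(carriers)) mode <- "frequency"
        } else if (mode == "inheritance") {
          carrier <- sample(unaffected_parent(fam), 1)
          side <- if (endsWith(carrier, "_M")) "maternal" else "paternal"
          gs <- if (side == "maternal")
            trio_geno(fam, "het", "hom_ref", "het")
          else trio_geno(fam, "het", "het", "hom_ref")
          inheritance <- side
        }
        ## ensure the fs/sor violations use class-appropriate thresholds:
        ## values above the indel bounds violate both classes
        add_variant(fam, gene, chrom,
                    if (mode == "not_deleterious") "benign" else category,
                    consequence, inheritance, qc = qc,
                    gnomad_ac = gnomad_ac, gnomad_af = gnomad_af,
                    geno_spec = gs, expected_tier = "none",
                    expected_failure = if (mode == "not_deleterious")
                      "not_deleterious" else mode)
        review[[length(review) + 1L]] <- .reviewRow(rows, 2L, FALSE)
      }
    }

    v <- do.call(rbind, rows)
    g <- do.call(rbind, genos)
    vt <- VariantTable(v, g)
    list(variants = vt, pedigree = Pedigree(ped),
         truth = do.call(rbind, truth),
         review = do.call(rbind, review))
  })
}

.reviewRow <- function(rows, acmg, consistent) {
  last <- rows[[length(rows)]]
  data.frame(family = last$family, chrom = last$chrom, pos = last$pos,
             ref = last$ref, alt = last$alt, acmg_class = acmg,
             phenotype_consistent = consistent)
}
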