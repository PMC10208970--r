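#' Filtering thresholds for trio variant triage
#'
#' Returns the threshold set used by the site-QC, genotype-QC, frequency and
#' structural-variant filters. Defaults follow GATK-style hard filtering of
#' joint-called genomes: SNVs are dropped for QD < 2, FS > 60, SOR > 3,
#' MQRankSum < -12.6 or ReadPosRankSum < -8; indels for QD < 2, FS > 200,
#' SOR > 10 or ReadPosRankSum < -20; any class for excess-heterozygosity
#' Z > 4.5 or a non-PASS filter flag. Genotypes must have DP > 10 and
#' GQ > 20 (strict) in the proband and every sequenced relative. Rarity:
#' gnomAD allele count <= 2 across all populations for dominant/de novo
#' models, allele frequency < 0.05\% for compound-heterozygous models.
#' Structural variants are excluded when seen in more than two cohort
#' families or at population frequency >= 0.05\%.
#'
#' @param ... named overrides of any default listed below.
#' @return a named list of thresholds with class \code{"FilterConfig"}.
#' @examples
#' cfg <- filterConfig()
#' cfg$ac_max
#' @export
filterConfig <- function(...) {
  cfg <- list(
    qd_min = 2, excess_het_z_max = 4.5,
    snv_fs_max = 60, snv_sor_max = 3, snv_mq_rank_sum_min = -12.6,
    snv_read_pos_rank_sum_min = -8,
    indel_fs_max = 200, indel_sor_max = 10,
    indel_read_pos_rank_sum_min = -20,
    dp_min = 10, gq_min = 20,
    ac_max = 2, comphet_af_max = 0.0005,
    sv_families_max = 2, sv_af_max = 0.0005)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown filter setting(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(all(vapply(cfg, is.finite, logical(1))))
  structure(cfg, class = "FilterConfig")
}

## Site-level QC. Missing metrics never trigger a drop: only explicitly
## flagged records and explicit threshold violations do. The reason names
## the first violated rule in a fixed order.
#' Site quality filter
#'
#' @param x a \linkS4class{VariantTable}.
#' @param cfg a \code{\link{filterConfig}}.
#' @return data.frame with \code{uid}, \code{keep}, \code{reason}
#'   (\code{""} when kept).
#' @export
filterSiteQC <- function(x, cfg = filterConfig()) {
  v <- variants(x)
  n <- nrow(v)
  reason <- rep("", n)
  viol <- function(x, bad) !is.na(x) & bad
  hit <- function(cond, label) reason <<- ifelse(reason == "" & cond,
                                                 label, reason)
  hit(!v$filter %in% c("PASS", "."), "filter_flag")
  hit(viol(v$excess_het_z, v$excess_het_z > cfg$excess_het_z_max),
      "excess_het")
  hit(viol(v$qd, v$qd < cfg$qd_min), "qd")
  snv <- v$variant_class == "snv"
  hit(viol(v$fs, ifelse(snv, v$fs > cfg$snv_fs_max,
                        v$fs > cfg$indel_fs_max)), "fs")
  hit(viol(v$sor, ifelse(snv, v$sor > cfg$snv_sor_max,
                         v$sor > cfg$indel_sor_max)), "sor")
  hit(snv & viol(v$mq_rank_sum, v$mq_rank_sum < cfg$snv_mq_rank_sum_min),
      "mq_rank_sum")
  hit(viol(v$read_pos_rank_sum,
           ifelse(snv, v$read_pos_rank_sum < cfg$snv_read_pos_rank_sum_min,
                  v$read_pos_rank_sum < cfg$indel_read_pos_rank_sum_min)),
      "read_pos_rank_sum")
  data.frame(uid = v$uid, keep = reason == "", reason = reason)
}

#' Genotype quality filter
#'
#' Keeps a variant only when the proband and every sequenced relative of
#' its family have DP > 10 and GQ > 20 (strict inequalities; DP = 10
#' fails). A relative is "sequenced" when it has a genotype record for the
#' variant.
#'
#' @inheritParams filterSiteQC
#' @param ped a \linkS4class{Pedigree}.
#' @return data.frame with \code{uid}, \code{keep}, \code{reason}.
#' @export
filterGenotypeQC <- function(x, ped, cfg = filterConfig()) {
  v <- variants(x)
  g <- genotypes(x)
  p <- pedTable(ped)
  fam_members <- split(p$id, p$family)
  pass_by_uid <- rep(TRUE, nrow(v))
  if (nrow(g)) {
    g_fam <- fam_members[v$family[match(g$uid, v$uid)]]
    in_family <- mapply(function(s, mem) s %in% mem, g$sample, g_fam)
    gg <- g[in_family, , drop = FALSE]
    ok <- !is.na(gg$dp) & !is.na(gg$gq) & gg$dp > cfg$dp_min &
      gg$gq > cfg$gq_min
    bad_uid <- unique(gg$uid[!ok])
    pass_by_uid <- !(v$uid %in% bad_uid)
  }
  ## a variant with no genotype for its proband cannot be assessed
  pro <- probands(ped)
  has_pro <- v$uid %in% g$uid[g$sample %in% pro]
  pass_by_uid <- pass_by_uid & has_pro
  data.frame(uid = v$uid, keep = pass_by_uid,
             reason = ifelse(pass_by_uid, "", "genotype_qc"))
}

#' Population-frequency filter
#'
#' Dominant/de-novo mode keeps alleles absent from gnomAD or with allele
#' count <= 2 in all populations; compound-heterozygous mode keeps alleles
#' absent from gnomAD or with mean allele frequency < 0.05\%.
#'
#' @inheritParams filterSiteQC
#' @param mode \code{"dominant_denovo"} or \code{"compound_het"}.
#' @return data.frame with \code{uid}, \code{keep}, \code{reason}.
#' @export
filterFrequency <- function(x, cfg = filterConfig(),
                            mode = c("dominant_denovo", "compound_het")) {
  mode <- match.arg(mode)
  v <- variants(x)
  keep <- if (mode == "dominant_denovo")
    is.na(v$gnomad_ac) | v$gnomad_ac <= cfg$ac_max
  else
    is.na(v$gnomad_af) | v$gnomad_af < cfg$comphet_af_max
  data.frame(uid = v$uid, keep = keep,
             reason = ifelse(keep, "", "frequency"))
}

#' Cohort recurrence filter
#'
#' Drops an allele when the identical allele (chrom, pos, ref, alt) is
#' carried by an unaffected individual in a different cohort family.
#' Within-family transmission from an unaffected parent is handled by the
#' inheritance-consistency flag, not here. Matching is exact; no fuzzy
#' matching of nearby indels.
#'
#' @inheritParams filterGenotypeQC
#' @return data.frame with \code{uid}, \code{keep}, \code{reason}.
#' @export
filterCohortRecurrence <- function(x, ped) {
  v <- variants(x)
  g <- genotypes(x)
  p <- pedTable(ped)
  allele <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  keep <- rep(TRUE, nrow(v))
  if (nrow(g)) {
    carrier <- g[g$gt %in% c("het", "hom_alt", "hemi_alt"), , drop = FALSE]
    carrier$affected <- p$affected[match(carrier$sample, p$id)]
    carrier$sample_family <- p$family[match(carrier$sample, p$id)]
    carrier$allele <- allele[match(carrier$uid, v$uid)]
    bad <- carrier[!is.na(carrier$affected) &
                     carrier$affected == "unaffected", , drop = FALSE]
    if (nrow(bad)) {
      ## allele is excluded for families other than the carrier's own
      for (i in seq_len(nrow(v))) {
        hits <- bad$allele == allele[i] & bad$sample_family != v$family[i]
        if (any(hits)) keep[i] <- FALSE
      }
    }
  }
  data.frame(uid = v$uid, keep = keep,
             reason = ifelse(keep, "", "recurrence"))
}

## genotype lookup helper: named vector sample -> gt for one variant
.gtOf <- function(g, uid, sample) {
  hit <- g$gt[g$uid == uid & g$sample == sample]
  if (length(hit)) hit[1] else NA_character_
}

## O(1) lookup table (uid \r sample) -> gt for hot loops
.gtIndex <- function(g) {
  env <- new.env(hash = TRUE, parent = emptyenv(), size = nrow(g) + 1L)
  if (nrow(g))
    for (i in seq_len(nrow(g)))
      assign(paste(g$uid[i], g$sample[i], sep = "\r"), g$gt[i], envir = env)
  function(uid, sample) {
    val <- get0(paste(uid, sample, sep = "\r"), envir = env,
                ifnotfound = NA_character_)
    val
  }
}

.carries <- function(gt) !is.na(gt) & gt %in% c("het", "hom_alt", "hemi_alt")

#' Infer the inheritance model of each variant
#'
#' For each variant, compares the proband genotype with the sequenced
#' parents': de novo when both parents are homozygous reference; inherited
#' maternal/paternal when exactly that parent carries the allele;
#' homozygous recessive when the proband is homozygous alternate and both
#' parents are heterozygous; unknown when transmission is unresolvable
#' (duos and singletons, or both parents carrying). Chromosome X variants
#' are flagged \code{x_linked} with sex-aware zygosity (hemizygous male,
#' heterozygous female). An inherited variant is candidate-eligible
#' (\code{consistent}) only when the transmitting parent is affected,
#' except maternal transmission to a hemizygous male on X, where unaffected
#' carrier mothers are expected.
#'
#' @inheritParams filterGenotypeQC
#' @param strict error when a proband genotype is missing (default); with
#'   \code{strict = FALSE} such variants are returned as non-carriers,
#'   which the filter cascade has already dropped at genotype QC.
#' @return data.frame with \code{uid}, \code{model}, \code{x_linked},
#'   \code{consistent}, \code{carrier} (does the proband carry the
#'   allele), and \code{proband}.
#' @export
inferInheritance <- function(x, ped, strict = TRUE) {
  v <- variants(x)
  g <- genotypes(x)
  p <- pedTable(ped)
  pro <- probands(ped)
  gt_lookup <- .gtIndex(g)
  n <- nrow(v)
  out <- data.frame(uid = v$uid, model = rep("unknown", n),
                    x_linked = rep(FALSE, n), consistent = rep(TRUE, n),
                    carrier = rep(FALSE, n),
                    proband = rep(NA_character_, n))
  for (i in seq_len(nrow(v))) {
    fam <- v$family[i]
    if (!fam %in% names(pro)) next
    pid <- pro[[fam]]
    out$proband[i] <- pid
    prow <- p[p$id == pid, ]
    gp <- gt_lookup(v$uid[i], pid)
    if (is.na(gp)) {
      if (strict) stop("proband genotype missing for variant ", v$uid[i])
      next
    }
    is_x <- v$chrom[i] %in% c("X", "chrX")
    out$x_linked[i] <- is_x
    if (!.carries(gp)) next
    out$carrier[i] <- TRUE
    fa <- prow$father; mo <- prow$mother
    gfa <- if (nzchar(fa)) gt_lookup(v$uid[i], fa) else NA_character_
    gmo <- if (nzchar(mo)) gt_lookup(v$uid[i], mo) else NA_character_
    fa_seq <- !is.na(gfa) & gfa != "missing"
    mo_seq <- !is.na(gmo) & gmo != "missing"
    fa_car <- fa_seq && .carries(gfa)
    mo_car <- mo_seq && .carries(gmo)
    model <- "unknown"
    if (is_x && prow$sex == "male") {
      ## hemizygous male: only the maternal allele is informative
      if (mo_seq) model <- if (mo_car) "inherited_maternal" else "de_novo"
    } else if (fa_seq && mo_seq) {
      if (!fa_car && !mo_car) model <- "de_novo"
      else if (gp == "hom_alt" && gfa == "het" && gmo == "het")
        model <- "homozygous_recessive"
      else if (mo_car && !fa_car) model <- "inherited_maternal"
      else if (fa_car && !mo_car) model <- "inherited_paternal"
      ## both parents carriers of a het proband: ambiguous -> unknown
    } else if (fa_seq && !mo_seq) {
      if (fa_car) model <- "inherited_paternal"
    } else if (mo_seq && !fa_seq) {
      if (mo_car) model <- "inherited_maternal"
    }
    out$model[i] <- model
    if (model %in% c("inherited_maternal", "inherited_paternal")) {
      parent <- if (model == "inherited_maternal") mo else fa
      parent_aff <- p$affected[match(parent, p$id)]
      consistent <- identical(parent_aff, "affected")
      if (is_x && model == "inherited_maternal" && prow$sex == "male")
        consistent <- TRUE   # unaffected carrier mothers expected on X
      out$consistent[i] <- consistent
    }
  }
  out
}

#' Pair compound heterozygotes within a gene
#'
#' A pair requires one maternally and one paternally transmitted
#' heterozygous variant in the same gene in the proband, with phase
#' inferred from parental genotypes only. With m maternal and p paternal
#' hets, all m x p pairs are reported.
#'
#' @inheritParams filterGenotypeQC
#' @param inheritance output of \code{\link{inferInheritance}} (computed
#'   when omitted).
#' @return data.frame with \code{uid_maternal}, \code{uid_paternal},
#'   \code{family}, \code{gene}.
#' @export
pairCompoundHets <- function(x, ped, inheritance = NULL) {
  v <- variants(x)
  g <- genotypes(x)
  if (is.null(inheritance)) inheritance <- inferInheritance(x, ped)
  inh <- inheritance[match(v$uid, inheritance$uid), ]
  gt_lookup <- .gtIndex(g)
  pro_gt <- vapply(seq_len(nrow(v)), function(i) {
    if (is.na(inh$proband[i])) return(NA_character_)
    gt_lookup(v$uid[i], inh$proband[i])
  }, character(1))
  het <- !is.na(pro_gt) & pro_gt == "het"
  out <- list()
  for (key in unique(paste(v$family, v$gene, sep = "\r"))) {
    idx <- which(paste(v$family, v$gene, sep = "\r") == key & het)
    mat <- idx[inh$model[idx] == "inherited_maternal"]
    pat <- idx[inh$model[idx] == "inherited_paternal"]
    if (length(mat) && length(pat)) {
      grid <- expand.grid(m = mat, p = pat)
      out[[length(out) + 1L]] <- data.frame(
        uid_maternal = v$uid[grid$m], uid_paternal = v$uid[grid$p],
        family = v$family[grid$m], gene = v$gene[grid$m])
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(uid_maternal = character(), uid_paternal = character(),
                  family = character(), gene = character())
}

#' Filter structural-variant calls
#'
#' Drops calls observed in more than two cohort families (technical-artefact
#' guard) or with population frequency >= 0.05\%; a missing frequency is
#' not a drop.
#'
#' @param sv data.frame of calls from \code{\link{readStructuralVariants}}.
#' @param cfg a \code{\link{filterConfig}}.
#' @return the kept calls, with a \code{reason} attribute-free contract:
#'   dropped rows are simply absent.
#' @export
filterSV <- function(sv, cfg = filterConfig()) {
  keep <- (sv$families_observed <= cfg$sv_families_max) &
    (is.na(sv$sv_af) | sv$sv_af < cfg$sv_af_max)
  sv[keep, , drop = FALSE]
}

#' Run the full triage filter cascade
#'
#' Applies, in order: site QC, genotype QC, cohort recurrence, proband
#' carrier status, population frequency (dominant/de-novo rule, with the
#' compound-heterozygous frequency rescue for paired hets), and
#' inheritance-model consistency. Returns the surviving pool together with
#' a per-variant attrition log whose counts conserve the input
#' (kept + dropped-per-reason = input).
#'
#' @inheritParams filterGenotypeQC
#' @return list with \code{pool} (a \linkS4class{VariantTable} restricted to
#'   survivors), \code{inheritance} (per-surviving-variant calls including
#'   \code{compound_het} models with partner uid), and \code{attrition}
#'   (data.frame uid, family, kept, reason).
#' @export
filterVariants <- function(x, ped, cfg = filterConfig()) {
  v <- variants(x)
  reason <- rep("", nrow(v))
  apply_step <- function(res) {
    idx <- match(v$uid, res$uid)
    reason <<- ifelse(reason == "" & !res$keep[idx], res$reason[idx], reason)
  }
  apply_step(filterSiteQC(x, cfg))
  apply_step(filterGenotypeQC(x, ped, cfg))
  apply_step(filterCohortRecurrence(x, ped))

  inh <- inferInheritance(x, ped, strict = FALSE)
  idx <- match(v$uid, inh$uid)
  reason <- ifelse(reason == "" & !inh$carrier[idx], "not_in_proband",
                   reason)

  freq_dom <- filterFrequency(x, cfg, "dominant_denovo")
  freq_ch <- filterFrequency(x, cfg, "compound_het")
  ## compound-het pairing among variants still alive at this point
  alive <- reason == ""
  sub <- VariantTable(v[alive, , drop = FALSE],
                      genotypes(x)[genotypes(x)$uid %in% v$uid[alive], ,
                                   drop = FALSE])
  pairs <- pairCompoundHets(sub, ped, inh[match(variants(sub)$uid, inh$uid), ])
  comphet_uid <- unique(c(pairs$uid_maternal, pairs$uid_paternal))
  comphet_ok <- v$uid %in% comphet_uid &
    freq_ch$keep[match(v$uid, freq_ch$uid)]
  reason <- ifelse(reason == "" & !freq_dom$keep[idx] & !comphet_ok,
                   "frequency", reason)

  model <- inh$model[idx]
  eligible <- model %in% c("de_novo", "homozygous_recessive", "unknown") |
    (model %in% c("inherited_maternal", "inherited_paternal") &
       inh$consistent[idx]) |
    (v$uid %in% comphet_uid)
  reason <- ifelse(reason == "" & !eligible, "inheritance", reason)

  kept <- reason == ""
  pool <- VariantTable(v[kept, , drop = FALSE],
                       genotypes(x)[genotypes(x)$uid %in% v$uid[kept], ,
                                    drop = FALSE])
  inh_out <- inh[match(v$uid[kept], inh$uid), , drop = FALSE]
  inh_out$model[inh_out$uid %in% comphet_uid &
                  inh_out$uid %in% variants(pool)$uid &
                  inh_out$model %in% c("inherited_maternal",
                                       "inherited_paternal") &
                  !freq_dom$keep[match(inh_out$uid, freq_dom$uid)]] <-
    "compound_het"
  partner <- rep(NA_character_, nrow(inh_out))
  m1 <- match(inh_out$uid, pairs$uid_maternal)
  partner[!is.na(m1)] <- pairs$uid_paternal[m1[!is.na(m1)]]
  m2 <- match(inh_out$uid, pairs$uid_paternal)
  partner[!is.na(m2)] <- pairs$uid_maternal[m2[!is.na(m2)]]
  inh_out$partner <- partner
  rownames(inh_out) <- NULL
  list(pool = pool, inheritance = inh_out,
       attrition = data.frame(uid = v$uid, family = v$family, kept = kept,
                              reason = ifelse(kept, "", reason)))
}
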