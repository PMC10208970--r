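test_that("site QC applies class-specific thresholds and names reasons", {
  cfg <- filterConfig()
  rows <- rbind(
    makeVariantRow(pos = 1, qd = 1.5),                       # QD < 2
    makeVariantRow(pos = 2, ref = "A", alt = "AT", fs = 150, sor = 5),
    makeVariantRow(pos = 3, fs = 150, sor = 5),              # SNV bounds
    makeVariantRow(pos = 4, qd = NA, fs = NA, sor = NA, mq_rank_sum = NA,
                   read_pos_rank_sum = NA, excess_het_z = NA),
    makeVariantRow(pos = 5, filter = "VQSRTrancheSNP99.70to100.00"),
    makeVariantRow(pos = 6, excess_het_z = 4.6),
    makeVariantRow(pos = 7, ref = "A", alt = "AT", mq_rank_sum = -15))
  vt <- VariantTable(rows, data.frame())
  res <- filterSiteQC(vt, cfg)
  expect_equal(res$keep, c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$reason[1], "qd")
  expect_equal(res$reason[3], "fs")         # first violated rule named
  expect_equal(res$reason[5], "filter_flag")
  expect_equal(res$reason[6], "excess_het")
  ## MQRankSum applies to SNVs only (row 7 is an indel)
})

test_that("genotype QC uses strict DP > 10 and GQ > 20 over the family", {
  ped <- makeTrioPed()
  row <- makeVariantRow()
  mk <- function(pdp, pgq, fdp = 30, fgq = 99) {
    g <- rbind(
      makeGenoRows(row, FAM001_P = "het", dp = pdp, gq = pgq),
      makeGenoRows(row, FAM001_F = "hom_ref", dp = fdp, gq = fgq),
      makeGenoRows(row, FAM001_M = "hom_ref", dp = 30, gq = 99))
    VariantTable(row, g)
  }
  expect_true(filterGenotypeQC(mk(11, 21), ped)$keep)   # boundary + 1
  expect_false(filterGenotypeQC(mk(10, 99), ped)$keep)  # DP = 10 fails
  expect_false(filterGenotypeQC(mk(40, 20), ped)$keep)  # GQ = 20 fails
  expect_false(filterGenotypeQC(mk(40, 99, fdp = 10), ped)$keep)

  ## duo: only sequenced members are checked
  duo <- Pedigree(data.frame(
    family = "FAM001", id = c("FAM001_P", "FAM001_F"),
    father = c("FAM001_F", ""), mother = "",
    sex = "male", affected = c("affected", "unaffected"), twin = ""))
  g <- rbind(makeGenoRows(row, FAM001_P = "het", dp = 30, gq = 99),
             makeGenoRows(row, FAM001_F = "hom_ref", dp = 30, gq = 99))
  expect_true(filterGenotypeQC(VariantTable(row, g), duo)$keep)
})

test_that("frequency filter distinguishes dominant and compound-het modes", {
  rows <- rbind(makeVariantRow(pos = 1, gnomad_ac = 2, gnomad_af = 0.001),
                makeVariantRow(pos = 2, gnomad_ac = 3, gnomad_af = 4e-4),
                makeVariantRow(pos = 3))
  vt <- VariantTable(rows, data.frame())
  dom <- filterFrequency(vt, mode = "dominant_denovo")
  expect_equal(dom$keep, c(TRUE, FALSE, TRUE))   # AC <= 2; missing keeps
  ch <- filterFrequency(vt, mode = "compound_het")
  expect_equal(ch$keep, c(FALSE, TRUE, TRUE))    # AF < 0.05%
})

test_that("cohort recurrence drops alleles seen in other families' unaffected members", {
  ped <- Pedigree(rbind(pedTable(makeTrioPed("FAM001")),
                        pedTable(makeTrioPed("FAM002"))))
  row1 <- makeVariantRow(family = "FAM001", pos = 500)
  row2 <- makeVariantRow(family = "FAM002", pos = 500)  # same allele
  g <- rbind(makeGenoRows(row1, FAM001_P = "het"),
             makeGenoRows(row2, FAM002_P = "het",
                          FAM002_F = "het"))   # unaffected father carries
  vt <- VariantTable(rbind(row1, row2), g)
  res <- filterCohortRecurrence(vt, ped)
  expect_false(res$keep[1])   # FAM001's copy: unaffected carrier elsewhere
  expect_true(res$keep[2])    # carrier is in FAM002's own family

  ## allele carried only by two affected probands is kept
  g2 <- rbind(makeGenoRows(row1, FAM001_P = "het"),
              makeGenoRows(row2, FAM002_P = "het"))
  expect_true(all(filterCohortRecurrence(VariantTable(rbind(row1, row2),
                                                      g2), ped)$keep))
  ## empty cohort index
  expect_true(filterCohortRecurrence(VariantTable(row1, data.frame()),
                                     ped)$keep)
})

test_that("inheritance inference matches a brute-force rule table over all trio configurations", {
  ped <- makeTrioPed(probandSex = "female")
  gts <- c("hom_ref", "het", "hom_alt")
  for (chrom in c("7", "X")) {
    for (cp in c("het", "hom_alt")) for (gf in gts) for (gm in gts) {
      row <- makeVariantRow(chrom = chrom, pos = 1000)
      g <- rbind(makeGenoRows(row, FAM001_P = cp),
                 makeGenoRows(row, FAM001_F = gf),
                 makeGenoRows(row, FAM001_M = gm))
      vt <- VariantTable(row, g)
      got <- inferInheritance(vt, ped)
      ## independent literal rules
      fa <- gf != "hom_ref"; mo <- gm != "hom_ref"
      want <- if (!fa && !mo) "de_novo"
      else if (cp == "hom_alt" && gf == "het" && gm == "het")
        "homozygous_recessive"
      else if (mo && !fa) "inherited_maternal"
      else if (fa && !mo) "inherited_paternal"
      else "unknown"
      expect_equal(got$model, want,
                   info = paste(chrom, cp, gf, gm))
      expect_equal(got$x_linked, chrom == "X")
    }
  }
})

test_that("X-linked male inheritance is maternal-aware and duos resolve to unknown", {
  ped <- makeTrioPed(probandSex = "male")
  ## hemizygous male, mother het carrier: maternal X-linked, consistent
  ## despite the unaffected carrier mother
  row <- makeVariantRow(chrom = "X")
  g <- rbind(makeGenoRows(row, FAM001_P = "hemi_alt"),
             makeGenoRows(row, FAM001_F = "hom_ref"),
             makeGenoRows(row, FAM001_M = "het"))
  got <- inferInheritance(VariantTable(row, g), ped)
  expect_equal(got$model, "inherited_maternal")
  expect_true(got$x_linked)
  expect_true(got$consistent)

  ## hemizygous male, mother hom_ref: de novo without parent attribution
  g2 <- rbind(makeGenoRows(row, FAM001_P = "hemi_alt"),
              makeGenoRows(row, FAM001_F = "hom_ref"),
              makeGenoRows(row, FAM001_M = "hom_ref"))
  expect_equal(inferInheritance(VariantTable(row, g2), ped)$model,
               "de_novo")

  ## duo with missing father, allele absent in mother -> unknown
  duo <- Pedigree(data.frame(
    family = "FAM001", id = c("FAM001_P", "FAM001_M"),
    father = "", mother = c("FAM001_M", ""),
    sex = c("female", "female"), affected = c("affected", "unaffected"),
    twin = ""))
  row3 <- makeVariantRow(chrom = "2")
  g3 <- rbind(makeGenoRows(row3, FAM001_P = "het"),
              makeGenoRows(row3, FAM001_M = "hom_ref"))
  expect_equal(inferInheritance(VariantTable(row3, g3), duo)$model,
               "unknown")

  ## proband genotype missing errors in strict mode
  g4 <- makeGenoRows(row3, FAM001_M = "hom_ref")
  expect_error(inferInheritance(VariantTable(row3, g4), duo), "missing")
})

test_that("inherited variants from unaffected parents are flagged inconsistent", {
  ped_df <- pedTable(makeTrioPed())
  row <- makeVariantRow()
  g <- rbind(makeGenoRows(row, FAM001_P = "het"),
             makeGenoRows(row, FAM001_F = "hom_ref"),
             makeGenoRows(row, FAM001_M = "het"))
  vt <- VariantTable(row, g)
  expect_false(inferInheritance(vt, Pedigree(ped_df))$consistent)
  ped_df$affected[ped_df$id == "FAM001_M"] <- "affected"
  got <- inferInheritance(vt, Pedigree(ped_df))
  expect_equal(got$model, "inherited_maternal")
  expect_true(got$consistent)
})

test_that("compound het pairing enumerates maternal x paternal het combinations", {
  ped <- makeTrioPed()
  mk <- function(pos, fg, mg) {
    row <- makeVariantRow(pos = pos, gene = "GENE1")
    list(row = row,
         g = rbind(makeGenoRows(row, FAM001_P = "het"),
                   makeGenoRows(row, FAM001_F = fg),
                   makeGenoRows(row, FAM001_M = mg)))
  }
  build <- function(...) {
    parts <- list(...)
    VariantTable(do.call(rbind, lapply(parts, `[[`, "row")),
                 do.call(rbind, lapply(parts, `[[`, "g")))
  }
  ## one maternal + one paternal -> one pair
  vt <- build(mk(1, "hom_ref", "het"), mk(2, "het", "hom_ref"))
  expect_equal(nrow(pairCompoundHets(vt, ped)), 1L)
  ## two maternal -> none
  vt2 <- build(mk(1, "hom_ref", "het"), mk(2, "hom_ref", "het"))
  expect_equal(nrow(pairCompoundHets(vt2, ped)), 0L)
  ## 2 maternal + 1 paternal -> 2 pairs (brute force over combinations)
  vt3 <- build(mk(1, "hom_ref", "het"), mk(2, "hom_ref", "het"),
               mk(3, "het", "hom_ref"))
  pairs <- pairCompoundHets(vt3, ped)
  expect_equal(nrow(pairs), 2L)
  expect_setequal(pairs$uid_paternal, variants(vt3)$uid[3])
})

test_that("SV filter drops recurrent and common calls", {
  sv <- data.frame(
    family = "F1", chrom = c("2", "3", "2"), start = c(1e6, 2e6, 230641603),
    end = c(1.1e6, 2.2e6, 230701402), sv_type = "DUP", caller = "manta",
    sv_af = c(4e-4, 6e-4, NA), families_observed = c(1L, 1L, 1L))
  kept <- filterSV(sv)
  expect_equal(nrow(kept), 2L)            # af 6e-4 >= 0.05% dropped
  expect_true(230641603 %in% kept$start)  # de novo dup, af missing: kept
  sv$families_observed <- c(3L, 1L, 2L)
  expect_equal(nrow(filterSV(sv)), 1L)    # > 2 families dropped
})

test_that("the filter cascade equals the brute-force oracle and conserves attrition", {
  for (s in 1:5) {
    sim <- simulateCohort(6, planted = list(
      list(family = 1, gene = "C1", category = "lof",
           inheritance = "de_novo"),
      list(family = 2, gene = "C2", category = "damaging_missense",
           inheritance = "maternal"),
      list(family = 3, gene = "C3", category = "lof",
           inheritance = "compound_het_pair")),
      backgroundRate = 8, seed = s)
    res <- filterVariants(sim$variants, sim$pedigree)
    got <- sort(variants(res$pool)$uid)
    expect_equal(got, oracleFilter(sim$variants, sim$pedigree))
    ## attrition conservation: input = kept + sum of per-reason drops
    att <- res$attrition
    expect_equal(nrow(att), nrow(variants(sim$variants)))
    expect_equal(sum(att$kept) + sum(!att$kept), nrow(att))
    expect_true(all(nzchar(att$reason[!att$kept])))
  }
})

test_that("the surviving set is invariant to input ordering", {
  sim <- simulateCohort(5, backgroundRate = 10, seed = 21)
  res1 <- filterVariants(sim$variants, sim$pedigree)
  v <- variants(sim$variants)
  perm <- withr::with_seed(1, sample(nrow(v)))
  shuffled <- VariantTable(v[perm, ], genotypes(sim$variants))
  res2 <- filterVariants(shuffled, sim$pedigree)
  expect_setequal(variants(res1$pool)$uid, variants(res2$pool)$uid)
})
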