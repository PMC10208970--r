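test_that("LoF classification reproduces clinical-table examples", {
  rows <- rbind(
    ## nonsense in a pLI = 0.98 gene with CADD 38
    makeVariantRow(pos = 1, consequence = "stop_gained", pli = 0.98,
                   loftool = 0.0652, cadd_phred = 38),
    ## frameshift: LoF-intolerant gene alone suffices
    makeVariantRow(pos = 2, ref = "A", alt = "AT",
                   consequence = "frameshift_variant", pli = 1),
    ## splice acceptor qualifying via the splice-prediction clause
    makeVariantRow(pos = 3, consequence = "splice_acceptor_variant",
                   pli = 1, cadd_phred = 24.6, ada_score = 0.999,
                   rf_score = 0.924),
    ## stop gained in a tolerant gene: clause 2 fails
    makeVariantRow(pos = 4, consequence = "stop_gained", pli = 0.3,
                   loftool = 0.5, cadd_phred = 38),
    ## non-frameshift LoF with no damage evidence: clause 3 fails
    makeVariantRow(pos = 5, consequence = "stop_gained", pli = 1),
    ## missense never qualifies as LoF
    makeVariantRow(pos = 6, consequence = "missense_variant", pli = 1,
                   cadd_phred = 38))
  res <- classifyLoF(VariantTable(rows, data.frame()))
  expect_equal(res$is_lof, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("missense classification requires at least 3 of 4 criteria", {
  rows <- rbind(
    ## PolyPhen possibly damaging + SIFT deleterious + CADD 25.9 (3 of 4)
    makeVariantRow(pos = 1, polyphen_call = "possibly_damaging",
                   polyphen_score = 0.737, sift_call = "deleterious",
                   sift_score = 0.05, cadd_phred = 25.9),
    makeVariantRow(pos = 2, polyphen_call = "benign",
                   sift_call = "tolerated", cadd_phred = 19),
    ## all four criteria
    makeVariantRow(pos = 3, polyphen_call = "probably_damaging",
                   sift_call = "deleterious", cadd_phred = 33,
                   mtr_fdr = 0.01),
    ## deleterious-low-confidence counts for SIFT
    makeVariantRow(pos = 4, polyphen_call = "probably_damaging",
                   sift_call = "deleterious_low_confidence",
                   cadd_phred = 26))
  res <- classifyMissense(VariantTable(rows, data.frame()))
  expect_equal(res$is_damaging_missense, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(res$n_criteria, c(3L, 0L, 4L, 3L))
})

test_that("the decision boundary sits at 3 criteria over all 16 subsets", {
  for (mask in 0:15) {
    crit <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)))
    row <- makeVariantRow(
      polyphen_call = if (crit[1]) "probably_damaging" else "benign",
      sift_call = if (crit[2]) "deleterious" else "tolerated",
      cadd_phred = if (crit[3]) 25 else 5,
      mtr_fdr = if (crit[4]) 0.01 else 0.5)
    res <- classifyMissense(VariantTable(row, data.frame()))
    expect_equal(res$is_damaging_missense, sum(crit) >= 3,
                 info = paste("mask", mask))
  }
})

test_that("classifier grid matches the independently coded truth table", {
  grid <- expand.grid(
    consequence = c("stop_gained", "frameshift_variant",
                    "splice_donor_variant", "missense_variant",
                    "synonymous_variant",
                    "missense_variant,splice_region_variant"),
    pli = c(NA, 0.5, 0.9), loftool = c(NA, 0.05),
    cadd = c(NA, 19.9, 20), ada = c(NA, 0.61), rf = NA,
    polyphen = c(NA, "possibly_damaging"),
    sift = c(NA, "deleterious"), mtr = c(NA, 0.049),
    stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    makeVariantRow(pos = i, consequence = g$consequence, pli = g$pli,
                   loftool = g$loftool, cadd_phred = g$cadd,
                   ada_score = g$ada, rf_score = g$rf,
                   polyphen_call = g$polyphen, sift_call = g$sift,
                   mtr_fdr = g$mtr)
  }))
  vt <- VariantTable(rows, data.frame())
  lof <- classifyLoF(vt)$is_lof
  mis <- classifyMissense(vt)$is_damaging_missense
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cons <- strsplit(g$consequence, ",")[[1]]
    expect_equal(lof[i],
                 oracleLoF(cons, g$pli, g$loftool, g$cadd, g$ada, g$rf),
                 info = paste("row", i))
    expect_equal(mis[i],
                 oracleMissense(cons, g$polyphen, g$sift, g$cadd, g$mtr),
                 info = paste("row", i))
  }
})

.shortlistFixture <- function() {
  ## FAM001: one LoF in a panel gene + one damaging missense outside;
  ## FAM002: one genome-wide LoF only; FAM003: nothing deleterious
  rows <- rbind(
    makeVariantRow(family = "FAM001", pos = 1, gene = "PANEL1",
                   consequence = "stop_gained", pli = 1, cadd_phred = 35),
    makeVariantRow(family = "FAM001", pos = 2, gene = "OTHER1",
                   polyphen_call = "probably_damaging",
                   sift_call = "deleterious", cadd_phred = 28),
    makeVariantRow(family = "FAM002", pos = 3, gene = "OTHER2",
                   consequence = "stop_gained", pli = 1, cadd_phred = 30),
    makeVariantRow(family = "FAM003", pos = 4, gene = "OTHER3",
                   consequence = "synonymous_variant"))
  VariantTable(rows, data.frame())
}

test_that("two-stage shortlisting searches genome-wide only when panels yield nothing", {
  pool <- .shortlistFixture()
  ps <- GenePanelSet(list(speech = c("PANEL1", "PANEL2")))
  sl <- shortlistCandidates(pool, ps)
  f1 <- sl[sl$family == "FAM001", ]
  expect_equal(nrow(f1), 1L)               # panel hit suppresses stage 2
  expect_equal(f1$gene, "PANEL1")
  expect_equal(f1$stage, "panel")
  f2 <- sl[sl$family == "FAM002", ]
  expect_equal(f2$stage, "genome_wide")
  expect_false("FAM003" %in% sl$family)    # nothing deleterious
  ## mutual exclusivity of stages per variant
  expect_false(any(duplicated(sl$uid)))
})

test_that("enlarging the panel union never demotes a variant to stage 2", {
  pool <- .shortlistFixture()
  small <- GenePanelSet(list(speech = "PANEL1"))
  big <- GenePanelSet(list(speech = "PANEL1",
                           extra = c("OTHER1", "OTHER2")))
  sl_small <- shortlistCandidates(pool, small)
  sl_big <- shortlistCandidates(pool, big)
  stage1_small <- sl_small$uid[sl_small$stage == "panel"]
  expect_true(all(stage1_small %in% sl_big$uid[sl_big$stage == "panel"]))
})

test_that("per-gene collapse takes the most severe transcript", {
  rows <- rbind(
    makeVariantRow(pos = 1, transcript = "T1",
                   consequence = "intron_variant", pli = 1,
                   cadd_phred = 30),
    makeVariantRow(pos = 1, transcript = "T2",
                   consequence = "stop_gained", pli = 1, cadd_phred = 30))
  pool <- VariantTable(rows, data.frame())
  sl <- shortlistCandidates(pool, GenePanelSet(list(p = "GENE1")))
  expect_equal(nrow(sl), 1L)               # one allele, not two records
  expect_equal(sl$uid, variants(pool)$uid[2])  # qualifying transcript
})

test_that("tiers follow ACMG class and phenotype consistency", {
  expect_equal(assignTier(5L, TRUE), "high_confidence")
  expect_equal(assignTier(4L, TRUE), "high_confidence")
  expect_equal(assignTier(3L, TRUE), "low_confidence")
  expect_equal(assignTier(3L, FALSE), "low_confidence")
  expect_equal(assignTier(4L, FALSE), "low_confidence")
  expect_equal(assignTier(2L, TRUE), "excluded")
  expect_equal(assignTier(5L, FALSE), "excluded")
  expect_equal(assignTier(NA_integer_, TRUE), "excluded")
})

test_that("cohort summary reproduces the diagnostic-yield arithmetic", {
  mk <- function(fam, class, consistent, del = "lof")
    data.frame(uid = paste0("u", fam, class, del), family = fam,
               gene = "G", deleterious_class = del, stage = "panel",
               acmg_class = class, phenotype_consistent = consistent,
               tier = assignTier(class, consistent))
  cands <- do.call(rbind, c(
    lapply(sprintf("F%02d", 1:18), mk, class = 5L, consistent = TRUE),
    lapply(sprintf("L%02d", 1:8), mk, class = 3L, consistent = FALSE,
           del = "damaging_missense")))
  s <- summarizeCohort(cands, 70)
  expect_equal(s$solved, 18L)
  expect_equal(s$yield_percent, 26)        # 18/70 prints as 26%
  expect_equal(s$low_conf_missense_probands, 8L)
  expect_equal(s$low_conf_missense_percent, 11.4)
  s0 <- summarizeCohort(cands[0, ], 70)
  expect_equal(s0$yield_percent, 0)
})
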