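test_that("TSV dialect parses VEP-style annotations and genotypes", {
  tsv <- tempfile(fileext = ".tsv")
  header <- paste(c("family", "chrom", "pos", "ref", "alt", "gene",
                    "transcript", "consequence", "gnomad_ac", "gnomad_af",
                    "pli", "loftool", "cadd_phred", "sift", "polyphen",
                    "mtr_fdr", "ada_score", "rf_score", "qd", "fs", "sor",
                    "mq_rank_sum", "read_pos_rank_sum", "excess_het_z",
                    "filter", "P1.gt", "P1.dp", "P1.gq"),
                  collapse = "\t")
  ## a missense record in the style of a clinical variant table:
  ## SIFT = Del(0); PolyPhen = Dam(0.99); CADD = 33
  row <- paste(c("FAM005", "3", "9788123", "A", "T", "BRPF1", "ENST1",
                 "missense_variant", "0", "", "", "", "33", "Del(0)",
                 "Dam(0.99)", "", "", "", "25", "2", "1", "0", "0", "0.1",
                 "PASS", "0/1", "44", "99"), collapse = "\t")
  writeLines(c(header, row), tsv)
  vt <- readAnnotatedVariants(tsv)
  v <- variants(vt)
  expect_equal(nrow(v), 1L)
  expect_equal(v$cadd_phred, 33)
  expect_equal(v$sift_call, "deleterious")
  expect_equal(v$sift_score, 0)
  expect_equal(v$polyphen_call, "probably_damaging")
  expect_equal(v$polyphen_score, 0.99)
  expect_equal(v$gnomad_ac, 0L)       # observed zero times, not missing
  expect_true(is.na(v$gnomad_af))     # absent stays missing
  expect_equal(v$variant_class, "snv")
  g <- genotypes(vt)
  expect_equal(g$gt, "het")
  expect_equal(g$dp, 44)

  ## empty file with valid header -> empty table
  writeLines(header, tsv)
  expect_equal(nrow(variants(readAnnotatedVariants(tsv))), 0L)
})

test_that("malformed rows error with a line number; unknown terms warn", {
  tsv <- tempfile(fileext = ".tsv")
  header <- readLines(textConnection(paste(
    c("family", "chrom", "pos", "ref", "alt", "gene", "transcript",
      "consequence", "gnomad_ac", "gnomad_af", "pli", "loftool",
      "cadd_phred", "sift", "polyphen", "mtr_fdr", "ada_score",
      "rf_score", "qd", "fs", "sor", "mq_rank_sum", "read_pos_rank_sum",
      "excess_het_z", "filter", "P1.gt", "P1.dp", "P1.gq"),
    collapse = "\t")))
  good <- paste(c("F1", "1", "100", "A", "T", "G1", "T1",
                  "missense_variant", rep("", 6), "", rep("", 3),
                  "20", "2", "1", "0", "0", "0", "PASS", "0/1", "30",
                  "60"), collapse = "\t")
  bad <- sub("\t100\t", "\tnotanumber\t", good)
  writeLines(c(header, good, bad), tsv)
  expect_error(readAnnotatedVariants(tsv), "line 3")

  odd <- sub("missense_variant", "weird_new_term", good)
  writeLines(c(header, odd), tsv)
  expect_warning(vt <- readAnnotatedVariants(tsv), "weird_new_term")
  expect_equal(variants(vt)$consequence, "weird_new_term")
})

test_that("variant TSV round-trips simulated records field by field", {
  sim <- simulateCohort(3, planted = list(
    list(family = 1, gene = "CAUSAL1", category = "lof",
         inheritance = "de_novo"),
    list(family = 2, gene = "CAUSAL2", category = "damaging_missense",
         inheritance = "maternal")),
    backgroundRate = 4, seed = 11)
  path <- tempfile(fileext = ".tsv")
  writeAnnotatedVariants(sim$variants, path)
  back <- readAnnotatedVariants(path)
  v1 <- variants(sim$variants); v2 <- variants(back)
  v2 <- v2[match(v1$uid, v2$uid), ]
  rownames(v2) <- NULL
  expect_equal(v2, v1, tolerance = 1e-12)
  g1 <- genotypes(sim$variants); g2 <- genotypes(back)
  key <- function(g) g[order(g$uid, g$sample), ]
  g1 <- key(g1); g2 <- key(g2)
  rownames(g1) <- rownames(g2) <- NULL
  expect_equal(g2, g1, tolerance = 1e-12)
  ## a missing gnomAD AC stays distinguishable from AC = 0 after parsing
  expect_true(any(is.na(v2$gnomad_ac)))
})

test_that("VCF dialect is equivalent to the TSV dialect", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=FAM,Number=1,Type=String,Description=\"Family\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Pos rank sum\">",
    "##INFO=<ID=ExcHetZ,Number=1,Type=Float,Description=\"Excess het Z\">",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations. Format: Allele|SYMBOL|Feature|Consequence|",
           "gnomAD_AC|gnomAD_AF|ExACpLI|LoFtool|CADD_PHRED|SIFT|PolyPhen|",
           "MTR_FDR|ada_score|rf_score\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##contig=<ID=7>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "P1", "F1", "M1", sep = "\t"),
    paste("7", "1000", ".", "C", "T", "100", "PASS",
          paste0("FAM=FAM001;QD=21.5;FS=3.2;SOR=1.1;MQRankSum=0.4;",
                 "ReadPosRankSum=-0.2;ExcHetZ=0.5;",
                 "CSQ=T|FOXP2|ENST7|stop_gained|0|.|0.98|0.06|38|.|.|.|.|."),
          "GT:DP:GQ", "0/1:40:99", "0/0:35:80", "0/0:38:90", sep = "\t")),
    vcf)
  vt <- readAnnotatedVariants(vcf, dialect = "vcf")
  v <- variants(vt)
  expect_equal(v$gene, "FOXP2")
  expect_equal(v$consequence, "stop_gained")
  expect_equal(v$pli, 0.98)
  expect_equal(v$cadd_phred, 38)
  expect_equal(v$qd, 21.5)
  expect_true(is.na(v$gnomad_af))
  expect_equal(v$gnomad_ac, 0L)
  g <- genotypes(vt)
  expect_setequal(g$sample, c("P1", "F1", "M1"))
  expect_equal(g$gt[g$sample == "P1"], "het")
})

test_that("PED reading handles trios, duos and error cases", {
  ped_path <- tempfile(fileext = ".ped")
  writeLines(c("F1\tP1\tD1\tM1\t1\t2", "F1\tD1\t0\t0\t1\t1",
               "F1\tM1\t0\t0\t2\t1"), ped_path)
  ped <- readPedigree(ped_path)
  expect_s4_class(ped, "Pedigree")
  expect_equal(unname(probands(ped)), "P1")

  ## duo: father unavailable
  writeLines(c("F1\tP1\t0\tM1\t1\t2", "F1\tM1\t0\t0\t2\t1"), ped_path)
  duo <- readPedigree(ped_path)
  expect_equal(pedTable(duo)$father[1], "")

  ## round trip
  out <- tempfile(fileext = ".ped")
  writePedigree(ped, out)
  expect_equal(pedTable(readPedigree(out)), pedTable(ped))

  ## child listing itself as parent
  writeLines(c("F1\tP1\tP1\t0\t1\t2"), ped_path)
  expect_error(readPedigree(ped_path))
  ## dangling parent
  writeLines(c("F1\tP1\tD9\t0\t1\t2"), ped_path)
  expect_error(readPedigree(ped_path), "D9")
  ## duplicate id
  writeLines(c("F1\tP1\t0\t0\t1\t2", "F1\tP1\t0\t0\t1\t2"), ped_path)
  expect_error(readPedigree(ped_path), "duplicate")
})

test_that("expression matrix reading validates genes, values and metadata", {
  mat <- tempfile(fileext = ".tsv")
  meta <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2\tS3", "G1\t1\t2\t3", "G2\t4\t5\t6"), mat)
  writeLines(c("sample_id\tdonor_id\tstage_label\tage_value\tage_unit",
               "S1\tD1\t8 pcw\t8\tpcw", "S2\tD1\t12 pcw\t12\tpcw",
               "S3\tD2\t4 mos\t4\tmos"), meta)
  em <- readExpressionMatrix(mat, meta)
  expect_s4_class(em, "ExpressionMatrix")
  expect_equal(dim(em), c(2L, 3L))
  expect_equal(SummarizedExperiment::colData(em)$donor_id,
               c("D1", "D1", "D2"))

  ## round trip preserves values and sample order
  out <- tempfile(fileext = ".tsv"); outm <- tempfile(fileext = ".tsv")
  writeExpressionMatrix(em, out, outm)
  em2 <- readExpressionMatrix(out, outm)
  expect_equal(SummarizedExperiment::assay(em2, "expr"),
               SummarizedExperiment::assay(em, "expr"))
  expect_equal(colnames(em2), colnames(em))

  writeLines(c("gene\tS1\tS2\tS3", "G1\t1\t2\t3", "G1\t4\t5\t6"), mat)
  expect_error(readExpressionMatrix(mat), "duplicate")
  writeLines(c("gene\tS1\tS2\tS3", "G1\t1\ttwo\t3"), mat)
  expect_error(readExpressionMatrix(mat), "non-numeric")
  writeLines(c("gene\tS1\tS2\tS3", "G1\t1\t2\t3", "G2\t4\t5\t6"), mat)
  writeLines(c("sample_id\tdonor_id\tstage_label\tage_value\tage_unit",
               "S1\tD1\t8 pcw\t8\tpcw"), meta)
  expect_error(readExpressionMatrix(mat, meta), "match")
})

test_that("a 280-sample matrix loads with sample count preserved", {
  em <- simulateExpression(100, 280, seed = 5)
  mat <- tempfile(fileext = ".tsv"); meta <- tempfile(fileext = ".tsv")
  writeExpressionMatrix(em, mat, meta)
  em2 <- readExpressionMatrix(mat, meta)
  expect_equal(ncol(em2), 280L)
  expect_equal(nrow(em2), 100L)
})

test_that("gene panel files read with comments and case normalization", {
  p1 <- tempfile(); p2 <- tempfile()
  writeLines(c("# speech panel", "FOXP2", "grin2a", ""), p1)
  writeLines(c("SETBP1", "FOXP2"), p2)
  ps <- readGenePanels(c(speech = p1, other = p2))
  expect_setequal(panels(ps)$speech, c("FOXP2", "GRIN2A"))
  expect_setequal(panelUnion(ps), c("FOXP2", "GRIN2A", "SETBP1"))
})
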