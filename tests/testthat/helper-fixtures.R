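## Small fixture builders used across test files.

## one fully specified variant row; every field overridable
makeVariantRow <- function(family = "FAM001", chrom = "1", pos = 1000L,
                           ref = "A", alt = "T", gene = "GENE1",
                           transcript = "ENST1",
                           consequence = "missense_variant",
                           gnomad_ac = NA, gnomad_af = NA, pli = NA,
                           loftool = NA, cadd_phred = NA,
                           sift_call = NA, sift_score = NA,
                           polyphen_call = NA, polyphen_score = NA,
                           mtr_fdr = NA, ada_score = NA, rf_score = NA,
                           qd = 20, fs = 5, sor = 1, mq_rank_sum = 0,
                           read_pos_rank_sum = 0, excess_het_z = 0,
                           filter = "PASS") {
  data.frame(family = family, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, gene = gene, transcript = transcript,
             consequence = consequence,
             gnomad_ac = as.integer(gnomad_ac),
             gnomad_af = as.numeric(gnomad_af), pli = as.numeric(pli),
             loftool = as.numeric(loftool),
             cadd_phred = as.numeric(cadd_phred),
             sift_call = as.character(sift_call),
             sift_score = as.numeric(sift_score),
             polyphen_call = as.character(polyphen_call),
             polyphen_score = as.numeric(polyphen_score),
             mtr_fdr = as.numeric(mtr_fdr),
             ada_score = as.numeric(ada_score),
             rf_score = as.numeric(rf_score), qd = as.numeric(qd),
             fs = as.numeric(fs), sor = as.numeric(sor),
             mq_rank_sum = as.numeric(mq_rank_sum),
             read_pos_rank_sum = as.numeric(read_pos_rank_sum),
             excess_het_z = as.numeric(excess_het_z), filter = filter)
}

## genotype triple for one variant row; gt strings are genotype classes
makeGenoRows <- function(row, ..., dp = 40, gq = 80) {
  gts <- list(...)
  uid <- trioTriage:::.variantUID(row$family, row$chrom, row$pos, row$ref,
                                  row$alt, row$transcript)
  do.call(rbind, lapply(names(gts), function(s)
    data.frame(uid = uid, sample = s, gt = gts[[s]], dp = dp, gq = gq)))
}

makeTrioPed <- function(family = "FAM001", probandSex = "male") {
  Pedigree(data.frame(
    family = family, id = paste0(family, c("_P", "_F", "_M")),
    father = c(paste0(family, "_F"), "", ""),
    mother = c(paste0(family, "_M"), "", ""),
    sex = c(probandSex, "male", "female"),
    affected = c("affected", "unaffected", "unaffected"), twin = ""))
}
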