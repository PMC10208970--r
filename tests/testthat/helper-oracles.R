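## Independent oracles, coded directly from the filtering and
## classification rules, without reusing package internals. Deliberately
## slow and literal: one variant at a time, plain conditionals.

.siteQCFields <- c("filter_flag", "excess_het", "qd", "fs", "sor",
                   "mq_rank_sum", "read_pos_rank_sum")

oracleCarries <- function(gt) !is.na(gt) && gt %in% c("het", "hom_alt",
                                                      "hemi_alt")

## returns the survivor uid set of the full cascade, re-evaluating every
## rule per variant
oracleFilter <- function(vt, ped) {
  v <- variants(vt)
  g <- genotypes(vt)
  p <- pedTable(ped)
  pro <- probands(ped)
  gt_of <- function(uid, s) {
    hit <- g[g$uid == uid & g$sample == s, ]
    if (nrow(hit)) list(gt = hit$gt[1], dp = hit$dp[1], gq = hit$gq[1])
    else NULL
  }
  passes_qc <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    r <- v[i, ]
    snv <- nchar(r$ref) == 1 && nchar(r$alt) == 1
    site_ok <- r$filter %in% c("PASS", ".") &&
      !(!is.na(r$excess_het_z) && r$excess_het_z > 4.5) &&
      !(!is.na(r$qd) && r$qd < 2) &&
      !(!is.na(r$fs) && r$fs > (if (snv) 60 else 200)) &&
      !(!is.na(r$sor) && r$sor > (if (snv) 3 else 10)) &&
      !(snv && !is.na(r$mq_rank_sum) && r$mq_rank_sum < -12.6) &&
      !(!is.na(r$read_pos_rank_sum) &&
          r$read_pos_rank_sum < (if (snv) -8 else -20))
    fam_ids <- p$id[p$family == r$family]
    geno_ok <- TRUE
    pro_geno <- NULL
    for (s in fam_ids) {
      gg <- gt_of(r$uid, s)
      if (is.null(gg)) next
      if (is.na(gg$dp) || is.na(gg$gq) || gg$dp <= 10 || gg$gq <= 20)
        geno_ok <- FALSE
      if (identical(s, unname(pro[r$family]))) pro_geno <- gg
    }
    if (is.null(pro_geno)) geno_ok <- FALSE
    passes_qc[i] <- site_ok && geno_ok
  }
  ## recurrence: identical allele carried by an unaffected individual of
  ## a different family
  recur_ok <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    allele <- paste(v$chrom[i], v$pos[i], v$ref[i], v$alt[i])
    bad <- FALSE
    same <- which(paste(v$chrom, v$pos, v$ref, v$alt) == allele)
    for (j in same) {
      gj <- g[g$uid == v$uid[j], ]
      for (k in seq_len(nrow(gj))) {
        s <- gj$sample[k]
        if (oracleCarries(gj$gt[k]) &&
            isTRUE(p$affected[p$id == s] == "unaffected") &&
            isTRUE(p$family[p$id == s] != v$family[i]))
          bad <- TRUE
      }
    }
    recur_ok[i] <- !bad
  }
  ## inheritance per variant
  inherit <- character(nrow(v))
  carrier <- logical(nrow(v))
  consistent <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    r <- v[i, ]
    pid <- unname(pro[r$family])
    prow <- p[p$id == pid, ]
    gp <- gt_of(r$uid, pid)
    if (is.null(gp) || !oracleCarries(gp$gt)) {
      inherit[i] <- "none"; next
    }
    carrier[i] <- TRUE
    gfa <- if (nzchar(prow$father)) gt_of(r$uid, prow$father) else NULL
    gmo <- if (nzchar(prow$mother)) gt_of(r$uid, prow$mother) else NULL
    fa_car <- !is.null(gfa) && gfa$gt != "missing" && oracleCarries(gfa$gt)
    mo_car <- !is.null(gmo) && gmo$gt != "missing" && oracleCarries(gmo$gt)
    fa_seq <- !is.null(gfa) && gfa$gt != "missing"
    mo_seq <- !is.null(gmo) && gmo$gt != "missing"
    is_x <- r$chrom %in% c("X", "chrX")
    model <- "unknown"
    if (is_x && prow$sex == "male") {
      if (mo_seq) model <- if (mo_car) "inherited_maternal" else "de_novo"
    } else if (fa_seq && mo_seq) {
      if (!fa_car && !mo_car) model <- "de_novo"
      else if (gp$gt == "hom_alt" && gfa$gt == "het" && gmo$gt == "het")
        model <- "homozygous_recessive"
      else if (mo_car && !fa_car) model <- "inherited_maternal"
      else if (fa_car && !mo_car) model <- "inherited_paternal"
    } else if (fa_seq && fa_car) model <- "inherited_paternal"
    else if (mo_seq && mo_car) model <- "inherited_maternal"
    inherit[i] <- model
    consistent[i] <- TRUE
    if (model == "inherited_maternal") {
      consistent[i] <- isTRUE(p$affected[p$id == prow$mother] ==
                                "affected") ||
        (is_x && prow$sex == "male")
    } else if (model == "inherited_paternal") {
      consistent[i] <- isTRUE(p$affected[p$id == prow$father] ==
                                "affected")
    }
  }
  ## compound het pairs among QC/recurrence-passing proband hets
  comphet <- logical(nrow(v))
  alive <- passes_qc & recur_ok & carrier
  for (i in which(alive)) {
    if (!inherit[i] %in% c("inherited_maternal", "inherited_paternal"))
      next
    pid <- unname(pro[v$family[i]])
    gp <- gt_of(v$uid[i], pid)
    if (gp$gt != "het") next
    want <- if (inherit[i] == "inherited_maternal") "inherited_paternal"
    else "inherited_maternal"
    for (j in which(alive & v$family == v$family[i] &
                      v$gene == v$gene[i] & inherit == want)) {
      gpj <- gt_of(v$uid[j], pid)
      if (!is.null(gpj) && gpj$gt == "het") comphet[i] <- TRUE
    }
  }
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    r <- v[i, ]
    freq_dom <- is.na(r$gnomad_ac) || r$gnomad_ac <= 2
    freq_ch <- is.na(r$gnomad_af) || r$gnomad_af < 0.0005
    freq_ok <- freq_dom || (comphet[i] && freq_ch)
    eligible <- inherit[i] %in% c("de_novo", "homozygous_recessive",
                                  "unknown") ||
      (inherit[i] %in% c("inherited_maternal", "inherited_paternal") &&
         consistent[i]) || comphet[i]
    keep[i] <- passes_qc[i] && recur_ok[i] && carrier[i] && freq_ok &&
      eligible
  }
  sort(v$uid[keep])
}

## literal re-coding of the deleteriousness rules
oracleLoF <- function(consequences, pli, loftool, cadd, ada, rf) {
  lofset <- c("frameshift_variant", "stop_gained", "start_lost",
              "stop_lost", "splice_acceptor_variant",
              "splice_donor_variant")
  c1 <- any(consequences %in% lofset)
  c2 <- (!is.na(pli) && pli >= 0.9) || (!is.na(loftool) && loftool < 0.1)
  fs <- "frameshift_variant" %in% consequences
  c3 <- fs || (!is.na(cadd) && cadd >= 20) ||
    (!is.na(ada) && ada >= 0.6) || (!is.na(rf) && rf >= 0.6)
  c1 && c2 && c3
}

oracleMissense <- function(consequences, polyphen, sift, cadd, mtr) {
  if (!"missense_variant" %in% consequences) return(FALSE)
  n <- 0
  if (!is.na(polyphen) && polyphen %in% c("probably_damaging",
                                          "possibly_damaging")) n <- n + 1
  if (!is.na(sift) && sift %in% c("deleterious",
                                  "deleterious_low_confidence")) n <- n + 1
  if (!is.na(cadd) && cadd >= 20) n <- n + 1
  if (!is.na(mtr) && mtr < 0.05) n <- n + 1
  n >= 3
}

## Benjamini-Hochberg step-up, literal
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

## median-linkage (WPGMC) agglomeration via the Lance-Williams update:
## d(k, ij) = d(k,i)/2 + d(k,j)/2 - d(i,j)/4. Returns merge heights in
## order and the member partition after each merge.
oracleMedianLinkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- seq_len(n)
  members <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  while (length(active) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a < b && d[active[a], active[b]] < bestd) {
        bestd <- d[active[a], active[b]]; best <- c(a, b)
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    heights <- c(heights, bestd)
    merges[[length(merges) + 1]] <- sort(c(members[[i]], members[[j]]))
    for (k in active) {
      if (k == i || k == j) next
      d[k, i] <- d[i, k] <- d[k, i] / 2 + d[k, j] / 2 - d[i, j] / 4
    }
    members[[i]] <- c(members[[i]], members[[j]])
    active <- setdiff(active, j)
  }
  list(heights = heights, merges = merges)
}

## map specific attrition reasons back to the truth table's vocabulary
collapseReason <- function(reason) {
  ifelse(reason %in% c("filter_flag", "excess_het", "qd", "fs", "sor",
                       "mq_rank_sum", "read_pos_rank_sum"),
         "site_qc", reason)
}
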