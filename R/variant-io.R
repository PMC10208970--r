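## Known sequence-ontology-style consequence vocabulary. Unknown terms are
## kept verbatim (with a warning) so novel VEP terms survive a round trip.
.KNOWN_CONSEQUENCES <- c(
  "frameshift_variant", "stop_gained", "start_lost", "stop_lost",
  "splice_acceptor_variant", "splice_donor_variant", "missense_variant",
  "synonymous_variant", "splice_region_variant", "intron_variant",
  "inframe_deletion", "inframe_insertion", "protein_altering_variant",
  "stop_retained_variant", "5_prime_UTR_variant", "3_prime_UTR_variant",
  "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant")

.variantUID <- function(family, chrom, pos, ref, alt, transcript)
  paste(family, chrom, pos, ref, alt, transcript, sep = "|")

.variantClass <- function(ref, alt)
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snv", "indel")

## "Del(0.01)" / "probably_damaging(0.98)" -> list(call, score).
## Accepts the VEP table vocabulary (Del, delLowConf, ProbDam, PosDam, Ben).
.parsePredictionString <- function(x, kind = c("sift", "polyphen")) {
  kind <- match.arg(kind)
  call <- rep(NA_character_, length(x))
  score <- rep(NA_real_, length(x))
  has <- !is.na(x) & nzchar(x)
  m <- regmatches(x[has], regexec("^\\s*([^()]+?)\\s*(\\(([^)]*)\\))?\\s*$",
                                  x[has]))
  raw_call <- vapply(m, function(g) g[2], character(1))
  raw_score <- vapply(m, function(g) g[4], character(1))
  call[has] <- .normalizePredictionCall(raw_call, kind)
  score[has] <- suppressWarnings(as.numeric(raw_score))
  list(call = call, score = score)
}

.normalizePredictionCall <- function(x, kind) {
  key <- gsub("[ _]", "", tolower(x))
  if (kind == "sift") {
    map <- c(deleterious = "deleterious", del = "deleterious",
             deleteriouslowconfidence = "deleterious_low_confidence",
             dellowconf = "deleterious_low_confidence",
             tolerated = "tolerated", tol = "tolerated",
             toleratedlowconfidence = "tolerated")
  } else {
    map <- c(probablydamaging = "probably_damaging",
             probdam = "probably_damaging", dam = "probably_damaging",
             possiblydamaging = "possibly_damaging",
             posdam = "possibly_damaging",
             benign = "benign", ben = "benign", unknown = NA)
  }
  out <- unname(map[key])
  out[!key %in% names(map)] <- NA_character_
  out
}

.formatPredictionString <- function(call, score) {
  out <- rep("", length(call))
  has <- !is.na(call)
  out[has] <- ifelse(is.na(score[has]), call[has],
                     sprintf("%s(%s)", call[has],
                             formatC(score[has], format = "g", digits = 15)))
  out
}

.gtFromString <- function(x) {
  x <- sub("\\|", "/", x)
  out <- rep("missing", length(x))
  out[x %in% c("0/0", "0")] <- "hom_ref"
  out[x %in% c("0/1", "1/0")] <- "het"
  out[x == "1/1"] <- "hom_alt"
  out[x == "1"] <- "hemi_alt"
  out
}

.gtToString <- function(x) {
  map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
           hemi_alt = "1", missing = "./.")
  unname(map[x])
}

.numOrNA <- function(x, col, lines) {
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop("non-numeric value '", x[bad[1]], "' in column '", col,
         "' at line ", lines[bad[1]], call. = FALSE)
  out
}

#' Construct a VariantTable
#'
#' @param variants data.frame of variant-level fields; derived columns
#'   (\code{variant_class}, \code{uid}) are filled in when absent.
#' @param genotypes data.frame with columns \code{uid}, \code{sample},
#'   \code{gt}, \code{dp}, \code{gq}.
#' @return a validated \linkS4class{VariantTable}.
#' @export
VariantTable <- function(variants, genotypes) {
  variants <- as.data.frame(variants)
  if (nrow(variants)) {
    variants$chrom <- as.character(variants$chrom)
    variants$pos <- as.integer(variants$pos)
    if (is.null(variants$variant_class))
      variants$variant_class <- .variantClass(variants$ref, variants$alt)
    if (is.null(variants$uid))
      variants$uid <- .variantUID(variants$family, variants$chrom,
                                  variants$pos, variants$ref, variants$alt,
                                  variants$transcript)
    for (col in setdiff(.VARIANT_COLUMNS,
                        c(names(variants))))
      variants[[col]] <- NA
  } else {
    variants <- .emptyVariantFrame()
  }
  variants <- variants[, .VARIANT_COLUMNS]
  genotypes <- as.data.frame(genotypes)
  if (!nrow(genotypes))
    genotypes <- data.frame(uid = character(), sample = character(),
                            gt = character(), dp = numeric(), gq = numeric())
  rownames(variants) <- NULL
  rownames(genotypes) <- NULL
  new("VariantTable", variants = variants, genotypes = genotypes)
}

.emptyVariantFrame <- function() {
  out <- data.frame(family = character(), chrom = character(),
                    pos = integer(), ref = character(), alt = character(),
                    gene = character(), transcript = character(),
                    consequence = character())
  for (col in c("gnomad_ac", "gnomad_af", "pli", "loftool", "cadd_phred",
                "sift_score", "polyphen_score", "mtr_fdr", "ada_score",
                "rf_score", "qd", "fs", "sor", "mq_rank_sum",
                "read_pos_rank_sum", "excess_het_z"))
    out[[col]] <- numeric()
  out$sift_call <- character(); out$polyphen_call <- character()
  out$filter <- character(); out$variant_class <- character()
  out$uid <- character()
  out[, .VARIANT_COLUMNS]
}

.TSV_FIXED <- c("family", "chrom", "pos", "ref", "alt", "gene", "transcript",
  "consequence", "gnomad_ac", "gnomad_af", "pli", "loftool", "cadd_phred",
  "sift", "polyphen", "mtr_fdr", "ada_score", "rf_score", "qd", "fs", "sor",
  "mq_rank_sum", "read_pos_rank_sum", "excess_het_z", "filter")

#' Read VEP-style annotated variants
#'
#' Reads the canonical tab-delimited dialect (or a VCF with a CSQ INFO
#' field) into a \linkS4class{VariantTable}, one record per (site, alternate
#' allele, transcript). The TSV dialect has fixed columns
#' \code{family .. filter} followed by per-sample genotype triplets
#' \code{SAMPLE.gt}, \code{SAMPLE.dp}, \code{SAMPLE.gq}; the empty string is
#' missing. SIFT/PolyPhen columns accept either combined "call(score)"
#' strings (VEP style, e.g. \code{Del(0.01)}) or split
#' \code{sift_call}/\code{sift_score} columns.
#'
#' @param path path to the variant file.
#' @param dialect \code{"tsv"} (canonical) or \code{"vcf"} (thin adapter via
#'   \pkg{VariantAnnotation}).
#' @return a \linkS4class{VariantTable}. Missing annotations are \code{NA},
#'   never 0.
#' @export
readAnnotatedVariants <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "vcf") return(.readVariantsVcf(path))
  .readVariantsTsv(path)
}

.readVariantsTsv <- function(path) {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  split_preds <- all(c("sift_call", "sift_score") %in% names(raw))
  fixed <- .TSV_FIXED
  if (split_preds)
    fixed <- c(setdiff(fixed, c("sift", "polyphen")),
               "sift_call", "sift_score", "polyphen_call", "polyphen_score")
  missing_cols <- setdiff(fixed, names(raw))
  if (length(missing_cols))
    stop("variant TSV is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(raw)
  lines <- seq_len(n) + 1L   # header is line 1
  if (!n) return(VariantTable(.emptyVariantFrame(), data.frame()))

  blank2na <- function(x) { x[!nzchar(x)] <- NA_character_; x }
  v <- data.frame(family = raw$family, chrom = raw$chrom,
                  pos = as.integer(.numOrNA(raw$pos, "pos", lines)),
                  ref = raw$ref, alt = raw$alt, gene = raw$gene,
                  transcript = raw$transcript,
                  consequence = raw$consequence)
  bad <- which(!nzchar(v$ref) | !nzchar(v$alt) | is.na(v$pos))
  if (length(bad))
    stop("malformed variant row at line ", lines[bad[1]])
  for (col in c("gnomad_ac", "gnomad_af", "pli", "loftool", "cadd_phred",
                "mtr_fdr", "ada_score", "rf_score", "qd", "fs", "sor",
                "mq_rank_sum", "read_pos_rank_sum", "excess_het_z"))
    v[[col]] <- .numOrNA(raw[[col]], col, lines)
  v$gnomad_ac <- as.integer(v$gnomad_ac)
  if (split_preds) {
    v$sift_call <- blank2na(raw$sift_call)
    v$sift_score <- .numOrNA(raw$sift_score, "sift_score", lines)
    v$polyphen_call <- blank2na(raw$polyphen_call)
    v$polyphen_score <- .numOrNA(raw$polyphen_score, "polyphen_score", lines)
  } else {
    s <- .parsePredictionString(raw$sift, "sift")
    p <- .parsePredictionString(raw$polyphen, "polyphen")
    v$sift_call <- s$call; v$sift_score <- s$score
    v$polyphen_call <- p$call; v$polyphen_score <- p$score
  }
  v$filter <- ifelse(nzchar(raw$filter), raw$filter, "PASS")
  terms <- unique(unlist(strsplit(v$consequence, ",", fixed = TRUE)))
  unknown <- setdiff(terms, .KNOWN_CONSEQUENCES)
  if (length(unknown))
    warning("unknown consequence term(s) retained verbatim: ",
            paste(unknown, collapse = ", "), call. = FALSE)

  gt_cols <- grep("\\.gt$", names(raw), value = TRUE)
  samples <- sub("\\.gt$", "", gt_cols)
  v$uid <- .variantUID(v$family, v$chrom, v$pos, v$ref, v$alt, v$transcript)
  geno <- list()
  for (s in samples) {
    gt_raw <- raw[[paste0(s, ".gt")]]
    keep <- nzchar(gt_raw)
    if (!any(keep)) next
    geno[[s]] <- data.frame(
      uid = v$uid[keep], sample = s, gt = .gtFromString(gt_raw[keep]),
      dp = .numOrNA(raw[[paste0(s, ".dp")]][keep], paste0(s, ".dp"),
                    lines[keep]),
      gq = .numOrNA(raw[[paste0(s, ".gq")]][keep], paste0(s, ".gq"),
                    lines[keep]))
  }
  geno <- if (length(geno)) do.call(rbind, geno) else data.frame()
  VariantTable(v, geno)
}

#' Write annotated variants in the canonical TSV dialect
#'
#' @param x a \linkS4class{VariantTable}.
#' @param path output path.
#' @return \code{path}, invisibly. \code{readAnnotatedVariants} on the
#'   output reproduces \code{x} field by field.
#' @export
writeAnnotatedVariants <- function(x, path) {
  stopifnot(is(x, "VariantTable"))
  v <- variants(x)
  g <- genotypes(x)
  numfmt <- function(z) ifelse(is.na(z), "",
                               formatC(z, format = "g", digits = 15))
  out <- data.frame(family = v$family, chrom = v$chrom, pos = v$pos,
                    ref = v$ref, alt = v$alt, gene = v$gene,
                    transcript = v$transcript, consequence = v$consequence,
                    check.names = FALSE)
  for (col in c("gnomad_ac", "gnomad_af", "pli", "loftool", "cadd_phred"))
    out[[col]] <- numfmt(v[[col]])
  out$sift <- .formatPredictionString(v$sift_call, v$sift_score)
  out$polyphen <- .formatPredictionString(v$polyphen_call, v$polyphen_score)
  for (col in c("mtr_fdr", "ada_score", "rf_score", "qd", "fs", "sor",
                "mq_rank_sum", "read_pos_rank_sum", "excess_het_z"))
    out[[col]] <- numfmt(v[[col]])
  out$filter <- v$filter
  for (s in sort(unique(g$sample))) {
    gs <- g[g$sample == s, , drop = FALSE]
    idx <- match(v$uid, gs$uid)
    out[[paste0(s, ".gt")]] <- ifelse(is.na(idx), "",
                                      .gtToString(gs$gt[idx]))
    out[[paste0(s, ".dp")]] <- ifelse(is.na(idx), "", numfmt(gs$dp[idx]))
    out[[paste0(s, ".gq")]] <- ifelse(is.na(idx), "", numfmt(gs$gq[idx]))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## VCF adapter: site INFO carries the QC metrics, CSQ carries per-transcript
## functional annotation, FORMAT GT:DP:GQ carries genotypes. FAM names the
## family of each record.
.CSQ_FIELDS <- c("Allele", "SYMBOL", "Feature", "Consequence", "gnomAD_AC",
  "gnomAD_AF", "ExACpLI", "LoFtool", "CADD_PHRED", "SIFT", "PolyPhen",
  "MTR_FDR", "ada_score", "rf_score")

.readVariantsVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  if (!n) return(VariantTable(.emptyVariantFrame(), data.frame()))
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  csq_desc <- VariantAnnotation::info(VariantAnnotation::header(vcf))["CSQ",
                                                                      "Description"]
  fields <- strsplit(sub(".*Format: *", "", csq_desc), "|",
                     fixed = TRUE)[[1]]
  num1 <- function(x) if (is.null(x)) rep(NA_real_, n) else
    vapply(as.list(x), function(e)
      if (length(e) == 0 || is.na(e[1])) NA_real_ else as.numeric(e[1]),
      numeric(1))
  site <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(as.list(rr$ALT), function(a) as.character(a)[1],
                 character(1)),
    family = vapply(as.list(info$FAM), function(e)
      if (length(e)) as.character(e[1]) else NA_character_, character(1)),
    qd = num1(info$QD), fs = num1(info$FS), sor = num1(info$SOR),
    mq_rank_sum = num1(info$MQRankSum),
    read_pos_rank_sum = num1(info$ReadPosRankSum),
    excess_het_z = num1(info$ExcHetZ),
    filter = as.character(VariantAnnotation::filt(vcf)))
  site$filter[is.na(site$filter) | site$filter == "."] <- "PASS"

  rows <- list()
  csq <- info$CSQ
  for (i in seq_len(n)) {
    for (entry in as.character(csq[[i]])) {
      parts <- strsplit(entry, "|", fixed = TRUE)[[1]]
      length(parts) <- length(fields)
      ann <- setNames(as.list(parts), fields)
      blank <- function(x) if (is.null(x) || is.na(x) || !nzchar(x))
        NA_character_ else x
      sift <- .parsePredictionString(blank(ann$SIFT) %||% "", "sift")
      poly <- .parsePredictionString(blank(ann$PolyPhen) %||% "", "polyphen")
      numf <- function(x) suppressWarnings(as.numeric(blank(x)))
      rows[[length(rows) + 1L]] <- data.frame(
        site[i, , drop = FALSE],
        gene = blank(ann$SYMBOL), transcript = blank(ann$Feature),
        consequence = gsub("&", ",", blank(ann$Consequence)),
        gnomad_ac = as.integer(numf(ann$gnomAD_AC)),
        gnomad_af = numf(ann$gnomAD_AF), pli = numf(ann$ExACpLI),
        loftool = numf(ann$LoFtool), cadd_phred = numf(ann$CADD_PHRED),
        sift_call = sift$call, sift_score = sift$score,
        polyphen_call = poly$call, polyphen_score = poly$score,
        mtr_fdr = numf(ann$MTR_FDR), ada_score = numf(ann$ada_score),
        rf_score = numf(ann$rf_score), row.names = NULL)
    }
  }
  v <- do.call(rbind, rows)
  v$uid <- .variantUID(v$family, v$chrom, v$pos, v$ref, v$alt, v$transcript)

  geno <- list()
  gt <- VariantAnnotation::geno(vcf)$GT
  dp <- VariantAnnotation::geno(vcf)$DP
  gq <- VariantAnnotation::geno(vcf)$GQ
  site_uid <- .variantUID(site$family, site$chrom, site$pos, site$ref,
                          site$alt, "x")
  for (s in colnames(gt)) {
    keep <- !is.na(gt[, s]) & gt[, s] != "./."
    if (!any(keep)) next
    site_idx <- which(keep)
    for (i in site_idx) {
      vrows <- which(v$family == site$family[i] & v$chrom == site$chrom[i] &
                       v$pos == site$pos[i] & v$alt == site$alt[i])
      geno[[length(geno) + 1L]] <- data.frame(
        uid = v$uid[vrows], sample = s, gt = .gtFromString(gt[i, s]),
        dp = as.numeric(dp[i, s]), gq = as.numeric(gq[i, s]))
    }
  }
  geno <- if (length(geno)) do.call(rbind, geno) else data.frame()
  VariantTable(v, geno)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Read a 6-column PED pedigree file
#'
#' Standard whitespace-delimited PED (FID IID PAT MAT SEX PHENO) with an
#' optional 7th \code{twin} column annotating monozygotic twin groups. Sex
#' is 1=male, 2=female, 0=unknown; phenotype 2=affected, 1=unaffected,
#' 0=unknown; a parent id of 0 means unavailable.
#'
#' @param path path to the PED file.
#' @return a validated \linkS4class{Pedigree}.
#' @export
readPedigree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.table(path, colClasses = "character", header = FALSE,
                    col.names = c("family", "id", "father", "mother",
                                  "sex", "affected", "twin"),
                    fill = TRUE)
  Pedigree(raw)
}

#' Construct a Pedigree from a data.frame
#'
#' @param df data.frame with PED columns (numeric or word coding accepted).
#' @return a validated \linkS4class{Pedigree}.
#' @export
Pedigree <- function(df) {
  df <- as.data.frame(df)
  if (is.null(df$twin)) df$twin <- ""
  df$twin[is.na(df$twin)] <- ""
  zero2blank <- function(x) ifelse(x %in% c("0", "", NA), "", x)
  df$father <- zero2blank(as.character(df$father))
  df$mother <- zero2blank(as.character(df$mother))
  sex <- as.character(df$sex)
  df$sex <- ifelse(sex %in% c("1", "male"), "male",
                   ifelse(sex %in% c("2", "female"), "female", "unknown"))
  aff <- as.character(df$affected)
  df$affected <- ifelse(aff %in% c("2", "affected"), "affected",
                        ifelse(aff %in% c("1", "unaffected"), "unaffected",
                               "unknown"))
  df$family <- as.character(df$family); df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicate sample id in pedigree: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  dangling <- setdiff(setdiff(c(df$father, df$mother), ""), df$id)
  if (length(dangling))
    stop("pedigree parent id does not resolve: ",
         paste(dangling, collapse = ", "))
  new("Pedigree", ped = df[, c("family", "id", "father", "mother", "sex",
                               "affected", "twin")])
}

#' Write a Pedigree as a 6(+1)-column PED file
#' @param x a \linkS4class{Pedigree}.
#' @param path output path.
#' @export
writePedigree <- function(x, path) {
  p <- pedTable(x)
  out <- data.frame(
    p$family, p$id,
    ifelse(p$father == "", "0", p$father),
    ifelse(p$mother == "", "0", p$mother),
    c(male = "1", female = "2", unknown = "0")[p$sex],
    c(affected = "2", unaffected = "1", unknown = "0")[p$affected])
  if (any(nzchar(p$twin))) out$twin <- ifelse(nzchar(p$twin), p$twin, "0")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Construct an ExpressionMatrix
#'
#' @param values numeric genes x samples matrix with gene symbols as
#'   rownames and sample ids as colnames.
#' @param sampleData optional data.frame of per-sample metadata (donor id,
#'   developmental stage); rownames or a \code{sample_id} column must match
#'   the matrix columns.
#' @return a validated \linkS4class{ExpressionMatrix}.
#' @export
ExpressionMatrix <- function(values, sampleData = NULL) {
  values <- as.matrix(values)
  if (is.null(sampleData)) {
    sampleData <- S4Vectors::DataFrame(row.names = colnames(values))
  } else {
    sampleData <- as.data.frame(sampleData)
    if ("sample_id" %in% names(sampleData))
      rownames(sampleData) <- sampleData$sample_id
    if (!setequal(rownames(sampleData), colnames(values)))
      stop("sample metadata does not match matrix columns")
    sampleData <- S4Vectors::DataFrame(sampleData[colnames(values), ,
                                                  drop = FALSE])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values), colData = sampleData)
  new("ExpressionMatrix", se)
}

#' Read a genes x samples expression matrix with sample metadata
#'
#' @param path TSV with gene symbols in the first column and one numeric
#'   column per sample.
#' @param metadataPath optional TSV with columns \code{sample_id},
#'   \code{donor_id}, \code{stage_label}, \code{age_value}, \code{age_unit}.
#' @return an \linkS4class{ExpressionMatrix}; sample order follows the
#'   matrix file.
#' @export
readExpressionMatrix <- function(path, metadataPath = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  genes <- raw[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene symbol(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                  dimnames = list(genes, colnames(m))))
  bad <- which(is.na(vals) & !is.na(m) & nzchar(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric expression value '", m[bad[1, 1], bad[1, 2]],
         "' for gene ", genes[bad[1, 1]])
  meta <- NULL
  if (!is.null(metadataPath)) {
    meta <- read.delim(metadataPath, check.names = FALSE)
    if (!setequal(meta$sample_id, colnames(vals)))
      stop("metadata samples do not match matrix samples")
  }
  ExpressionMatrix(vals, meta)
}

#' Write an ExpressionMatrix (values + metadata) as TSV
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path output TSV for the matrix.
#' @param metadataPath optional output TSV for the sample metadata.
#' @export
writeExpressionMatrix <- function(x, path, metadataPath = NULL) {
  vals <- SummarizedExperiment::assay(x, "expr")
  out <- data.frame(gene = rownames(vals),
                    formatC(vals, format = "g", digits = 15),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadataPath)) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    if (!"sample_id" %in% names(cd)) cd <- cbind(sample_id = colnames(vals), cd)
    write.table(cd, metadataPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read gene panel files (one symbol per line, # comments allowed)
#'
#' @param paths named character vector of file paths; names become panel
#'   names (file base names are used when unnamed).
#' @return a \linkS4class{GenePanelSet}; symbols are upper-cased.
#' @export
readGenePanels <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  panels <- lapply(paths, function(p) {
    lines <- trimws(readLines(p))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    unique(toupper(lines))
  })
  GenePanelSet(panels)
}

#' Construct a GenePanelSet
#' @param panels named list of character vectors of gene symbols.
#' @param provenance optional named character vector of source labels.
#' @export
GenePanelSet <- function(panels, provenance = NULL) {
  panels <- lapply(panels, function(p) unique(toupper(p)))
  if (is.null(provenance))
    provenance <- setNames(names(panels), names(panels))
  new("GenePanelSet", panels = panels, provenance = provenance)
}

#' Read structural/copy-number variant calls (BED-derived TSV)
#'
#' Columns: family, chrom, start, end, sv_type, caller, sv_af,
#' families_observed. Coordinates are 1-based inclusive.
#'
#' @param path input TSV.
#' @return data.frame of calls.
#' @export
readStructuralVariants <- function(path) {
  sv <- read.delim(path, check.names = FALSE)
  need <- c("family", "chrom", "start", "end", "sv_type", "caller",
            "sv_af", "families_observed")
  missing_cols <- setdiff(need, names(sv))
  if (length(missing_cols))
    stop("SV table missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(sv$start > sv$end)) stop("SV start must be <= end")
  sv$sv_af <- suppressWarnings(as.numeric(sv$sv_af))
  sv
}
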