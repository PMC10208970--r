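#' @rdname VariantTable-class
#' @param x,object a \code{VariantTable}
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname VariantTable-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname Pedigree-class
#' @export
setGeneric("pedTable", function(x) standardGeneric("pedTable"))

#' @rdname Pedigree-class
#' @export
setGeneric("probands", function(x) standardGeneric("probands"))

#' @rdname GenePanelSet-class
#' @export
setGeneric("panels", function(x) standardGeneric("panels"))

#' @rdname GenePanelSet-class
#' @export
setGeneric("panelUnion", function(x) standardGeneric("panelUnion"))

#' @rdname CoexpressionResult-class
#' @export
setGeneric("setStatistic", function(x) standardGeneric("setStatistic"))

#' @rdname CoexpressionResult-class
#' @export
setGeneric("mcPValue", function(x) standardGeneric("mcPValue"))

#' @rdname CoexpressionResult-class
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))

#' @rdname CoexpressionResult-class
#' @export
setGeneric("edgeThreshold", function(x) standardGeneric("edgeThreshold"))

setMethod("variants", "VariantTable", function(x) x@variants)
setMethod("genotypes", "VariantTable", function(x) x@genotypes)

setMethod("show", "VariantTable", function(object) {
  v <- object@variants
  cat("VariantTable with", nrow(v), "records in",
      length(unique(v$family)), "families;",
      length(unique(object@genotypes$sample)), "genotyped samples\n")
  if (nrow(v))
    cat("  genes:", paste(head(sort(unique(v$gene)), 6), collapse = ", "),
        if (length(unique(v$gene)) > 6) "..." else "", "\n")
})

setMethod("pedTable", "Pedigree", function(x) x@ped)

#' @describeIn Pedigree-class affected individuals with at least one listed
#'   parent (one analysis proband per family; monozygotic co-twins are
#'   collapsed to the first twin).
setMethod("probands", "Pedigree", function(x) {
  p <- x@ped
  cand <- p[p$affected == "affected" &
              (p$father != "" | p$mother != ""), , drop = FALSE]
  ## singleton families: an affected individual without listed parents
  solo <- p[p$affected == "affected" & !(p$family %in% cand$family), ,
            drop = FALSE]
  cand <- rbind(cand, solo)
  out <- character()
  for (fam in unique(cand$family)) {
    rows <- cand[cand$family == fam, , drop = FALSE]
    if (nrow(rows) > 1 && any(nzchar(rows$twin))) {
      keep <- !duplicated(ifelse(nzchar(rows$twin), rows$twin, rows$id))
      rows <- rows[keep, , drop = FALSE]
    }
    out <- c(out, setNames(rows$id[1], fam))
  }
  out
})

setMethod("show", "Pedigree", function(object) {
  p <- object@ped
  cat("Pedigree with", nrow(p), "individuals in",
      length(unique(p$family)), "families (",
      sum(p$affected == "affected"), "affected )\n")
})

setMethod("panels", "GenePanelSet", function(x) x@panels)
setMethod("panelUnion", "GenePanelSet", function(x)
  unique(unlist(x@panels, use.names = FALSE)))

setMethod("show", "GenePanelSet", function(object) {
  sizes <- vapply(object@panels, length, integer(1))
  cat("GenePanelSet with", length(sizes), "panels (union",
      length(panelUnion(object)), "genes)\n")
  for (nm in names(sizes)) cat("  ", nm, ": ", sizes[[nm]], " genes\n",
                               sep = "")
})

setMethod("setStatistic", "CoexpressionResult", function(x) x@setStatistic)
setMethod("mcPValue", "CoexpressionResult", function(x) x@mcP)
setMethod("edgeList", "CoexpressionResult", function(x) x@edges)
setMethod("edgeThreshold", "CoexpressionResult", function(x) x@threshold)

setMethod("show", "CoexpressionResult", function(object) {
  cat("CoexpressionResult for", length(object@geneSet), "genes\n")
  cat("  median |rho| =", format(object@setStatistic, digits = 4),
      "over", object@nPairs, "pairs",
      if (object@nMissing) paste0("(", object@nMissing, " undefined)") else "",
      "\n")
  if (length(object@mcP) && !is.na(object@mcP))
    cat("  Monte-Carlo p =", format(object@mcP, digits = 4),
        "(", object@nIter, "draws, seed", object@seed, ")\n")
  if (length(object@threshold) && !is.na(object@threshold))
    cat("  edge threshold |rho| >=", format(object@threshold, digits = 4),
        ":", nrow(object@edges), "edges\n")
})
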