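## Generics, accessors and show methods.

#' @rdname Pedigree-class
#' @param object,x an object.
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))
#' @rdname Pedigree-class
#' @export
setMethod("familyId", "Pedigree", function(x) x@familyId)

#' @rdname Pedigree-class
#' @export
setGeneric("pedSamples", function(x) standardGeneric("pedSamples"))
#' @rdname Pedigree-class
#' @export
setMethod("pedSamples", "Pedigree", function(x) x@samples)

.idsByRole <- function(ped, role) {
  s <- ped@samples
  s$sample_id[s$role %in% role]
}

#' Sample identifiers by analysis role
#'
#' @param ped a \linkS4class{Pedigree}.
#' @return character vector of sample ids.
#' @export
caseIds <- function(ped) .idsByRole(ped, "case")

#' @rdname caseIds
#' @export
controlIds <- function(ped) .idsByRole(ped, "control")

#' @rdname caseIds
#' @export
obligateCarrierIds <- function(ped) .idsByRole(ped, "obligate_carrier")

setMethod("show", "Pedigree", function(object) {
  s <- object@samples
  cat(sprintf("Pedigree %s: %d samples (%d cases, %d controls, %d obligate carriers)\n",
              object@familyId, nrow(s), sum(s$role == "case"),
              sum(s$role == "control"), sum(s$role == "obligate_carrier")))
})

#' @rdname VariantCohort-class
#' @param x a VariantCohort.
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname VariantCohort-class
#' @export
setMethod("annotations", "VariantCohort", function(x) x@ann)

#' @rdname VariantCohort-class
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname VariantCohort-class
#' @export
setMethod("dosages", "VariantCohort", function(x) x@dosage)

#' @rdname VariantCohort-class
#' @export
setGeneric("strandCounts", function(x) standardGeneric("strandCounts"))
#' @rdname VariantCohort-class
#' @export
setMethod("strandCounts", "VariantCohort",
          function(x) list(forward = x@adf, reverse = x@adr))

#' @rdname VariantCohort-class
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname VariantCohort-class
#' @export
setMethod("nVariants", "VariantCohort", function(x) nrow(x@ann))

#' @rdname VariantCohort-class
#' @export
setGeneric("cohortSamples", function(x) standardGeneric("cohortSamples"))
#' @rdname VariantCohort-class
#' @export
setMethod("cohortSamples", "VariantCohort", function(x) colnames(x@dosage))

#' Subset a VariantCohort by variant
#'
#' @param x a \linkS4class{VariantCohort}.
#' @param i logical/integer/character index over variants (character matches
#'   variant_id).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "VariantCohort", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ann$variant_id)
  ann <- x@ann[i, , drop = FALSE]
  rownames(ann) <- NULL
  initialize(x, ann = ann,
             dosage = x@dosage[i, , drop = FALSE],
             depth = x@depth[i, , drop = FALSE],
             gq = x@gq[i, , drop = FALSE],
             adf = x@adf[i, , drop = FALSE],
             adr = x@adr[i, , drop = FALSE])
})

setMethod("show", "VariantCohort", function(object) {
  cat(sprintf("VariantCohort: %d variants x %d samples\n",
              nrow(object@ann), ncol(object@dosage)))
  if (nrow(object@ann)) {
    tab <- table(object@ann$functional_class)
    cat("  functional classes:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
})

#' @rdname RegulatoryTrack-class
#' @param x a RegulatoryTrack.
#' @export
setGeneric("trackCategory", function(x) standardGeneric("trackCategory"))
#' @rdname RegulatoryTrack-class
#' @export
setMethod("trackCategory", "RegulatoryTrack", function(x) x@category)

#' @rdname RegulatoryTrack-class
#' @export
setGeneric("trackIntervals", function(x) standardGeneric("trackIntervals"))
#' @rdname RegulatoryTrack-class
#' @export
setMethod("trackIntervals", "RegulatoryTrack", function(x) x@intervals)

setMethod("show", "RegulatoryTrack", function(object) {
  cat(sprintf("RegulatoryTrack %s [%s]: %d intervals\n", object@name,
              object@category, length(object@intervals)))
})

#' @rdname GenePanel-class
#' @param x a GenePanel.
#' @export
setGeneric("panelEntries", function(x) standardGeneric("panelEntries"))
#' @rdname GenePanel-class
#' @export
setMethod("panelEntries", "GenePanel", function(x) x@entries)

#' @rdname GenePanel-class
#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))
#' @rdname GenePanel-class
#' @export
setMethod("panelName", "GenePanel", function(x) x@name)

#' @rdname GenePanel-class
#' @export
setMethod("length", "GenePanel", function(x) length(x@entries))

setMethod("show", "GenePanel", function(object) {
  cat(sprintf("GenePanel %s: %d genes (%s)\n", object@name,
              length(object@entries),
              paste(names(sort(table(object@entries), decreasing = TRUE)),
                    collapse = ", ")))
})

setMethod("show", "SegregationPolicy", function(object) {
  cat(sprintf(
    "SegregationPolicy: %s; all cases carry: %s; obligate carriers carry: %s; max control carriers: %d; missing genotypes: %s\n",
    object@inheritance, object@requireAllCases,
    object@obligateCarriersMustCarry, object@maxControlCarriers,
    object@missingGenotypeHandling))
})

## Chromosome ordering used by every deterministic tie-break -----------------

chromOrderKey <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  key <- suppressWarnings(as.integer(chrom))
  key[chrom == "X"] <- 23L
  key[chrom == "Y"] <- 24L
  key[chrom %in% c("M", "MT")] <- 25L
  key[is.na(key)] <- 26L
  key
}
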