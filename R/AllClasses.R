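#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats rbinom rpois rnorm runif rbeta rgamma qgamma pgamma
#'   pnorm pbeta setNames
#' @importFrom utils read.delim write.table
NULL

## Controlled vocabularies shared across the package ------------------------

.SEX_LEVELS <- c("male", "female", "unknown")
.ROLE_LEVELS <- c("case", "control", "obligate_carrier", "unknown")
.FUNCTIONAL_CLASSES <- c(
  "nonsynonymous_snv", "synonymous_snv", "stopgain_snv",
  "frameshift_deletion", "frameshift_insertion",
  "utr5", "utr3", "upstream", "downstream", "intronic", "intergenic", "other"
)
.TRACK_CATEGORIES <- c(
  "mirna_target", "promoter", "enhancer", "super_enhancer", "tfbs",
  "cpg_island"
)

## Effect-predictor panels consumed from the annotation table. Ten missense
## tools vote deleterious/tolerated; eight nonsense tools vote
## pathogenic/benign; three gene-intolerance sources flag intolerant/tolerant.
.MISSENSE_PREDICTORS <- c(
  "sift", "polyphen2_hdiv", "polyphen2_hvar", "lrt", "mutation_taster",
  "mutation_assessor", "fathmm", "metasvm", "metalr", "provean"
)
.NONSENSE_PREDICTORS <- c(
  "dann", "mutation_taster", "fathmm_mkl", "fathmm_xf", "aloft",
  "eigen", "eigen_pc", "primateai"
)
.INTOLERANCE_SOURCES <- c("esp6500", "exac", "local")

missenseColumns <- function() paste0("mis_", .MISSENSE_PREDICTORS)
nonsenseColumns <- function() paste0("non_", .NONSENSE_PREDICTORS)
intoleranceColumns <- function() paste0("int_", .INTOLERANCE_SOURCES)

.ANNOTATION_COLUMNS <- function() c(
  "chrom", "pos", "ref", "alt", "variant_id", "variant_class",
  "site_quality", "site_coverage", "platypus_pass",
  "gene_symbols", "functional_class", "protein_effect",
  "maf_1000g", "maf_exac_nontcga", "cadd_phred",
  "gerp", "phastcons", "phylop",
  missenseColumns(), nonsenseColumns(), intoleranceColumns(),
  "pli", "missense_z", "mirsvr"
)

#' Compose the canonical variant identifier
#'
#' Variants are keyed throughout the package as `chrom_pos_ref_alt`
#' (1-based position), the notation used in candidate tables.
#'
#' @param chrom,pos,ref,alt vectors describing one allele per element.
#' @return character vector of identifiers.
#' @export
variantId <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = "_")
}

## Pedigree ------------------------------------------------------------------

#' Pedigree of one family
#'
#' Holds the family structure and affection-derived analysis roles. Each row
#' of `samples` describes one individual: `sample_id`, `father_id`,
#' `mother_id` (NA when unknown/founder), `sex` (male/female/unknown) and
#' `role` (case/control/obligate_carrier/unknown). An obligate carrier is an
#' unaffected individual who must carry the familial variant by pedigree
#' position; the role is distinct from control so segregation filtering can
#' require carriage without counting the individual as a carrier control.
#'
#' @slot familyId single family identifier.
#' @slot samples data.frame of individuals as described above.
#' @export
setClass("Pedigree", representation(familyId = "character",
                                    samples = "data.frame"))

.validPedigree <- function(object) {
  msg <- character()
  s <- object@samples
  need <- c("sample_id", "father_id", "mother_id", "sex", "role")
  if (!all(need %in% names(s)))
    return(paste("samples must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(s$sample_id))
    msg <- c(msg, "duplicate sample_id within family")
  if (!all(s$sex %in% .SEX_LEVELS))
    msg <- c(msg, "sex must be male/female/unknown")
  if (!all(s$role %in% .ROLE_LEVELS))
    msg <- c(msg, "role must be case/control/obligate_carrier/unknown")
  if (!any(s$role == "case"))
    msg <- c(msg, "pedigree must contain at least one case")
  for (col in c("father_id", "mother_id")) {
    ref <- s[[col]]
    bad <- !is.na(ref) & !(ref %in% s$sample_id)
    if (any(bad))
      msg <- c(msg, sprintf("unresolvable %s for sample(s): %s", col,
                            paste(s$sample_id[bad], collapse = ", ")))
  }
  ## parent sex compatibility (unknown tolerated)
  fsex <- s$sex[match(s$father_id, s$sample_id)]
  if (any(!is.na(fsex) & fsex == "female"))
    msg <- c(msg, "father_id refers to a female sample")
  msex <- s$sex[match(s$mother_id, s$sample_id)]
  if (any(!is.na(msex) & msex == "male"))
    msg <- c(msg, "mother_id refers to a male sample")
  ## no individual is its own ancestor
  for (id in s$sample_id) {
    seen <- character(); frontier <- id
    while (length(frontier)) {
      i <- match(frontier, s$sample_id)
      parents <- c(s$father_id[i], s$mother_id[i])
      parents <- unique(parents[!is.na(parents)])
      if (id %in% parents) {
        msg <- c(msg, sprintf("sample %s is its own ancestor", id))
        break
      }
      frontier <- setdiff(parents, seen)
      seen <- union(seen, parents)
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("Pedigree", .validPedigree)

#' Construct a Pedigree
#'
#' @param familyId family identifier.
#' @param samples data.frame with columns sample_id, father_id, mother_id,
#'   sex, role (see \linkS4class{Pedigree}).
#' @return a \linkS4class{Pedigree}.
#' @export
Pedigree <- function(familyId, samples) {
  samples$sample_id <- as.character(samples$sample_id)
  samples$father_id <- as.character(samples$father_id)
  samples$mother_id <- as.character(samples$mother_id)
  samples$sex <- as.character(samples$sex)
  samples$role <- as.character(samples$role)
  rownames(samples) <- NULL
  new("Pedigree", familyId = as.character(familyId), samples = samples)
}

## VariantCohort -------------------------------------------------------------

#' Annotated variant calls joined with per-sample genotypes
#'
#' One row of `ann` per (chrom, pos, ref, alt) allele, carrying call-level
#' fields (site quality, coverage, caller PASS flag), gene and functional
#' annotation, population frequencies, CADD PHRED, conservation scores
#' (GERP/PhastCons/PhyloP), ten missense-predictor calls, eight
#' nonsense-predictor calls, three gene-intolerance flags, pLI, missense
#' Z-score and mirSVR. Missing annotation is NA, never zero. The genotype
#' matrices are variants x samples: `dosage` counts alternate alleles
#' (0/1/2, NA missing; male X may legitimately be 0/1), `depth` and `gq` are
#' per-sample read depth and genotype quality, `adf`/`adr` the
#' forward/reverse-strand alternate read counts used by the strand-bias
#' filter.
#'
#' @slot ann data.frame of per-variant annotation (see above).
#' @slot dosage,depth,gq,adf,adr numeric matrices, rownames = variant_id,
#'   colnames = sample_id.
#' @export
setClass("VariantCohort", representation(
  ann = "data.frame", dosage = "matrix", depth = "matrix",
  gq = "matrix", adf = "matrix", adr = "matrix"))

.validVariantCohort <- function(object) {
  msg <- character()
  ann <- object@ann
  need <- .ANNOTATION_COLUMNS()
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols))
    return(paste("ann lacks columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(ann)) {
    if (any(ann$pos < 1)) msg <- c(msg, "pos must be >= 1")
    rebuilt <- variantId(ann$chrom, ann$pos, ann$ref, ann$alt)
    if (!identical(as.character(ann$variant_id), rebuilt))
      msg <- c(msg, "variant_id does not round-trip chrom_pos_ref_alt")
    if (anyDuplicated(ann$variant_id))
      msg <- c(msg, "duplicate variant_id")
    ## NA functional_class = variant lacking an annotation row
    bad_fc <- !is.na(ann$functional_class) &
      !ann$functional_class %in% .FUNCTIONAL_CLASSES
    if (any(bad_fc))
      msg <- c(msg, paste("unknown functional_class:",
                          paste(unique(ann$functional_class[bad_fc]),
                                collapse = ", ")))
    if (!all(ann$variant_class %in% c("snv", "indel")))
      msg <- c(msg, "variant_class must be snv or indel")
  }
  for (nm in c("dosage", "depth", "gq", "adf", "adr")) {
    m <- slot(object, nm)
    if (nrow(m) != nrow(ann))
      msg <- c(msg, sprintf("%s has %d rows for %d variants", nm,
                            nrow(m), nrow(ann)))
    else if (nrow(m) && !identical(rownames(m), as.character(ann$variant_id)))
      msg <- c(msg, sprintf("%s rownames do not match variant_id", nm))
  }
  d <- object@dosage
  if (length(d) && !all(d %in% c(0, 1, 2) | is.na(d)))
    msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
}
setValidity("VariantCohort", .validVariantCohort)

#' Construct a VariantCohort
#'
#' @param ann annotation data.frame (one row per allele; see
#'   \linkS4class{VariantCohort}). Missing columns are added as NA.
#' @param dosage,depth,gq,adf,adr variants x samples matrices; all but
#'   `dosage` default to all-NA matrices of matching shape.
#' @return a \linkS4class{VariantCohort}.
#' @export
VariantCohort <- function(ann, dosage, depth = NULL, gq = NULL,
                          adf = NULL, adr = NULL) {
  for (col in .ANNOTATION_COLUMNS())
    if (is.null(ann[[col]])) ann[[col]] <- rep(NA, nrow(ann))
  ann$chrom <- as.character(ann$chrom)
  ann$variant_id <- variantId(ann$chrom, ann$pos, ann$ref, ann$alt)
  rownames(ann) <- NULL
  blank <- function(m) {
    if (!is.null(m)) return(.namedMatrix(m, ann$variant_id))
    matrix(NA_real_, nrow(dosage), ncol(dosage),
           dimnames = dimnames(.namedMatrix(dosage, ann$variant_id)))
  }
  dosage <- .namedMatrix(dosage, ann$variant_id)
  new("VariantCohort", ann = ann, dosage = dosage,
      depth = blank(depth), gq = blank(gq), adf = blank(adf),
      adr = blank(adr))
}

.namedMatrix <- function(m, ids) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  rownames(m) <- as.character(ids)
  m
}

## RegulatoryTrack ------------------------------------------------------------

#' Named set of regulatory intervals
#'
#' Wraps a \linkS4class{GRanges} of regulatory features of one category
#' (miRNA target sites, promoters, enhancers, super-enhancers, TFBS or CpG
#' islands). Interval labels, when the source BED carries a name column, are
#' kept in `mcols(intervals)$label`.
#'
#' @slot name track name.
#' @slot category one of mirna_target, promoter, enhancer, super_enhancer,
#'   tfbs, cpg_island.
#' @slot intervals GRanges, sorted by (chrom, start).
#' @export
setClass("RegulatoryTrack", representation(
  name = "character", category = "character", intervals = "GRanges"))

.validRegulatoryTrack <- function(object) {
  msg <- character()
  if (!object@category %in% .TRACK_CATEGORIES)
    msg <- c(msg, paste("category must be one of",
                        paste(.TRACK_CATEGORIES, collapse = ", ")))
  if (length(object@intervals) &&
      any(GenomicRanges::width(object@intervals) < 1))
    msg <- c(msg, "intervals must have start < end")
  if (length(msg)) msg else TRUE
}
setValidity("RegulatoryTrack", .validRegulatoryTrack)

#' Construct a RegulatoryTrack
#'
#' @param name track name.
#' @param category track category (see \linkS4class{RegulatoryTrack}).
#' @param intervals a GRanges; a `label` metadata column is added (NA) when
#'   absent. Intervals are sorted by (chrom, start).
#' @return a \linkS4class{RegulatoryTrack}.
#' @export
RegulatoryTrack <- function(name, category, intervals) {
  if (is.null(intervals$label))
    intervals$label <- NA_character_
  o <- order(as.character(GenomicRanges::seqnames(intervals)),
             GenomicRanges::start(intervals))
  new("RegulatoryTrack", name = name, category = category,
      intervals = intervals[o])
}

## GenePanel ------------------------------------------------------------------

#' Gene panel for candidate screening
#'
#' A named character vector mapping uppercased gene symbols to a category
#' string (e.g. "Autosomal Dominant", "Other CancerGene").
#'
#' @slot name panel name.
#' @slot entries named character vector, names = symbols, values = category.
#' @export
setClass("GenePanel", representation(name = "character",
                                     entries = "character"))

.validGenePanel <- function(object) {
  e <- object@entries
  if (length(e) && (is.null(names(e)) || any(!nzchar(names(e)))))
    return("entries must be named by non-empty gene symbols")
  if (length(e) && any(names(e) != toupper(names(e))))
    return("panel symbols must be uppercase")
  TRUE
}
setValidity("GenePanel", .validGenePanel)

#' Construct a GenePanel
#'
#' @param name panel name.
#' @param symbols character vector of gene symbols (uppercased on entry).
#' @param categories category per symbol (recycled if length 1). On
#'   duplicated symbols the first category wins and a warning names the
#'   conflicts.
#' @return a \linkS4class{GenePanel}.
#' @export
GenePanel <- function(name, symbols, categories) {
  symbols <- toupper(as.character(symbols))
  categories <- rep_len(as.character(categories), length(symbols))
  dup <- duplicated(symbols)
  if (any(dup)) {
    conflict <- vapply(unique(symbols[dup]), function(s) {
      length(unique(categories[symbols == s])) > 1L
    }, logical(1))
    if (any(conflict))
      warning("conflicting categories for symbol(s): ",
              paste(names(conflict)[conflict], collapse = ", "),
              "; keeping first occurrence")
    categories <- categories[!dup]
    symbols <- symbols[!dup]
  }
  new("GenePanel", name = name, entries = setNames(categories, symbols))
}

## SegregationPolicy ----------------------------------------------------------

#' Policy for dominant-model pedigree segregation filtering
#'
#' The default policy keeps a variant only when every genotyped case carries
#' at least one alternate allele, every genotyped obligate carrier does too,
#' and no control carries it. `maxControlCarriers` relaxes the control side
#' (tolerating phenocopies/reduced penetrance); `missingGenotypeHandling`
#' decides whether an ungenotyped case fails the variant ("strict") or is
#' ignored ("permissive", the default).
#'
#' @slot inheritance currently only "dominant".
#' @slot maxControlCarriers maximum number of carrier controls tolerated.
#' @slot requireAllCases all genotyped cases must carry (else at least one).
#' @slot obligateCarriersMustCarry require carriage in obligate carriers.
#' @slot missingGenotypeHandling "permissive" or "strict".
#' @export
setClass("SegregationPolicy", representation(
  inheritance = "character", maxControlCarriers = "integer",
  requireAllCases = "logical", obligateCarriersMustCarry = "logical",
  missingGenotypeHandling = "character"))

setValidity("SegregationPolicy", function(object) {
  msg <- character()
  if (!identical(object@inheritance, "dominant"))
    msg <- c(msg, "only the dominant model is supported")
  if (object@maxControlCarriers < 0L)
    msg <- c(msg, "maxControlCarriers must be >= 0")
  if (!object@missingGenotypeHandling %in% c("permissive", "strict"))
    msg <- c(msg, "missingGenotypeHandling must be permissive or strict")
  if (length(msg)) msg else TRUE
})

#' Construct a SegregationPolicy
#'
#' @param maxControlCarriers integer >= 0 (default 0).
#' @param requireAllCases logical (default TRUE).
#' @param obligateCarriersMustCarry logical (default TRUE).
#' @param missingGenotypeHandling "permissive" (default) or "strict".
#' @param inheritance "dominant".
#' @return a \linkS4class{SegregationPolicy}.
#' @export
SegregationPolicy <- function(maxControlCarriers = 0L,
                              requireAllCases = TRUE,
                              obligateCarriersMustCarry = TRUE,
                              missingGenotypeHandling = "permissive",
                              inheritance = "dominant") {
  new("SegregationPolicy", inheritance = inheritance,
      maxControlCarriers = as.integer(maxControlCarriers),
      requireAllCases = requireAllCases,
      obligateCarriersMustCarry = obligateCarriersMustCarry,
      missingGenotypeHandling = missingGenotypeHandling)
}
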