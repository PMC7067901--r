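## Tiered per-family candidate reports and the pathway-analysis input
## export. Tier 1: retained variant hitting at least one gene panel;
## tier 2: retained coding, no panel hit; tier 3: retained non-coding, no
## panel hit. Every retained variant appears exactly once.

#' Per-family candidate report
#'
#' @slot familyId family identifier.
#' @slot rows data.frame of retained variants with arm, category, tier
#'   and rank.
#' @slot funnel per-stage funnel counts for the family.
#' @slot categoryCounts data.frame (arm, category, n).
#' @export
setClass("CandidateReport", representation(
  familyId = "character", rows = "data.frame", funnel = "data.frame",
  categoryCounts = "data.frame"))

setMethod("show", "CandidateReport", function(object) {
  r <- object@rows
  cat(sprintf("CandidateReport %s: %d candidates (tier1 %d, tier2 %d, tier3 %d)\n",
              object@familyId, nrow(r), sum(r$tier == 1),
              sum(r$tier == 2), sum(r$tier == 3)))
})

#' @rdname CandidateReport-class
#' @param x a CandidateReport.
#' @export
setGeneric("reportRows", function(x) standardGeneric("reportRows"))
#' @rdname CandidateReport-class
#' @export
setMethod("reportRows", "CandidateReport", function(x) x@rows)

#' @rdname CandidateReport-class
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))
#' @rdname CandidateReport-class
#' @export
setMethod("categoryCounts", "CandidateReport", function(x) x@categoryCounts)

.noncodingCategories <- function(noncoding) {
  ## per retained non-coding row, the regulatory categories it hits,
  ## valid for its region side
  lapply(seq_len(nrow(noncoding)), function(i) {
    if (noncoding$region[i] == "utr3_or_downstream") {
      if (nzchar(noncoding$hits_mirna_target[i])) "mirna_target" else
        character()
    } else {
      cats <- .FIVE_PRIME_CATEGORIES
      cats[vapply(paste0("hits_", cats),
                  function(c) nzchar(noncoding[[c]][i]), logical(1))]
    }
  })
}

#' Build tiered per-family candidate reports
#'
#' Combines the retained coding and non-coding candidates, panel hits and
#' funnel counts into one \linkS4class{CandidateReport} per family. A
#' variant present in both the coding and non-coding retained sets is an
#' annotation inconsistency and is rejected. Totals are conserved:
#' panel hits re-tier variants, they never duplicate them.
#'
#' @param coding result of [prioritizeCoding()] (all rows; only retained
#'   ones enter the report).
#' @param noncoding the `assessments` element of [selectNoncoding()]
#'   (needs a family_id column when more than one family is present).
#' @param panelHits result of [screenPanel()] (or rbind of several), or
#'   NULL.
#' @param funnel rbind of [runFunnel()] `counts`, or NULL.
#' @return named list of \linkS4class{CandidateReport}, one per family.
#' @export
buildReport <- function(coding, noncoding = NULL, panelHits = NULL,
                        funnel = NULL) {
  codingKeep <- coding[coding$retained, , drop = FALSE]
  if (is.null(noncoding)) {
    noncoding <- data.frame(variant_id = character(),
                            family_id = character(), retained = logical())
  }
  ncKeep <- noncoding[noncoding$retained, , drop = FALSE]
  both <- intersect(codingKeep$variant_id, ncKeep$variant_id)
  if (length(both))
    stop("variant(s) retained as both coding and non-coding: ",
         paste(both, collapse = ", "))
  hitIds <- if (is.null(panelHits)) character() else
    unique(panelHits$variant_id)

  famOf <- function(df) {
    if (!is.null(df$family_id) && nrow(df)) as.character(df$family_id)
    else rep("cohort", nrow(df))
  }
  codingFam <- famOf(codingKeep); ncFam <- famOf(ncKeep)
  families <- sort(unique(c(codingFam, ncFam,
                            if (!is.null(funnel)) funnel$family_id)))
  if (!length(families)) families <- "cohort"

  reports <- lapply(families, function(fam) {
    cd <- codingKeep[codingFam == fam, , drop = FALSE]
    nc <- ncKeep[ncFam == fam, , drop = FALSE]
    ncCats <- .noncodingCategories(nc)
    rows <- rbind(
      if (nrow(cd)) data.frame(
        variant_id = cd$variant_id, arm = "coding",
        gene_symbols = cd$gene_symbols, category = cd$path,
        rank = cd$rank, stringsAsFactors = FALSE),
      if (nrow(nc)) data.frame(
        variant_id = nc$variant_id, arm = "noncoding",
        gene_symbols = if (is.null(nc$gene)) NA_character_ else nc$gene,
        category = vapply(ncCats, paste, "", collapse = ";"),
        rank = NA_integer_, stringsAsFactors = FALSE))
    if (is.null(rows))
      rows <- data.frame(variant_id = character(), arm = character(),
                         gene_symbols = character(), category = character(),
                         rank = integer(), stringsAsFactors = FALSE)
    rows$tier <- ifelse(rows$variant_id %in% hitIds, 1L,
                        ifelse(rows$arm == "coding", 2L, 3L))
    counts <- data.frame(
      arm = c("coding", "coding", rep("noncoding", 5)),
      category = c("missense", "nonsense", "mirna_target",
                   .FIVE_PRIME_CATEGORIES),
      stringsAsFactors = FALSE)
    counts$n <- c(sum(cd$path == "missense"), sum(cd$path == "nonsense"),
                  vapply(counts$category[-(1:2)], function(cat)
                    sum(vapply(ncCats, function(x) cat %in% x, logical(1))),
                    numeric(1)))
    new("CandidateReport", familyId = fam, rows = rows,
        funnel = if (is.null(funnel)) data.frame() else
          funnel[funnel$family_id == fam, , drop = FALSE],
        categoryCounts = counts)
  })
  names(reports) <- families
  reports
}

#' Export the pathway-analysis input gene set
#'
#' Distinct gene symbols of retained, segregating coding candidates with
#' CADD PHRED strictly above `caddCutoff` (default 20); multi-gene
#' annotations contribute each symbol. Intergenic and intronic variants
#' never reach the coding assessment, so the set matches the "segregating,
#' CADD > 20, not intergenic/intronic" contract. Sorted; optionally
#' written one symbol per line.
#'
#' @param coding result of [prioritizeCoding()].
#' @param caddCutoff strict CADD PHRED lower bound (default 20).
#' @param path optional output file.
#' @return sorted character vector of gene symbols.
#' @export
exportPathwayInput <- function(coding, caddCutoff = 20, path = NULL) {
  keep <- coding[coding$retained & caddFilter(coding$cadd_phred, caddCutoff),
                 , drop = FALSE]
  genes <- sort(unique(toupper(trimws(unlist(
    strsplit(as.character(keep$gene_symbols), ","))))))
  genes <- genes[nzchar(genes)]
  if (!is.null(path)) writeLines(genes, path)
  genes
}
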