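## Bundled example data: curated candidate tables, gene-panel subsets,
## pedigrees and per-family UTR counts from a three-family familial
## Hodgkin-lymphoma whole-genome study, reconstructed from the published
## summary tables (the underlying sequencing data are not public). The
## non-coding fixture is fully synthetic and constructed in code.

hlFixturePath <- function(file) {
  system.file("extdata", file, package = "FamVarPrior", mustWork = TRUE)
}

#' Curated coding candidate tables from three HL families
#'
#' The published per-family missense and nonsense candidate tables:
#' variant id, gene, protein effect, CADD PHRED, intolerance count
#' (n/3, "." = unavailable), deleterious vote count (n/10, missense) or
#' aggregate pathogenicity verdict (nonsense).
#'
#' @return list(missense, nonsense) of data.frames as printed.
#' @export
hlCandidateTables <- function() {
  rd <- function(f) read.delim(hlFixturePath(f), colClasses = "character",
                               check.names = FALSE)
  list(missense = rd("candidate_missense.tsv"),
       nonsense = rd("candidate_nonsense.tsv"))
}

.classificationMap <- c("Stopgain SNV" = "stopgain_snv",
                        "stopgain SNV" = "stopgain_snv",
                        "Frameshift deletion" = "frameshift_deletion",
                        "Non-synonymous SNV" = "nonsynonymous_snv")

#' Coding candidate tables as an annotation data.frame
#'
#' Expands the printed vote counts of [hlCandidateTables()] into
#' per-predictor calls (the first k predictors vote deleterious /
#' pathogenic / intolerant, the remainder the opposite; an unavailable
#' intolerance count becomes three missing flags) so the rows run through
#' [prioritizeCoding()] exactly as the printed candidates. Conservation
#' scores are not printed and stay missing (not_applicable downstream).
#' The nonsense pathogenicity vote count is parsed from the "PP3 (k)"
#' component of the printed verdict (no such component = 0 votes).
#'
#' @return annotation data.frame with family_id, ready for
#'   [prioritizeCoding()].
#' @export
hlCodingAnnotation <- function() {
  tabs <- hlCandidateTables()
  parseId <- function(vid) {
    parts <- do.call(rbind, strsplit(vid, "_"))
    data.frame(chrom = parts[, 1], pos = as.numeric(parts[, 2]),
               ref = parts[, 3], alt = parts[, 4], variant_id = vid,
               stringsAsFactors = FALSE)
  }
  base <- function(tab, fc) {
    ann <- parseId(tab$variant_id)
    ann$variant_class <- ifelse(nchar(ann$ref) == nchar(ann$alt),
                                "snv", "indel")
    ann$site_quality <- 99; ann$site_coverage <- 30
    ann$platypus_pass <- TRUE
    ann$family_id <- tab$family_id
    ann$gene_symbols <- tab$gene_symbols
    ann$protein_effect <- tab$protein_effect
    ann$functional_class <- fc
    ann$cadd_phred <- as.numeric(tab$cadd_phred)
    intk <- suppressWarnings(as.integer(tab$int_count))
    for (j in seq_along(intoleranceColumns()))
      ann[[intoleranceColumns()[j]]] <- ifelse(
        is.na(intk), NA_character_,
        ifelse(j <= intk, "intolerant", "tolerant"))
    ann
  }
  mis <- base(tabs$missense, "nonsynonymous_snv")
  delk <- as.integer(tabs$missense$del_votes)
  for (j in seq_along(missenseColumns()))
    mis[[missenseColumns()[j]]] <- ifelse(j <= delk, "deleterious",
                                          "tolerated")
  non <- base(tabs$nonsense,
              unname(.classificationMap[tabs$nonsense$classification]))
  ppk <- rep(0L, nrow(non))
  m <- regmatches(tabs$nonsense$verdict,
                  regexpr("PP3 \\(([0-9]+)\\)", tabs$nonsense$verdict))
  has <- grepl("PP3 \\(", tabs$nonsense$verdict)
  ppk[has] <- as.integer(sub("PP3 \\(([0-9]+)\\)", "\\1", m))
  for (j in seq_along(nonsenseColumns()))
    non[[nonsenseColumns()[j]]] <- ifelse(j <= ppk, "pathogenic", "benign")
  mis$verdict_printed <- tabs$missense$verdict
  non$verdict_printed <- tabs$nonsense$verdict
  for (col in nonsenseColumns()) mis[[col]] <- NA_character_
  for (col in missenseColumns()) non[[col]] <- NA_character_
  out <- rbind(mis, non[, names(mis)])
  rownames(out) <- NULL
  out
}

#' Pedigrees of the three study families
#'
#' Family 1: affected mother and daughter plus the unaffected father.
#' Family 2: nine sequenced members — three affected siblings, one
#' obligate-carrier relative, four healthy relatives and one relative
#' with uterine cancer treated as a control. Family 3: two affected
#' siblings and their parents, one of whom is an obligate carrier.
#'
#' @return named list of \linkS4class{Pedigree}.
#' @export
hlPedigrees <- function() readPedigree(hlFixturePath("families.ped"))

#' Gene-panel subsets matched by the study candidates
#'
#' `cpg`: the cancer-predisposition genes (from a 565-gene panel) hit by
#' the study's candidates, with their panel categories. `hl`: the genes
#' shared with a large WES-based familial HL candidate study (from a
#' 2,383-gene list). Only the printed, matched subsets are bundled — the
#' full panels are not redistributed here.
#'
#' @return list(cpg, hl) of \linkS4class{GenePanel}.
#' @export
hlPanels <- function() {
  list(cpg = readPanel(hlFixturePath("cpg_panel_subset.tsv"),
                       name = "cancer_predisposition_565"),
       hl = readPanel(hlFixturePath("hl_panel_subset.tsv"),
                      name = "familial_hl_2383"))
}

#' Shortlisted variants screened against each panel
#'
#' The candidate variants (coding and non-coding) that the study screened
#' against the two panels, with variant type and classification as
#' printed.
#'
#' @return list(cpg, hl) of data.frames keyed by variant_id.
#' @export
hlPanelHitTables <- function() {
  rd <- function(f) {
    tab <- read.delim(hlFixturePath(f), colClasses = "character",
                      na.strings = ".", check.names = FALSE)
    tab$cadd_phred <- as.numeric(tab$cadd_phred)
    tab
  }
  list(cpg = rd("cpg_panel_hits.tsv"), hl = rd("hl_panel_hits.tsv"))
}

#' Per-family UTR variant counts after pedigree filtering
#'
#' @return data.frame(family_id, utr5_variants, utr3_variants).
#' @export
hlUtrRegionCounts <- function() {
  tab <- read.delim(hlFixturePath("utr_region_counts.tsv"))
  tab$utr5_variants <- as.integer(tab$utr5_variants)
  tab$utr3_variants <- as.integer(tab$utr3_variants)
  tab
}

#' Per-family cohorts with genotypes consistent with segregation
#'
#' Builds one \linkS4class{VariantCohort} per family from the coding
#' candidate annotation, assigning each family's candidate variants a
#' heterozygous genotype in every case and obligate carrier and
#' homozygous reference elsewhere (depth 30, GQ 99, balanced strand
#' counts), so each family's records pass the whole filter funnel against
#' its pedigree.
#'
#' @return named list of \linkS4class{VariantCohort}.
#' @export
hlFamilyCohorts <- function() {
  ann <- hlCodingAnnotation()
  peds <- hlPedigrees()
  lapply(peds, function(ped) {
    fam <- familyId(ped)
    famAnn <- ann[ann$family_id == fam, , drop = FALSE]
    s <- pedSamples(ped)
    carrier <- s$role %in% c("case", "obligate_carrier")
    dosage <- matrix(rep(as.numeric(carrier), each = nrow(famAnn)),
                     nrow(famAnn), nrow(s),
                     dimnames = list(NULL, s$sample_id))
    m <- function(v) matrix(v, nrow(famAnn), nrow(s),
                            dimnames = list(NULL, s$sample_id))
    VariantCohort(famAnn, dosage = dosage, depth = m(30), gq = m(99),
                  adf = m(7) * dosage, adr = m(8) * dosage)
  })
}

#' Synthetic non-coding fixture with planted per-category counts
#'
#' A fully synthetic construction (no published coordinates): 56 3'-UTR
#' variants on miRNA target sites, 15 5'-UTR variants on promoters, 4
#' upstream variants on super-enhancers and 4 5'-UTR variants on TFBS —
#' all with CADD above the cutoff — plus decoys that must not be retained
#' (CADD below cutoff on a target site; high CADD without regulatory
#' evidence; a downstream variant without a miRNA site).
#'
#' @return list(ann, geneModel, tracks, expected_counts).
#' @export
syntheticNoncodingFixture <- function() {
  nGenes <- 85
  starts <- (seq_len(nGenes) - 1) * 9000 + 4000
  gm <- data.frame(gene = sprintf("H%03d", seq_len(nGenes)), chrom = "2",
                   strand = "+", tx_start = starts,
                   tx_end = starts + 5000, stringsAsFactors = FALSE)
  spec <- rbind(
    data.frame(g = 1:56, fc = "utr3", cat = "mirna_target", cadd = 15,
               stringsAsFactors = FALSE),
    data.frame(g = 57:71, fc = "utr5", cat = "promoter", cadd = 14),
    data.frame(g = 72:75, fc = "upstream", cat = "super_enhancer",
               cadd = 13),
    data.frame(g = 76:79, fc = "utr5", cat = "tfbs", cadd = 16),
    ## decoys
    data.frame(g = 80, fc = "utr3", cat = "mirna_target", cadd = 5),
    data.frame(g = 81, fc = "utr5", cat = NA, cadd = 15),
    data.frame(g = 82, fc = "downstream", cat = NA, cadd = 15))
  pos0 <- ifelse(spec$fc == "utr3", gm$tx_end[spec$g] - 100,
          ifelse(spec$fc == "utr5", gm$tx_start[spec$g] + 50,
          ifelse(spec$fc == "upstream", gm$tx_start[spec$g] - 200,
                 gm$tx_end[spec$g] + 199)))
  ann <- data.frame(
    chrom = "2", pos = pos0 + 1, ref = "C", alt = "T",
    variant_class = "snv", site_quality = 99, site_coverage = 30,
    platypus_pass = TRUE, gene_symbols = gm$gene[spec$g],
    functional_class = spec$fc,
    cadd_phred = spec$cadd,
    mirsvr = ifelse(spec$fc %in% c("utr3", "downstream"),
                    -0.2 - spec$g / 100, NA_real_),
    family_id = "Family_1", stringsAsFactors = FALSE)
  ann$variant_id <- variantId(ann$chrom, ann$pos, ann$ref, ann$alt)
  tracks <- lapply(unique(spec$cat[!is.na(spec$cat)]), function(cat) {
    idx <- which(spec$cat %in% cat)
    gr <- GenomicRanges::GRanges(
      "2", IRanges::IRanges(start = ann$pos[idx] - 10,
                            end = ann$pos[idx] + 10))
    gr$label <- sprintf("%s_%02d", cat, seq_along(gr))
    RegulatoryTrack(cat, cat, gr)
  })
  list(ann = ann, geneModel = gm, tracks = tracks,
       expected_counts = c(mirna_target = 56, promoter = 15,
                           enhancer = 0, super_enhancer = 4, tfbs = 4))
}
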