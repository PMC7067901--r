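## Screening prioritized variants against gene panels (e.g. a cancer
## predisposition gene panel, or candidate genes from an independent
## familial cohort) and the rare-structural-variant filter chain.

#' Screen prioritized variants against a gene panel
#'
#' Emits one hit per (variant, matching symbol): a multi-gene annotation
#' ("GENE1,GENE2") tests each symbol independently and can yield several
#' hits for one variant, but the variant counts once in the summary.
#' Matching is exact after uppercasing; an optional alias map (named
#' character vector alias -> panel symbol) is applied first.
#'
#' @param records data.frame of prioritized variants with at least
#'   variant_id and gene_symbols (comma-separated); family_id,
#'   variant_type and variant_classification are carried through when
#'   present.
#' @param panel a \linkS4class{GenePanel}.
#' @param aliasMap optional named character vector mapping alias symbols
#'   to panel symbols.
#' @return data.frame of hits: variant_id, gene_symbol, panel_name,
#'   category (+ passthrough columns).
#' @export
screenPanel <- function(records, panel, aliasMap = NULL) {
  entries <- panelEntries(panel)
  passthrough <- intersect(c("family_id", "variant_type",
                             "variant_classification", "cadd_phred"),
                           names(records))
  hits <- lapply(seq_len(nrow(records)), function(i) {
    syms <- toupper(trimws(strsplit(
      as.character(records$gene_symbols[i]), ",")[[1]]))
    if (!is.null(aliasMap)) {
      aliased <- aliasMap[syms]
      syms[!is.na(aliased)] <- aliased[!is.na(aliased)]
    }
    syms <- unique(syms[syms %in% names(entries)])
    if (!length(syms)) return(NULL)
    cbind(data.frame(variant_id = records$variant_id[i],
                     gene_symbol = syms,
                     panel_name = panelName(panel),
                     category = unname(entries[syms]),
                     stringsAsFactors = FALSE),
          records[rep(i, length(syms)), passthrough, drop = FALSE])
  })
  hits <- do.call(rbind, Filter(Negate(is.null), hits))
  if (is.null(hits))
    hits <- data.frame(variant_id = character(), gene_symbol = character(),
                       panel_name = character(), category = character(),
                       stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  hits
}

#' Summarize panel hits
#'
#' @param hits result of [screenPanel()].
#' @return list(n_variants = distinct variant ids,
#'   n_genes = distinct matched symbols).
#' @export
panelSummary <- function(hits) {
  list(n_variants = length(unique(hits$variant_id)),
       n_genes = length(unique(hits$gene_symbol)))
}

#' Filter structural variants down to rare, segregating, panel-gene hits
#'
#' Retains a structural variant only when it passed the caller's filters,
#' is carried by every case in the family, is not a common structural
#' variant (gnomAD overlap allele frequency missing or <= 1\%), and its
#' span overlaps the transcript bounds of at least one panel gene
#' (gene-level overlap, not exon-resolved).
#'
#' @param svs data.frame of structural variant records (see
#'   [readStructuralVariants()]).
#' @param ped the family \linkS4class{Pedigree}.
#' @param panel \linkS4class{GenePanel} of cancer predisposition genes.
#' @param geneModel transcript bounds (see [readGeneModel()]), 0-based
#'   half-open.
#' @return the retained rows of `svs`, with a `panel_genes` column
#'   (comma-separated overlapped panel symbols).
#' @export
filterStructuralVariants <- function(svs, ped, panel, geneModel) {
  if (!nrow(svs)) {
    svs$panel_genes <- character()
    return(svs)
  }
  cases <- caseIds(ped)
  allCases <- vapply(svs$carrier_sample_ids,
                     function(ids) all(cases %in% ids), logical(1))
  rare <- is.na(svs$gnomad_overlap_af) | svs$gnomad_overlap_af <= 0.01
  gm <- geneModel[toupper(geneModel$gene) %in% names(panelEntries(panel)), ,
                  drop = FALSE]
  svGr <- GenomicRanges::GRanges(
    svs$chrom, IRanges::IRanges(start = svs$start, end = svs$end))
  panelGenes <- rep("", nrow(svs))
  if (nrow(gm)) {
    gmGr <- GenomicRanges::GRanges(
      gm$chrom, IRanges::IRanges(start = gm$tx_start + 1, end = gm$tx_end))
    ov <- GenomicRanges::findOverlaps(svGr, gmGr)
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov)
      genes <- vapply(split(gm$gene[S4Vectors::subjectHits(ov)], qi),
                      function(g) paste(sort(unique(g)), collapse = ","), "")
      panelGenes[as.integer(names(genes))] <- genes
    }
  }
  keep <- svs$filter_pass & allCases & rare & nzchar(panelGenes)
  out <- svs[keep, , drop = FALSE]
  out$panel_genes <- panelGenes[keep]
  rownames(out) <- NULL
  out
}
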