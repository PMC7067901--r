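## Non-coding prioritization: UTR/flank window assignment against a
## transcript-bounds gene model, interval intersection with regulatory
## tracks, CADD cutoff, and ranking by regulatory evidence and mirSVR.
## 3' UTR and downstream variants need a predicted miRNA target site;
## 5' UTR and upstream variants need a promoter, enhancer, super-enhancer
## or TFBS hit. CpG-island membership is recorded but is not a retention
## criterion.

.FIVE_PRIME_CATEGORIES <- c("promoter", "enhancer", "super_enhancer", "tfbs")

#' Assign variants to UTR/flank windows
#'
#' Variants annotated utr5/upstream within 1 kb of the transcription start
#' site map to `utr5_or_upstream`; utr3/downstream within 1 kb of the
#' transcription end site map to `utr3_or_downstream`; everything else is
#' `other`. The 1 kb window is inclusive at exactly 1000 bp and
#' strand-aware (upstream of a minus-strand gene lies at higher
#' coordinates). Inside-UTR variants get distance 0. A variant whose gene
#' is absent from the model maps to `other` with a warning.
#'
#' @param x a \linkS4class{VariantCohort} or its annotation data.frame.
#' @param geneModel data.frame(gene, chrom, strand, tx_start, tx_end),
#'   0-based half-open (see [readGeneModel()]).
#' @param flank window size in bases (default 1000).
#' @return data.frame(variant_id, region, distance_to_gene_edge, gene).
#' @export
assignRegion <- function(x, geneModel, flank = 1000) {
  ann <- if (is(x, "VariantCohort")) annotations(x) else x
  n <- nrow(ann)
  region <- rep("other", n)
  dist <- rep(NA_real_, n)
  geneHit <- rep(NA_character_, n)
  missingGenes <- character()
  for (i in seq_len(n)) {
    fc <- ann$functional_class[i]
    if (!fc %in% c("utr5", "utr3", "upstream", "downstream")) next
    syms <- strsplit(as.character(ann$gene_symbols[i]), ",")[[1]]
    syms <- trimws(syms)
    gm <- geneModel[geneModel$gene %in% syms, , drop = FALSE]
    if (!nrow(gm)) {
      missingGenes <- c(missingGenes, syms[1])
      next
    }
    p0 <- ann$pos[i] - 1  # 0-based point
    for (j in seq_len(nrow(gm))) {
      plus <- gm$strand[j] == "+"
      if (fc %in% c("utr5", "utr3")) {
        region[i] <- if (fc == "utr5") "utr5_or_upstream" else
          "utr3_or_downstream"
        dist[i] <- 0; geneHit[i] <- gm$gene[j]
        break
      }
      ## flank distance to the relevant transcript edge, 1 = adjacent base
      d <- if ((fc == "upstream") == plus)
        gm$tx_start[j] - p0 else p0 - gm$tx_end[j] + 1
      if (d >= 1 && d <= flank) {
        region[i] <- if (fc == "upstream") "utr5_or_upstream" else
          "utr3_or_downstream"
        dist[i] <- d; geneHit[i] <- gm$gene[j]
        break
      }
    }
  }
  if (length(missingGenes))
    warning("gene(s) absent from gene model: ",
            paste(unique(missingGenes), collapse = ", "))
  data.frame(variant_id = ann$variant_id, region = region,
             distance_to_gene_edge = dist, gene = geneHit,
             stringsAsFactors = FALSE)
}

#' Intersect region-assigned variants with regulatory tracks
#'
#' Each variant is a 1-base point; an interval contains it under 0-based
#' half-open semantics (left-closed, right-open). Hit labels per category
#' are listed deterministically by (interval start, label); unlabeled
#' intervals are identified as "chrom:start-end" (0-based half-open).
#'
#' @param x a \linkS4class{VariantCohort} or its annotation data.frame.
#' @param assignments result of [assignRegion()] over the same variants.
#' @param tracks list of \linkS4class{RegulatoryTrack}.
#' @return data.frame with one row per variant: variant_id, region, chrom,
#'   pos, cadd_phred, mirsvr, cpg_island, one `hits_<category>` column of
#'   semicolon-joined labels per regulatory category, and
#'   n_hit_categories (regulatory categories with >= 1 hit).
#' @export
intersectTracks <- function(x, assignments, tracks) {
  ann <- if (is(x, "VariantCohort")) annotations(x) else x
  for (col in c("cadd_phred", "mirsvr"))
    if (is.null(ann[[col]])) ann[[col]] <- rep(NA_real_, nrow(ann))
  stopifnot(identical(ann$variant_id, assignments$variant_id))
  points <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(start = ann$pos, width = 1L))
  out <- data.frame(
    variant_id = ann$variant_id, region = assignments$region,
    chrom = ann$chrom, pos = ann$pos,
    cadd_phred = ann$cadd_phred, mirsvr = ann$mirsvr,
    cpg_island = rep(FALSE, nrow(ann)), stringsAsFactors = FALSE)
  if (!is.null(ann$family_id)) out$family_id <- ann$family_id
  out$gene <- assignments$gene
  regCats <- c("mirna_target", .FIVE_PRIME_CATEGORIES)
  for (cat in regCats) out[[paste0("hits_", cat)]] <- rep("", nrow(out))
  for (track in tracks) {
    iv <- trackIntervals(track)
    hits <- GenomicRanges::findOverlaps(points, iv)
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    if (trackCategory(track) == "cpg_island") {
      out$cpg_island[unique(qi)] <- TRUE
      next
    }
    lab <- iv$label[si]
    lab[is.na(lab)] <- sprintf("%s:%d-%d",
                               as.character(GenomicRanges::seqnames(iv))[si],
                               GenomicRanges::start(iv)[si] - 1L,
                               GenomicRanges::end(iv)[si])
    o <- order(qi, GenomicRanges::start(iv)[si], lab)
    col <- paste0("hits_", trackCategory(track))
    agg <- vapply(split(lab[o], qi[o]), paste, "", collapse = ";")
    idx <- as.integer(names(agg))
    out[[col]][idx] <- ifelse(nzchar(out[[col]][idx]),
                              paste(out[[col]][idx], agg, sep = ";"), agg)
  }
  out$n_hit_categories <- rowSums(.hitMatrix(out, regCats))
  out
}

.hitMatrix <- function(df, cats) {
  m <- vapply(paste0("hits_", cats), function(c) nzchar(df[[c]]),
              logical(nrow(df)))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(df))  # nrow(df) == 1
  m
}

#' Select non-coding candidates
#'
#' A variant is retained when its CADD PHRED is strictly above
#' `caddCutoff` and it carries regulatory evidence valid for its region:
#' a miRNA target site for 3'-side variants; a promoter, enhancer,
#' super-enhancer or TFBS for 5'-side variants. Per-category counts are
#' over retained variants (a variant hitting two categories counts in
#' both); the total deduplicates by variant_id.
#'
#' @param assessments result of [intersectTracks()].
#' @param caddCutoff strict CADD PHRED lower bound (default 10).
#' @return list: `assessments` (with a retained column),
#'   `category_counts` (data.frame category, n) and `n_retained`.
#' @export
selectNoncoding <- function(assessments, caddCutoff = 10) {
  a <- assessments
  caddPass <- caddFilter(a$cadd_phred, caddCutoff)
  mirna <- nzchar(a$hits_mirna_target)
  five <- rowSums(.hitMatrix(a, .FIVE_PRIME_CATEGORIES)) > 0
  a$cadd_pass <- caddPass
  a$retained <- caddPass &
    ((a$region == "utr3_or_downstream" & mirna) |
     (a$region == "utr5_or_upstream" & five))
  cats <- c("mirna_target", .FIVE_PRIME_CATEGORIES)
  counts <- vapply(cats, function(cat) {
    side <- if (cat == "mirna_target") "utr3_or_downstream" else
      "utr5_or_upstream"
    sum(a$retained & a$region == side & nzchar(a[[paste0("hits_", cat)]]))
  }, numeric(1))
  list(assessments = a,
       category_counts = data.frame(category = cats, n = unname(counts),
                                    stringsAsFactors = FALSE),
       n_retained = length(unique(a$variant_id[a$retained])))
}

#' Rank retained non-coding candidates
#'
#' 3'-side candidates rank by ascending mirSVR (more negative = stronger
#' predicted down-regulation; missing last), then descending CADD;
#' 5'-side candidates by descending number of hit regulatory categories,
#' then descending CADD. Ties break by ascending (chrom, pos). Ranks run
#' 1..n within each side.
#'
#' @param retained data.frame of retained rows from [selectNoncoding()].
#' @return the same data.frame with a `rank` column, reordered.
#' @export
rankNoncoding <- function(retained) {
  if (!nrow(retained)) {
    retained$rank <- integer()
    return(retained)
  }
  three <- retained$region == "utr3_or_downstream"
  key1 <- ifelse(three, ifelse(is.na(retained$mirsvr), Inf,
                               retained$mirsvr),
                 -retained$n_hit_categories)
  o <- order(retained$region, key1, -retained$cadd_phred,
             chromOrderKey(retained$chrom), retained$chrom, retained$pos)
  retained <- retained[o, , drop = FALSE]
  retained$rank <- stats::ave(seq_len(nrow(retained)), retained$region,
                              FUN = seq_along)
  rownames(retained) <- NULL
  retained
}
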