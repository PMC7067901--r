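## Coding-variant prioritization: CADD and conservation thresholds, a
## 10-tool consensus deleteriousness vote for missense variants, an 8-tool
## pathogenicity tally for nonsense/frameshift variants (which annotates
## but never excludes), and intolerance-based ranking of what survives.

#' Classify a variant onto the coding assessment path
#'
#' Non-synonymous SNVs go to the missense path; stopgain SNVs and
#' frameshift indels to the nonsense path; everything else is not a coding
#' candidate.
#'
#' @param functionalClass character vector of functional classes.
#' @return character vector: "missense", "nonsense" or
#'   "not_coding_candidate".
#' @export
classifyPath <- function(functionalClass) {
  functionalClass[is.na(functionalClass)] <- "other"
  ifelse(functionalClass == "nonsynonymous_snv", "missense",
  ifelse(functionalClass %in% c("stopgain_snv", "frameshift_deletion",
                                "frameshift_insertion"), "nonsense",
         "not_coding_candidate"))
}

#' CADD PHRED threshold
#'
#' TRUE only when the scaled PHRED-like CADD score is present and strictly
#' above `cutoff` (default 10, approximately the top 1\% most deleterious
#' substitutions genome-wide). Missing CADD fails.
#'
#' @param caddPhred numeric vector (NA = missing).
#' @param cutoff strict lower bound.
#' @return logical vector.
#' @export
caddFilter <- function(caddPhred, cutoff = 10) {
  !is.na(caddPhred) & caddPhred > cutoff
}

#' Conservation threshold cascade
#'
#' Evaluates GERP > 2.0, PhastCons > 0.3 and PhyloP >= 3.0 (note the
#' non-strict PhyloP bound) over whichever of the three scores are
#' present: "pass" when every present score meets its threshold, "fail"
#' when any present score misses it, "not_applicable" when all three are
#' missing (treated as pass downstream but flagged in reports).
#'
#' @param gerp,phastcons,phylop numeric vectors (NA = missing).
#' @return character vector: "pass", "fail" or "not_applicable".
#' @export
conservationFilter <- function(gerp, phastcons, phylop) {
  n <- max(length(gerp), length(phastcons), length(phylop))
  gerp <- rep_len(gerp, n); phastcons <- rep_len(phastcons, n)
  phylop <- rep_len(phylop, n)
  fails <- (!is.na(gerp) & gerp <= 2.0) |
    (!is.na(phastcons) & phastcons <= 0.3) |
    (!is.na(phylop) & phylop < 3.0)
  none <- is.na(gerp) & is.na(phastcons) & is.na(phylop)
  ifelse(none, "not_applicable", ifelse(fails, "fail", "pass"))
}

#' Consensus deleteriousness vote over ten missense predictors
#'
#' Counts "deleterious" calls among the ten missense effect predictors.
#' The variant passes when at least `fraction` (default 60\%) of the
#' *available* (non-missing) calls vote deleterious — with a floor of five
#' available tools, so sparsely annotated variants are not waved through
#' on one or two votes. With all ten available this reduces to
#' del_votes >= 6.
#'
#' @param ann annotation data.frame carrying the ten `mis_*` columns.
#' @param fraction required deleterious fraction of available calls.
#' @return data.frame(del_votes, del_available, pass).
#' @export
consensusDeleteriousness <- function(ann, fraction = 0.6) {
  calls <- as.matrix(ann[, missenseColumns(), drop = FALSE])
  votes <- rowSums(calls == "deleterious", na.rm = TRUE)
  avail <- rowSums(!is.na(calls))
  data.frame(del_votes = votes, del_available = avail,
             pass = avail >= 5 & votes >= ceiling(fraction * avail))
}

#' Pathogenicity tally over eight nonsense predictors
#'
#' Counts "pathogenic" calls among the eight tools backing the aggregate
#' verdict for nonsense/frameshift variants. The vote annotates but never
#' excludes: truncating variants of uncertain significance are retained,
#' and the label records the level of computational support —
#' "no_support" (0 votes), "supporting(k)" (1-4) or "majority_pathogenic"
#' (>= 5).
#'
#' @param ann annotation data.frame carrying the eight `non_*` columns.
#' @return data.frame(varsome_votes, varsome_available, verdict_label).
#' @export
nonsenseVerdict <- function(ann) {
  calls <- as.matrix(ann[, nonsenseColumns(), drop = FALSE])
  votes <- rowSums(calls == "pathogenic", na.rm = TRUE)
  avail <- rowSums(!is.na(calls))
  label <- ifelse(votes == 0, "no_support",
           ifelse(votes >= 5, "majority_pathogenic",
                  sprintf("supporting(%d)", votes)))
  data.frame(varsome_votes = votes, varsome_available = avail,
             verdict_label = label, stringsAsFactors = FALSE)
}

#' Rank retained coding assessments by gene intolerance
#'
#' Intolerance evidence ranks candidates but never cuts them. The total
#' order is: descending intolerance-source count (n/3), then descending
#' CADD PHRED, then descending predictor votes (deleterious votes for
#' missense, pathogenicity votes for nonsense), then ascending
#' (chrom, pos) — which makes ties impossible and the ranking
#' permutation-invariant. Ranks are assigned 1..n within each family.
#'
#' @param assessments data.frame of retained coding assessments (see
#'   [prioritizeCoding()]).
#' @return the same data.frame with a `rank` column, reordered.
#' @export
intoleranceRank <- function(assessments) {
  if (!nrow(assessments)) {
    assessments$rank <- integer()
    return(assessments)
  }
  votes <- ifelse(assessments$path == "missense",
                  assessments$del_votes, assessments$varsome_votes)
  fam <- if (is.null(assessments$family_id)) "" else assessments$family_id
  o <- order(fam, -assessments$int_count, -assessments$cadd_phred,
             -votes, chromOrderKey(assessments$chrom), assessments$chrom,
             assessments$pos)
  assessments <- assessments[o, , drop = FALSE]
  assessments$rank <- stats::ave(seq_len(nrow(assessments)),
                                 fam[o], FUN = seq_along)
  rownames(assessments) <- NULL
  assessments
}

#' Run the coding prioritization cascade
#'
#' For variants that already passed the basic filter funnel: missense
#' variants are retained when CADD passes, conservation does not fail and
#' the ten-tool consensus passes; nonsense/frameshift variants are
#' retained when CADD passes and conservation does not fail (predictor
#' votes annotate only). Retained variants are ranked per family by
#' [intoleranceRank()].
#'
#' @param x a \linkS4class{VariantCohort} or its annotation data.frame
#'   (an optional `family_id` column groups the ranking).
#' @param caddCutoff strict CADD PHRED lower bound (default 10).
#' @param fraction consensus fraction for [consensusDeleteriousness()].
#' @return data.frame of per-variant coding assessments with columns
#'   variant_id, family_id, chrom, pos, gene_symbols, path, cadd_phred,
#'   cadd_pass, conservation_pass, del_votes, del_available,
#'   consensus_pass, varsome_votes, varsome_available, verdict_label,
#'   int_count, pli, missense_z, retained, rank.
#' @export
prioritizeCoding <- function(x, caddCutoff = 10, fraction = 0.6) {
  ann <- if (is(x, "VariantCohort")) annotations(x) else x
  for (col in .ANNOTATION_COLUMNS())  # tolerate partial annotation tables
    if (is.null(ann[[col]])) ann[[col]] <- rep(NA, nrow(ann))
  path <- classifyPath(ann$functional_class)
  caddPass <- caddFilter(ann$cadd_phred, caddCutoff)
  cons <- conservationFilter(ann$gerp, ann$phastcons, ann$phylop)
  del <- consensusDeleteriousness(ann, fraction)
  vs <- nonsenseVerdict(ann)
  intCalls <- as.matrix(ann[, intoleranceColumns(), drop = FALSE])
  out <- data.frame(
    variant_id = ann$variant_id,
    family_id = if (is.null(ann$family_id))
      rep(NA_character_, nrow(ann)) else ann$family_id,
    chrom = ann$chrom, pos = ann$pos, gene_symbols = ann$gene_symbols,
    path = path, cadd_phred = ann$cadd_phred, cadd_pass = caddPass,
    conservation_pass = cons,
    del_votes = del$del_votes, del_available = del$del_available,
    consensus_pass = del$pass,
    varsome_votes = vs$varsome_votes,
    varsome_available = vs$varsome_available,
    verdict_label = ifelse(path == "nonsense", vs$verdict_label,
                           NA_character_),
    int_count = rowSums(intCalls == "intolerant", na.rm = TRUE),
    pli = ann$pli, missense_z = ann$missense_z,
    stringsAsFactors = FALSE)
  out$retained <- ifelse(path == "missense",
                         caddPass & cons != "fail" & del$pass,
                  ifelse(path == "nonsense",
                         caddPass & cons != "fail", FALSE))
  ranked <- intoleranceRank(out[out$retained, , drop = FALSE])
  out$rank <- rep(NA_integer_, nrow(out))
  out$rank[match(ranked$variant_id, out$variant_id)] <- ranked$rank
  out
}

#' Write coding assessments as a candidate-table TSV
#'
#' Mirrors the layout of a per-family candidate table: variant_id, gene,
#' effect path, CADD PHRED, Int (n/3), Del (n/10) or pathogenicity votes,
#' verdict label, rank.
#'
#' @param assessments result of [prioritizeCoding()].
#' @param path output path.
#' @param retainedOnly write only retained rows (default TRUE).
#' @export
writeCodingTable <- function(assessments, path, retainedOnly = TRUE) {
  tab <- if (retainedOnly)
    assessments[assessments$retained, , drop = FALSE] else assessments
  tab <- tab[order(tab$family_id, tab$rank), c(
    "family_id", "variant_id", "gene_symbols", "path", "cadd_phred",
    "int_count", "del_votes", "varsome_votes", "verdict_label", "rank")]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
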