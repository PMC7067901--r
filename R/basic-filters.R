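## The funnel from raw joint calls to family-consistent rare variants:
## call quality -> strand bias -> population frequency -> dominant-model
## segregation. Each stage is a pure predicate over one variant; stages are
## applied in that fixed order, and every variant reaching a stage receives
## exactly one decision row (variant_id, stage, passed, detail).

.decision <- function(ids, stage, passed, detail) {
  data.frame(variant_id = ids, stage = rep_len(stage, length(ids)),
             passed = rep_len(passed, length(ids)),
             detail = rep_len(detail, length(ids)),
             stringsAsFactors = FALSE)
}

#' Call-quality filter
#'
#' Keeps variants with site quality strictly above `qualityMin` and site
#' coverage strictly above `coverageMin`; indels additionally require the
#' caller's internal PASS flag. A missing quality or coverage metric fails
#' the variant (detail "missing_metric").
#'
#' @param cohort a \linkS4class{VariantCohort}.
#' @param qualityMin,coverageMin strict lower bounds (defaults 20 and 5).
#' @return decision data.frame (variant_id, stage, passed, detail).
#' @export
qualityFilter <- function(cohort, qualityMin = 20, coverageMin = 5) {
  ann <- annotations(cohort)
  q <- ann$site_quality; cov <- ann$site_coverage
  missing <- is.na(q) | is.na(cov)
  ok <- !missing & q > qualityMin & cov > coverageMin &
    (ann$variant_class == "snv" | ann$platypus_pass %in% TRUE)
  detail <- ifelse(missing, "missing_metric",
                   ifelse(ok, "pass", "below_threshold"))
  .decision(ann$variant_id, "quality", ok, detail)
}

#' Strand-bias filter
#'
#' An SNV passes when at least one carrier sample (dosage >= 1) shows at
#' least one alternate read on each strand. Indels pass unconditionally
#' (the stage applies to SNV calls only). When no carrier has any strand
#' information the behaviour is configurable: pass with a warning
#' (default) or fail.
#'
#' @param cohort a \linkS4class{VariantCohort}.
#' @param noStrandInfo "pass" (default, warns) or "fail".
#' @return decision data.frame.
#' @export
strandBiasFilter <- function(cohort, noStrandInfo = c("pass", "fail")) {
  noStrandInfo <- match.arg(noStrandInfo)
  ann <- annotations(cohort)
  carrier <- !is.na(cohort@dosage) & cohort@dosage >= 1
  both <- carrier & !is.na(cohort@adf) & !is.na(cohort@adr) &
    cohort@adf >= 1 & cohort@adr >= 1
  supported <- if (ncol(carrier)) rowSums(both) > 0 else
    rep(FALSE, nrow(ann))
  anyInfo <- if (ncol(carrier))
    rowSums(carrier & (!is.na(cohort@adf) | !is.na(cohort@adr))) > 0 else
    rep(FALSE, nrow(ann))
  isSnv <- ann$variant_class == "snv"
  passed <- !isSnv | supported
  detail <- ifelse(!isSnv, "not_applicable",
                   ifelse(supported, "pass", "one_sided"))
  blind <- isSnv & !anyInfo
  if (any(blind)) {
    if (noStrandInfo == "pass") {
      passed[blind] <- TRUE
      detail[blind] <- "no_strand_info"
      warning(sum(blind), " SNV(s) without strand information passed ",
              "unchecked")
    } else detail[blind] <- "no_strand_info"
  }
  .decision(ann$variant_id, "strand_bias", passed, detail)
}

#' Population-frequency filter
#'
#' Keeps variants whose maximum minor allele frequency across the two
#' reference panels (1000 Genomes, non-TCGA ExAC) is strictly below
#' `threshold` (default 0.001, i.e. MAF < 0.1\%). A missing frequency is
#' treated as 0: a variant absent from both panels is maximally rare.
#'
#' @param cohort a \linkS4class{VariantCohort}.
#' @param threshold strict upper bound in (0, 1).
#' @return decision data.frame.
#' @export
frequencyFilter <- function(cohort, threshold = 0.001) {
  stopifnot(threshold > 0, threshold < 1)
  ann <- annotations(cohort)
  maf <- pmax(ifelse(is.na(ann$maf_1000g), 0, ann$maf_1000g),
              ifelse(is.na(ann$maf_exac_nontcga), 0, ann$maf_exac_nontcga))
  maf <- as.numeric(maf)
  .decision(ann$variant_id, "frequency", maf < threshold,
            sprintf("max_maf=%s", .num2str(maf)))
}

#' Dominant-model segregation filter
#'
#' Under the default \linkS4class{SegregationPolicy} a variant passes when
#' every genotyped case carries at least one alternate allele
#' (homozygous-alternate cases count as carriers), every genotyped
#' obligate carrier does too, and at most `maxControlCarriers` controls
#' carry it. Under "strict" missing-genotype handling a missing genotype
#' in a case (or obligate carrier, when required) fails the variant;
#' under "permissive" (default) it is ignored. The detail records the
#' carrier pattern, e.g. "cases 2/2; controls 0/1".
#'
#' @param cohort a \linkS4class{VariantCohort} whose samples all belong to
#'   `ped` (an unknown sample is an error).
#' @param ped a \linkS4class{Pedigree} with at least one genotyped case.
#' @param policy a \linkS4class{SegregationPolicy}.
#' @return decision data.frame.
#' @export
segregationFilter <- function(cohort, ped, policy = SegregationPolicy()) {
  samples <- cohortSamples(cohort)
  unknown <- setdiff(samples, pedSamples(ped)$sample_id)
  if (length(unknown))
    stop("genotyped sample(s) not in pedigree: ",
         paste(unknown, collapse = ", "))
  cases <- intersect(caseIds(ped), samples)
  if (!length(cases)) stop("pedigree has zero genotyped cases")
  controls <- intersect(controlIds(ped), samples)
  obligates <- intersect(obligateCarrierIds(ped), samples)
  d <- cohort@dosage
  strict <- policy@missingGenotypeHandling == "strict"

  carrierStats <- function(ids) {
    sub <- d[, ids, drop = FALSE]
    list(carriers = rowSums(sub >= 1, na.rm = TRUE),
         genotyped = rowSums(!is.na(sub)),
         missing = rowSums(is.na(sub)))
  }
  cs <- carrierStats(cases)
  os <- carrierStats(obligates)
  xs <- carrierStats(controls)

  ## "every case with a non-missing genotype carries": vacuously true when
  ## all case genotypes are missing under permissive handling
  caseOk <- if (policy@requireAllCases)
    cs$carriers == cs$genotyped else cs$carriers >= 1
  if (strict) caseOk <- caseOk & cs$missing == 0
  obligOk <- if (policy@obligateCarriersMustCarry) {
    ok <- os$carriers == os$genotyped
    if (strict) ok <- ok & os$missing == 0
    ok
  } else rep(TRUE, nrow(d))
  ctrlOk <- xs$carriers <= policy@maxControlCarriers

  detail <- sprintf("cases %d/%d; controls %d/%d",
                    cs$carriers, cs$genotyped, xs$carriers, xs$genotyped)
  .decision(annotations(cohort)$variant_id, "segregation",
            caseOk & obligOk & ctrlOk, detail)
}

#' Restrict a cohort to a set of samples
#'
#' @param cohort a \linkS4class{VariantCohort}.
#' @param sampleIds sample identifiers to keep.
#' @return a \linkS4class{VariantCohort} over the selected samples.
#' @export
subsetSamples <- function(cohort, sampleIds) {
  keep <- intersect(colnames(cohort@dosage), sampleIds)
  initialize(cohort,
             dosage = cohort@dosage[, keep, drop = FALSE],
             depth = cohort@depth[, keep, drop = FALSE],
             gq = cohort@gq[, keep, drop = FALSE],
             adf = cohort@adf[, keep, drop = FALSE],
             adr = cohort@adr[, keep, drop = FALSE])
}

#' Run the whole filter funnel for one family
#'
#' Applies quality, strand-bias, frequency and segregation filtering in
#' that fixed order, restricting genotypes to the family's samples first.
#' Because each stage is a pure per-variant predicate, the survivor set is
#' order-invariant; the per-stage counts are not.
#'
#' @param cohort a \linkS4class{VariantCohort} (may contain samples of
#'   other families; they are dropped).
#' @param ped the family \linkS4class{Pedigree}.
#' @param policy a \linkS4class{SegregationPolicy}.
#' @param qualityMin,coverageMin,mafThreshold stage thresholds.
#' @param stages stages to run, in order; disabling a stage (for
#'   sensitivity analysis) can only grow the survivor set.
#' @param noStrandInfo passed to [strandBiasFilter()].
#' @return list with `survivors` (a VariantCohort), `counts`
#'   (data.frame family_id, stage, n_in, n_out) and `decisions` (all
#'   per-stage decision rows).
#' @export
runFunnel <- function(cohort, ped, policy = SegregationPolicy(),
                      qualityMin = 20, coverageMin = 5,
                      mafThreshold = 0.001,
                      stages = c("quality", "strand_bias", "frequency",
                                 "segregation"),
                      noStrandInfo = "pass") {
  stages <- match.arg(stages, several.ok = TRUE)
  current <- subsetSamples(cohort, pedSamples(ped)$sample_id)
  counts <- list(); decisions <- list()
  for (stage in stages) {
    dec <- switch(stage,
      quality = qualityFilter(current, qualityMin, coverageMin),
      strand_bias = strandBiasFilter(current, noStrandInfo),
      frequency = frequencyFilter(current, mafThreshold),
      segregation = segregationFilter(current, ped, policy))
    counts[[stage]] <- data.frame(
      family_id = familyId(ped), stage = stage,
      n_in = nVariants(current), n_out = sum(dec$passed),
      stringsAsFactors = FALSE)
    decisions[[stage]] <- dec
    current <- current[which(dec$passed)]
  }
  list(survivors = current, counts = do.call(rbind, c(counts,
         list(make.row.names = FALSE))),
       decisions = do.call(rbind, c(decisions,
         list(make.row.names = FALSE))))
}

#' Write per-stage funnel counts as TSV
#'
#' @param counts the `counts` element of one or more [runFunnel()] results
#'   (rbind them for a cohort-level table).
#' @param path output path.
#' @export
writeFunnelCounts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
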