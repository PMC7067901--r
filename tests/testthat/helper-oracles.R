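# Builders for tiny in-code fixtures and independent brute-force oracles.
# The oracles re-state the filtering rules directly, one scalar case at a
# time, and never call the vectorized implementation paths they check.

# minimal annotation data.frame; override any field via ...
makeAnn <- function(n = 1, ...) {
  ann <- data.frame(
    chrom = rep("1", n), pos = seq_len(n) * 100, ref = rep("A", n),
    alt = rep("G", n), variant_class = rep("snv", n),
    site_quality = rep(99, n), site_coverage = rep(30, n),
    platypus_pass = rep(TRUE, n), gene_symbols = rep("GENE1", n),
    functional_class = rep("nonsynonymous_snv", n),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) ann[[nm]] <- over[[nm]]
  ann$variant_id <- variantId(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann
}

makeCohort <- function(ann, dosage = NULL, ...) {
  if (is.null(dosage))
    dosage <- matrix(1, nrow(ann), 1, dimnames = list(NULL, "S1"))
  VariantCohort(ann, dosage = dosage, ...)
}

trioPed <- function(famId = "FAM1",
                    roles = c(F = "control", M = "case", C = "case")) {
  Pedigree(famId, data.frame(
    sample_id = c("F", "M", "C"), father_id = c(NA, NA, "F"),
    mother_id = c(NA, NA, "M"), sex = c("male", "female", "female"),
    role = unname(roles), stringsAsFactors = FALSE))
}

# pedigree shapes with <= 4 members used for exhaustive segregation checks
smallPedigrees <- function() {
  mk <- function(ids, fa, mo, roles) Pedigree("P", data.frame(
    sample_id = ids, father_id = fa, mother_id = mo,
    sex = "unknown", role = roles, stringsAsFactors = FALSE))
  list(
    pair = mk(c("A", "B"), c(NA, NA), c(NA, NA), c("case", "control")),
    sibs = mk(c("A", "B", "C"), c(NA, NA, NA), c(NA, NA, NA),
              c("case", "case", "control")),
    trio = mk(c("F", "M", "C"), c(NA, NA, "F"), c(NA, NA, "M"),
              c("control", "case", "case")),
    quad = mk(c("F", "M", "C1", "C2"), c(NA, NA, "F", "F"),
              c(NA, NA, "M", "M"),
              c("control", "case", "case", "control")),
    oblig = mk(c("F", "M", "C1", "C2"), c(NA, NA, "F", "F"),
               c(NA, NA, "M", "M"),
               c("obligate_carrier", "control", "case", "case")))
}

# scalar restatement of the dominant segregation rule
segOracle <- function(dosage, roles, maxControlCarriers = 0,
                      requireAllCases = TRUE,
                      obligateCarriersMustCarry = TRUE, strict = FALSE) {
  ok <- TRUE
  for (i in seq_along(dosage)) {
    d <- dosage[i]; r <- roles[i]
    if (r == "case") {
      if (is.na(d)) { if (strict) ok <- FALSE }
      else if (requireAllCases && d < 1) ok <- FALSE
    }
    if (r == "obligate_carrier" && obligateCarriersMustCarry) {
      if (is.na(d)) { if (strict) ok <- FALSE }
      else if (d < 1) ok <- FALSE
    }
  }
  if (!requireAllCases) {
    caseD <- dosage[roles == "case"]
    if (!any(!is.na(caseD) & caseD >= 1)) ok <- FALSE
  }
  ctrl <- dosage[roles == "control"]
  if (sum(!is.na(ctrl) & ctrl >= 1) > maxControlCarriers) ok <- FALSE
  ok
}

# O(n*m) point-in-interval scan; intervals 0-based half-open
overlapOracle <- function(chrom, pos, ivChrom, ivStart0, ivEnd0) {
  hits <- matrix(FALSE, length(pos), length(ivStart0))
  for (i in seq_along(pos))
    for (j in seq_along(ivStart0))
      hits[i, j] <- chrom[i] == ivChrom[j] &&
        ivStart0[j] <= pos[i] - 1 && pos[i] - 1 < ivEnd0[j]
  hits
}

# scalar restatement of the UTR/flank window rule
regionOracle <- function(fc, pos, gene, geneModel, flank = 1000) {
  gm <- geneModel[geneModel$gene == gene, ]
  if (!nrow(gm)) return("other")
  if (fc == "utr5") return("utr5_or_upstream")
  if (fc == "utr3") return("utr3_or_downstream")
  if (!fc %in% c("upstream", "downstream")) return("other")
  p0 <- pos - 1
  plus <- gm$strand == "+"
  before <- gm$tx_start - p0          # >=1 when p0 left of the gene
  after <- p0 - gm$tx_end + 1         # >=1 when p0 right of the gene
  d <- if (fc == "upstream") { if (plus) before else after } else {
    if (plus) after else before }
  if (d >= 1 && d <= flank) {
    if (fc == "upstream") "utr5_or_upstream" else "utr3_or_downstream"
  } else "other"
}

# enumerate all dosage assignments (0, 1, 2, NA) over n samples
dosageGrid <- function(n) {
  vals <- list(c(0, 1, 2, NA))
  as.matrix(expand.grid(rep(vals, n)))
}
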