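test_that("quality filter applies strict bounds and caller flags", {
  ann <- makeAnn(4,
    site_quality = c(30, 20, 30, 30), site_coverage = c(12, 12, 5, 12),
    variant_class = c("snv", "snv", "snv", "indel"),
    ref = c("A", "A", "A", "AT"),
    platypus_pass = c(TRUE, TRUE, TRUE, FALSE))
  dec <- qualityFilter(makeCohort(ann))
  expect_equal(dec$passed, c(TRUE, FALSE, FALSE, FALSE))

  miss <- qualityFilter(makeCohort(makeAnn(1, site_quality = NA)))
  expect_false(miss$passed)
  expect_equal(miss$detail, "missing_metric")
})

test_that("quality filter equals the predicate oracle on random records", {
  set.seed(41)
  n <- 1000
  ann <- makeAnn(n,
    site_quality = sample(c(NA, 5, 19, 20, 21, 60), n, TRUE),
    site_coverage = sample(c(NA, 2, 5, 6, 40), n, TRUE),
    variant_class = sample(c("snv", "indel"), n, TRUE),
    platypus_pass = sample(c(TRUE, FALSE), n, TRUE))
  ann$ref <- ifelse(ann$variant_class == "indel", "AT", "A")
  dec <- qualityFilter(makeCohort(ann))
  oracle <- vapply(seq_len(n), function(i) {
    q <- ann$site_quality[i]; cv <- ann$site_coverage[i]
    !is.na(q) && !is.na(cv) && q > 20 && cv > 5 &&
      (ann$variant_class[i] == "snv" || ann$platypus_pass[i])
  }, TRUE)
  expect_equal(dec$passed, oracle)
})

test_that("strand bias requires alternate reads on both strands of a carrier", {
  mkC <- function(adf, adr, dosage = 1, class = "snv") {
    ann <- makeAnn(1, variant_class = class,
                   ref = if (class == "indel") "AT" else "A")
    makeCohort(ann,
               dosage = matrix(dosage, 1, 1, dimnames = list(NULL, "S1")),
               adf = matrix(adf, 1, 1), adr = matrix(adr, 1, 1))
  }
  expect_true(strandBiasFilter(mkC(3, 1))$passed)
  expect_false(strandBiasFilter(mkC(4, 0))$passed)
  expect_true(strandBiasFilter(mkC(NA, NA, class = "indel"))$passed)
  # support in a non-carrier does not rescue the variant
  ann <- makeAnn(1)
  two <- makeCohort(ann,
    dosage = matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("S1", "S2"))),
    adf = matrix(c(0, 5), 1, 2), adr = matrix(c(2, 5), 1, 2))
  expect_false(strandBiasFilter(two)$passed)
  # SNV with no strand info anywhere: configurable
  expect_warning(d <- strandBiasFilter(mkC(NA, NA)), "strand")
  expect_true(d$passed)
  expect_false(strandBiasFilter(mkC(NA, NA), noStrandInfo = "fail")$passed)
})

test_that("frequency filter takes the max over panels, missing as zero", {
  ann <- makeAnn(3, maf_1000g = c(0.0005, NA, 0.0002),
                 maf_exac_nontcga = c(NA, 0.001, 0.0009))
  dec <- frequencyFilter(makeCohort(ann))
  expect_equal(dec$passed, c(TRUE, FALSE, TRUE))  # 0.001 fails strict <

  set.seed(42)
  vals <- c(NA, 0, 1e-5, 5e-4, 1e-3, 2e-3, 0.05)
  ann <- makeAnn(500, maf_1000g = sample(vals, 500, TRUE),
                 maf_exac_nontcga = sample(vals, 500, TRUE))
  dec <- frequencyFilter(makeCohort(ann))
  oracle <- vapply(seq_len(500), function(i) {
    m <- c(ann$maf_1000g[i], ann$maf_exac_nontcga[i])
    m[is.na(m)] <- 0
    max(m) < 0.001
  }, TRUE)
  expect_equal(dec$passed, oracle)
})

test_that("segregation matches the family-shaped carrier pattern", {
  ped <- trioPed()
  ann <- makeAnn(2)
  # variant het in both cases (M, C), hom-ref in control father
  dosage <- matrix(c(0, 0, 1, 0, 1, 0), 2, 3,
                   dimnames = list(NULL, c("F", "M", "C")))
  dec <- segregationFilter(makeCohort(ann, dosage = dosage), ped)
  expect_equal(dec$passed, c(TRUE, FALSE))
  expect_equal(dec$detail[1], "cases 2/2; controls 0/1")

  expect_error(segregationFilter(
    makeCohort(makeAnn(1), dosage = matrix(1, 1, 1,
                                           dimnames = list(NULL, "XX"))),
    ped), "not in pedigree")
  ctrlOnly <- makeCohort(makeAnn(1), dosage = matrix(
    1, 1, 1, dimnames = list(NULL, "F")))
  expect_error(segregationFilter(ctrlOnly, ped), "zero genotyped cases")
})

test_that("segregation equals brute-force enumeration on small pedigrees", {
  for (ped in smallPedigrees()) {
    roles <- pedSamples(ped)$role
    ids <- pedSamples(ped)$sample_id
    grid <- dosageGrid(length(ids))
    colnames(grid) <- ids
    ann <- makeAnn(nrow(grid))
    for (policy in list(
      SegregationPolicy(),
      SegregationPolicy(maxControlCarriers = 1L),
      SegregationPolicy(requireAllCases = FALSE),
      SegregationPolicy(missingGenotypeHandling = "strict"),
      SegregationPolicy(obligateCarriersMustCarry = FALSE))) {
      got <- segregationFilter(makeCohort(ann, dosage = grid), ped,
                               policy)$passed
      want <- vapply(seq_len(nrow(grid)), function(i) segOracle(
        grid[i, ], roles,
        maxControlCarriers = policy@maxControlCarriers,
        requireAllCases = policy@requireAllCases,
        obligateCarriersMustCarry = policy@obligateCarriersMustCarry,
        strict = policy@missingGenotypeHandling == "strict"), TRUE)
      expect_equal(got, want)
    }
  }
})

test_that("the funnel keeps a planted segregating variant and counts stages", {
  cfg <- simulationConfig(seed = 5, nBackgroundVariants = 500L)
  sim <- suppressWarnings(simulateCohort(cfg))
  ped <- sim$pedigrees[[1]]
  res <- suppressWarnings(runFunnel(sim$cohort, ped))
  planted <- sim$truth$variant_id[sim$truth$family_id == familyId(ped)]
  expect_true(planted %in% annotations(res$survivors)$variant_id)
  expect_equal(res$counts$stage,
               c("quality", "strand_bias", "frequency", "segregation"))
  expect_equal(res$counts$n_in[1], nVariants(sim$cohort))
  expect_equal(res$counts$n_in[-1], res$counts$n_out[-4])
  expect_equal(nVariants(res$survivors), res$counts$n_out[4])
})

test_that("empty input yields empty survivors and zero counts", {
  empty <- makeCohort(makeAnn(0), dosage = matrix(
    numeric(), 0, 3, dimnames = list(NULL, c("F", "M", "C"))))
  res <- runFunnel(empty, trioPed())
  expect_equal(nVariants(res$survivors), 0)
  expect_true(all(res$counts$n_in == 0) && all(res$counts$n_out == 0))
})

test_that("survivors are monotone under stage removal and threshold relaxation", {
  cfg <- simulationConfig(seed = 6, nBackgroundVariants = 400L)
  sim <- suppressWarnings(simulateCohort(cfg))
  ped <- sim$pedigrees[[2]]
  full <- suppressWarnings(runFunnel(sim$cohort, ped))
  fullIds <- annotations(full$survivors)$variant_id
  allStages <- c("quality", "strand_bias", "frequency", "segregation")
  for (drop in allStages) {
    sub <- suppressWarnings(runFunnel(sim$cohort, ped,
                                      stages = setdiff(allStages, drop)))
    expect_true(all(fullIds %in% annotations(sub$survivors)$variant_id))
  }
  relaxed <- suppressWarnings(runFunnel(
    sim$cohort, ped, qualityMin = 10, coverageMin = 2, mafThreshold = 0.01,
    policy = SegregationPolicy(maxControlCarriers = 2L)))
  expect_true(all(fullIds %in% annotations(relaxed$survivors)$variant_id))
})

test_that("the survivor set is invariant to stage order", {
  cfg <- simulationConfig(seed = 8, nBackgroundVariants = 300L)
  sim <- suppressWarnings(simulateCohort(cfg))
  ped <- sim$pedigrees[[1]]
  allStages <- c("quality", "strand_bias", "frequency", "segregation")
  ids <- lapply(list(allStages, rev(allStages),
                     c("segregation", "quality", "frequency",
                       "strand_bias")),
                function(ss) sort(annotations(suppressWarnings(
                  runFunnel(sim$cohort, ped, stages = ss))$survivors
                )$variant_id))
  expect_identical(ids[[1]], ids[[2]])
  expect_identical(ids[[1]], ids[[3]])
})
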