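test_that("PED reading maps affection codes and preserves role overrides", {
  peds <- hlPedigrees()
  expect_named(peds, c("Family_1", "Family_2", "Family_3"))
  f1 <- pedSamples(peds$Family_1)
  expect_equal(sum(f1$role == "case"), 2)       # affected mother + daughter
  expect_equal(sum(f1$role == "control"), 1)
  f2 <- pedSamples(peds$Family_2)
  expect_equal(f2$role[f2$sample_id == "II-6"], "obligate_carrier")
  expect_false("II-6" %in% controlIds(peds$Family_2))
  expect_equal(length(caseIds(peds$Family_2)), 3)

  empty <- tempfile(); writeLines(character(), empty)
  expect_length(readPedigree(empty), 0)

  dup <- tempfile()
  writeLines(c("F1\tA\t0\t0\t1\t2", "F1\tA\t0\t0\t1\t1"), dup)
  expect_error(readPedigree(dup), "duplicate")

  orphan <- tempfile()
  writeLines(c("F1\tA\tGHOST\t0\t1\t2"), orphan)
  expect_error(readPedigree(orphan), "A")
})

test_that("pedigree validity rejects cycles and sex-incompatible parents", {
  expect_error(Pedigree("F", data.frame(
    sample_id = c("A", "B"), father_id = c("B", "A"),
    mother_id = c(NA, NA), sex = "male",
    role = c("case", "case"))), "ancestor")
  expect_error(Pedigree("F", data.frame(
    sample_id = c("A", "B"), father_id = c(NA, "A"),
    mother_id = c(NA, NA), sex = c("female", "male"),
    role = c("control", "case"))), "female")
  expect_error(Pedigree("F", data.frame(
    sample_id = "A", father_id = NA_character_,
    mother_id = NA_character_, sex = "male", role = "control")),
    "at least one case")
})

test_that("VCF reading splits multi-allelic sites with allele-specific dosages", {
  # all 3x3 diploid genotypes over alleles {0,1,2} across nine samples
  gts <- c("0/0", "0/1", "0/2", "1/1", "1/2", "2/2", "./.", "1|2", "2|0")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("S", 1:9)), collapse = "\t"),
    paste(c("1", "500", ".", "A", "C,T", "50", "PASS", ".", "GT", gts),
          collapse = "\t")), vcf)
  cohort <- readVariants(vcf)
  expect_equal(nVariants(cohort), 2)
  expect_equal(annotations(cohort)$variant_id,
               c("1_500_A_C", "1_500_A_T"))
  # brute-force oracle: dosage = count of allele index among called alleles
  oracle <- function(gt, k) {
    a <- strsplit(gt, "[/|]")[[1]]
    a <- a[a != "."]
    if (!length(a)) NA_real_ else sum(a == as.character(k))
  }
  expect_equal(unname(dosages(cohort)[1, ]),
               vapply(gts, oracle, 0, k = 1), ignore_attr = TRUE)
  expect_equal(unname(dosages(cohort)[2, ]),
               vapply(gts, oracle, 0, k = 2), ignore_attr = TRUE)
})

test_that("annotation joins by variant id; stray rows warn; empty VCF works", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    paste(c("14", "95560456", ".", "A", "C", "60", "PASS", ".", "GT",
            "0/1"), collapse = "\t")), vcf)
  annPath <- tempfile()
  writeLines(c("variant_id\tgene_symbols\tcadd_phred",
               "14_95560456_A_C\tDICER1\t24",
               "9_1_G_A\tGHOSTGENE\t5"), annPath)
  expect_warning(cohort <- readVariants(vcf, annPath), "9_1_G_A")
  ann <- annotations(cohort)
  expect_equal(ann$variant_id, "14_95560456_A_C")
  expect_equal(ann$gene_symbols, "DICER1")
  expect_equal(ann$cadd_phred, 24)

  headerOnly <- tempfile(fileext = ".vcf")
  writeLines(readLines(vcf)[1:3], headerOnly)
  expect_equal(nVariants(readVariants(headerOnly)), 0)
})

test_that("BED track reading sorts, keeps labels and rejects degenerate intervals", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("2\t500\t600\tenh_b", "1\t100\t120\tmiR-21 seed",
               "1\t50\t70\tenh_a"), bed)
  track <- readTrack(bed, "mirna_target")
  iv <- trackIntervals(track)
  # comparison-sort oracle over (chrom, start): input order (2,500),
  # (1,100), (1,50) sorts to (1,50), (1,100), (2,500)
  key <- order(c("2", "1", "1"), c(500, 100, 50))
  expect_equal(as.vector(GenomicRanges::start(iv)),
               (c(500, 100, 50) + 1)[key])
  expect_equal(iv$label, c("enh_a", "miR-21 seed", "enh_b"))

  bad <- tempfile(fileext = ".bed")
  writeLines(c("1\t10\t20\tok", "1\t30\t30\tempty"), bad)
  expect_error(readTrack(bad, "promoter"), "line")
})

test_that("panel reading uppercases, deduplicates and rejects empty files", {
  pan <- tempfile()
  writeLines(c("symbol\tcategory", "ptch1\tAutosomal Dominant",
               "PTCH1\tOther CancerGene", "lpp\tOther CancerGene"), pan)
  expect_warning(panel <- readPanel(pan), "PTCH1")
  expect_equal(length(panel), 2)
  expect_equal(unname(panelEntries(panel)["PTCH1"]), "Autosomal Dominant")
  expect_true("LPP" %in% names(panelEntries(panel)))

  empty <- tempfile(); writeLines("symbol\tcategory", empty)
  expect_error(readPanel(empty), "empty")
})

test_that("writing then re-reading a cohort reproduces every field bit-identically", {
  sim <- suppressWarnings(simulateCohort(
    simulationConfig(seed = 11, nBackgroundVariants = 80L)))
  d <- tempfile(); writeSimulation(sim, d)
  back <- suppressWarnings(readVariants(file.path(d, "cohort.vcf"),
                                        file.path(d, "annotation.tsv")))
  a1 <- annotations(sim$cohort)
  a2 <- annotations(back)[match(a1$variant_id, annotations(back)$variant_id), ]
  expect_equal(nrow(a2), nrow(a1))            # no record silently dropped
  for (col in names(a1))
    if (col %in% names(a2))
      expect_equal(unname(a2[[col]]), unname(a1[[col]]),
                   info = col, tolerance = 0)
  ord <- a1$variant_id
  sam <- cohortSamples(sim$cohort)
  expect_identical(dosages(back)[ord, sam], dosages(sim$cohort))
  expect_identical(strandCounts(back)$forward[ord, sam], sim$cohort@adf)
  expect_identical(strandCounts(back)$reverse[ord, sam], sim$cohort@adr)
})

test_that("variant ids round-trip the chrom_pos_ref_alt notation", {
  tabs <- hlCandidateTables()
  ids <- c(tabs$missense$variant_id, tabs$nonsense$variant_id,
           hlPanelHitTables()$cpg$variant_id)
  parts <- strsplit(ids, "_")
  expect_true(all(lengths(parts) == 4))
  rebuilt <- vapply(parts, function(p) variantId(p[1], p[2], p[3], p[4]), "")
  expect_identical(rebuilt, ids)
})
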