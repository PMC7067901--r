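toyGeneModel <- function() data.frame(
  gene = c("PLUSG", "MINUSG"), chrom = "1", strand = c("+", "-"),
  tx_start = c(10000, 40000), tx_end = c(20000, 50000),
  stringsAsFactors = FALSE)

test_that("UTR/flank windows are strand-aware and inclusive at 1 kb", {
  gm <- toyGeneModel()
  mk <- function(fc, pos, gene) makeAnn(1, functional_class = fc,
                                        pos = pos, gene_symbols = gene)
  # 400 bp beyond a plus-strand gene's end, class downstream
  expect_equal(assignRegion(mk("downstream", 20400, "PLUSG"), gm)$region,
               "utr3_or_downstream")
  # exactly 1000 bp upstream is in; 1001 is out
  expect_equal(assignRegion(mk("upstream", 9001, "PLUSG"), gm)$region,
               "utr5_or_upstream")
  expect_equal(assignRegion(mk("upstream", 9000, "PLUSG"), gm)$region,
               "other")
  # upstream of a minus-strand gene lies at higher coordinates
  expect_equal(assignRegion(mk("upstream", 50500, "MINUSG"), gm)$region,
               "utr5_or_upstream")
  expect_equal(assignRegion(mk("downstream", 39800, "MINUSG"), gm)$region,
               "utr3_or_downstream")
  # inside-UTR: distance 0
  utr <- assignRegion(mk("utr3", 19990, "PLUSG"), gm)
  expect_equal(utr$region, "utr3_or_downstream")
  expect_equal(utr$distance_to_gene_edge, 0)
  # unknown gene: other, with a warning
  expect_warning(res <- assignRegion(mk("upstream", 9500, "GHOST"), gm),
                 "GHOST")
  expect_equal(res$region, "other")
})

test_that("region assignment equals the distance/strand oracle on random variants", {
  set.seed(21)
  gm <- toyGeneModel()
  n <- 200
  ann <- makeAnn(n,
    functional_class = sample(c("upstream", "downstream", "utr5", "utr3",
                                "intronic"), n, TRUE),
    pos = sample(c(8000:11000, 19000:22000, 38000:41000, 49000:52000),
                 n, TRUE),
    gene_symbols = sample(c("PLUSG", "MINUSG"), n, TRUE))
  got <- assignRegion(ann, gm)
  want <- vapply(seq_len(n), function(i) regionOracle(
    ann$functional_class[i], ann$pos[i], ann$gene_symbols[i], gm), "")
  expect_equal(got$region, want)
})

test_that("point-in-interval intersection is left-closed, right-open", {
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(start = 101,
                                                     end = 120))
  gr$label <- "site"
  track <- RegulatoryTrack("t", "mirna_target", gr)
  mk <- function(pos1) {
    ann <- makeAnn(1, functional_class = "utr3", pos = pos1)
    list(ann = ann,
         asg = data.frame(variant_id = ann$variant_id,
                          region = "utr3_or_downstream",
                          distance_to_gene_edge = 0, gene = "G"))
  }
  # 0-based position 100 = 1-based 101: inside [100, 120)
  x <- mk(101)
  expect_equal(intersectTracks(x$ann, x$asg, list(track))$hits_mirna_target,
               "site")
  # 0-based position 120: excluded by the open right end
  y <- mk(121)
  expect_equal(intersectTracks(y$ann, y$asg, list(track))$hits_mirna_target,
               "")
})

test_that("intersection equals the brute-force overlap scan on fuzzed pairs", {
  set.seed(22)
  nV <- 100; nI <- 60
  ann <- makeAnn(nV, functional_class = "utr3",
                 pos = sample(1:500, nV, TRUE),
                 chrom = sample(c("1", "2"), nV, TRUE))
  ann$variant_id <- variantId(ann$chrom, ann$pos, ann$ref, ann$alt)
  asg <- data.frame(variant_id = ann$variant_id,
                    region = "utr3_or_downstream",
                    distance_to_gene_edge = 0, gene = "G")
  s0 <- sample(0:480, nI, TRUE)
  ivChrom <- sample(c("1", "2"), nI, TRUE)
  w <- sample(1:30, nI, TRUE)
  gr <- GenomicRanges::GRanges(ivChrom,
                               IRanges::IRanges(start = s0 + 1,
                                                end = s0 + w))
  gr$label <- sprintf("iv%02d", seq_len(nI))
  got <- intersectTracks(ann, asg,
                         list(RegulatoryTrack("t", "mirna_target", gr)))
  want <- overlapOracle(ann$chrom, ann$pos, ivChrom, s0, s0 + w)
  for (i in seq_len(nV)) {
    labs <- sprintf("iv%02d", which(want[i, ]))
    o <- order(s0[which(want[i, ])], labs)
    expect_equal(got$hits_mirna_target[i], paste(labs[o], collapse = ";"))
  }
})

test_that("selection requires CADD and region-appropriate evidence", {
  fx <- syntheticNoncodingFixture()
  asg <- assignRegion(fx$ann, fx$geneModel)
  sel <- selectNoncoding(intersectTracks(fx$ann, asg, fx$tracks))
  a <- sel$assessments
  # a 3'UTR variant with CADD 13.59-like score and one miRNA hit is kept
  expect_true(all(a$retained[a$region == "utr3_or_downstream" &
                               a$cadd_phred > 10 &
                               nzchar(a$hits_mirna_target)]))
  # CADD below cutoff is never kept, evidence or not
  expect_false(any(a$retained[a$cadd_phred <= 10]))
  # 5' variant without any track hit is not kept
  expect_false(any(a$retained[a$region == "utr5_or_upstream" &
                                a$n_hit_categories == 0]))
  counts <- setNames(sel$category_counts$n, sel$category_counts$category)
  expect_equal(counts[names(fx$expected_counts)], fx$expected_counts)
})

test_that("shrinking a track never grows the retained set", {
  fx <- syntheticNoncodingFixture()
  asg <- assignRegion(fx$ann, fx$geneModel)
  full <- selectNoncoding(intersectTracks(fx$ann, asg, fx$tracks))
  shrunk <- lapply(fx$tracks, function(t) {
    iv <- trackIntervals(t)
    RegulatoryTrack(t@name, trackCategory(t),
                    iv[seq_len(floor(length(iv) / 2))])
  })
  sub <- selectNoncoding(intersectTracks(fx$ann, asg, shrunk))
  keptFull <- full$assessments$variant_id[full$assessments$retained]
  keptSub <- sub$assessments$variant_id[sub$assessments$retained]
  expect_true(all(keptSub %in% keptFull))
})

test_that("non-coding ranking favors stronger down-regulation and is stable", {
  mk <- function(vid, region, mirsvr, cadd, nCat = 1, pos = 1) data.frame(
    variant_id = vid, region = region, chrom = "1", pos = pos,
    cadd_phred = cadd, mirsvr = mirsvr, n_hit_categories = nCat,
    stringsAsFactors = FALSE)
  two <- rbind(mk("a", "utr3_or_downstream", -0.1, 30, pos = 1),
               mk("b", "utr3_or_downstream", -0.9, 12, pos = 2))
  r <- rankNoncoding(two)
  expect_equal(r$variant_id[r$rank == 1], "b")  # -0.9 ranks first

  one <- rankNoncoding(mk("solo", "utr5_or_upstream", NA, 15))
  expect_equal(one$rank, 1)

  set.seed(30)
  pool <- do.call(rbind, lapply(1:30, function(i) mk(
    paste0("v", i),
    sample(c("utr3_or_downstream", "utr5_or_upstream"), 1),
    sample(c(NA, -0.5, -0.9), 1), sample(10:30, 1),
    sample(1:3, 1), pos = i)))
  r1 <- rankNoncoding(pool)
  r2 <- rankNoncoding(pool[sample(nrow(pool)), ])
  expect_identical(r1$variant_id, r2$variant_id)
  expect_identical(r1$rank, r2$rank)
})
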