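test_that("functional classes map onto assessment paths", {
  expect_equal(classifyPath(c("nonsynonymous_snv", "stopgain_snv",
                              "frameshift_deletion",
                              "frameshift_insertion", "utr3",
                              "synonymous_snv", "intergenic")),
               c("missense", "nonsense", "nonsense", "nonsense",
                 rep("not_coding_candidate", 3)))
})

test_that("CADD threshold is strict and missing fails", {
  expect_equal(caddFilter(c(22.6, 10, 10.001, NA, 9)),
               c(TRUE, FALSE, TRUE, FALSE, FALSE))
  # relaxing the cutoff can only grow the pass set
  x <- c(NA, runif(50, 0, 40))
  expect_true(all(!caddFilter(x, 20) | caddFilter(x, 10)))
})

test_that("conservation cascade is conjunctive over present scores", {
  expect_equal(conservationFilter(4.1, 0.9, 3.0), "pass")  # PhyloP >= 3
  expect_equal(conservationFilter(1.9, 0.9, 4.0), "fail")
  expect_equal(conservationFilter(NA, NA, NA), "not_applicable")
  expect_equal(conservationFilter(2.0, 0.9, 4.0), "fail")  # GERP strict >
  expect_equal(conservationFilter(NA, NA, 2.9), "fail")

  set.seed(7)
  g <- sample(c(NA, 1.9, 2.0, 2.1, 5), 300, TRUE)
  pc <- sample(c(NA, 0.2, 0.3, 0.31, 0.9), 300, TRUE)
  pp <- sample(c(NA, 2.9, 3.0, 4), 300, TRUE)
  got <- conservationFilter(g, pc, pp)
  want <- vapply(seq_len(300), function(i) {
    present <- c(gerp = !is.na(g[i]), pc = !is.na(pc[i]),
                 pp = !is.na(pp[i]))
    if (!any(present)) return("not_applicable")
    ok <- TRUE
    if (present["gerp"] && !(g[i] > 2.0)) ok <- FALSE
    if (present["pc"] && !(pc[i] > 0.3)) ok <- FALSE
    if (present["pp"] && !(pp[i] >= 3.0)) ok <- FALSE
    if (ok) "pass" else "fail"
  }, "")
  expect_equal(got, want)
})

test_that("consensus vote needs 60% of available calls with a 5-tool floor", {
  mkAnn <- function(del, tol, na) {
    ann <- makeAnn(1)
    calls <- c(rep("deleterious", del), rep("tolerated", tol),
               rep(NA_character_, na))
    for (j in seq_along(missenseColumns()))
      ann[[missenseColumns()[j]]] <- calls[j]
    ann
  }
  case <- function(del, tol, na) consensusDeleteriousness(mkAnn(del, tol, na))
  expect_true(case(10, 0, 0)$pass)              # unanimous
  expect_true(case(6, 4, 0)$pass)               # exactly 60%
  expect_false(case(5, 5, 0)$pass)              # ceiling(6) > 5
  expect_false(case(4, 0, 6)$pass)              # only 4 available: floor
  expect_true(case(4, 1, 5)$pass)               # ceiling(0.6*5) = 3 <= 4
  expect_equal(case(6, 4, 0)$del_votes, 6)
  expect_equal(case(4, 1, 5)$del_available, 5)
})

test_that("nonsense verdict annotates but does not exclude", {
  mkAnn <- function(k) {
    ann <- makeAnn(1, functional_class = "stopgain_snv", cadd_phred = 36)
    for (j in seq_along(nonsenseColumns()))
      ann[[nonsenseColumns()[j]]] <- if (j <= k) "pathogenic" else "benign"
    ann
  }
  expect_equal(nonsenseVerdict(mkAnn(4))$verdict_label, "supporting(4)")
  expect_equal(nonsenseVerdict(mkAnn(0))$verdict_label, "no_support")
  expect_equal(nonsenseVerdict(mkAnn(8))$verdict_label,
               "majority_pathogenic")
  # zero support, high CADD: still retained
  out <- prioritizeCoding(mkAnn(0))
  expect_true(out$retained)
})

test_that("intolerance ranks candidates without cutting them", {
  mk <- function(vid, int, cadd, votes, chrom = "1", pos = 1) data.frame(
    variant_id = vid, family_id = "F", chrom = chrom, pos = pos,
    path = "missense", int_count = int, cadd_phred = cadd,
    del_votes = votes, varsome_votes = 0, stringsAsFactors = FALSE)
  two <- rbind(mk("a", 3, 34, 6, pos = 10), mk("b", 2, 35, 9, pos = 5))
  ranked <- intoleranceRank(two)
  expect_equal(ranked$variant_id[ranked$rank == 1], "a")  # int beats CADD

  one <- intoleranceRank(mk("solo", 1, 20, 6))
  expect_equal(one$rank, 1)

  set.seed(9)
  pool <- do.call(rbind, lapply(1:40, function(i) mk(
    paste0("v", i), sample(0:3, 1), sample(c(15, 20, 25), 1),
    sample(6:10, 1), pos = i)))
  r1 <- intoleranceRank(pool)
  for (k in 1:5) {
    r2 <- intoleranceRank(pool[sample(nrow(pool)), ])
    expect_identical(r2$variant_id, r1$variant_id)
    expect_identical(r2$rank, r1$rank)
  }
})

test_that("the coding cascade equals the conjunction-of-predicates oracle", {
  set.seed(13)
  n <- 400
  ann <- makeAnn(n,
    functional_class = sample(c("nonsynonymous_snv", "stopgain_snv",
                                "frameshift_deletion", "utr3",
                                "synonymous_snv"), n, TRUE),
    cadd_phred = sample(c(NA, 5, 10, 15, 30), n, TRUE),
    gerp = sample(c(NA, 1, 3), n, TRUE),
    phastcons = sample(c(NA, 0.1, 0.9), n, TRUE),
    phylop = sample(c(NA, 1, 4), n, TRUE))
  ann$pos <- seq_len(n)
  for (col in missenseColumns())
    ann[[col]] <- sample(c("deleterious", "tolerated", NA), n, TRUE)
  for (col in nonsenseColumns())
    ann[[col]] <- sample(c("pathogenic", "benign", NA), n, TRUE)
  out <- prioritizeCoding(ann)
  oracle <- vapply(seq_len(n), function(i) {
    path <- classifyPath(ann$functional_class[i])
    if (path == "not_coding_candidate") return(FALSE)
    cadd <- !is.na(ann$cadd_phred[i]) && ann$cadd_phred[i] > 10
    cons <- conservationFilter(ann$gerp[i], ann$phastcons[i],
                               ann$phylop[i])
    if (path == "nonsense") return(cadd && cons != "fail")
    calls <- unlist(ann[i, missenseColumns()])
    votes <- sum(calls == "deleterious", na.rm = TRUE)
    avail <- sum(!is.na(calls))
    cadd && cons != "fail" && avail >= 5 &&
      votes >= ceiling(0.6 * avail)
  }, TRUE)
  expect_equal(out$retained, oracle)
  # missense with CADD 9 can never be retained
  expect_false(any(out$retained & !is.na(out$cadd_phred) &
                     out$cadd_phred <= 10))
  # retained set is monotone in the CADD cutoff
  strict <- prioritizeCoding(ann, caddCutoff = 20)
  expect_true(all(!strict$retained | out$retained))
})
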