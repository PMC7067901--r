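## Synthetic multi-family cohort generator: pedigrees shaped like the
## three study families, a planted dominant causal variant per family, and
## annotated background variants drawn from explicit distributions, so the
## whole funnel and both prioritization arms can be exercised end to end
## without any patient data. The seed fully determines the output.

#' Simulation configuration
#'
#' Background annotation distributions are explicit package conventions:
#' MAF is a mixture of a point mass at 0 (weight `mafW0`; private
#' variants) and a Beta(`mafBetaShape1`, `mafBetaShape2`) scaled to
#' [0, `mafBetaMax`]; CADD PHRED is Gamma(`caddShape`, scale `caddScale`)
#' truncated at `caddMax`; conservation scores share a latent Gaussian
#' with CADD (correlation `conservationRho`); predictor calls are
#' Bernoulli with deleterious probability logistic in CADD
#' (midpoint `delLogisticMid`, scale `delLogisticScale`). `phenocopyRate`
#' is the probability an affected case does not carry the planted
#' variant; `1 - penetrance` the probability an unaffected control
#' carries it.
#'
#' @slot seed integer; fully determines the output.
#' @slot nFamilies number of families.
#' @slot pedigreeTemplates template per family, recycled: "trio" (parents
#'   plus affected child, affected mother), "three_generation" (carrier
#'   founder, affected parent and child) or "extended_9" (nine members,
#'   three affected siblings, one obligate-carrier parent).
#' @slot nBackgroundVariants background variants in the joint call set.
#' @slot planted list(gene, functional_class, cadd, del_votes, maf).
#' @slot mafW0,mafBetaShape1,mafBetaShape2,mafBetaMax MAF mixture.
#' @slot caddShape,caddScale,caddMax CADD distribution.
#' @slot conservationRho latent correlation between CADD and conservation.
#' @slot delLogisticMid,delLogisticScale deleterious-call model.
#' @slot phenocopyRate,penetrance planted-variant carriage model.
#' @slot meanDepth mean per-sample sequencing depth (Poisson).
#' @export
setClass("SimulationConfig", representation(
  seed = "integer", nFamilies = "integer", pedigreeTemplates = "character",
  nBackgroundVariants = "integer", planted = "list",
  mafW0 = "numeric", mafBetaShape1 = "numeric", mafBetaShape2 = "numeric",
  mafBetaMax = "numeric", caddShape = "numeric", caddScale = "numeric",
  caddMax = "numeric", conservationRho = "numeric",
  delLogisticMid = "numeric", delLogisticScale = "numeric",
  phenocopyRate = "numeric", penetrance = "numeric", meanDepth = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@mafW0 < 0 || object@mafW0 > 1)
    msg <- c(msg, "mafW0 must be in [0,1]")
  if (object@phenocopyRate < 0 || object@phenocopyRate > 1)
    msg <- c(msg, "phenocopyRate must be in [0,1]")
  if (object@penetrance <= 0 || object@penetrance > 1)
    msg <- c(msg, "penetrance must be in (0,1]")
  if (object@conservationRho < -1 || object@conservationRho > 1)
    msg <- c(msg, "conservationRho must be in [-1,1]")
  if (!all(object@pedigreeTemplates %in%
           c("trio", "three_generation", "extended_9")))
    msg <- c(msg, "unknown pedigree template")
  if (object@nBackgroundVariants < 0 || object@nFamilies < 1)
    msg <- c(msg, "need nFamilies >= 1 and nBackgroundVariants >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param seed integer seed.
#' @param nFamilies,pedigreeTemplates,nBackgroundVariants,planted see
#'   slots.
#' @param mafW0,mafBetaShape1,mafBetaShape2,mafBetaMax,caddShape,caddScale
#'   see slots.
#' @param caddMax,conservationRho,delLogisticMid,delLogisticScale see
#'   slots.
#' @param phenocopyRate,penetrance,meanDepth see slots.
#' @export
simulationConfig <- function(seed = 1L, nFamilies = 3L,
                             pedigreeTemplates = c("trio", "extended_9",
                                                   "three_generation"),
                             nBackgroundVariants = 500L,
                             planted = list(gene = NULL,
                                            functional_class =
                                              "nonsynonymous_snv",
                                            cadd = 25, del_votes = 9,
                                            maf = 0),
                             mafW0 = 0.3, mafBetaShape1 = 0.5,
                             mafBetaShape2 = 20, mafBetaMax = 0.05,
                             caddShape = 2, caddScale = 4, caddMax = 60,
                             conservationRho = 0.6, delLogisticMid = 15,
                             delLogisticScale = 4, phenocopyRate = 0,
                             penetrance = 1, meanDepth = 30) {
  new("SimulationConfig", seed = as.integer(seed),
      nFamilies = as.integer(nFamilies),
      pedigreeTemplates = pedigreeTemplates,
      nBackgroundVariants = as.integer(nBackgroundVariants),
      planted = planted, mafW0 = mafW0, mafBetaShape1 = mafBetaShape1,
      mafBetaShape2 = mafBetaShape2, mafBetaMax = mafBetaMax,
      caddShape = caddShape, caddScale = caddScale, caddMax = caddMax,
      conservationRho = conservationRho, delLogisticMid = delLogisticMid,
      delLogisticScale = delLogisticScale, phenocopyRate = phenocopyRate,
      penetrance = penetrance, meanDepth = meanDepth)
}

## Pedigree templates --------------------------------------------------------

.pedigreeTemplate <- function(template, famId) {
  p <- function(id, f, m, sex, role) data.frame(
    sample_id = paste0(famId, "_", id),
    father_id = if (is.na(f)) NA_character_ else paste0(famId, "_", f),
    mother_id = if (is.na(m)) NA_character_ else paste0(famId, "_", m),
    sex = sex, role = role, stringsAsFactors = FALSE)
  rows <- switch(template,
    trio = rbind(
      p("F", NA, NA, "male", "control"),
      p("M", NA, NA, "female", "case"),
      p("C", "F", "M", "female", "case")),
    three_generation = rbind(
      p("GF", NA, NA, "male", "obligate_carrier"),
      p("GM", NA, NA, "female", "control"),
      p("P", "GF", "GM", "male", "case"),
      p("SP", NA, NA, "female", "control"),
      p("C", "P", "SP", "female", "case")),
    extended_9 = rbind(
      p("A", NA, NA, "female", "obligate_carrier"),
      p("B", NA, NA, "male", "control"),
      p("C1", "B", "A", "male", "case"),
      p("C2", "B", "A", "female", "case"),
      p("C3", "B", "A", "male", "case"),
      p("D1", "B", "A", "female", "control"),
      p("D2", "B", "A", "male", "control"),
      p("E1", NA, NA, "female", "control"),
      p("E2", NA, NA, "male", "control")),
    stop("unknown pedigree template: ", template))
  Pedigree(famId, rows)
}

## Synthetic gene model: genes tiled along one chromosome, alternating
## strands; 0-based half-open transcript bounds.
.syntheticGeneModel <- function(nGenes = 60, geneLength = 10000,
                                gap = 3000, chrom = "1") {
  starts <- (seq_len(nGenes) - 1) * (geneLength + gap) + gap
  data.frame(gene = sprintf("G%03d", seq_len(nGenes)), chrom = chrom,
             strand = rep(c("+", "-"), length.out = nGenes),
             tx_start = starts, tx_end = starts + geneLength,
             stringsAsFactors = FALSE)
}

.CLASS_PROBS <- c(intergenic = 0.40, intronic = 0.33, synonymous_snv = 0.05,
                  nonsynonymous_snv = 0.08, utr3 = 0.05, utr5 = 0.03,
                  upstream = 0.025, downstream = 0.02,
                  stopgain_snv = 0.005, frameshift_deletion = 0.01)

.classPosition <- function(fc, gm) {
  ## 0-based point position for one variant of class fc in gene-model row gm
  plus <- gm$strand == "+"
  u <- function(a, b) floor(runif(1, a, b))  # integer in [a, b)
  switch(fc,
    utr5 = if (plus) u(gm$tx_start, gm$tx_start + 200) else
      u(gm$tx_end - 200, gm$tx_end),
    utr3 = if (plus) u(gm$tx_end - 200, gm$tx_end) else
      u(gm$tx_start, gm$tx_start + 200),
    upstream = if (plus) gm$tx_start - sample(1000, 1) else
      gm$tx_end + sample(1000, 1) - 1,
    downstream = if (plus) gm$tx_end + sample(1000, 1) - 1 else
      gm$tx_start - sample(1000, 1),
    intergenic = u(max(0, gm$tx_start - 2900), gm$tx_start - 1100),
    u(gm$tx_start + 300, gm$tx_end - 300))
}

.BASES <- c("A", "C", "G", "T")

## Mendelian genotype drop: founders from HWE at the drawn MAF, children
## one transmitted allele per parent; private variants are a singleton
## het in one random individual.
.dropGenotypes <- function(peds, maf) {
  unlist(unname(lapply(peds, function(ped) {
    s <- pedSamples(ped)
    d <- setNames(numeric(nrow(s)), s$sample_id)
    for (i in seq_len(nrow(s))) {
      fa <- s$father_id[i]; mo <- s$mother_id[i]
      transmit <- function(pid) {
        if (is.na(pid)) rbinom(1, 1, maf) else rbinom(1, 1, d[pid] / 2)
      }
      d[i] <- transmit(fa) + transmit(mo)
    }
    d
  })))
}

#' Simulate a multi-family cohort with a planted causal variant
#'
#' Generates pedigrees from the configured templates, one planted dominant
#' causal variant per family (carried by every case and obligate carrier
#' and by no control when penetrance is 1 and the phenocopy rate 0),
#' `nBackgroundVariants` annotated background variants with Mendelian
#' genotype transmission from founder genotypes, regulatory tracks that
#' cover a designated subset of the non-coding variants, and a truth
#' table of the planted variant ids. `set.seed(seed)` is called
#' internally: identical configurations produce identical cohorts.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return list with elements `cohort` (\linkS4class{VariantCohort} over
#'   all samples), `pedigrees` (list of \linkS4class{Pedigree}), `tracks`
#'   (list of \linkS4class{RegulatoryTrack}), `geneModel`, `truth`
#'   (data.frame variant_id, family_id, planted) and `config`.
#' @export
simulateCohort <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  templates <- rep_len(cfg@pedigreeTemplates, cfg@nFamilies)
  peds <- lapply(seq_len(cfg@nFamilies), function(i)
    .pedigreeTemplate(templates[i], paste0("FAM", i)))
  names(peds) <- vapply(peds, familyId, "")
  samples <- unlist(lapply(peds, function(p) pedSamples(p)$sample_id),
                    use.names = FALSE)
  gm <- .syntheticGeneModel()

  n <- cfg@nBackgroundVariants
  fc <- sample(names(.CLASS_PROBS), n, replace = TRUE, prob = .CLASS_PROBS)
  gidx <- sample(nrow(gm), n, replace = TRUE)
  pos0 <- vapply(seq_len(n), function(i)
    .classPosition(fc[i], gm[gidx[i], ]), numeric(1))
  ref <- sample(.BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1), "")
  del <- fc == "frameshift_deletion"
  ref[del] <- paste0(ref[del], sample(.BASES, sum(del), replace = TRUE))

  ## planted variants: one per family, mid-gene missense in distinct genes
  plantGene <- gm[seq(5, by = 7, length.out = cfg@nFamilies), ]
  plantPos0 <- plantGene$tx_start + 5000 + seq_len(cfg@nFamilies)
  plantedGeneNames <- if (is.null(cfg@planted$gene)) plantGene$gene else
    paste0(cfg@planted$gene, seq_len(cfg@nFamilies))
  fc <- c(rep(cfg@planted$functional_class, cfg@nFamilies), fc)
  pos0 <- c(plantPos0, pos0)
  ref <- c(rep("G", cfg@nFamilies), ref)
  alt <- c(rep("A", cfg@nFamilies), alt)
  genes <- c(plantedGeneNames, gm$gene[gidx])
  isPlanted <- seq_along(pos0) <= cfg@nFamilies
  plantedFamily <- c(names(peds), rep(NA_character_, n))

  ## de-duplicate positions deterministically
  key <- paste(pos0, ref, alt)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    pos0[dup] <- pos0[dup] + 1
    key <- paste(pos0, ref, alt)
  }
  N <- length(pos0)

  ## annotation distributions
  z1 <- rnorm(N)
  cadd <- pmin(cfg@caddMax,
               qgamma(pnorm(z1), shape = cfg@caddShape,
                      scale = cfg@caddScale))
  z2 <- cfg@conservationRho * z1 +
    sqrt(1 - cfg@conservationRho^2) * rnorm(N)
  gerp <- round(1.5 * z2 + 1, 2)
  phastcons <- round(pnorm(z2), 3)
  phylop <- round(1.8 * z2 + 0.5, 2)
  maf <- signif(ifelse(runif(N) < cfg@mafW0, 0,
                       cfg@mafBetaMax * rbeta(N, cfg@mafBetaShape1,
                                              cfg@mafBetaShape2)), 6)
  pdel <- stats::plogis((cadd - cfg@delLogisticMid) / cfg@delLogisticScale)

  ann <- data.frame(
    chrom = "1", pos = pos0 + 1, ref = ref, alt = alt,
    variant_class = ifelse(nchar(ref) == nchar(alt), "snv", "indel"),
    site_quality = round(rgamma(N, shape = 4, scale = 15), 1),
    site_coverage = rpois(N, cfg@meanDepth),
    platypus_pass = runif(N) > 0.05,
    gene_symbols = genes, functional_class = fc,
    protein_effect = NA_character_,
    maf_1000g = maf, maf_exac_nontcga = maf,
    cadd_phred = round(cadd, 2), gerp = gerp, phastcons = phastcons,
    phylop = phylop, pli = round(runif(N), 3),
    missense_z = round(rnorm(N), 2),
    mirsvr = ifelse(fc %in% c("utr3", "downstream"),
                    round(-runif(N), 3), NA_real_),
    stringsAsFactors = FALSE)
  lowCov <- runif(N) < 0.03
  ann$site_coverage[lowCov] <- rpois(sum(lowCov), 3)

  call01 <- function(active, yes, no) {
    out <- rep(NA_character_, N)
    out[active] <- ifelse(runif(sum(active)) < pdel[active], yes, no)
    out
  }
  isMis <- fc == "nonsynonymous_snv"
  isNon <- fc %in% c("stopgain_snv", "frameshift_deletion",
                     "frameshift_insertion")
  for (col in missenseColumns()) ann[[col]] <- call01(isMis, "deleterious",
                                                      "tolerated")
  for (col in nonsenseColumns()) ann[[col]] <- call01(isNon, "pathogenic",
                                                      "benign")
  exonic <- isMis | isNon | fc == "synonymous_snv"
  for (col in intoleranceColumns()) {
    v <- rep(NA_character_, N)
    v[exonic] <- ifelse(runif(sum(exonic)) < 0.3, "intolerant", "tolerant")
    ann[[col]] <- v
  }

  ## planted annotation overrides: passes every coding-arm criterion
  pi <- which(isPlanted)
  ann$site_quality[pi] <- 99
  ann$site_coverage[pi] <- cfg@meanDepth
  ann$platypus_pass[pi] <- TRUE
  ann$maf_1000g[pi] <- if (cfg@planted$maf > 0) cfg@planted$maf else NA
  ann$maf_exac_nontcga[pi] <- ann$maf_1000g[pi]
  ann$cadd_phred[pi] <- cfg@planted$cadd
  ann$gerp[pi] <- 4; ann$phastcons[pi] <- 0.9; ann$phylop[pi] <- 4
  for (k in seq_along(missenseColumns()))
    ann[[missenseColumns()[k]]][pi] <-
      if (k <= cfg@planted$del_votes) "deleterious" else "tolerated"
  for (col in nonsenseColumns()) ann[[col]][pi] <-
    if (cfg@planted$functional_class %in%
        c("stopgain_snv", "frameshift_deletion", "frameshift_insertion"))
      "pathogenic" else NA_character_
  for (col in intoleranceColumns()) ann[[col]][pi] <- "intolerant"
  ann$pli[pi] <- 0.99; ann$missense_z[pi] <- 3.2

  ## genotypes
  founderIds <- unlist(lapply(peds, function(p) {
    s <- pedSamples(p)
    s$sample_id[is.na(s$father_id) & is.na(s$mother_id)]
  }), use.names = FALSE)
  dosage <- matrix(0, N, length(samples),
                   dimnames = list(NULL, samples))
  for (v in seq_len(N)) {
    if (isPlanted[v]) {
      ped <- peds[[plantedFamily[v]]]
      s <- pedSamples(ped)
      carries <- (s$role == "case" & runif(nrow(s)) >= cfg@phenocopyRate) |
        s$role == "obligate_carrier" |
        (s$role == "control" & runif(nrow(s)) >= cfg@penetrance)
      dosage[v, s$sample_id] <- as.numeric(carries)
    } else if (ann$maf_1000g[v] == 0 || is.na(ann$maf_1000g[v])) {
      ## private variant: singleton het in one random founder, so child
      ## genotypes stay Mendelian-consistent
      dosage[v, sample(founderIds, 1)] <- 1
    } else {
      dosage[v, ] <- .dropGenotypes(peds, ann$maf_1000g[v])[samples]
    }
  }

  depth <- matrix(rpois(N * length(samples), cfg@meanDepth), N,
                  dimnames = list(NULL, samples))
  gq <- matrix(sample(30:99, N * length(samples), replace = TRUE), N)
  altReads <- matrix(rbinom(length(depth), depth, dosage / 2), N)
  adf <- matrix(rbinom(length(altReads), altReads, 0.5), N)
  adr <- altReads - adf
  colnames(gq) <- colnames(adf) <- colnames(adr) <- samples

  cohort <- VariantCohort(ann, dosage = dosage, depth = depth, gq = gq,
                          adf = adf, adr = adr)
  tracks <- .syntheticTracks(annotations(cohort))
  truth <- data.frame(variant_id = annotations(cohort)$variant_id[pi],
                      family_id = plantedFamily[pi], planted = TRUE,
                      stringsAsFactors = FALSE)
  list(cohort = cohort, pedigrees = peds, tracks = tracks, geneModel = gm,
       truth = truth, config = cfg)
}

## Tracks covering a designated fraction of the non-coding variants, plus
## decoy intervals nowhere near any variant.
.syntheticTracks <- function(ann, coverFraction = c(
    mirna_target = 0.6, promoter = 0.3, enhancer = 0.15,
    super_enhancer = 0.1, tfbs = 0.25, cpg_island = 0.2)) {
  mkTrack <- function(category, side) {
    idx <- which(ann$functional_class %in% side)
    idx <- idx[runif(length(idx)) < coverFraction[[category]]]
    covered <- if (length(idx)) GenomicRanges::GRanges(
      ann$chrom[idx],
      IRanges::IRanges(start = pmax(1, ann$pos[idx] -
                                      sample(0:30, length(idx), TRUE)),
                       end = ann$pos[idx] + sample(5:40, length(idx), TRUE)))
      else GenomicRanges::GRanges()
    decoys <- GenomicRanges::GRanges(
      "1", IRanges::IRanges(start = sample(2e6:3e6, 5), width = 50))
    gr <- c(covered, decoys)
    gr$label <- sprintf("%s_%02d", category, seq_along(gr))
    RegulatoryTrack(category, category, gr)
  }
  list(
    mkTrack("mirna_target", c("utr3", "downstream")),
    mkTrack("promoter", c("utr5", "upstream")),
    mkTrack("enhancer", c("utr5", "upstream")),
    mkTrack("super_enhancer", c("utr5", "upstream")),
    mkTrack("tfbs", c("utr5", "upstream")),
    mkTrack("cpg_island", c("utr5", "upstream")))
}

#' Write a simulated cohort to disk
#'
#' Emits the exact formats the package readers consume: `cohort.vcf` and
#' `annotation.tsv`, `pedigrees.ped`, `gene_model.tsv`, one
#' `track_<category>.bed` per regulatory track, and `truth.tsv`.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCohort(sim$cohort, file.path(dir, "cohort.vcf"),
              file.path(dir, "annotation.tsv"))
  writePedigree(sim$pedigrees, file.path(dir, "pedigrees.ped"))
  write.table(sim$geneModel, file.path(dir, "gene_model.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (track in sim$tracks) {
    iv <- trackIntervals(track)
    writeLines(sprintf("%s\t%d\t%d\t%s",
                       as.character(GenomicRanges::seqnames(iv)),
                       GenomicRanges::start(iv) - 1L,
                       GenomicRanges::end(iv), iv$label),
               file.path(dir, paste0("track_", trackCategory(track),
                                     ".bed")))
  }
  invisible(dir)
}

#' Planted-variant recovery benchmark
#'
#' Runs the full filter funnel and coding prioritization on `nReplicates`
#' freshly simulated cohorts (seeds `seed + 1 .. seed + nReplicates`) and
#' reports how often the planted variant survives to the retained coding
#' set and its mean within-family intolerance rank when it does.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param nReplicates number of simulated cohorts.
#' @param policy a \linkS4class{SegregationPolicy}.
#' @param caddCutoff coding CADD cutoff.
#' @return list(recovery_rate, mean_rank, details) where details has one
#'   row per (replicate, family).
#' @export
recoveryBenchmark <- function(cfg, nReplicates = 20,
                              policy = SegregationPolicy(),
                              caddCutoff = 10) {
  stopifnot(nReplicates >= 1)
  rows <- list()
  for (rep in seq_len(nReplicates)) {
    repCfg <- cfg
    repCfg@seed <- cfg@seed + rep
    sim <- simulateCohort(repCfg)
    for (ped in sim$pedigrees) {
      fam <- familyId(ped)
      plantedId <- sim$truth$variant_id[sim$truth$family_id == fam]
      funnel <- suppressWarnings(
        runFunnel(sim$cohort, ped, policy = policy))
      coding <- prioritizeCoding(funnel$survivors, caddCutoff = caddCutoff)
      hit <- coding$retained & coding$variant_id == plantedId
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep, family_id = fam, recovered = any(hit),
        rank = if (any(hit)) coding$rank[which(hit)] else NA_integer_,
        n_retained = sum(coding$retained), stringsAsFactors = FALSE)
    }
  }
  details <- do.call(rbind, rows)
  list(recovery_rate = mean(details$recovered),
       mean_rank = mean(details$rank, na.rm = TRUE),
       details = details)
}
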