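## Readers and writers for the formats the pipeline touches:
## PED pedigrees, joint-genotyped VCF + annotation TSV, BED regulatory
## tracks, gene-panel TSV, gene-model TSV and structural-variant TSV.
## Coordinate convention: VCF positions and variant_id are 1-based; all
## interval work is 0-based half-open; an SNV at pos p occupies [p-1, p).

#' Read pedigrees from a PED file
#'
#' Standard 6-column tab-separated PED (family, sample, father, mother,
#' sex, affection) with an optional 7th column carrying role overrides
#' (e.g. `obligate_carrier` for an unaffected individual who must carry the
#' familial variant). Affection 2 maps to case, 1 to control, 0/-9 to
#' unknown; parent id "0" means absent.
#'
#' @param path PED file path.
#' @return named list of \linkS4class{Pedigree}, one per family.
#' @export
readPedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 6))
    stop("PED line(s) with fewer than 6 columns: ",
         paste(which(ncols < 6), collapse = ", "))
  tab <- data.frame(
    family_id = vapply(fields, `[`, "", 1L),
    sample_id = vapply(fields, `[`, "", 2L),
    father_id = vapply(fields, `[`, "", 3L),
    mother_id = vapply(fields, `[`, "", 4L),
    sex_code  = vapply(fields, `[`, "", 5L),
    aff_code  = vapply(fields, `[`, "", 6L),
    role_override = vapply(fields, function(f)
      if (length(f) >= 7L) f[7L] else NA_character_, ""),
    stringsAsFactors = FALSE)
  tab$father_id[tab$father_id %in% c("0", "")] <- NA_character_
  tab$mother_id[tab$mother_id %in% c("0", "")] <- NA_character_
  sex <- c("1" = "male", "2" = "female")[tab$sex_code]
  sex[is.na(sex)] <- "unknown"
  role <- c("2" = "case", "1" = "control")[tab$aff_code]
  role[is.na(role)] <- "unknown"
  override <- !is.na(tab$role_override) & nzchar(tab$role_override)
  role[override] <- tab$role_override[override]
  peds <- lapply(split(seq_len(nrow(tab)), tab$family_id), function(i) {
    Pedigree(tab$family_id[i[1]], data.frame(
      sample_id = tab$sample_id[i], father_id = tab$father_id[i],
      mother_id = tab$mother_id[i], sex = unname(sex[i]),
      role = unname(role[i]), stringsAsFactors = FALSE))
  })
  peds[unique(tab$family_id)]
}

#' Write pedigrees to a PED file
#'
#' Inverse of [readPedigree()]; the 7th column carries the role only where
#' it cannot be derived from the affection code.
#'
#' @param peds list of \linkS4class{Pedigree}.
#' @param path output path.
#' @export
writePedigree <- function(peds, path) {
  rows <- unlist(lapply(peds, function(ped) {
    s <- pedSamples(ped)
    aff <- c(case = "2", control = "1", obligate_carrier = "1",
             unknown = "0")[s$role]
    sexc <- c(male = "1", female = "2", unknown = "0")[s$sex]
    override <- ifelse(s$role == "obligate_carrier", s$role, "")
    paste(familyId(ped), s$sample_id,
          ifelse(is.na(s$father_id), "0", s$father_id),
          ifelse(is.na(s$mother_id), "0", s$mother_id),
          sexc, aff, override, sep = "\t")
  }), use.names = FALSE)
  writeLines(sub("\t$", "", rows), path)
}

## VCF + annotation ----------------------------------------------------------

.gtDosage <- function(gt, altIndex) {
  ## count of alleles equal to altIndex among called alleles; "./." -> NA
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    a <- a[a != "."]
    if (!length(a)) return(NA_real_)
    sum(a == as.character(altIndex))
  }, numeric(1))
}

.perAlleleField <- function(cell, altIndex) {
  ## Number=R field: vector (ref, alt1, alt2, ...) -> entry for this alt
  if (is.null(cell) || all(is.na(cell))) return(NA_real_)
  v <- suppressWarnings(as.numeric(cell))
  if (length(v) >= altIndex + 1L) v[altIndex + 1L] else v[1L]
}

#' Read a joint-genotyped VCF and its annotation table
#'
#' Parses the VCF with `VariantAnnotation::readVcf`, splits multi-allelic
#' sites into one record per alternate allele (recomputing allele-specific
#' dosages from GT), and joins the annotation TSV by the
#' `chrom_pos_ref_alt` key. Variants without an annotation row are kept
#' with all annotation fields missing; annotation rows matching no VCF
#' record are dropped with a warning.
#'
#' @param vcfPath VCF 4.2 path (FORMAT GT and optionally DP, GQ and
#'   per-allele ADF/ADR strand counts).
#' @param annotationPath annotation TSV path (see [readAnnotationTable()]),
#'   or NULL to skip the join.
#' @return a \linkS4class{VariantCohort}.
#' @export
readVariants <- function(vcfPath, annotationPath = NULL) {
  vcf <- VariantAnnotation::readVcf(vcfPath)
  n <- nrow(vcf)
  samples <- colnames(vcf)
  gt <- if (n) VariantAnnotation::geno(vcf)$GT else
    matrix(character(), 0, length(samples))
  g <- VariantAnnotation::geno(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  qual <- VariantAnnotation::fixed(vcf)$QUAL
  filt <- VariantAnnotation::filt(vcf)
  infoDP <- tryCatch(VariantAnnotation::info(vcf)$DP, error = function(e) NULL)

  rows <- list(); dos <- list(); dep <- list(); gqm <- list()
  adf <- list(); adr <- list()
  k <- 0L
  for (i in seq_len(n)) {
    alts <- as.character(altList[[i]])
    for (j in seq_along(alts)) {
      k <- k + 1L
      cov <- if (!is.null(infoDP) && !is.na(infoDP[i])) infoDP[i] else {
        if (!is.null(g$DP)) sum(g$DP[i, ], na.rm = TRUE) else NA_real_
      }
      rows[[k]] <- data.frame(
        chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alts[j],
        variant_class = if (nchar(ref[i]) == 1L && nchar(alts[j]) == 1L)
          "snv" else "indel",
        site_quality = as.numeric(qual[i]), site_coverage = as.numeric(cov),
        platypus_pass = identical(filt[i], "PASS"),
        stringsAsFactors = FALSE)
      dos[[k]] <- .gtDosage(gt[i, ], j)
      dep[[k]] <- if (!is.null(g$DP)) as.numeric(g$DP[i, ]) else
        rep(NA_real_, length(samples))
      gqm[[k]] <- if (!is.null(g$GQ)) as.numeric(g$GQ[i, ]) else
        rep(NA_real_, length(samples))
      adf[[k]] <- if (!is.null(g$ADF))
        vapply(seq_along(samples),
               function(s) .perAlleleField(g$ADF[i, s][[1]], j), numeric(1))
        else rep(NA_real_, length(samples))
      adr[[k]] <- if (!is.null(g$ADR))
        vapply(seq_along(samples),
               function(s) .perAlleleField(g$ADR[i, s][[1]], j), numeric(1))
        else rep(NA_real_, length(samples))
    }
  }
  asMat <- function(lst) {
    m <- if (length(lst)) do.call(rbind, lst) else
      matrix(numeric(), 0, length(samples))
    colnames(m) <- samples
    m
  }
  ann <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), variant_class = character(),
               site_quality = numeric(), site_coverage = numeric(),
               platypus_pass = logical(), stringsAsFactors = FALSE)
  ann$variant_id <- variantId(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (!is.null(annotationPath)) {
    tab <- readAnnotationTable(annotationPath)
    unmatched <- setdiff(tab$variant_id, ann$variant_id)
    if (length(unmatched))
      warning("annotation row(s) matching no VCF record ignored: ",
              paste(unmatched, collapse = ", "))
    idx <- match(ann$variant_id, tab$variant_id)
    for (col in setdiff(names(tab), c("variant_id", names(ann))))
      ann[[col]] <- tab[[col]][idx]
  }
  VariantCohort(ann, dosage = asMat(dos), depth = asMat(dep),
                gq = asMat(gqm), adf = asMat(adf), adr = asMat(adr))
}

.annNumericColumns <- function() c(
  "maf_1000g", "maf_exac_nontcga", "cadd_phred", "gerp", "phastcons",
  "phylop", "pli", "missense_z", "mirsvr")

#' Read a per-variant annotation table
#'
#' Tab-separated with header; keyed by `variant_id`. Expected columns:
#' gene_symbols (comma-separated for multi-gene annotations),
#' functional_class, protein_effect, maf_1000g, maf_exac_nontcga,
#' cadd_phred, gerp, phastcons, phylop, the ten `mis_*` missense-predictor
#' calls (deleterious/tolerated), the eight `non_*` nonsense-predictor
#' calls (pathogenic/benign), the three `int_*` intolerance flags
#' (intolerant/tolerant), pli, missense_z, mirsvr. "." or empty means
#' missing.
#'
#' @param path TSV path.
#' @return data.frame, one row per variant_id.
#' @export
readAnnotationTable <- function(path) {
  tab <- read.delim(path, colClasses = "character",
                    na.strings = c(".", "NA", ""), check.names = FALSE)
  if (is.null(tab$variant_id)) stop("annotation table lacks variant_id")
  for (col in intersect(.annNumericColumns(), names(tab)))
    tab[[col]] <- as.numeric(tab[[col]])
  tab
}

.num2str <- function(x) ifelse(is.na(x), ".", sprintf("%.15g", x))

#' Write a VariantCohort as a VCF + annotation TSV pair
#'
#' Emits a minimal VCF 4.2 (FORMAT GT:DP:GQ:ADF:ADR, per-allele strand
#' counts; one biallelic record per stored allele) and the annotation table
#' read back by [readVariants()]. Missing values become "." throughout.
#'
#' @param cohort a \linkS4class{VariantCohort}.
#' @param vcfPath,annotationPath output paths.
#' @export
writeCohort <- function(cohort, vcfPath, annotationPath = NULL) {
  ann <- annotations(cohort)
  samples <- cohortSamples(cohort)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FILTER=<ID=caller_fail,Description=\"Failed caller internal filters\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Forward-strand allelic depths\">",
    "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Reverse-strand allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  o <- order(chromOrderKey(ann$chrom), ann$chrom, ann$pos, ann$ref, ann$alt)
  body <- vapply(o, function(i) {
    gtField <- function(s) {
      d <- cohort@dosage[i, s]
      gt <- if (is.na(d)) "./." else c("0/0", "0/1", "1/1")[d + 1L]
      int0 <- function(x) ifelse(is.na(x), ".", format(x))
      paste(gt, int0(cohort@depth[i, s]), int0(cohort@gq[i, s]),
            ifelse(is.na(cohort@adf[i, s]), ".",
                   paste0("0,", format(cohort@adf[i, s]))),
            ifelse(is.na(cohort@adr[i, s]), ".",
                   paste0("0,", format(cohort@adr[i, s]))), sep = ":")
    }
    paste(c(ann$chrom[i], ann$pos[i], ann$variant_id[i], ann$ref[i],
            ann$alt[i], .num2str(ann$site_quality[i]),
            if (isTRUE(ann$platypus_pass[i])) "PASS" else "caller_fail",
            paste0("DP=", ifelse(is.na(ann$site_coverage[i]), ".",
                                 format(ann$site_coverage[i]))),
            "GT:DP:GQ:ADF:ADR",
            vapply(samples, gtField, "")), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), vcfPath)
  if (!is.null(annotationPath)) writeAnnotationTable(ann, annotationPath)
  invisible(vcfPath)
}

#' @rdname readAnnotationTable
#' @param ann annotation data.frame (as in a \linkS4class{VariantCohort}).
#' @export
writeAnnotationTable <- function(ann, path) {
  cols <- c("variant_id", "gene_symbols", "functional_class",
            "protein_effect", .annNumericColumns(),
            missenseColumns(), nonsenseColumns(), intoleranceColumns())
  out <- ann[, intersect(cols, names(ann)), drop = FALSE]
  for (col in names(out)) {
    v <- out[[col]]
    out[[col]] <- if (is.numeric(v)) .num2str(v) else
      ifelse(is.na(v) | !nzchar(as.character(v)), ".", as.character(v))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## BED tracks ----------------------------------------------------------------

#' Read a regulatory track from a BED file
#'
#' 3+ column BED, 0-based half-open. Intervals are sorted by
#' (chrom, start); overlapping intervals are retained as-is. A 4th (name)
#' column becomes the interval label.
#'
#' @param path BED path.
#' @param category track category (see \linkS4class{RegulatoryTrack}).
#' @param name track name; defaults to the file name.
#' @return a \linkS4class{RegulatoryTrack}.
#' @export
readTrack <- function(path, category, name = basename(path)) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) < 1))
    stop("BED interval(s) with start >= end at line(s): ",
         paste(which(GenomicRanges::width(gr) < 1), collapse = ", "))
  if (!is.null(gr$name)) gr$label <- gr$name
  RegulatoryTrack(name, category, gr)
}

## Gene panels ---------------------------------------------------------------

#' Read a gene panel from a two-column TSV
#'
#' Columns: symbol, category (header required). Symbols are uppercased and
#' deduplicated; on conflicting categories for one symbol the first wins
#' with a warning. An empty panel is rejected.
#'
#' @param path TSV path.
#' @param name panel name; defaults to the file name.
#' @return a \linkS4class{GenePanel}.
#' @export
readPanel <- function(path, name = basename(path)) {
  tab <- read.delim(path, colClasses = "character", check.names = FALSE)
  if (!nrow(tab)) stop("empty gene panel: ", path)
  GenePanel(name, tab[[1]], tab[[2]])
}

## Gene models and structural variants ---------------------------------------

#' Read a transcript-bounds gene model
#'
#' Tab-separated with header: gene, chrom, strand (+/-), tx_start, tx_end.
#' Coordinates are 0-based half-open, matching the package's internal
#' interval convention.
#'
#' @param path TSV path.
#' @return data.frame(gene, chrom, strand, tx_start, tx_end).
#' @export
readGeneModel <- function(path) {
  tab <- read.delim(path, colClasses = "character", check.names = FALSE)
  tab$tx_start <- as.numeric(tab$tx_start)
  tab$tx_end <- as.numeric(tab$tx_end)
  stopifnot(all(c("gene", "chrom", "strand") %in% names(tab)),
            all(tab$strand %in% c("+", "-")),
            all(tab$tx_start < tab$tx_end))
  tab
}

#' Read structural variant calls from a TSV
#'
#' Columns: chrom, start, end (1-based inclusive span), sv_type
#' (deletion/duplication/other), filter (PASS or anything else), carriers
#' (comma-separated sample ids), gnomad_af ("." when no overlap with a
#' common structural variant).
#'
#' @param path TSV path.
#' @return data.frame with filter_pass (logical), carrier_sample_ids
#'   (list column) and gnomad_overlap_af (numeric, NA missing).
#' @export
readStructuralVariants <- function(path) {
  tab <- read.delim(path, colClasses = "character",
                    na.strings = c(".", ""), check.names = FALSE)
  out <- data.frame(chrom = tab$chrom, start = as.numeric(tab$start),
                    end = as.numeric(tab$end), sv_type = tab$sv_type,
                    stringsAsFactors = FALSE)
  stopifnot(all(out$start <= out$end))
  out$filter_pass <- tab$filter == "PASS" & !is.na(tab$filter)
  out$carrier_sample_ids <- I(strsplit(ifelse(is.na(tab$carriers), "",
                                              tab$carriers), ","))
  out$gnomad_overlap_af <- as.numeric(tab$gnomad_af)
  out
}
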