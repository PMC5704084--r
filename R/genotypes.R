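#' Load a VCF into a raw alternate-allele count matrix
#'
#' Reads a VCF v4.2 with GT fields, keeps records whose FILTER equals
#' `"PASS"` (or `"."`, treated as unfiltered), and parses genotypes to
#' alternate-allele counts. Multiallelic records are split into one biallelic
#' record per alternate allele, or rejected, per `multiallelic`.
#'
#' @param path path to a VCF file.
#' @param subject_ids subjects to extract; every id must be present in the
#'   file (extra file samples are ignored).
#' @param multiallelic `"split"` (default) or `"reject"`.
#' @return list with `counts` (subjects x variants matrix of raw ALT allele
#'   counts, `NA` for missing calls) and `info` (data frame: `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`).
#' @export
load_vcf <- function(path, subject_ids, multiallelic = c("split", "reject")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || nrow(gt) == 0) stop("VCF has no genotype records")
  fmt <- gt[, "FORMAT"]
  if (!all(grepl("GT", fmt))) stop("GT missing from FORMAT field")
  samples <- colnames(gt)[-1]
  absent <- setdiff(subject_ids, samples)
  if (length(absent) > 0) {
    stop("subjects absent from VCF: ", paste(absent, collapse = ", "))
  }

  keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  if (nrow(fix) == 0) stop("no records with FILTER=PASS")

  gt_field <- function(x) sub(":.*", "", x)

  count_allele <- function(gt_strings, allele) {
    vapply(gt_strings, function(g) {
      g <- gt_field(g)
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles == as.character(allele))
    }, numeric(1), USE.NAMES = FALSE)
  }

  counts_cols <- list()
  info_rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1 && multiallelic == "reject") next
    g <- gt[i, subject_ids]
    for (a in seq_along(alts)) {
      vid <- fix$ID[i]
      if (is.na(vid) || vid == ".") {
        vid <- paste(fix$CHROM[i], fix$POS[i], fix$REF[i], alts[a], sep = ":")
      } else if (length(alts) > 1) {
        vid <- paste0(vid, "_", alts[a])
      }
      counts_cols[[vid]] <- count_allele(g, a)
      info_rows[[vid]] <- data.frame(
        variant_id = vid, chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[a])
    }
  }
  counts <- do.call(cbind, counts_cols)
  rownames(counts) <- subject_ids
  list(counts = counts, info = do.call(rbind, c(info_rows, make.row.names = FALSE)))
}

#' Orient allele counts to minor-allele dosages
#'
#' Codes each variant as the number of minor alleles (#MA). The minor allele
#' is defined by whole-cohort frequency: if the ALT frequency among called
#' genotypes is <= 0.5 the ALT allele is minor and dosages are the raw
#' counts; otherwise dosages are flipped to `2 - count`. A frequency of
#' exactly 0.5 keeps ALT as minor.
#'
#' @param counts numeric vector (one variant) or matrix (subjects x variants)
#'   of raw ALT allele counts in `{0, 1, 2, NA}`.
#' @return for a vector: list with `dosages`, `maf`, `flipped`; for a
#'   matrix: list with `dosages` matrix, `maf` vector, `flipped` vector.
#' @export
orient_minor_allele <- function(counts) {
  orient_one <- function(x) {
    called <- x[!is.na(x)]
    if (length(called) == 0) stop("all genotypes missing; cannot orient")
    freq <- sum(called) / (2 * length(called))
    flipped <- freq > 0.5
    dos <- if (flipped) 2 - x else x
    list(dosages = dos, maf = min(freq, 1 - freq), flipped = flipped)
  }
  if (is.matrix(counts)) {
    per <- apply(counts, 2, orient_one, simplify = FALSE)
    dos <- do.call(cbind, lapply(per, `[[`, "dosages"))
    dimnames(dos) <- dimnames(counts)
    list(dosages = dos,
         maf = vapply(per, `[[`, numeric(1), "maf"),
         flipped = vapply(per, `[[`, logical(1), "flipped"))
  } else {
    orient_one(counts)
  }
}

#' Unique genotype profiles within a stratum
#'
#' Variants sharing an identical dosage vector over a stratum's subjects
#' collapse into one profile group; one model is fitted per group and its
#' p-value is copied back to every member. Groups whose dosage vector has no
#' variability among called genotypes (monomorphic in the stratum) are
#' excluded. The returned count `m` is the multiple-testing family size for
#' that stratum.
#'
#' @param dosages subjects x variants dosage matrix (minor-allele oriented).
#' @param subjects subject ids belonging to the stratum (default all rows).
#' @return list with `groups` (list of `profile_key`, `dosages`,
#'   `member_variant_ids`) and `m` (number of groups).
#' @export
unique_profiles <- function(dosages, subjects = rownames(dosages)) {
  stopifnot(is.matrix(dosages))
  sub <- dosages[subjects, , drop = FALSE]
  keys <- apply(sub, 2, function(x) paste(ifelse(is.na(x), ".", x), collapse = ":"))
  poly <- apply(sub, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && stats::var(x) > 0
  })
  keys <- keys[poly]
  if (length(keys) == 0) return(list(groups = list(), m = 0L))
  by_key <- split(names(keys), keys)
  groups <- lapply(names(by_key), function(k) {
    members <- by_key[[k]]
    list(profile_key = k,
         dosages = sub[, members[1]],
         member_variant_ids = members)
  })
  list(groups = groups, m = length(groups))
}

#' Dominant recoding of minor-allele dosages
#'
#' `SNPr = 0` for zero copies of the minor allele and `1` for one or two
#' copies; missing stays missing.
#'
#' @param dosages vector of dosages in `{0, 1, 2, NA}`.
#' @export
dominant_recode <- function(dosages) {
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or missing")
  ifelse(is.na(dosages), NA_real_, as.numeric(dosages >= 1))
}

#' Read a VCF as an oriented genotype matrix
#'
#' Convenience wrapper: [load_vcf()] then [orient_minor_allele()], with
#' per-stratum minor-allele frequencies attached.
#'
#' @inheritParams load_vcf
#' @param strata optional named character vector mapping subject id to
#'   stratum label, for per-stratum MAFs.
#' @return list of class `"genotype_matrix"`: `dosages` (subjects x
#'   variants), `info` (variant metadata with `maf`, `flipped`, and
#'   per-stratum MAF columns).
#' @export
genotype_matrix <- function(path, subject_ids, strata = NULL,
                            multiallelic = c("split", "reject")) {
  raw <- load_vcf(path, subject_ids, multiallelic)
  ori <- orient_minor_allele(raw$counts)
  info <- raw$info
  info$maf <- unname(ori$maf[info$variant_id])
  info$flipped <- unname(ori$flipped[info$variant_id])
  if (!is.null(strata)) {
    for (st in unique(strata)) {
      ids <- names(strata)[strata == st]
      info[[paste0("maf_", st)]] <- apply(
        ori$dosages[ids, info$variant_id, drop = FALSE], 2, function(x) {
          x <- x[!is.na(x)]
          if (length(x) == 0) return(NA_real_)
          sum(x) / (2 * length(x))
        })
    }
  }
  structure(list(dosages = ori$dosages, info = info), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$dosages), "subjects x",
      ncol(x$dosages), "variants\n")
  invisible(x)
}
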