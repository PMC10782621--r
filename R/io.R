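# Readers/writers for the standard input formats and GATK-style hard
# filtering. VCF parsing is delegated to vcfR; window counts and TPM
# tables are plain tab-separated text.

GENOTYPE_LEVELS <- c("missing", "REF/REF", "REF/ALT", "ALT/ALT")

INFO_KEYS <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")

#' Default hard-filter thresholds
#'
#' The conventional GATK hard-filter thresholds for germline short
#' variants. A SNV fails when QD < 2.0, FS > 60.0, MQ < 40.0,
#' MQRankSum < -12.5 or ReadPosRankSum < -8.0; an indel fails when
#' QD < 2.0, FS > 200.0 or ReadPosRankSum < -20.0. All inequalities are
#' strict; a site at the boundary (e.g. FS = 60.0) is retained.
#'
#' @param snp,indel Named lists overriding individual thresholds.
#' @return List of class `"filter_thresholds"` with elements `snp` and
#'   `indel`.
#' @export
filter_thresholds <- function(snp = list(), indel = list()) {
  def_snp <- list(QD = 2.0, FS = 60.0, MQ = 40.0,
                  MQRankSum = -12.5, ReadPosRankSum = -8.0)
  def_indel <- list(QD = 2.0, FS = 200.0, ReadPosRankSum = -20.0)
  bad <- c(setdiff(names(snp), names(def_snp)),
           setdiff(names(indel), names(def_indel)))
  if (length(bad) > 0L)
    stop("unknown threshold name(s): ", paste(bad, collapse = ", "))
  def_snp[names(snp)] <- snp
  def_indel[names(indel)] <- indel
  structure(list(snp = def_snp, indel = def_indel),
            class = "filter_thresholds")
}

map_genotype <- function(gt) {
  out <- rep(NA_character_, length(gt))
  gt_clean <- gsub("\\|", "/", gt)
  out[is.na(gt) | gt_clean %in% c(".", "./.", ".|.")] <- "missing"
  out[gt_clean %in% c("0/0")] <- "REF/REF"
  out[gt_clean %in% c("0/1", "1/0")] <- "REF/ALT"
  out[gt_clean %in% c("1/1")] <- "ALT/ALT"
  bad <- is.na(out)
  if (any(bad))
    stop("unknown genotype encoding: ",
         paste(unique(gt[bad]), collapse = ", "))
  out
}

#' Read biallelic variant sites with allelic depths from a VCF
#'
#' Parses a VCF (plain or bgzipped) with GT and AD FORMAT fields into a
#' long-format data frame: one row per biallelic site per sample.
#' Multiallelic rows are excluded at parse time. Rows lacking a usable AD
#' field get depths 0, 0 and are flagged in `ad_missing` rather than
#' silently dropped. Site-level INFO metrics QD, FS, MQ, MQRankSum and
#' ReadPosRankSum are carried along for hard filtering; metrics absent
#' from a record are NA.
#'
#' @param vcf_source Path to a VCF file.
#' @param sample_names Samples to extract (default: all samples in the
#'   file). Unknown names are an error listing the available samples.
#' @param classes Variant classes to keep: subset of `c("SNP", "indel")`.
#' @return Data frame of class `"allelic_sites"` with columns `chrom`,
#'   `pos`, `ref_allele`, `alt_allele`, `variant_class`, the five INFO
#'   metrics, `sample`, `genotype`, `ref_depth`, `alt_depth`,
#'   `ad_missing`.
#' @export
read_allelic_sites <- function(vcf_source, sample_names = NULL,
                               classes = c("SNP", "indel")) {
  classes <- match.arg(classes, several.ok = TRUE)
  vcf <- vcfR::read.vcfR(vcf_source, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  available <- colnames(vcf@gt)[-1L]
  if (is.null(sample_names)) sample_names <- available
  unknown <- setdiff(sample_names, available)
  if (length(unknown) > 0L)
    stop("sample(s) not in VCF: ", paste(unknown, collapse = ", "),
         "; available samples: ", paste(available, collapse = ", "))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  vclass <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "indel")
  keep <- biallelic & vclass %in% classes
  info <- lapply(INFO_KEYS, function(k)
    suppressWarnings(vcfR::extract.info(vcf, element = k, as.numeric = TRUE)))
  names(info) <- INFO_KEYS
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  rows <- which(keep)
  per_sample <- lapply(sample_names, function(s) {
    ads <- strsplit(ifelse(is.na(ad[rows, s]), "", ad[rows, s]), ",", fixed = TRUE)
    rd <- suppressWarnings(vapply(ads, function(v)
      if (length(v) >= 2L) as.numeric(v[1L]) else NA_real_, numeric(1)))
    al <- suppressWarnings(vapply(ads, function(v)
      if (length(v) >= 2L) as.numeric(v[2L]) else NA_real_, numeric(1)))
    bad_ad <- is.na(rd) | is.na(al)
    rd[bad_ad] <- 0; al[bad_ad] <- 0
    data.frame(
      chrom = unname(fix[rows, "CHROM"]),
      pos = as.integer(fix[rows, "POS"]),
      ref_allele = unname(ref[rows]),
      alt_allele = unname(alt[rows]),
      variant_class = unname(vclass[rows]),
      QD = unname(info$QD[rows]), FS = unname(info$FS[rows]),
      MQ = unname(info$MQ[rows]), MQRankSum = unname(info$MQRankSum[rows]),
      ReadPosRankSum = unname(info$ReadPosRankSum[rows]),
      sample = s,
      genotype = map_genotype(unname(gt[rows, s])),
      ref_depth = rd, alt_depth = al, ad_missing = bad_ad,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_sample)
  row.names(out) <- NULL
  class(out) <- c("allelic_sites", "data.frame")
  out
}

#' Apply hard filters to variant sites
#'
#' Removes a site when any strict threshold inequality of the applicable
#' class (SNP vs indel) holds; see [filter_thresholds()]. A metric absent
#' from a record (NA) never fails the site — GATK emits the rank-sum
#' annotations only where they are defined. Filtering is per site: all
#' sample rows of a failing site are removed together. Idempotent.
#'
#' @param sites `allelic_sites` data frame.
#' @param thresholds A [filter_thresholds()] object.
#' @return The retained rows, same class.
#' @export
apply_hard_filters <- function(sites, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  sites <- as.data.frame(sites)
  lt <- function(x, cut) !is.na(x) & x < cut
  gt_ <- function(x, cut) !is.na(x) & x > cut
  snp <- thresholds$snp
  ind <- thresholds$indel
  fail_snp <- lt(sites$QD, snp$QD) | gt_(sites$FS, snp$FS) |
    lt(sites$MQ, snp$MQ) | lt(sites$MQRankSum, snp$MQRankSum) |
    lt(sites$ReadPosRankSum, snp$ReadPosRankSum)
  fail_ind <- lt(sites$QD, ind$QD) | gt_(sites$FS, ind$FS) |
    lt(sites$ReadPosRankSum, ind$ReadPosRankSum)
  fail <- ifelse(sites$variant_class == "SNP", fail_snp, fail_ind)
  out <- sites[!fail, , drop = FALSE]
  row.names(out) <- NULL
  class(out) <- c("allelic_sites", "data.frame")
  out
}

#' Genotype concordance crosstable between two samples
#'
#' Counts sites by genotype call in sample A against genotype call in
#' sample B, over the categories missing, REF/REF, REF/ALT and ALT/ALT.
#' SNPs and indels are tabulated separately; each table's total equals the
#' number of input sites of that class shared by both samples.
#'
#' @param sites `allelic_sites` data frame carrying both samples.
#' @param sample_a,sample_b Sample names (A in rows, B in columns).
#' @return List with components `SNP` and `indel`, each a 4 x 4
#'   contingency table.
#' @export
genotype_crosstab <- function(sites, sample_a, sample_b) {
  sites <- as.data.frame(sites)
  for (s in c(sample_a, sample_b))
    if (!s %in% sites$sample && nrow(sites) > 0L)
      stop("sample not present: ", s)
  bad <- !sites$genotype %in% GENOTYPE_LEVELS
  if (any(bad))
    stop("unknown genotype encoding: ",
         paste(unique(sites$genotype[bad]), collapse = ", "))
  out <- lapply(c(SNP = "SNP", indel = "indel"), function(cl) {
    sub <- sites[sites$variant_class == cl, , drop = FALSE]
    a <- sub[sub$sample == sample_a, , drop = FALSE]
    b <- sub[sub$sample == sample_b, , drop = FALSE]
    key_a <- paste(a$chrom, a$pos, a$ref_allele, a$alt_allele)
    key_b <- paste(b$chrom, b$pos, b$ref_allele, b$alt_allele)
    m <- match(key_a, key_b)
    if (anyNA(m))
      stop("both samples must be present on every site")
    table(factor(a$genotype, levels = GENOTYPE_LEVELS),
          factor(b$genotype[m], levels = GENOTYPE_LEVELS),
          dnn = c(sample_a, sample_b))
  })
  out
}

#' Read and write BED-like window read counts
#'
#' Four tab-separated columns without header: chromosome, 0-based start,
#' exclusive end, read count. Windows must be non-negative, non-empty
#' (start < end), and sorted and non-overlapping within each chromosome;
#' violations are errors naming the offending line. Output of
#' `write_window_counts()` re-reads identically.
#'
#' @param bed_source Path to the window-count file.
#' @return Data frame of class `"window_counts"` with columns `chrom`,
#'   `start`, `end`, `count`, sorted by (chrom, start).
#' @export
read_window_counts <- function(bed_source) {
  raw <- utils::read.table(bed_source, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric"),
                           col.names = c("chrom", "start", "end", "count"))
  validate_windows(raw)
  out <- raw[order(match(raw$chrom, unique(raw$chrom)), raw$start), ,
             drop = FALSE]
  row.names(out) <- NULL
  class(out) <- c("window_counts", "data.frame")
  out
}

validate_windows <- function(w) {
  bad <- which(w$start >= w$end)
  if (length(bad) > 0L)
    stop("window with start >= end at line ", bad[1L])
  bad <- which(w$start < 0 | w$count < 0)
  if (length(bad) > 0L)
    stop("negative start or count at line ", bad[1L])
  for (chrom in unique(w$chrom)) {
    idx <- which(w$chrom == chrom)
    if (is.unsorted(w$start[idx], strictly = TRUE))
      stop("unsorted windows on chromosome ", chrom, " at line ",
           idx[which(diff(w$start[idx]) <= 0)[1L] + 1L])
    if (any(w$end[idx][-length(idx)] > w$start[idx][-1L]))
      stop("overlapping windows on chromosome ", chrom, " at line ",
           idx[which(w$end[idx][-length(idx)] > w$start[idx][-1L])[1L] + 1L])
  }
  invisible(w)
}

#' @rdname read_window_counts
#' @param windows Window-count data frame.
#' @param sink Path to write to.
#' @export
write_window_counts <- function(windows, sink) {
  windows <- as.data.frame(windows)
  validate_windows(windows)
  utils::write.table(windows[, c("chrom", "start", "end", "count")], sink,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(sink)
}

#' Read a transcript-level TPM expression table
#'
#' Tab-separated table with a header naming a transcript-id column
#' (`target_id`, `transcript_id` or `transcript`) and a `tpm` column
#' (case-insensitive); an `est_counts` column is carried along when
#' present, as produced by common pseudo-alignment quantifiers.
#'
#' @param tsv_source Path to the table.
#' @return Data frame with columns `target_id`, `tpm`, and `est_counts`
#'   (NA when absent from the source).
#' @export
read_tpm_table <- function(tsv_source) {
  tab <- utils::read.table(tsv_source, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  lower <- tolower(names(tab))
  id_col <- match(c("target_id", "transcript_id", "transcript"), lower)
  id_col <- id_col[!is.na(id_col)][1L]
  tpm_col <- match("tpm", lower)
  if (is.na(id_col) || is.na(tpm_col))
    stop("table must have a transcript-id column and a 'tpm' column")
  cnt_col <- match("est_counts", lower)
  out <- data.frame(target_id = as.character(tab[[id_col]]),
                    tpm = as.numeric(tab[[tpm_col]]),
                    est_counts = if (is.na(cnt_col)) rep(NA_real_, nrow(tab))
                                 else as.numeric(tab[[cnt_col]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$tpm)) || any(out$tpm < 0))
    stop("TPM values must be non-negative numbers")
  out
}
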