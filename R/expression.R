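#' Per-chromosome expression-dosage summary
#'
#' Averages the base-10 logarithm of TPM over expressed transcripts
#' (estimated reads > 0; transcripts with TPM > 0 when the table carries
#' no counts) within each chromosome, as corroborating evidence for
#' aneuploidy: a chromosome present in extra copies tends to show
#' elevated average expression. The genome-wide mean over the included
#' transcripts is attached, together with reference levels at 0.5 and 1.5
#' times that mean — the conventional guide lines drawn on the
#' per-chromosome bar plot.
#'
#' @param tpm_records Data frame from [read_tpm_table()] or
#'   [simulate_tpm_table()] (`target_id`, `tpm`, optional `est_counts`).
#' @param transcript_chrom_map Data frame mapping `target_id` to `chrom`
#'   (optionally with a `gene` column for gene-level aggregation).
#' @param exclude_chroms Chromosomes omitted from the summary (default
#'   `"Y"`, whose expression is negligible).
#' @param aggregate `"transcript"` (default) or `"gene"`: with `"gene"`,
#'   TPM is summed over each gene's transcripts before taking logs.
#' @return Data frame with columns `chrom`, `mean_log10_tpm`,
#'   `n_transcripts`, plus attributes `overall_mean`, `ref_levels`
#'   (0.5x and 1.5x the overall mean) and `n_unmapped`.
#' @export
chromosome_expression_summary <- function(tpm_records, transcript_chrom_map,
                                          exclude_chroms = "Y",
                                          aggregate = c("transcript", "gene")) {
  aggregate <- match.arg(aggregate)
  tpm_records <- as.data.frame(tpm_records)
  if (any(tpm_records$tpm < 0)) stop("TPM values must be non-negative")
  m <- match(tpm_records$target_id, transcript_chrom_map$target_id)
  n_unmapped <- sum(is.na(m))
  if (n_unmapped > 0L)
    message(n_unmapped, " transcript(s) without a chromosome mapping excluded")
  tpm_records$chrom <- transcript_chrom_map$chrom[m]
  keep <- !is.na(m) & !tpm_records$chrom %in% exclude_chroms
  expressed <- if ("est_counts" %in% names(tpm_records) &&
                   !all(is.na(tpm_records$est_counts)))
    !is.na(tpm_records$est_counts) & tpm_records$est_counts > 0
  else tpm_records$tpm > 0
  d <- tpm_records[keep & expressed, , drop = FALSE]
  if (aggregate == "gene") {
    if (!"gene" %in% names(transcript_chrom_map))
      stop("gene-level aggregation needs a 'gene' column in the map")
    d$gene <- transcript_chrom_map$gene[match(d$target_id,
                                              transcript_chrom_map$target_id)]
    tpm_sum <- tapply(d$tpm, paste(d$chrom, d$gene, sep = "\r"), sum)
    d <- data.frame(chrom = sub("\r.*$", "", names(tpm_sum)),
                    tpm = as.numeric(tpm_sum), stringsAsFactors = FALSE)
  }
  d$log10_tpm <- log10(d$tpm)
  sp <- split(d$log10_tpm, d$chrom)
  out <- data.frame(chrom = names(sp),
                    mean_log10_tpm = vapply(sp, mean, numeric(1)),
                    n_transcripts = vapply(sp, length, integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  overall <- mean(d$log10_tpm)
  attr(out, "overall_mean") <- overall
  attr(out, "ref_levels") <- c(low = 0.5 * overall, high = 1.5 * overall)
  attr(out, "n_unmapped") <- n_unmapped
  out
}
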