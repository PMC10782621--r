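#' Standardize windowed read coverage by a baseline-chromosome median
#'
#' Divides every window's read count by the median count over windows on
#' the baseline chromosomes — chromosomes assumed to carry the sample's
#' most common copy number — so that a standardized ratio of 1.0
#' corresponds to baseline ploidy and, e.g., 1.5 to a trisomic chromosome
#' on a diploid baseline.
#'
#' @param windows Window-count data frame (`chrom`, `start`, `end`,
#'   `count`), e.g. from [read_window_counts()] or
#'   [simulate_window_counts()].
#' @param baseline_chroms Character vector of baseline chromosome names;
#'   must all be present among the windows.
#' @return The input data frame with a `ratio` column added, carrying the
#'   attribute `baseline_median`; class `"standardized_windows"`.
#' @examples
#' w <- data.frame(chrom = c("1", "1", "1", "2"), start = c(0, 1, 2, 0) * 1e4,
#'                 end = c(1, 2, 3, 1) * 1e4, count = c(80, 100, 120, 150))
#' sw <- standardize_coverage(w, "1")
#' sw$ratio[4]  # 1.5
#' @export
standardize_coverage <- function(windows, baseline_chroms) {
  windows <- as.data.frame(windows)
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(windows)))
  if (length(baseline_chroms) == 0L)
    stop("'baseline_chroms' must be non-empty")
  missing <- setdiff(baseline_chroms, unique(windows$chrom))
  if (length(missing) > 0L)
    stop("baseline chromosome(s) not present in windows: ",
         paste(missing, collapse = ", "))
  med <- stats::median(windows$count[windows$chrom %in% baseline_chroms])
  if (!is.finite(med) || med <= 0)
    stop("baseline median coverage is not positive; cannot standardize")
  windows$ratio <- windows$count / med
  attr(windows, "baseline_median") <- med
  class(windows) <- c("standardized_windows", "data.frame")
  windows
}

#' Per-chromosome coverage summaries
#'
#' Mean standardized ratio, standard error of the mean (sample SD /
#' sqrt(n)), and window count per chromosome. The conventional display
#' interval is mean +/- 2 * se.
#'
#' @param sw Output of [standardize_coverage()].
#' @param chrom_order Optional character vector fixing the row order
#'   (chromosomes absent from the data are dropped with a notice).
#' @return Data frame with columns `chrom`, `mean_ratio`, `se`,
#'   `n_windows`.
#' @export
summarize_chromosomes <- function(sw, chrom_order = NULL) {
  stopifnot(is.data.frame(sw), "ratio" %in% names(sw))
  sp <- split(sw$ratio, sw$chrom)
  out <- data.frame(
    chrom = names(sp),
    mean_ratio = vapply(sp, mean, numeric(1)),
    se = vapply(sp, function(x)
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0, numeric(1)),
    n_windows = vapply(sp, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(chrom_order)) {
    absent <- setdiff(chrom_order, out$chrom)
    if (length(absent) > 0L)
      message("chromosome(s) with no windows omitted: ",
              paste(absent, collapse = ", "))
    out <- out[match(intersect(chrom_order, out$chrom), out$chrom), ,
               drop = FALSE]
    row.names(out) <- NULL
  }
  out
}

#' Expected standardized coverage for candidate copy numbers
#'
#' Under median standardization, a chromosome with copy number c on a
#' baseline of ploidy p sits at ratio c / p — the horizontal reference
#' lines drawn on coverage plots (monosomic 0.5, trisomic 1.5, ... on a
#' diploid baseline).
#'
#' @param baseline_ploidy Integer >= 1.
#' @param copy_numbers Integer copy numbers >= 0 (default 0:5).
#' @return Named numeric vector of expected ratios.
#' @examples
#' expected_coverage_levels(2, 1:3)  # 0.5, 1.0, 1.5
#' @export
expected_coverage_levels <- function(baseline_ploidy, copy_numbers = 0:5) {
  if (!is.numeric(baseline_ploidy) || length(baseline_ploidy) != 1L ||
      baseline_ploidy < 1 || baseline_ploidy != round(baseline_ploidy))
    stop("'baseline_ploidy' must be a single integer >= 1")
  if (any(copy_numbers < 0)) stop("'copy_numbers' must be >= 0")
  stats::setNames(copy_numbers / baseline_ploidy, copy_numbers)
}
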