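# Within-sample allele frequencies: site selection, AF computation,
# kernel density estimation and mode detection.

#' Select sites for genome-sequencing allele-frequency analysis
#'
#' For jointly called samples, a site enters a sample's AF set if it was
#' called heterozygous in *either* sample (policy `"either"`); for samples
#' called alone, only sites heterozygous in that sample are used (policy
#' `"self"`). A site called heterozygous in the other sample but showing
#' reads from only one allele here is informative of allele loss, so it is
#' kept (its AF is near 0 or 1 and feeds the fixed-allele fraction);
#' `min_reads_each` restricts to sites with read support for both alleles
#' if a stricter set is wanted.
#'
#' @param sites Long-format allelic-site data frame from
#'   [read_allelic_sites()] (SNVs are used; indel rows are dropped).
#' @param samples Character vector of sample names participating in the
#'   joint call.
#' @param policy `"either"` or `"self"`.
#' @param min_reads_each Minimum reads per allele in the evaluated sample
#'   (default 0).
#' @return Named list (one element per sample) of site data frames with
#'   total depth > 0.
#' @export
select_sites_genomic <- function(sites, samples,
                                 policy = c("either", "self"),
                                 min_reads_each = 0) {
  policy <- match.arg(policy)
  sites <- as.data.frame(sites)
  sites <- sites[sites$variant_class == "SNP", , drop = FALSE]
  miss <- setdiff(samples, unique(sites$sample))
  if (length(miss) > 0L)
    stop("sample(s) not present: ", paste(miss, collapse = ", "),
         "; available: ", paste(unique(sites$sample), collapse = ", "))
  key <- paste(sites$chrom, sites$pos)
  het_keys <- lapply(samples, function(s)
    unique(key[sites$sample == s & sites$genotype == "REF/ALT"]))
  names(het_keys) <- samples
  either_keys <- unique(unlist(het_keys))
  out <- lapply(samples, function(s) {
    wanted <- if (policy == "either") either_keys else het_keys[[s]]
    rows <- sites$sample == s & key %in% wanted &
      (sites$ref_depth + sites$alt_depth) > 0 &
      sites$ref_depth >= min_reads_each & sites$alt_depth >= min_reads_each
    sites[rows, , drop = FALSE]
  })
  names(out) <- samples
  out
}

#' Select sites for RNA-seq allele-frequency analysis
#'
#' RNA-seq read coverage varies far more between sites than genome
#' sequencing, so AF analysis is restricted to positions where both
#' alleles are solidly observed: at least `min_reads_per_allele` reads
#' from each allele (default 5).
#'
#' @param sites Allelic-site data frame (long format).
#' @param min_reads_per_allele Integer >= 1, default 5.
#' @return The retained rows.
#' @export
select_sites_rnaseq <- function(sites, min_reads_per_allele = 5) {
  if (min_reads_per_allele < 1)
    stop("'min_reads_per_allele' must be >= 1")
  sites <- as.data.frame(sites)
  sites[sites$ref_depth >= min_reads_per_allele &
          sites$alt_depth >= min_reads_per_allele, , drop = FALSE]
}

#' Within-sample allele frequency of each site
#'
#' The observed frequency of the alternative allele from allelic read
#' depths: `af = alt_depth / (ref_depth + alt_depth)`. Sites with zero
#' total depth carry no information and are skipped; their count is
#' attached as attribute `n_skipped` and reported.
#'
#' @param sites Data frame with `ref_depth` and `alt_depth` columns
#'   (and optionally `chrom`, `pos`).
#' @return Data frame of class `"af_observations"` with columns `chrom`,
#'   `pos`, `af`, `total_depth`.
#' @examples
#' compute_af(data.frame(ref_depth = c(10, 20), alt_depth = c(10, 10)))$af
#' @export
compute_af <- function(sites) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("ref_depth", "alt_depth") %in% names(sites)))
  total <- sites$ref_depth + sites$alt_depth
  skip <- total <= 0
  if (any(skip))
    message(sum(skip), " site(s) with zero total depth skipped")
  keep <- !skip
  out <- data.frame(
    chrom = if ("chrom" %in% names(sites)) sites$chrom[keep] else NA_character_,
    pos = if ("pos" %in% names(sites)) sites$pos[keep] else NA_integer_,
    af = sites$alt_depth[keep] / total[keep],
    total_depth = total[keep],
    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(skip)
  class(out) <- c("af_observations", "data.frame")
  out
}

#' Fraction of sites with a fixed allele
#'
#' Fraction of AF observations at the boundary (af <= `low` or
#' af >= `high`), where kernel density modes are unreliable. A high fixed
#' fraction at nominally heterozygous sites signals loss of one allele
#' (monosomy, uniparental disomy).
#'
#' @param af Numeric AF vector or an `af_observations` data frame.
#' @param low,high Boundary cutoffs (defaults 0.05 and 0.95).
#' @return Fraction in \[0, 1\] (NA for empty input).
#' @export
fixed_allele_fraction <- function(af, low = 0.05, high = 0.95) {
  if (is.data.frame(af)) af <- af$af
  if (length(af) == 0L) return(NA_real_)
  mean(af <= low | af >= high)
}

#' Kernel density estimate of within-sample allele frequencies
#'
#' Gaussian-kernel density on a uniform grid over \[0, 1\], renormalized
#' so the trapezoid-rule integral over \[0, 1\] is 1 (mass smoothed beyond
#' the boundaries is folded back by renormalization rather than
#' reflection). Fewer than `min_sites` observations give an unstable
#' density; such input is reported as insufficient rather than an error so
#' per-chromosome pipelines keep running.
#'
#' @param af Numeric AF vector or `af_observations` data frame.
#' @param bandwidth Kernel bandwidth on the AF scale (default 0.02, which
#'   resolves modes 1/5 apart at read depths >= 20).
#' @param grid_size Number of grid points (default 512).
#' @param min_sites Minimum observations required (default 200).
#' @return Object of class `"af_density"`: list with `grid`, `density`,
#'   `bandwidth`, `n`, and logical `insufficient`.
#' @export
estimate_af_density <- function(af, bandwidth = 0.02, grid_size = 512,
                                min_sites = 200) {
  if (is.data.frame(af)) af <- af$af
  if (any(af < 0 | af > 1)) stop("allele frequencies must lie in [0, 1]")
  if (length(af) < min_sites)
    return(structure(list(grid = NULL, density = NULL, bandwidth = bandwidth,
                          n = length(af), insufficient = TRUE),
                     class = "af_density"))
  d <- stats::density(af, bw = bandwidth, n = grid_size, from = 0, to = 1)
  area <- trapezoid(d$x, d$y)
  structure(list(grid = d$x, density = d$y / area, bandwidth = bandwidth,
                 n = length(af), insufficient = FALSE),
            class = "af_density")
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' @export
print.af_density <- function(x, ...) {
  if (x$insufficient) {
    cat("<af_density> insufficient data (", x$n, " sites)\n", sep = "")
  } else {
    cat("<af_density> n = ", x$n, ", bandwidth ", x$bandwidth,
        ", grid ", length(x$grid), " points\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.af_density <- function(x, ...) {
  if (x$insufficient) stop("insufficient data; nothing to plot")
  graphics::plot(x$grid, x$density, type = "l", xlab = "allele frequency",
                 ylab = "density", ...)
  graphics::abline(v = detect_modes(x), lty = 3)
  invisible(x)
}

#' Detect modes of an allele-frequency density
#'
#' Local maxima of the density curve (boundary points included) retained
#' when their topographic prominence exceeds `prominence_fraction` times
#' the maximum density; equal-height maxima are all retained. Returned in
#' increasing AF order.
#'
#' @param dens An [estimate_af_density()] result (insufficient-data
#'   densities yield an empty mode set).
#' @param prominence_fraction Prominence threshold as a fraction of the
#'   density maximum (default 0.1).
#' @return Numeric vector of mode locations (grid points), increasing.
#' @export
detect_modes <- function(dens, prominence_fraction = 0.1) {
  stopifnot(inherits(dens, "af_density"))
  if (dens$insufficient) return(numeric(0))
  y <- dens$density
  x <- dens$grid
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  peak_idx <- integer(0)
  for (j in seq_len(k)) {
    left <- if (j == 1L) -Inf else r$values[j - 1L]
    right <- if (j == k) -Inf else r$values[j + 1L]
    if (r$values[j] > left && r$values[j] > right)
      peak_idx <- c(peak_idx, as.integer(floor((starts[j] + ends[j]) / 2)))
  }
  if (length(peak_idx) == 0L) return(numeric(0))
  prom <- vapply(peak_idx, function(i) peak_prominence(y, i), numeric(1))
  keep <- prom > prominence_fraction * max(y)
  sort(x[peak_idx[keep]])
}

# Topographic prominence of the peak at index i: height above the higher
# of the two key saddles (minima toward the nearest strictly higher
# ground, or toward the boundary).
peak_prominence <- function(y, i) {
  h <- y[i]
  side_min <- function(idx_seq) {
    m <- h
    for (j in idx_seq) {
      if (y[j] > h) return(m)
      if (y[j] < m) m <- y[j]
    }
    m
  }
  left <- if (i > 1L) side_min((i - 1L):1L) else h
  right <- if (i < length(y)) side_min((i + 1L):length(y)) else h
  h - max(if (i == 1L) -Inf else left, if (i == length(y)) -Inf else right,
          na.rm = TRUE)
}
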