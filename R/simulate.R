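# Generative models: allelic read counts at heterozygous sites under a
# karyotype state, and complete synthetic inputs (window counts, VCF, TPM
# tables) from a karyotype specification.

#' Simulate allelic read counts at heterozygous sites under a karyotype
#'
#' Minimal generative model for within-sample allele frequencies under
#' aneuploidy: per site, the total read depth is Poisson, the site's
#' allele orientation is chosen uniformly between the two orientations of
#' the state's signature (which haplotype role the alternative allele
#' plays), and alternative-allele reads are Binomial(depth, expected AF of
#' that orientation).
#'
#' `depth_mean` is the expected total depth per site for this state; when
#' `baseline_ploidy` is supplied it is instead the depth at baseline
#' ploidy and per-site depth scales by the state's coverage ratio.
#'
#' @param state A [mixture_state()].
#' @param depth_mean Expected reads per site (> 0).
#' @param n_sites Number of sites to draw (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @param min_reads_per_allele Discard sites with fewer reads than this
#'   from either allele (default 0: keep everything with depth > 0).
#' @param baseline_ploidy Optional; see above.
#' @return `af_observations` data frame (columns `chrom`, `pos`, `af`,
#'   `total_depth`) plus columns `ref_depth` and `alt_depth`.
#' @examples
#' af <- simulate_af_sample(mixture_state(5, 1), 50, 1000, seed = 1)
#' @export
simulate_af_sample <- function(state, depth_mean, n_sites, seed = NULL,
                               min_reads_per_allele = 0,
                               baseline_ploidy = NULL) {
  stopifnot(inherits(state, "mixture_state"))
  if (depth_mean <= 0) stop("'depth_mean' must be > 0")
  if (n_sites < 1) stop("'n_sites' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  factor <- if (is.null(baseline_ploidy)) 1
            else sum(state$f * state$n) / baseline_ploidy
  p <- expected_af(state)
  orient <- sample(c(TRUE, FALSE), n_sites, replace = TRUE)
  p_site <- ifelse(orient, p, 1 - p)
  depth <- stats::rpois(n_sites, depth_mean * factor)
  alt <- stats::rbinom(n_sites, depth, p_site)
  ref <- depth - alt
  keep <- depth > 0 & ref >= min_reads_per_allele & alt >= min_reads_per_allele
  out <- data.frame(chrom = rep(NA_character_, sum(keep)), pos = which(keep),
                    af = alt[keep] / depth[keep],
                    total_depth = depth[keep],
                    ref_depth = ref[keep], alt_depth = alt[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("af_observations", "data.frame")
  out
}

#' Specify a synthetic karyotype
#'
#' Configuration for the synthetic-data generator: a set of chromosomes
#' with lengths and per-chromosome karyotype states ([mixture_state()]),
#' plus sequencing parameters. The defaults describe a compact
#' five-chromosome genome (5 Mb each: 500 windows of 10 kbp and ~2,500
#' heterozygous sites per chromosome) spanning the canonical states —
#' disomic, trisomic, tetrasomic with 1:1 alleles, pentasomic with 1:4
#' alleles, and monosomic — large enough for stable density modes yet
#' fast to simulate.
#'
#' @param states Named list of [mixture_state()] per chromosome.
#' @param lengths Named numeric vector of chromosome lengths in bp.
#' @param baseline_ploidy Copy number at standardized coverage 1 (default
#'   2).
#' @param depth_mean Expected reads per full window at baseline ploidy
#'   (default 100).
#' @param window_size Window size in bp (default 10,000).
#' @param het_density Heterozygous sites per bp (default 5e-4).
#' @param site_depth_mean Expected total reads per site at baseline
#'   ploidy (default 50).
#' @param overdispersion Optional negative-binomial size parameter for
#'   window counts (NULL = Poisson).
#' @param seed Default seed used by the simulators (may be overridden per
#'   call).
#' @return Object of class `"karyotype_spec"`.
#' @export
karyotype_spec <- function(states = NULL, lengths = NULL,
                           baseline_ploidy = 2, depth_mean = 100,
                           window_size = 10000, het_density = 5e-4,
                           site_depth_mean = 50, overdispersion = NULL,
                           seed = NULL) {
  if (is.null(states))
    states <- list(`1` = mixture_state(2, 1), `2` = mixture_state(3, 1),
                   `3` = mixture_state(4, 2), `4` = mixture_state(5, 1),
                   `5` = mixture_state(1, 1))
  if (is.null(names(states)) || any(names(states) == ""))
    stop("'states' must be a named list (chromosome names)")
  if (!all(vapply(states, inherits, logical(1), "mixture_state")))
    stop("every element of 'states' must be a mixture_state")
  if (is.null(lengths))
    lengths <- stats::setNames(rep(5e6, length(states)), names(states))
  if (!setequal(names(lengths), names(states)))
    stop("'lengths' must name the same chromosomes as 'states'")
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  if (depth_mean <= 0 || het_density <= 0 || site_depth_mean <= 0)
    stop("'depth_mean', 'het_density' and 'site_depth_mean' must be positive")
  if (window_size < 1) stop("'window_size' must be >= 1")
  structure(list(states = states, lengths = lengths[names(states)],
                 baseline_ploidy = baseline_ploidy, depth_mean = depth_mean,
                 window_size = window_size, het_density = het_density,
                 site_depth_mean = site_depth_mean,
                 overdispersion = overdispersion, seed = seed),
            class = "karyotype_spec")
}

#' @export
print.karyotype_spec <- function(x, ...) {
  cat("<karyotype_spec> ", length(x$states), " chromosome(s), baseline ploidy ",
      x$baseline_ploidy, "\n", sep = "")
  for (ch in names(x$states))
    cat("  ", ch, " (", format(x$lengths[[ch]], big.mark = ","), " bp): ",
        format(x$states[[ch]]), "\n", sep = "")
  invisible(x)
}

coverage_ratio_of <- function(spec, chrom) {
  st <- spec$states[[chrom]]
  sum(st$f * st$n) / spec$baseline_ploidy
}

#' Simulate windowed read counts from a karyotype
#'
#' Each chromosome is tiled with `window_size` windows (the last window
#' may be shorter); the count of a window of width w is Poisson with mean
#' `depth_mean * coverage_ratio * w / window_size`, or negative binomial
#' with the spec's `overdispersion` size parameter.
#'
#' @param spec A [karyotype_spec()].
#' @param seed Seed (default: the spec's).
#' @return `window_counts` data frame (`chrom`, `start`, `end`, `count`).
#' @export
simulate_window_counts <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "karyotype_spec"))
  if (!is.null(seed)) set.seed(seed)
  per_chrom <- lapply(names(spec$states), function(ch) {
    len <- spec$lengths[[ch]]
    starts <- seq(0, len - 1, by = spec$window_size)
    ends <- pmin(starts + spec$window_size, len)
    mu <- spec$depth_mean * coverage_ratio_of(spec, ch) *
      (ends - starts) / spec$window_size
    count <- if (is.null(spec$overdispersion)) stats::rpois(length(mu), mu)
             else stats::rnbinom(length(mu), size = spec$overdispersion, mu = mu)
    data.frame(chrom = ch, start = starts, end = ends, count = count,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_chrom)
  row.names(out) <- NULL
  class(out) <- c("window_counts", "data.frame")
  out
}

#' Simulate a VCF of heterozygous sites with allelic depths
#'
#' Emits a VCF 4.2 with GT and AD FORMAT fields and the five hard-filter
#' INFO metrics. Heterozygous SNVs are placed uniformly at the spec's
#' `het_density`; allelic depths are drawn per chromosome state via
#' [simulate_af_sample()] (site depth scaled by the chromosome's coverage
#' ratio), with the allele orientation of each site shared across
#' samples, as for samples of a common cell line. INFO metrics are drawn
#' from ranges that pass the default hard filters (QD 10-30, FS 0-10, MQ
#' 55-60, rank sums -2..2); a fraction `fail_fraction` of records instead
#' gets QD = 1.0 and would be removed by [apply_hard_filters()].
#'
#' @param spec A [karyotype_spec()].
#' @param sample_names Sample column names (default `"sample1"`).
#' @param file Optional path; when given the VCF is written there.
#' @param seed Seed (default: the spec's).
#' @param fail_fraction Fraction of records given a failing QD (default
#'   0).
#' @return Character vector of VCF lines, invisibly when `file` is given.
#' @export
simulate_allelic_vcf <- function(spec, sample_names = "sample1", file = NULL,
                                 seed = spec$seed, fail_fraction = 0) {
  stopifnot(inherits(spec, "karyotype_spec"))
  if (fail_fraction < 0 || fail_fraction > 1)
    stop("'fail_fraction' must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  body <- character(0)
  for (ch in names(spec$states)) {
    len <- spec$lengths[[ch]]
    n_sites <- max(1L, round(len * spec$het_density))
    pos <- sort(sample.int(len, n_sites))
    st <- spec$states[[ch]]
    p <- expected_af(st)
    p_site <- ifelse(sample(c(TRUE, FALSE), n_sites, replace = TRUE),
                     p, 1 - p)
    depth_mu <- spec$site_depth_mean * coverage_ratio_of(spec, ch)
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    qd <- round(stats::runif(n_sites, 10, 30), 2)
    fail <- stats::runif(n_sites) < fail_fraction
    qd[fail] <- 1.0
    fs <- round(stats::runif(n_sites, 0, 10), 3)
    mq <- round(stats::runif(n_sites, 55, 60), 2)
    mqrs <- round(stats::runif(n_sites, -2, 2), 3)
    rprs <- round(stats::runif(n_sites, -2, 2), 3)
    gt_cols <- matrix("", n_sites, length(sample_names))
    for (j in seq_along(sample_names)) {
      depth <- stats::rpois(n_sites, depth_mu)
      altd <- stats::rbinom(n_sites, depth, p_site)
      gt_cols[, j] <- sprintf("0/1:%d,%d", depth - altd, altd)
    }
    info <- sprintf("QD=%.2f;FS=%.3f;MQ=%.2f;MQRankSum=%.3f;ReadPosRankSum=%.3f",
                    qd, fs, mq, mqrs, rprs)
    body <- c(body, paste(ch, pos, ".", ref, alt, "100", "PASS", info,
                          "GT:AD", apply(gt_cols, 1L, paste, collapse = "\t"),
                          sep = "\t"))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(spec$lengths),
            as.integer(spec$lengths)),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
  lines <- c(header, body)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Simulate a TPM expression table with dosage effect
#'
#' Per transcript, log10 TPM is Normal with mean `base_log10_tpm +
#' log10(coverage ratio)` of its chromosome — expression scales with gene
#' dosage — and standard deviation `base_log10_tpm_sd`. Estimated counts
#' are proportional to TPM.
#'
#' @param spec A [karyotype_spec()].
#' @param transcripts_per_chrom Transcripts per chromosome (default 200).
#' @param base_log10_tpm Baseline mean log10 TPM (default 1).
#' @param base_log10_tpm_sd SD of log10 TPM (default 0.5).
#' @param seed Seed (default: the spec's).
#' @return List with `tpm` (data frame `target_id`, `tpm`, `est_counts`)
#'   and `map` (data frame `target_id`, `chrom`).
#' @export
simulate_tpm_table <- function(spec, transcripts_per_chrom = 200,
                               base_log10_tpm = 1, base_log10_tpm_sd = 0.5,
                               seed = spec$seed) {
  stopifnot(inherits(spec, "karyotype_spec"))
  if (!is.null(seed)) set.seed(seed)
  per_chrom <- lapply(names(spec$states), function(ch) {
    ratio <- coverage_ratio_of(spec, ch)
    if (ratio <= 0) stop("chromosome ", ch, " has coverage ratio 0")
    lt <- stats::rnorm(transcripts_per_chrom,
                       base_log10_tpm + log10(ratio), base_log10_tpm_sd)
    data.frame(target_id = sprintf("tx_%s_%03d", ch,
                                   seq_len(transcripts_per_chrom)),
               chrom = ch, tpm = 10^lt, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_chrom)
  row.names(all) <- NULL
  list(tpm = data.frame(target_id = all$target_id, tpm = all$tpm,
                        est_counts = round(all$tpm * 10),
                        stringsAsFactors = FALSE),
       map = all[, c("target_id", "chrom")])
}
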