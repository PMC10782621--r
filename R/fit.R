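#' Infer per-chromosome copy-number states from coverage and allele
#' frequencies
#'
#' The package's main fitting function. It (1) standardizes windowed read
#' counts by the median over the baseline chromosomes, (2) summarizes
#' coverage per chromosome, (3) computes within-sample allele frequencies
#' at heterozygous sites, estimates their density and detects modes per
#' chromosome, and (4) classifies every chromosome against an enumerated
#' space of single-clone and clonal-mixture karyotype hypotheses,
#' reporting for each the ranked candidates and the degeneracy class of
#' hypotheses indistinguishable from the best fit.
#'
#' @param windows Window-count data frame (`chrom`, `start`, `end`,
#'   `count`).
#' @param sites Optional `allelic_sites` data frame from
#'   [read_allelic_sites()]; without it, classification rests on coverage
#'   alone.
#' @param sample Sample whose allele frequencies are analysed (default:
#'   first sample in `sites`).
#' @param baseline_chroms Chromosomes assumed to carry the most common
#'   copy number, used for median standardization.
#' @param baseline_ploidy Copy number at standardized coverage 1
#'   (default 2).
#' @param policy Heterozygous-site selection policy, `"self"` or
#'   `"either"` (see [select_sites_genomic()]); `"either"` considers all
#'   samples in `sites`.
#' @param candidates Hypothesis space (default:
#'   `enumerate_candidates(max_copies, if (include_mixtures) 2 else 1)`).
#' @param max_copies,include_mixtures Control the default hypothesis
#'   space.
#' @param bandwidth,grid_size,min_sites,prominence_fraction Density and
#'   mode-detection settings (see [estimate_af_density()],
#'   [detect_modes()]).
#' @param w_cov,w_af,lambda,tol,fixed_threshold Classification settings
#'   (see [classify_chromosome()]).
#' @param chrom_order Optional display order of chromosomes.
#' @return Object of class `"karyotype_fit"` with components `coverage`
#'   (per-chromosome summary), `calls` (list of `chromosome_call`),
#'   `densities` (per-chromosome `af_density`), `baseline_median`,
#'   and the call. Methods: `print`, `summary`, `plot`, `coef`,
#'   `as.data.frame`.
#' @examples
#' spec <- karyotype_spec(seed = 1)
#' w <- simulate_window_counts(spec)
#' fit <- infer_karyotype(w, baseline_chroms = "1")
#' coef(fit)
#' @export
infer_karyotype <- function(windows, sites = NULL, sample = NULL,
                            baseline_chroms, baseline_ploidy = 2,
                            policy = c("self", "either"),
                            candidates = NULL, max_copies = 6,
                            include_mixtures = TRUE, bandwidth = 0.02,
                            grid_size = 512, min_sites = 200,
                            prominence_fraction = 0.1, w_cov = 1, w_af = 1,
                            lambda = 0.25, tol = 1e-3,
                            fixed_threshold = 0.6, chrom_order = NULL) {
  policy <- match.arg(policy)
  sw <- standardize_coverage(windows, baseline_chroms)
  cov <- summarize_chromosomes(sw, chrom_order)
  if (is.null(candidates))
    candidates <- enumerate_candidates(max_copies,
                                       if (include_mixtures) 2 else 1)
  densities <- list()
  modes <- list()
  fixed <- list()
  if (!is.null(sites)) {
    all_samples <- unique(as.data.frame(sites)$sample)
    if (is.null(sample)) sample <- all_samples[1L]
    sel <- select_sites_genomic(sites,
                                samples = if (policy == "either") all_samples
                                          else sample,
                                policy = policy)[[sample]]
    af <- compute_af(sel)
    for (ch in cov$chrom) {
      af_ch <- af[!is.na(af$chrom) & af$chrom == ch, , drop = FALSE]
      densities[[ch]] <- estimate_af_density(af_ch, bandwidth = bandwidth,
                                             grid_size = grid_size,
                                             min_sites = min_sites)
      modes[[ch]] <- detect_modes(densities[[ch]], prominence_fraction)
      fixed[[ch]] <- fixed_allele_fraction(af_ch)
    }
  }
  calls <- lapply(cov$chrom, function(ch) {
    classify_chromosome(
      observed_ratio = cov$mean_ratio[cov$chrom == ch],
      observed_modes = if (is.null(modes[[ch]])) numeric(0) else modes[[ch]],
      fixed_fraction = if (is.null(fixed[[ch]]) || is.na(fixed[[ch]])) 0
                       else fixed[[ch]],
      candidates = candidates, baseline_ploidy = baseline_ploidy,
      w_cov = w_cov, w_af = w_af, lambda = lambda, tol = tol,
      fixed_threshold = fixed_threshold, chrom = ch)
  })
  names(calls) <- cov$chrom
  structure(list(coverage = cov, calls = calls, densities = densities,
                 baseline_median = attr(sw, "baseline_median"),
                 baseline_ploidy = baseline_ploidy, sample = sample,
                 standardized = sw, call = match.call()),
            class = "karyotype_fit")
}

#' @export
as.data.frame.karyotype_fit <- function(x, ...) {
  data.frame(
    chrom = x$coverage$chrom,
    n_windows = x$coverage$n_windows,
    mean_ratio = x$coverage$mean_ratio,
    se = x$coverage$se,
    modes = vapply(x$calls, function(cl)
      paste(format(round(cl$observed_modes, 3)), collapse = ","),
      character(1)),
    fixed_fraction = vapply(x$calls, function(cl) cl$fixed_fraction,
                            numeric(1)),
    best_state = vapply(x$calls, function(cl) format(cl$best), character(1)),
    score = vapply(x$calls, function(cl) cl$scores[1L], numeric(1)),
    n_degenerate = vapply(x$calls, function(cl) length(cl$degeneracy),
                          integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.karyotype_fit <- function(x, digits = 3, ...) {
  cat("Karyotype inference (baseline ploidy ", x$baseline_ploidy,
      ", baseline median ", format(x$baseline_median), " reads/window",
      if (!is.null(x$sample)) paste0(", sample ", x$sample), ")\n\n", sep = "")
  df <- as.data.frame(x)
  df$mean_ratio <- round(df$mean_ratio, digits)
  df$se <- signif(df$se, 2)
  df$fixed_fraction <- round(df$fixed_fraction, digits)
  df$score <- signif(df$score, 2)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.karyotype_fit <- function(object, ...) {
  structure(object, class = c("summary.karyotype_fit", "karyotype_fit"))
}

#' @export
print.summary.karyotype_fit <- function(x, ...) {
  class(x) <- "karyotype_fit"
  print(x)
  cat("\nDegeneracy classes (hypotheses indistinguishable from the best fit):\n")
  for (ch in names(x$calls)) {
    cl <- x$calls[[ch]]
    cat("  ", ch, ": ",
        paste(vapply(cl$degeneracy, format, character(1)), collapse = " ; "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.karyotype_fit <- function(object, ...) {
  vapply(object$calls, function(cl) format(cl$best), character(1))
}

#' Plot a karyotype fit
#'
#' Top panel: per-chromosome mean standardized coverage with +/- 2 SE
#' error bars and horizontal expected-level lines for integer copy
#' numbers. Bottom panel (when allele frequencies were analysed):
#' per-chromosome AF density curves with detected modes.
#'
#' @param x A `karyotype_fit`.
#' @param copy_numbers Copy numbers for the reference lines (default
#'   0:5).
#' @param ... Passed to the coverage panel's `plot`.
#' @export
plot.karyotype_fit <- function(x, copy_numbers = 0:5, ...) {
  has_af <- length(x$densities) > 0 &&
    any(!vapply(x$densities, function(d) d$insufficient, logical(1)))
  old <- graphics::par(mfrow = c(if (has_af) 2 else 1, 1),
                       mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  cov <- x$coverage
  k <- seq_len(nrow(cov))
  graphics::plot(k, cov$mean_ratio, ylim = range(0, cov$mean_ratio + 2 * cov$se,
                                                 max(copy_numbers) / x$baseline_ploidy),
                 xaxt = "n", xlab = "chromosome",
                 ylab = "standardized coverage", pch = 19, ...)
  graphics::axis(1, at = k, labels = cov$chrom)
  graphics::arrows(k, cov$mean_ratio - 2 * cov$se, k,
                   cov$mean_ratio + 2 * cov$se,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = expected_coverage_levels(x$baseline_ploidy,
                                                copy_numbers),
                   col = "grey", lty = 2)
  if (has_af) {
    ok <- names(x$densities)[!vapply(x$densities, function(d) d$insufficient,
                                     logical(1))]
    ymax <- max(vapply(x$densities[ok], function(d) max(d$density),
                       numeric(1)))
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, ymax),
                   xlab = "within-sample allele frequency", ylab = "density")
    for (i in seq_along(ok)) {
      d <- x$densities[[ok[i]]]
      graphics::lines(d$grid, d$density, col = i)
      graphics::abline(v = x$calls[[ok[i]]]$observed_modes, col = i, lty = 3)
    }
    graphics::legend("topright", legend = ok, col = seq_along(ok), lty = 1,
                     cex = 0.7, bty = "n")
  }
  invisible(x)
}
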