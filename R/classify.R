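# Joint coverage + AF-mode classification of one chromosome against an
# enumerated hypothesis space, with degeneracy-aware reporting.

# Minimal cost of partially matching observed modes to expected modes:
# each matched pair costs the squared difference, each unmatched mode on
# either side costs `lambda`. Exact search; mode sets are tiny.
mode_match_cost <- function(obs, exp, lambda) {
  if (length(obs) == 0L) return(lambda * length(exp))
  best <- lambda + mode_match_cost(obs[-1L], exp, lambda)  # leave obs[1] unmatched
  for (j in seq_along(exp)) {
    cost <- (obs[1L] - exp[j])^2 + mode_match_cost(obs[-1L], exp[-j], lambda)
    if (cost < best) best <- cost
  }
  best
}

#' Classify one chromosome's copy-number state
#'
#' Scores every candidate karyotype state against the chromosome's
#' observed standardized coverage ratio and detected allele-frequency
#' modes:
#' \deqn{score = w_{cov} (r_{obs} - r_{exp})^2 + w_{af} C_{modes}}
#' where the mode cost is the optimal partial assignment of observed to
#' expected modes (squared differences, penalty `lambda` per unmatched
#' mode on either side). Candidates are returned ranked by score; the
#' degeneracy class collects every candidate within `tol` of the best
#' score — clonal mixtures that mimic a single aneuploid clone land in the
#' same class rather than being arbitrarily tie-broken.
#'
#' Chromosomes where most sites carry a fixed allele (AF near 0 or 1,
#' e.g. monosomy or uniparental disomy) defeat KDE mode reading; when
#' `fixed_fraction` exceeds `fixed_threshold` the candidate space is
#' restricted to states whose mode set touches the boundary (a mode
#' <= 0.05 or >= 0.95).
#'
#' @param observed_ratio Standardized coverage ratio of the chromosome.
#' @param observed_modes Numeric vector of detected AF modes (possibly
#'   empty).
#' @param fixed_fraction Fraction of sites with AF <= 0.05 or >= 0.95.
#' @param candidates List of [mixture_state()] hypotheses, e.g. from
#'   [enumerate_candidates()].
#' @param baseline_ploidy Copy number at standardized coverage 1.0.
#' @param w_cov,w_af Weights of the coverage and mode terms (default 1, 1).
#' @param lambda Penalty per unmatched mode (default 0.25).
#' @param tol Score tolerance defining the degeneracy class (default 1e-3).
#' @param fixed_threshold Fixed-allele fraction above which only
#'   boundary-mode candidates are considered (default 0.6).
#' @param chrom Optional chromosome label carried into the result.
#' @return An object of class `"chromosome_call"`: list with the observed
#'   evidence, `candidates` (ranked), `scores`, `best` (state), and
#'   `degeneracy` (list of states indistinguishable from the best at
#'   `tol`).
#' @examples
#' cand <- enumerate_candidates(5)
#' call <- classify_chromosome(1.5, c(1/3, 2/3), 0, cand)
#' format(call$best)  # "3:1"
#' @export
classify_chromosome <- function(observed_ratio, observed_modes,
                                fixed_fraction = 0, candidates,
                                baseline_ploidy = 2, w_cov = 1, w_af = 1,
                                lambda = 0.25, tol = 1e-3,
                                fixed_threshold = 0.6, chrom = NA_character_) {
  if (!is.numeric(observed_ratio) || observed_ratio < 0)
    stop("'observed_ratio' must be >= 0")
  if (length(candidates) == 0L) stop("'candidates' must be non-empty")
  sigs <- lapply(candidates, signature_of, baseline_ploidy = baseline_ploidy)
  if (!is.na(fixed_fraction) && fixed_fraction > fixed_threshold) {
    keep <- vapply(sigs, function(s)
      any(s$af_modes <= 0.05 | s$af_modes >= 0.95), logical(1))
    if (any(keep)) {
      candidates <- candidates[keep]
      sigs <- sigs[keep]
    }
  }
  scores <- vapply(seq_along(sigs), function(i) {
    s <- sigs[[i]]
    w_cov * (observed_ratio - s$coverage_ratio)^2 +
      w_af * mode_match_cost(observed_modes, s$af_modes, lambda)
  }, numeric(1))
  if (!any(is.finite(scores))) stop("no candidate scored finitely")
  o <- order(scores)
  candidates <- candidates[o]
  scores <- scores[o]
  degeneracy <- candidates[scores <= scores[1L] + tol]
  structure(list(chrom = chrom,
                 observed_ratio = observed_ratio,
                 observed_modes = observed_modes,
                 fixed_fraction = fixed_fraction,
                 candidates = candidates,
                 scores = scores,
                 best = candidates[[1L]],
                 degeneracy = degeneracy),
            class = "chromosome_call")
}

#' @export
print.chromosome_call <- function(x, ...) {
  cat("<chromosome_call>", if (!is.na(x$chrom)) paste0(" chr ", x$chrom), "\n",
      sep = "")
  cat("  observed ratio ", format(x$observed_ratio, digits = 4),
      ", modes {", paste(format(x$observed_modes, digits = 3), collapse = ", "),
      "}, fixed fraction ", format(x$fixed_fraction, digits = 3), "\n", sep = "")
  cat("  best state ", format(x$best), " (score ",
      format(x$scores[1L], digits = 3), ")\n", sep = "")
  cat("  degeneracy class: ",
      paste(vapply(x$degeneracy, format, character(1)), collapse = " ; "),
      "\n", sep = "")
  invisible(x)
}
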