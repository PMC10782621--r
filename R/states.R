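#' Karyotype states: clones and clonal mixtures
#'
#' A clone state describes the karyotype of one cell subpopulation at one
#' chromosome: its total copy number `n` and the number of copies `a`
#' carrying the alternative allele at a heterozygous site (the "allelic
#' relationship" a : n - a). A mixture state is a set of clone states with
#' population fractions, modelling clonal heterogeneity within a cultured
#' cell line. A single-clone mixture is canonically identical to its clone.
#'
#' `mixture_state()` canonicalizes its input: identical clones are merged
#' (fractions summed) and clones are ordered by (n, a), so two mixtures
#' that differ only in clone order or in duplicated clones compare equal.
#'
#' @param n Integer vector of total copy numbers, one per clone (>= 0).
#' @param a Integer vector of alternative-allele copy counts, `0 <= a <= n`.
#' @param f Numeric vector of clone fractions, positive and summing to 1.
#'   Defaults to equal fractions.
#' @return An object of class `"mixture_state"`: a list with integer
#'   vectors `n`, `a` and numeric vector `f`.
#' @examples
#' mixture_state(3, 1)                      # trisomic, 1:2 allelic relationship
#' mixture_state(c(2, 1), c(1, 1))          # 1:1 mix of diploid and monosomic
#' @export
mixture_state <- function(n, a, f = NULL) {
  if (length(n) == 0L || length(n) != length(a))
    stop("'n' and 'a' must be non-empty vectors of equal length")
  if (any(n != round(n)) || any(a != round(a)))
    stop("copy numbers must be integers")
  n <- as.integer(n)
  a <- as.integer(a)
  if (any(n < 0L)) stop("total copy number 'n' must be >= 0")
  if (any(a < 0L) || any(a > n)) stop("'a' must satisfy 0 <= a <= n")
  if (is.null(f)) f <- rep(1 / length(n), length(n))
  if (length(f) != length(n)) stop("'f' must match the number of clones")
  if (any(f <= 0)) stop("clone fractions must be positive")
  if (abs(sum(f) - 1) > 1e-9) stop("clone fractions must sum to 1")
  # merge identical clones, then order canonically
  key <- paste(n, a, sep = ":")
  if (anyDuplicated(key)) {
    f <- as.numeric(tapply(f, key, sum)[unique(key)])
    keep <- !duplicated(key)
    n <- n[keep]; a <- a[keep]
  }
  o <- order(n, a)
  structure(list(n = n[o], a = a[o], f = f[o]), class = "mixture_state")
}

#' @export
format.mixture_state <- function(x, ...) {
  if (length(x$n) == 1L) return(paste0(x$n, ":", x$a))
  paste(sprintf("%.3g*(%d:%d)", x$f, x$n, x$a), collapse = " + ")
}

#' @export
print.mixture_state <- function(x, ...) {
  cat("<mixture_state> ", format(x), "\n", sep = "")
  invisible(x)
}

state_key <- function(state) {
  paste(sprintf("%d:%d:%.10g", state$n, state$a, state$f), collapse = "|")
}

#' Expected within-sample allele frequency of a mixture state
#'
#' At a heterozygous site, a clone with total copy number n and a copies of
#' the alternative allele contributes a alternative-allele templates out of
#' n. Averaging over clones weighted by copy number gives the expected
#' alternative-allele read fraction
#' \deqn{E[AF] = \sum_j f_j a_j / \sum_j f_j n_j.}
#'
#' @param state A [mixture_state()].
#' @return Expected allele frequency in \[0, 1\].
#' @examples
#' expected_af(mixture_state(3, 1))                 # 1/3
#' expected_af(mixture_state(c(2, 1), c(1, 1)))     # 2/3: mimics trisomy
#' @export
expected_af <- function(state) {
  stopifnot(inherits(state, "mixture_state"))
  denom <- sum(state$f * state$n)
  if (denom <= 0) stop("all clones have copy number 0: allele frequency undefined")
  sum(state$f * state$a) / denom
}

#' Coverage-ratio and allele-frequency-mode signature of a karyotype state
#'
#' The observable signature of a karyotype hypothesis: its standardized
#' coverage ratio, `sum(f * n) / baseline_ploidy`, and the set of allele
#' frequency modes expected at heterozygous sites. Because either allele of
#' a heterozygous site can play the amplified role, the mode set contains
#' both orientations: the expected AF with alternative-copy counts `a` and
#' with the complemented counts `n - a`, deduplicated (a 1:1 allelic
#' relationship gives the single mode 0.5).
#'
#' @param state A [mixture_state()].
#' @param baseline_ploidy Copy number corresponding to standardized
#'   coverage 1.0 (default 2).
#' @return A list of class `"ploidy_signature"` with `coverage_ratio` and
#'   sorted numeric `af_modes`.
#' @examples
#' signature_of(mixture_state(5, 1))  # ratio 2.5, modes 0.2 and 0.8
#' signature_of(mixture_state(4, 2))  # ratio 2.0, single mode 0.5
#' @export
signature_of <- function(state, baseline_ploidy = 2) {
  stopifnot(inherits(state, "mixture_state"))
  if (!is.numeric(baseline_ploidy) || baseline_ploidy < 1)
    stop("'baseline_ploidy' must be >= 1")
  p <- expected_af(state)
  q <- 1 - p  # complemented orientation a -> n - a
  modes <- if (abs(p - q) < 1e-12) p else sort(c(p, q))
  structure(list(coverage_ratio = sum(state$f * state$n) / baseline_ploidy,
                 af_modes = modes, state = state),
            class = "ploidy_signature")
}

#' @export
print.ploidy_signature <- function(x, ...) {
  cat("<ploidy_signature> ratio ", format(x$coverage_ratio, digits = 4),
      ", AF modes {", paste(format(x$af_modes, digits = 4), collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

#' Are two karyotype signatures indistinguishable?
#'
#' Distinct clonal mixtures can produce identical observables: a 1:1
#' mixture of diploid and monosomic cells has the same AF modes as a fully
#' trisomic population, and a 1:1 mixture of diploid and trisomic cells the
#' same modes as a pentasomic one. This predicate declares two signatures
#' equal when their mode sets have the same size and match pairwise within
#' `tol_modes`, and (optionally) their coverage ratios agree within
#' `tol_ratio`.
#'
#' @param s1,s2 Signatures from [signature_of()].
#' @param tol_modes Mode-position tolerance (default 1e-9, i.e. exact up to
#'   floating-point arithmetic).
#' @param compare_coverage Also require coverage ratios to match?
#' @param tol_ratio Coverage-ratio tolerance when `compare_coverage`.
#' @return Logical scalar.
#' @export
signatures_equal <- function(s1, s2, tol_modes = 1e-9,
                             compare_coverage = FALSE, tol_ratio = 0.05) {
  stopifnot(inherits(s1, "ploidy_signature"), inherits(s2, "ploidy_signature"))
  if (tol_modes <= 0 || tol_ratio <= 0) stop("tolerances must be positive")
  m1 <- sort(s1$af_modes); m2 <- sort(s2$af_modes)
  if (length(m1) != length(m2)) return(FALSE)
  if (any(abs(m1 - m2) > tol_modes)) return(FALSE)
  if (compare_coverage &&
      abs(s1$coverage_ratio - s2$coverage_ratio) > tol_ratio) return(FALSE)
  TRUE
}

#' Enumerate candidate karyotype states
#'
#' Builds the hypothesis space scanned by [classify_chromosome()]: every
#' single clone with total copy number `1..max_copies` and every
#' alternative-copy count `0..n`, plus (when `max_clones = 2`) every
#' two-clone mixture of distinct single-clone states with clone fractions
#' drawn from `fraction_grid`. States are canonically deduplicated (clone
#' order and fraction symmetry do not create duplicates).
#'
#' @param max_copies Largest total copy number per clone (default 6).
#' @param max_clones 1 (single clones only) or 2.
#' @param fraction_grid Fractions for the first clone of two-clone
#'   mixtures, in (0, 1); default 0.5 (1:1 mixtures only).
#' @return List of [mixture_state()] objects.
#' @examples
#' length(enumerate_candidates(3, max_clones = 1))  # 9 single-clone states
#' @export
enumerate_candidates <- function(max_copies = 6, max_clones = 2,
                                 fraction_grid = 0.5) {
  if (max_copies < 1) stop("'max_copies' must be >= 1")
  if (!max_clones %in% c(1, 2)) stop("'max_clones' must be 1 or 2")
  if (any(fraction_grid <= 0 | fraction_grid >= 1))
    stop("'fraction_grid' must lie strictly inside (0, 1)")
  singles <- list()
  for (n in seq_len(max_copies))
    for (a in 0:n)
      singles[[length(singles) + 1L]] <- mixture_state(n, a)
  if (max_clones == 1L) return(singles)
  out <- singles
  seen <- vapply(singles, state_key, character(1))
  ns <- length(singles)
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    ci <- singles[[i]]; cj <- singles[[j]]
    for (fr in unique(c(fraction_grid, 1 - fraction_grid))) {
      st <- mixture_state(c(ci$n, cj$n), c(ci$a, cj$a), c(fr, 1 - fr))
      k <- state_key(st)
      if (!k %in% seen) {
        seen <- c(seen, k)
        out[[length(out) + 1L]] <- st
      }
    }
  }
  out
}

#' Probability of repairing every copy at an edited site
#'
#' In genome editing, a phenotype from homology-directed repair (HDR)
#' generally requires concurrent repair of all allele copies. With
#' independent per-copy efficiency `e`, the all-copy repair rate at a site
#' of copy number `n` is `e^n` — so aneuploidy directly depresses editing
#' efficiency: at 20% per-copy efficiency, 4% of disomic sites but only
#' 0.8% of trisomic sites are fully repaired.
#'
#' @param per_copy_efficiency HDR efficiency per copy, in \[0, 1\].
#' @param copy_number Integer copy number >= 1.
#' @return All-copy repair probability in \[0, 1\].
#' @examples
#' hdr_all_copy_rate(0.2, 2)  # 0.04
#' hdr_all_copy_rate(0.2, 3)  # 0.008
#' @export
hdr_all_copy_rate <- function(per_copy_efficiency, copy_number) {
  if (!is.numeric(per_copy_efficiency) ||
      any(per_copy_efficiency < 0 | per_copy_efficiency > 1))
    stop("'per_copy_efficiency' must lie in [0, 1]")
  if (any(copy_number < 1) || any(copy_number != round(copy_number)))
    stop("'copy_number' must be an integer >= 1")
  per_copy_efficiency ^ copy_number
}
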