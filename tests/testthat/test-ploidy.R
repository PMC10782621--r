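test_that("mixture states validate and canonicalize", {
  expect_error(mixture_state(2, 3), "0 <= a <= n")
  expect_error(mixture_state(-1, 0), ">= 0")
  expect_error(mixture_state(c(2, 1), c(1, 1), c(0.6, 0.6)), "sum to 1")
  expect_error(mixture_state(2.5, 1), "integers")
  # clone order does not matter
  s1 <- mixture_state(c(2, 1), c(1, 1), c(0.5, 0.5))
  s2 <- mixture_state(c(1, 2), c(1, 1), c(0.5, 0.5))
  expect_identical(s1, s2)
  # duplicated clones merge
  s3 <- mixture_state(c(2, 2), c(1, 1), c(0.5, 0.5))
  expect_identical(s3, mixture_state(2, 1))
  expect_equal(format(mixture_state(5, 1)), "5:1")
})

test_that("expected AF is the copy-weighted alternative-allele fraction", {
  expect_equal(expected_af(mixture_state(3, 1)), 1 / 3)
  expect_equal(expected_af(mixture_state(5, 1)), 0.2)
  expect_equal(expected_af(mixture_state(4, 2)), 0.5)
  expect_equal(expected_af(mixture_state(2, 1)), 0.5)
  # 1:1 mix of diploid het and monosomic alt: (0.5 + 0.5) / (1 + 0.5)
  expect_equal(expected_af(mixture_state(c(2, 1), c(1, 1))), 2 / 3)
  expect_error(expected_af(mixture_state(0, 0)), "copy number 0")
})

test_that("expected AF of complemented states sums to one", {
  set.seed(21)
  for (i in 1:50) {
    k <- sample(1:3, 1)
    n <- sample(1:6, k, replace = TRUE)
    a <- vapply(n, function(ni) sample(0:ni, 1), integer(1))
    f <- as.numeric(rmultinom(1, 20, rep(1, k))) + 1
    f <- f / sum(f)
    st <- mixture_state(n, a, f)
    co <- mixture_state(n, n - a, f)
    expect_equal(expected_af(st) + expected_af(co), 1)
  }
})

test_that("signatures carry coverage ratio and both allele orientations", {
  s <- signature_of(mixture_state(2, 1), 2)
  expect_equal(s$coverage_ratio, 1)
  expect_equal(s$af_modes, 0.5)
  s2 <- signature_of(mixture_state(4, 2), 2)
  expect_equal(s2$coverage_ratio, 2)
  expect_equal(s2$af_modes, 0.5)
  s3 <- signature_of(mixture_state(5, 1), 3)
  expect_equal(s3$coverage_ratio, 5 / 3)
  expect_equal(s3$af_modes, c(0.2, 0.8))
  # single-clone consistency: a 1-clone mixture equals its clone
  expect_equal(signature_of(mixture_state(c(3, 3), c(1, 1), c(0.4, 0.6)))[1:2],
               signature_of(mixture_state(3, 1))[1:2])
})

test_that("clonal-mixture degeneracies match single clones exactly", {
  # 1:1 diploid + monosomic vs trisomic, in exact rational arithmetic
  expect_identical(oracle_mode_fracs(c(2, 1), c(1, 1), c(1, 1)),
                   oracle_mode_fracs(3, 1))
  # 1:1 diploid(hom-ref) + trisomic vs pentasomic
  expect_identical(oracle_mode_fracs(c(2, 3), c(0, 1), c(1, 1)),
                   oracle_mode_fracs(5, 1))
  # and the implementation agrees with the oracle's fractions
  tri <- signature_of(mixture_state(c(2, 1), c(1, 1)))
  expect_true(signatures_equal(tri, signature_of(mixture_state(3, 1))))
  pent <- signature_of(mixture_state(c(2, 3), c(0, 1)))
  expect_true(signatures_equal(pent, signature_of(mixture_state(5, 1))))
  # coverage separates them when requested
  expect_false(signatures_equal(tri, signature_of(mixture_state(3, 1)),
                                compare_coverage = TRUE, tol_ratio = 0.05))
  # plainly different states are not equal
  expect_false(signatures_equal(signature_of(mixture_state(2, 1)),
                                signature_of(mixture_state(3, 1))))
})

test_that("candidate enumeration covers the hypothesis space without duplicates", {
  singles <- enumerate_candidates(3, max_clones = 1)
  expect_length(singles, 9)
  keys <- vapply(singles, format, character(1))
  expect_false(anyDuplicated(keys) > 0)
  cand <- enumerate_candidates(2, max_clones = 2, fraction_grid = 0.5)
  keys2 <- vapply(cand, format, character(1))
  expect_false(anyDuplicated(keys2) > 0)
  # includes the 1:1 diploid + monosomic mixture
  expect_true(class_contains(cand, mixture_state(c(2, 1), c(1, 1))))
  # 5 singles + choose(5, 2) 1:1 pairs
  expect_length(cand, 5 + 10)
  expect_error(enumerate_candidates(0), ">= 1")
  expect_error(enumerate_candidates(2, max_clones = 3), "1 or 2")
  expect_error(enumerate_candidates(2, fraction_grid = 1), "inside")
})

test_that("simulated AF samples are reproducible and recover their modes", {
  a1 <- simulate_af_sample(mixture_state(5, 1), 50, 2000, seed = 8)
  a2 <- simulate_af_sample(mixture_state(5, 1), 50, 2000, seed = 8)
  expect_identical(a1, a2)
  m <- detect_modes(estimate_af_density(a1))
  expect_length(m, 2)
  expect_lt(max(abs(m - c(0.2, 0.8))), 0.03)
  d <- simulate_af_sample(mixture_state(2, 1), 30, 5000, seed = 8)
  m2 <- detect_modes(estimate_af_density(d))
  expect_length(m2, 1)
  expect_lt(abs(m2 - 0.5), 0.02)
  # depth scaling by coverage ratio when a baseline is given
  tri <- simulate_af_sample(mixture_state(3, 1), 30, 4000, seed = 8,
                            baseline_ploidy = 2)
  expect_lt(abs(mean(tri$total_depth) - 45), 3 * sd(tri$total_depth) / sqrt(4000) + 1)
  # read-support filter discards boundary sites
  mono <- simulate_af_sample(mixture_state(1, 1), 30, 500, seed = 8,
                             min_reads_per_allele = 1)
  expect_equal(nrow(mono), 0)
  expect_error(simulate_af_sample(mixture_state(2, 1), 0, 10), "> 0")
})

test_that("classification ranks the generating state first and reports degeneracy", {
  cand <- enumerate_candidates(6, max_clones = 2)
  # trisomic pattern: modes {1/3, 2/3} at ratio 1.5; the two allele
  # orientations 3:1 and 3:2 share one signature, so both sit in the class
  cl <- classify_chromosome(1.5, c(1 / 3, 2 / 3), 0, cand)
  expect_true(class_contains(cl$degeneracy, mixture_state(3, 1)))
  expect_true(class_contains(cl$degeneracy, mixture_state(3, 2)))
  # under mode-only scoring the clonal mimic joins the degeneracy class
  cl_af <- classify_chromosome(1.5, c(1 / 3, 2 / 3), 0, cand, w_cov = 0)
  expect_true(class_contains(cl_af$degeneracy,
                             mixture_state(c(2, 1), c(1, 1))))
  # diploid null case
  cl2 <- classify_chromosome(1.0, 0.5, 0, cand)
  expect_identical(cl2$best, mixture_state(2, 1))
  # pentasomic on a triploid baseline (orientation twin 5:4 is degenerate)
  cl3 <- classify_chromosome(5 / 3, c(0.2, 0.8), 0, cand, baseline_ploidy = 3)
  expect_true(class_contains(cl3$degeneracy, mixture_state(5, 1)))
  # high fixed fraction restricts to boundary-mode states
  cl4 <- classify_chromosome(0.5, numeric(0), 1, cand)
  expect_true(all(vapply(cl4$degeneracy, function(s) {
    m <- signature_of(s)$af_modes
    any(m <= 0.05 | m >= 0.95)
  }, logical(1))))
  expect_true(class_contains(cl4$degeneracy, mixture_state(1, 1)))
  expect_error(classify_chromosome(-1, 0.5, 0, cand), ">= 0")
  expect_error(classify_chromosome(1, 0.5, 0, list()), "non-empty")
})

test_that("classification recovers every simulated single-clone state", {
  cand <- enumerate_candidates(6, max_clones = 2)
  for (n in 1:5) for (a in 0:n) {
    st <- mixture_state(n, a)
    af <- simulate_af_sample(st, 50, 5000, seed = 100 + 10 * n + a)
    modes <- detect_modes(estimate_af_density(af))
    cl <- classify_chromosome(n / 2, modes, fixed_allele_fraction(af),
                              cand, baseline_ploidy = 2)
    expect_true(class_contains(cl$degeneracy, st),
                label = sprintf("degeneracy class contains %d:%d", n, a))
  }
})

test_that("all-copy HDR rate is e^n and decreasing in copy number", {
  expect_equal(hdr_all_copy_rate(0.2, 2), 0.04)
  expect_equal(hdr_all_copy_rate(0.2, 3), 0.008)
  expect_equal(hdr_all_copy_rate(1, 7), 1)
  expect_equal(hdr_all_copy_rate(0, 2), 0)
  rates <- hdr_all_copy_rate(0.35, 1:6)
  expect_true(all(diff(rates) < 0))
  expect_error(hdr_all_copy_rate(1.2, 2), "\\[0, 1\\]")
  expect_error(hdr_all_copy_rate(0.2, 0), ">= 1")
})
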