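test_that("genomic site selection honours the either/self policies", {
  a <- make_sites(pos = 1:3, sample = "A",
                  genotype = c("REF/ALT", "REF/REF", "REF/REF"),
                  ref_depth = c(10, 20, 20), alt_depth = c(10, 1, 0))
  b <- make_sites(pos = 1:3, sample = "B",
                  genotype = c("REF/REF", "REF/ALT", "REF/REF"),
                  ref_depth = c(25, 10, 20), alt_depth = c(0, 12, 0))
  sites <- rbind(a, b)
  either <- select_sites_genomic(sites, c("A", "B"), "either")
  # site 1 het in A only, site 2 het in B only: both enter both samples
  expect_equal(sort(either$A$pos), c(1, 2))
  expect_equal(sort(either$B$pos), c(1, 2))
  # B's AF at site 1 is near 0 (loss-informative, still included)
  expect_equal(compute_af(either$B[either$B$pos == 1, ])$af, 0)
  self <- select_sites_genomic(sites, c("A", "B"), "self")
  expect_equal(self$A$pos, 1)
  expect_equal(self$B$pos, 2)
  # hom-ref in both under "either" stays excluded (site 3)
  expect_false(3 %in% either$A$pos)
  expect_error(select_sites_genomic(sites, "C"), "not present")
})

test_that("either-policy counts match construction on simulated joint sites", {
  # 40 sites het in A only, 30 het in both, 30 het in neither
  gt_a <- c(rep("REF/ALT", 40), rep("REF/ALT", 30), rep("REF/REF", 30))
  gt_b <- c(rep("REF/REF", 40), rep("REF/ALT", 30), rep("REF/REF", 30))
  sites <- rbind(make_sites(pos = 1:100, sample = "A", genotype = gt_a),
                 make_sites(pos = 1:100, sample = "B", genotype = gt_b))
  sel <- select_sites_genomic(sites, c("A", "B"), "either")
  expect_equal(nrow(sel$A), 70)
  expect_equal(nrow(sel$B), 70)
})

test_that("RNA-seq selection requires both alleles at depth", {
  d <- make_sites(pos = 1:4, ref_depth = c(5, 4, 100, 7),
                  alt_depth = c(5, 6, 0, 9))
  kept <- select_sites_rnaseq(d)
  expect_equal(kept$pos, c(1, 4))
  expect_equal(nrow(select_sites_rnaseq(make_sites(pos = 1, ref_depth = 10,
                                                   alt_depth = 4))), 0)
  expect_error(select_sites_rnaseq(d, 0), ">= 1")
})

test_that("allele frequencies are exact ratios and zero-depth sites are skipped", {
  af <- compute_af(data.frame(ref_depth = c(10, 20, 0),
                              alt_depth = c(10, 10, 25)))
  expect_equal(af$af, c(0.5, 1 / 3, 1))
  expect_equal(af$total_depth, c(20, 30, 25))
  expect_message(
    out <- compute_af(data.frame(ref_depth = c(0, 5), alt_depth = c(0, 5))),
    "skipped")
  expect_equal(attr(out, "n_skipped"), 1)
  expect_equal(nrow(out), 1)
  # agreement with exact rational arithmetic on random integer depths
  set.seed(4)
  r <- sample.int(500, 50); a <- sample.int(500, 50)
  expect_identical(compute_af(data.frame(ref_depth = r, alt_depth = a))$af,
                   a / (r + a))
})

test_that("AF density integrates to one and finds binomial modes", {
  set.seed(9)
  af <- rbinom(10000, 30, 0.5) / 30
  d <- estimate_af_density(af)
  expect_false(d$insufficient)
  area <- sum(diff(d$grid) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_equal(area, 1, tolerance = 0.01)
  m <- detect_modes(d)
  expect_length(m, 1)
  expect_lt(abs(m - 0.5), 0.02)
  # two equal halves at p = 1/3 and 2/3 give two symmetric modes
  af2 <- c(rbinom(5000, 30, 1 / 3), rbinom(5000, 30, 2 / 3)) / 30
  m2 <- detect_modes(estimate_af_density(af2))
  expect_length(m2, 2)
  expect_lt(max(abs(m2 - c(1 / 3, 2 / 3))), 0.03)
  # degenerate input: all observations at exactly 0.5
  m3 <- detect_modes(estimate_af_density(rep(0.5, 300)))
  expect_length(m3, 1)
  expect_lt(abs(m3 - 0.5), 2 / 511)
  # too few sites is not an exception
  small <- estimate_af_density(runif(10))
  expect_true(small$insufficient)
  expect_length(detect_modes(small), 0)
  expect_error(estimate_af_density(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pentasomic-style simulation yields boundary-adjacent mode pairs", {
  set.seed(10)
  af <- c(rbinom(5000, 50, 0.2), rbinom(5000, 50, 0.8)) / 50
  m <- detect_modes(estimate_af_density(af))
  expect_length(m, 2)
  expect_lt(max(abs(m - c(0.2, 0.8))), 0.03)
})

test_that("mode detection is mirror symmetric and monotone in bandwidth", {
  set.seed(12)
  af <- c(rbinom(4000, 40, 0.25), rbinom(2000, 40, 0.6)) / 40
  m <- detect_modes(estimate_af_density(af))
  m_flip <- detect_modes(estimate_af_density(1 - af))
  expect_equal(sort(1 - m_flip), m, tolerance = 2 / 511)
  # widening the bandwidth never adds modes
  bws <- c(0.01, 0.02, 0.05, 0.1, 0.2)
  counts <- vapply(bws, function(b)
    length(detect_modes(estimate_af_density(af, bandwidth = b))), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fixed-allele fraction flags loss of heterozygosity", {
  expect_equal(fixed_allele_fraction(c(0, 0.01, 1, 0.5)), 0.75)
  expect_equal(fixed_allele_fraction(numeric(0)), NA_real_)
  af <- simulate_af_sample(mixture_state(1, 1), 30, 2000, seed = 3)
  expect_gt(fixed_allele_fraction(af), 0.99)
})
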