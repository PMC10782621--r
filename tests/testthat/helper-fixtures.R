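# Shared fixtures and independent oracles, built in code.

# A 10-row toy VCF with two samples (A, B): 7 biallelic SNVs, 1 indel,
# 2 multiallelic rows (excluded at parse time).
toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  info <- function(qd, fs, mq = 58, mqrs = 0.5, rprs = 0.5)
    sprintf("QD=%g;FS=%g;MQ=%g;MQRankSum=%g;ReadPosRankSum=%g",
            qd, fs, mq, mqrs, rprs)
  rows <- c(
    paste("1", 100, ".", "A", "G", ".", "PASS", info(20, 5),
          "GT:AD", "0/1:20,10", "0/1:15,15", sep = "\t"),
    paste("1", 200, ".", "C", "T", ".", "PASS", info(1.5, 5),
          "GT:AD", "0/1:10,10", "1/1:0,30", sep = "\t"),
    paste("1", 300, ".", "A", "G,T", ".", "PASS", info(20, 5),
          "GT:AD", "1/2:0,10,10", "0/1:10,10,0", sep = "\t"),
    paste("1", 400, ".", "G", "A", ".", "PASS", info(20, 60, mq = 50),
          "GT:AD", "1/1:0,25", "1/1:2,28", sep = "\t"),
    paste("1", 500, ".", "T", "C", ".", "PASS", info(20, 5),
          "GT:AD", "./.:.", "0/1:12,14", sep = "\t"),
    paste("1", 600, ".", "A", "AT", ".", "PASS", info(20, 100),
          "GT:AD", "0/1:12,8", "0/1:10,10", sep = "\t"),
    paste("1", 700, ".", "C", "G", ".", "PASS", info(20, 5, mq = 39),
          "GT:AD", "0/0:30,0", "0/1:18,12", sep = "\t"),
    paste("1", 800, ".", "G", "T", ".", "PASS", info(20, 5),
          "GT:AD", "0/1:14,16", "0/1:13,17", sep = "\t"),
    paste("1", 900, ".", "C", "A,G", ".", "PASS", info(20, 5),
          "GT:AD", "0/1:10,10,0", "0/2:12,0,12", sep = "\t"),
    paste("1", 1000, ".", "T", "A", ".", "PASS", info(20, 5),
          "GT:AD", "1/1:0,22", "0/1:11,11", sep = "\t"))
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=1,length=1000000>",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", "A", "B", sep = "\t"))
  writeLines(c(header, rows), path)
  path
}

# Construct a bare allelic-sites data frame for unit tests that do not
# need a VCF on disk.
make_sites <- function(chrom = "1", pos, sample = "A", genotype = "REF/ALT",
                       ref_depth = 10, alt_depth = 10,
                       variant_class = "SNP", QD = 20, FS = 5, MQ = 58,
                       MQRankSum = 0.5, ReadPosRankSum = 0.5) {
  df <- data.frame(chrom = chrom, pos = pos, ref_allele = "A",
                   alt_allele = "G", variant_class = variant_class,
                   QD = QD, FS = FS, MQ = MQ, MQRankSum = MQRankSum,
                   ReadPosRankSum = ReadPosRankSum, sample = sample,
                   genotype = genotype, ref_depth = ref_depth,
                   alt_depth = alt_depth, ad_missing = FALSE,
                   stringsAsFactors = FALSE)
  class(df) <- c("allelic_sites", "data.frame")
  df
}

# Independent rational-arithmetic oracle for expected AF modes of a
# clonal mixture with integer clone weights: returns the reduced
# fractions {sum(w a) / sum(w n), sum(w (n - a)) / sum(w n)} as
# (numerator, denominator) pairs, sorted, deduplicated. Pure integer
# arithmetic, exact.
gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

oracle_mode_fracs <- function(n, a, w = rep(1, length(n))) {
  stopifnot(all(w == round(w)), all(n == round(n)), all(a == round(a)))
  N <- sum(w * n)
  A <- sum(w * a)
  red <- function(num, den) {
    g <- gcd2(num, den)
    c(num / g, den / g)
  }
  u <- unique(list(red(A, N), red(N - A, N)))
  u[order(vapply(u, function(x) x[1] / x[2], numeric(1)))]
}

# Does a degeneracy class (list of mixture_state) contain the given state?
class_contains <- function(degeneracy, state) {
  any(vapply(degeneracy, function(s)
    identical(s$n, state$n) && identical(s$a, state$a) &&
      all(abs(s$f - state$f) < 1e-9), logical(1)))
}
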