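# Small shared fixtures, all built in code at test time.

small_model <- function(chrom_length = 2e5, ...)
  ancestor_model(n_chromosomes = 3, chrom_length = chrom_length, ...)

# a small planted hexaploid with its truth table
small_hexaploid <- function(seed = 1, chrom_length = 2e5) {
  anc <- simulate_ancestors(small_model(chrom_length), seed = seed)
  hex <- simulate_allohexaploid(anc, default_rearrangements(chrom_length))
  list(anc = anc, hex = hex)
}

# a hand-crafted VCF fixture (12 SNP records + 1 InDel anchor), written via
# the package writer: 2 low-quality, 1 triallelic, 1 within 5 bp of the
# InDel, 1 whose genotypes get depth-masked into a MAF failure, 7 clean
reseq_fixture <- function() {
  samples <- paste0("S", 1:4)
  v <- data.frame(
    chrom = "1A",
    pos = c(100, 200, 300, 400, 504, 500, 700, 800, 900, 1000, 1100,
            1200, 1300),
    ref = c(rep("A", 4), "A", "AT", rep("A", 7)),
    alt = c("G", "G", "G", "G,T", "G", "A", "G", "G", "G", "G", "G", "G",
            "G"),
    qual = c(40, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100,
             100),
    qd = c(25, 1.5, 25, 25, 25, 25, 25, 25, 25, 25, 25, 25, 25),
    fs = 1, mq = 60,
    stringsAsFactors = FALSE)
  # records: 1 qual<50, 2 QD<2, 4 triallelic, 6 the InDel, 5 within 5 bp of
  # it, 7 depth-masked into MAF failure, rest clean
  gt <- matrix("0/1", nrow = 13, ncol = 4,
               dimnames = list(NULL, samples))
  gt[7, ] <- c("0/1", "0/0", "0/0", "0/0") # MAF 1/8 before masking
  dp <- matrix(20, nrow = 13, ncol = 4, dimnames = list(NULL, samples))
  dp[7, 1] <- 200 # masks the only alt carrier -> MAF 0
  path <- tempfile(fileext = ".vcf")
  write_vcf_lite(v, path, gt = gt, dp = dp)
  path
}
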