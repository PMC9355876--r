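test_that("resequencing hard filter reproduces a manual rule walk-through", {
  vcf <- read_vcf_lite(reseq_fixture())
  res <- filter_resequencing_snps(vcf)
  r <- res$report
  expect_equal(r$input, 13)
  expect_equal(unname(r$removals["indel_record"]), 1)
  expect_equal(unname(r$removals["rule1_quality"]), 2)
  expect_equal(unname(r$removals["rule2_multiallelic"]), 1)
  expect_equal(unname(r$removals["rule3_near_indel"]), 1)
  expect_equal(unname(r$removals["rule5_maf"]), 1)
  expect_equal(unname(r$removals["rule6_missing"]), 0)
  expect_equal(r$retained, 7)
  expect_equal(r$input, r$retained + sum(r$removals))

  # MQ just below the cutoff fails rule 1
  v2 <- vcf
  v2$variants$mq[9] <- 39
  r2 <- filter_resequencing_snps(v2)$report
  expect_equal(unname(r2$removals["rule1_quality"]), 3)

  # empty input
  empty <- list(variants = vcf$variants[0, ], gt = vcf$gt[0, , drop = FALSE],
                dp = vcf$dp[0, , drop = FALSE])
  re <- filter_resequencing_snps(empty)$report
  expect_equal(re$input, 0)
  expect_equal(re$retained, 0)
  expect_true(all(re$removals == 0))
})

test_that("GBS filter enforces MAF, missingness and heterozygosity gates", {
  samples <- paste0("S", 1:20)
  mkgt <- function(...) matrix(c(...), nrow = 1,
                               dimnames = list(NULL, samples))
  base <- data.frame(chrom = "1A", pos = 1, ref = "A", alt = "G",
                     qual = 100, qd = 25, fs = 1, mq = 60,
                     allele_count = 2, is_indel = FALSE,
                     stringsAsFactors = FALSE)
  # site with 25% missing data
  gt_miss <- mkgt(rep(c("0/0", "1/1"), 7), "0/1", rep(NA, 5))
  r <- filter_gbs_snps(list(variants = base, gt = gt_miss))$report
  expect_equal(unname(r$removals["rule3_missing"]), 1)

  # site with 3/20 = 15% heterozygous calls (MAF and missingness clean)
  gt_het <- mkgt(rep(c("0/0", "1/1"), 8), "0/1", "0/1", "0/1", "0/0")
  r2 <- filter_gbs_snps(list(variants = base, gt = gt_het))$report
  expect_equal(unname(r2$removals["rule4_het"]), 1)

  # clean fixture retained unchanged
  gt_ok <- mkgt(rep(c("0/0", "1/1"), 10))
  r3 <- filter_gbs_snps(list(variants = base, gt = gt_ok))$report
  expect_equal(r3$retained, 1)

  tri <- transform(base, allele_count = 3)
  r4 <- filter_gbs_snps(list(variants = tri, gt = gt_ok))$report
  expect_equal(unname(r4$removals["rule1_not_biallelic"]), 1)
})

test_that("assembly QC arithmetic reproduces printed rates exactly", {
  expect_equal(heterozygosity_rate(1093198, 66019, 10757433345), 0.011)
  expect_equal(heterozygosity_rate(0, 0, 12345), 0)
  expect_equal(heterozygosity_rate(5, 5, 100000, digits = 2), 0.01)
  expect_equal(accuracy_rate(98885, 19444, 10757433345), 99.999)
  expect_equal(accuracy_rate(0, 0, 1e6), 100)
  expect_equal(accuracy_rate(100, 0, 100000, digits = 1), 99.9)
  expect_equal(anchoring_rate(10656159659, 10757433345), 99.06)
  expect_equal(anchoring_rate(7, 7), 100)
  expect_equal(anchoring_rate(1, 3), 33.33)
  expect_error(anchoring_rate(5, 4), class = "sg_validation_error")
})

test_that("contiguity statistics follow the standard definitions", {
  s <- contig_stats(c(10, 10, 10))
  expect_equal(s$n50, 10)
  expect_equal(s$l50, 2)
  s2 <- contig_stats(c(50, 30, 20))
  expect_equal(s2$n50, 50)
  expect_equal(s2$l50, 1)
  expect_equal(s2$n90, 20)
  expect_equal(s2$l90, 3)
  # NG50 with genome size equal to the assembly total equals N50
  s3 <- contig_stats(c(40, 25, 11, 9), genome_size = 85)
  expect_equal(s3$ng$ng[50], s3$n50)
  expect_equal(nrow(s3$ng), 100)
  expect_error(contig_stats(numeric(0)), class = "sg_validation_error")
})

test_that("identity profiles order accessions by divergence", {
  model <- ancestor_model(n_chromosomes = 1, chrom_length = 3e4,
                          divergence = c(A = 0.02, C = 0.15, D = 0.05),
                          satellite_density = 0)
  anc <- simulate_ancestors(model, seed = 21)
  hex <- simulate_allohexaploid(anc, default_rearrangements(3e4)[0, ])
  asgmap <- hex$truth$subgenome_of_chromosome
  # error-free reads from the A ancestor land on A at identity 1
  reads <- simulate_reads(anc$A, coverage = 2, error_rate = 0, seed = 1)
  pl <- map_fragments(reads[, c("id", "seq")], hex$genome, 5)
  prof <- identity_profile(pl, asgmap)
  a_row <- prof$modal[prof$modal$subgenome == "A", ]
  expect_gt(a_row$modal_identity, 0.999)
  expect_equal(sum(prof$hist$count), sum(pl$unique))

  # modal identity decreases with divergence: map the same accession's
  # reads onto each subgenome separately (per-subgenome profiling)
  reads_root <- simulate_reads(anc$root, coverage = 2, error_rate = 0,
                               seed = 2)
  plr <- do.call(rbind, lapply(c("A", "C", "D"), function(sg) {
    chroms <- names(asgmap)[asgmap == sg]
    map_fragments(reads_root[, c("id", "seq")], hex$genome[chroms], 25)
  }))
  profr <- identity_profile(plr, asgmap)
  m <- setNames(profr$modal$modal_identity, profr$modal$subgenome)
  expect_true(m["A"] > m["D"] && m["D"] > m["C"])
})

test_that("the association threshold reproduces the printed value", {
  expect_equal(bonferroni_neglog_threshold(0.01, 49702), 6.70)
  expect_equal(bonferroni_neglog_threshold(0.01, 1), 2.00)
  expect_equal(bonferroni_neglog_threshold(0.05, 100), 3.30)
  expect_error(bonferroni_neglog_threshold(1.2, 10),
               class = "sg_validation_error")
})

test_that("LD r2 behaves at the limits and recovers the decay length", {
  d <- matrix(rep(c(0, 1, 2, 1), 10), nrow = 2, byrow = TRUE)
  ld <- ld_r2_decay(d, c(100, 200), window = 5)
  expect_equal(ld$pairs$r2, 1)

  gen <- simulate_genotypes(n_samples = 300, n_snps = 400,
                            maf_range = c(0.3, 0.5),
                            ld_block_length = 2e5, region_length = 5e6,
                            seed = 2)
  ld2 <- ld_r2_decay(gen$dosage, gen$positions, window = 50,
                     threshold = 0.2)
  # analytic crossing of r2(d) = exp(-2 d / L) at threshold 0.2
  analytic <- 2e5 * log(1 / 0.2) / 2
  expect_lt(abs(ld2$decay_distance - analytic) / analytic, 0.20)
  expect_true(all(diff(ld2$curve$smoothed) <= 1e-12))
})
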