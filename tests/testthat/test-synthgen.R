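test_that("ancestor divergence matches the binomial model and the hierarchy", {
  model <- ancestor_model(n_chromosomes = 1, chrom_length = 1e4,
                          divergence = c(A = 0.05, C = 0.15, D = 0.05),
                          satellite_density = 0)
  anc <- simulate_ancestors(model, seed = 2)
  mism <- sum(strsplit(anc$A[[1]], "")[[1]] != strsplit(anc$root[[1]], "")[[1]])
  expect_lt(abs(mism - 500), 3 * sqrt(1e4 * 0.05 * 0.95))

  zero <- ancestor_model(n_chromosomes = 1, chrom_length = 5e3,
                         divergence = c(A = 0, C = 0, D = 0),
                         satellite_density = 0)
  anc0 <- simulate_ancestors(zero, seed = 1)
  expect_identical(unname(anc0$A), unname(anc0$C))
  expect_identical(unname(anc0$A), unname(anc0$root))

  expect_error(ancestor_model(divergence = c(A = 0.1, C = 0.05, D = 0.02)),
               class = "sg_config_error")
})

test_that("generators are pure functions of (config, seed)", {
  m <- small_model(chrom_length = 2e4)
  a1 <- simulate_ancestors(m, seed = 7)
  a2 <- simulate_ancestors(m, seed = 7)
  expect_identical(a1, a2)
  r1 <- simulate_reads(a1$A, coverage = 2, seed = 5)
  r2 <- simulate_reads(a1$A, coverage = 2, seed = 5)
  expect_identical(r1, r2)
  expect_identical(simulate_pav(n_genes = 500, seed = 3),
                   simulate_pav(n_genes = 500, seed = 3))
  expect_false(identical(simulate_ancestors(m, seed = 8)$A, a1$A))
})

test_that("hexaploid assembly applies events with copy semantics", {
  hx <- small_hexaploid(seed = 1, chrom_length = 5e4)
  none <- simulate_allohexaploid(hx$anc, default_rearrangements(5e4)[0, ])
  expect_identical(none$genome, c(hx$anc$A, hx$anc$C, hx$anc$D))
  expect_equal(nrow(none$truth$events), 0)

  ev <- data.frame(kind = "translocation", donor = "C",
                   src_chrom = "1C", src_start = 0, src_end = 5e3,
                   dst_chrom = "1D", dst_start = 0, dst_end = 5e3,
                   stage = "tetraploid", stringsAsFactors = FALSE)
  one <- simulate_allohexaploid(hx$anc, ev)
  expect_identical(substr(one$genome[["1D"]], 1, 5e3),
                   substr(hx$anc$C[["1C"]], 1, 5e3))
  expect_identical(one$genome[["1C"]], hx$anc$C[["1C"]]) # source untouched

  full <- default_rearrangements(5e4)
  expect_equal(nrow(full), 8)
  expect_equal(sum(full$stage == "tetraploid"), 6)
  expect_equal(sum(full$kind == "inversion"), 1)
  both <- simulate_allohexaploid(hx$anc, full)
  expect_equal(nrow(both$truth$events), 8)

  overlap <- rbind(ev, transform(ev, src_chrom = "2C"))
  expect_error(simulate_allohexaploid(hx$anc, overlap),
               class = "sg_validation_error")
})

test_that("read simulation respects count arithmetic and the error model", {
  g <- simulate_ancestors(ancestor_model(n_chromosomes = 1,
                                         chrom_length = 1e6,
                                         satellite_density = 0),
                          seed = 3)$A
  reads <- simulate_reads(g, coverage = 1, read_length = 100,
                          error_rate = 0, seed = 1)
  expect_equal(nrow(reads), 10000)
  sub <- reads[1:50, ]
  orig <- substring(g[sub$chrom], sub$start + 1, sub$start + 100)
  obs <- ifelse(sub$strand == "+", sub$seq,
                chartr("ACGT", "TGCA",
                       vapply(strsplit(sub$seq, ""), function(x)
                         paste(rev(x), collapse = ""), "")))
  expect_identical(unname(obs), unname(orig))

  noisy <- simulate_reads(g, coverage = 1, read_length = 100,
                          error_rate = 0.01, seed = 2)
  orig <- substring(g[noisy$chrom], noisy$start + 1, noisy$start + 100)
  fwd <- ifelse(noisy$strand == "+", noisy$seq,
                chartr("ACGT", "TGCA",
                       vapply(strsplit(noisy$seq, ""), function(x)
                         paste(rev(x), collapse = ""), "")))
  mism <- sum(vapply(seq_len(nrow(noisy)), function(i)
    sum(strsplit(fwd[i], "")[[1]] != strsplit(orig[i], "")[[1]]),
    numeric(1)))
  expect_lt(abs(mism - 10000), 3 * sqrt(1e6 * 0.01 * 0.99))

  expect_error(simulate_reads(c(c1 = "ACGT"), coverage = 1,
                              read_length = 100),
               class = "sg_config_error")
})

test_that("triad generator plants the requested bias structure", {
  tri <- simulate_triads(n_triads = 1000, bias_fraction = 0.2, seed = 1)
  expect_equal(sum(tri$truth$biased), 200)
  expect_true(all(is.na(tri$truth$direction[!tri$truth$biased])))

  null <- simulate_triads(n_triads = 2000, bias_fraction = 0, seed = 2)
  fc <- log2((null$tpm[seq(1, 6000, 3), ] + 0.5) /
               (null$tpm[seq(2, 6000, 3), ] + 0.5))
  expect_lt(abs(mean(fc)), 3 * stats::sd(fc) / sqrt(length(fc)))
})

test_that("PAV generator loss counts follow the binomial model", {
  pav <- simulate_pav(n_genes = 10000,
                      loss_rate = c(A = 0.1, C = 0.2, D = 0.1), seed = 1)
  lost_C <- sum(pav$pav[, "C"] == 0)
  lost_A <- sum(pav$pav[, "A"] == 0)
  expect_lt(abs(lost_C - 2000), 3 * sqrt(10000 * 0.2 * 0.8))
  expect_lt(abs(lost_A - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  expect_identical(pav$truth$C, rownames(pav$pav)[pav$pav[, "C"] == 0])

  none <- simulate_pav(n_genes = 100, loss_rate = c(A = 0, C = 0, D = 0),
                       seed = 1)
  expect_true(all(none$pav == 1))
})

test_that("genotype generator: LD limit, trait construction", {
  indep <- simulate_genotypes(n_samples = 150, n_snps = 100,
                              ld_block_length = 0, seed = 1)
  ld0 <- ld_r2_decay(indep$dosage, indep$positions, window = 20)
  # permutation baseline for independent dosages
  perm <- apply(indep$dosage, 1, sample)
  ldp <- ld_r2_decay(t(perm), indep$positions, window = 20)
  expect_lt(abs(mean(ld0$pairs$r2) - mean(ldp$pairs$r2)),
            3 * stats::sd(ldp$pairs$r2) / sqrt(nrow(ldp$pairs)) +
              3 * stats::sd(ld0$pairs$r2) / sqrt(nrow(ld0$pairs)))

  full <- simulate_genotypes(n_samples = 200, n_snps = 60,
                             ld_block_length = 1e5, penetrance = 1,
                             seed = 3)
  p <- vapply(seq_len(nrow(full$dosage)), function(j) {
    d <- full$dosage[j, ]
    if (stats::sd(d) == 0) return(1)
    suppressWarnings(stats::cor.test(d, full$phenotype$trait)$p.value)
  }, numeric(1))
  expect_equal(p[full$truth$trait_locus], min(p))
})
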