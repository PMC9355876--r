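#' Hard-filter resequencing SNPs (six ordered rules)
#'
#' Applies, in order: (1) quality score < 50, QD < 2, FS > 60 or MQ < 40
#' (records with any of these fields missing fail rule 1 by convention);
#' (2) more than two alleles; (3) at or within 5 bp of any InDel record;
#' (4) genotypes with depth above three-fold or below one-third of the
#' sample's mean depth are masked to missing (this may cascade into rules
#' 5-6); (5) minor allele frequency < 0.05; (6) missing sample rate > 0.3.
#' Each removed record is attributed to the first rule that removes it, so
#' input = retained + sum of removals. InDel records themselves are set
#' aside (counted under `indel_record`) and serve only as rule-3 anchors.
#'
#' @param vcf list from [read_vcf_lite()].
#' @param mean_depth named per-sample mean depth (defaults to the mean of
#'   the VCF's DP matrix).
#' @return list: `retained` (vcf-like subset), `report` (input, removals,
#'   retained, per-sample missingness after masking).
#' @export
filter_resequencing_snps <- function(vcf, mean_depth = NULL) {
  v <- vcf$variants
  gt <- vcf$gt
  dp <- vcf$dp
  input <- nrow(v)
  removals <- c(indel_record = 0, rule1_quality = 0, rule2_multiallelic = 0,
                rule3_near_indel = 0, rule5_maf = 0, rule6_missing = 0)
  status <- rep(NA_character_, input)
  status[v$is_indel] <- "indel_record"
  fail1 <- with(v, is.na(qual) | is.na(qd) | is.na(fs) | is.na(mq) |
                  qual < 50 | qd < 2 | fs > 60 | mq < 40)
  status[is.na(status) & fail1] <- "rule1_quality"
  status[is.na(status) & v$allele_count > 2] <- "rule2_multiallelic"
  indel_idx <- which(v$is_indel)
  if (length(indel_idx) > 0) {
    near <- vapply(seq_len(input), function(i) {
      if (!is.na(status[i])) return(FALSE)
      same <- indel_idx[v$chrom[indel_idx] == v$chrom[i]]
      length(same) > 0 && min(abs(v$pos[same] - v$pos[i])) <= 5
    }, logical(1))
    status[is.na(status) & near] <- "rule3_near_indel"
  }
  if (!is.null(gt) && !is.null(dp)) {
    if (is.null(mean_depth)) mean_depth <- colMeans(dp, na.rm = TRUE)
    hi <- sweep(dp, 2, 3 * mean_depth[colnames(dp)], ">")
    lo <- sweep(dp, 2, mean_depth[colnames(dp)] / 3, "<")
    mask <- (hi | lo) & !is.na(dp)
    gt[mask] <- NA_character_
  }
  if (!is.null(gt)) {
    dos <- t(apply(gt, 1, gt_dosage))
    miss <- rowMeans(is.na(dos))
    f <- rowMeans(dos, na.rm = TRUE) / 2
    maf <- pmin(f, 1 - f)
    maf[is.nan(maf)] <- 0
    status[is.na(status) & maf < 0.05] <- "rule5_maf"
    status[is.na(status) & miss > 0.3] <- "rule6_missing"
  }
  for (r in names(removals)) removals[r] <- sum(status == r, na.rm = TRUE)
  keep <- is.na(status)
  report <- list(input = input, removals = removals,
                 retained = sum(keep),
                 per_sample_missingness = if (!is.null(gt))
                   colMeans(is_missing_gt(gt) | is.na(gt)) else NULL)
  stopifnot(report$input == report$retained + sum(report$removals))
  list(retained = list(variants = v[keep, , drop = FALSE],
                       gt = if (!is.null(gt)) gt[keep, , drop = FALSE],
                       dp = if (!is.null(dp)) dp[keep, , drop = FALSE]),
       report = report)
}

#' Hard-filter GBS SNPs
#'
#' Retains only biallelic sites with minor allele frequency > 0.05, missing
#' data rate < 20% and heterozygous calls < 10%; removals are attributed to
#' the first failing rule.
#'
#' @param vcf list from [read_vcf_lite()] (or an equivalent list with
#'   `variants` and `gt`).
#' @return list: `retained`, `report` as in [filter_resequencing_snps()].
#' @export
filter_gbs_snps <- function(vcf) {
  v <- vcf$variants
  gt <- vcf$gt
  input <- nrow(v)
  status <- rep(NA_character_, input)
  status[v$allele_count != 2 | v$is_indel] <- "rule1_not_biallelic"
  if (!is.null(gt)) {
    dos <- t(apply(gt, 1, gt_dosage))
    f <- rowMeans(dos, na.rm = TRUE) / 2
    maf <- pmin(f, 1 - f)
    maf[is.nan(maf)] <- 0
    miss <- rowMeans(is.na(dos))
    het <- rowMeans(t(apply(gt, 1, is_het_gt)), na.rm = TRUE)
    het[is.nan(het)] <- 0
    status[is.na(status) & maf <= 0.05] <- "rule2_maf"
    status[is.na(status) & miss >= 0.2] <- "rule3_missing"
    status[is.na(status) & het >= 0.1] <- "rule4_het"
  }
  removals <- table(factor(status, levels = c("rule1_not_biallelic",
                                              "rule2_maf", "rule3_missing",
                                              "rule4_het")))
  keep <- is.na(status)
  report <- list(input = input, removals = c(removals),
                 retained = sum(keep))
  list(retained = list(variants = v[keep, , drop = FALSE],
                       gt = if (!is.null(gt)) gt[keep, , drop = FALSE]),
       report = report)
}

#' Assembly heterozygosity rate from heterozygous variant counts
#'
#' `100 * (het_snps + het_indels) / genome_length`, rounded to the printed
#' precision (3 decimals by default).
#'
#' @param het_snps,het_indels heterozygous SNP / InDel counts.
#' @param genome_length assembly length in bp.
#' @param digits decimals to report.
#' @return percentage.
#' @export
heterozygosity_rate <- function(het_snps, het_indels, genome_length,
                                digits = 3) {
  if (genome_length <= 0)
    sg_error("sg_validation_error", "genome_length must be positive")
  round(100 * (het_snps + het_indels) / genome_length, digits)
}

#' Assembly nucleotide accuracy rate from homozygous variant counts
#'
#' `100 * (1 - (hom_snps + hom_indels) / genome_length)`.
#'
#' @param hom_snps,hom_indels homozygous SNP / InDel counts (assembly
#'   errors).
#' @param genome_length assembly length in bp.
#' @param digits decimals to report.
#' @return percentage.
#' @export
accuracy_rate <- function(hom_snps, hom_indels, genome_length, digits = 3) {
  if (genome_length <= 0)
    sg_error("sg_validation_error", "genome_length must be positive")
  round(100 * (1 - (hom_snps + hom_indels) / genome_length), digits)
}

#' Chromosome anchoring rate
#'
#' `100 * anchored_bp / total_bp`.
#'
#' @param anchored_bp bp assigned to chromosomes.
#' @param total_bp total assembly bp (`anchored_bp <= total_bp`).
#' @param digits decimals to report.
#' @return percentage.
#' @export
anchoring_rate <- function(anchored_bp, total_bp, digits = 2) {
  if (total_bp <= 0)
    sg_error("sg_validation_error", "total_bp must be positive")
  if (anchored_bp > total_bp)
    sg_error("sg_validation_error", "anchored_bp exceeds total_bp")
  round(100 * anchored_bp / total_bp, digits)
}

#' Assembly contiguity statistics (N50/L50/N90/L90 and the NG curve)
#'
#' N(x) is the length of the contig at which the cumulative sorted length
#' first reaches x% of the assembly; NG(x) uses a supplied genome size
#' instead of the assembly total (NA where the assembly never reaches x% of
#' it). The NG curve is emitted for x = 1..100.
#'
#' @param lengths positive contig lengths.
#' @param genome_size genome size for NG values (default: assembly total,
#'   which makes NG50 equal N50).
#' @return list: n50, l50, n90, l90, total, `ng` (data.frame x, ng, lg).
#' @export
contig_stats <- function(lengths, genome_size = NULL) {
  if (length(lengths) == 0)
    sg_error("sg_validation_error", "empty length list")
  if (any(lengths <= 0))
    sg_error("sg_validation_error", "contig lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  total <- cum[length(cum)]
  if (is.null(genome_size)) genome_size <- total
  nx <- function(frac, size) {
    i <- which(cum >= frac * size)
    if (length(i) == 0) c(NA_real_, NA_real_) else c(s[i[1]], i[1])
  }
  n50 <- nx(0.5, total); n90 <- nx(0.9, total)
  ng <- t(vapply(1:100, function(x) nx(x / 100, genome_size), numeric(2)))
  list(n50 = n50[1], l50 = n50[2], n90 = n90[1], l90 = n90[2],
       total = total,
       ng = data.frame(x = 1:100, ng = ng[, 1], lg = ng[, 2]))
}

#' Per-accession read-identity profile against assigned subgenomes
#'
#' Identity of a uniquely mapped read is `1 - mismatches / aligned length`.
#' Reads are histogrammed per (accession, subgenome) at 0.001 bin width and
#' the modal identity reported.
#'
#' @param placements data.frame from [map_fragments()] with an optional
#'   `accession` column; only unique placements are used.
#' @param assignment named character vector chrom -> subgenome.
#' @param bin_width histogram bin width on the identity axis.
#' @return list: `hist` (accession, subgenome, bin_mid, count), `modal`
#'   (accession, subgenome, modal_identity, n_reads).
#' @export
identity_profile <- function(placements, assignment, bin_width = 0.001) {
  pl <- placements[placements$unique, , drop = FALSE]
  if (is.null(pl$accession)) pl$accession <- "sample"
  pl$subgenome <- assignment[pl$chrom]
  len <- pl$tend - pl$tstart
  pl$identity <- 1 - pl$mismatches / len
  pl$bin <- floor(pl$identity / bin_width) * bin_width + bin_width / 2
  pl$bin[pl$identity == 1] <- 1 - bin_width / 2
  key <- interaction(pl$accession, pl$subgenome, drop = TRUE)
  hist <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- pl[key == k, ]
    tab <- table(sub$bin)
    data.frame(accession = sub$accession[1], subgenome = sub$subgenome[1],
               bin_mid = as.numeric(names(tab)), count = as.integer(tab),
               stringsAsFactors = FALSE)
  }))
  modal <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- hist[interaction(hist$accession, hist$subgenome) == k, ]
    data.frame(accession = sub$accession[1], subgenome = sub$subgenome[1],
               modal_identity = sub$bin_mid[which.max(sub$count)],
               n_reads = sum(sub$count), stringsAsFactors = FALSE)
  }))
  rownames(hist) <- rownames(modal) <- NULL
  list(hist = hist, modal = modal)
}

#' Bonferroni-style -log10 association threshold
#'
#' `-log10(alpha / n_tests)`, reported to two decimals.
#'
#' @param alpha significance level in (0, 1).
#' @param n_tests effective number of tests (>= 1).
#' @param digits decimals to report.
#' @return threshold on the -log10(p) scale.
#' @export
bonferroni_neglog_threshold <- function(alpha, n_tests, digits = 2) {
  if (alpha <= 0 || alpha >= 1)
    sg_error("sg_validation_error", "alpha must lie in (0, 1)")
  if (n_tests < 1)
    sg_error("sg_validation_error", "n_tests must be >= 1")
  round(-log10(alpha / n_tests), digits)
}

#' Pairwise LD r-squared and decay distance
#'
#' Composite LD: r-squared is the squared Pearson correlation of genotype
#' dosages for SNP pairs within a sliding window of `window` SNPs
#' (monomorphic pairs skipped). Pairs are binned by physical distance, the
#' bin means are smoothed monotone non-increasing (isotonic regression) and
#' the decay distance is the smallest distance at which the smoothed curve
#' drops to `threshold` (linear interpolation between bins).
#'
#' @param dosage numeric matrix, SNPs x samples (0/1/2, NA allowed).
#' @param positions physical positions (bp), same order as rows.
#' @param window number of downstream SNPs paired with each SNP.
#' @param threshold r-squared level defining decay.
#' @param n_bins number of distance bins for the mean curve.
#' @return list: `pairs` (i, j, distance, r2), `curve` (distance, mean_r2,
#'   smoothed), `decay_distance` (NA when the curve never reaches the
#'   threshold).
#' @export
ld_r2_decay <- function(dosage, positions, window = 50, threshold = 0.2,
                        n_bins = 25) {
  n <- nrow(dosage)
  res_i <- integer(0); res_j <- integer(0); res_r2 <- numeric(0)
  sds <- apply(dosage, 1, stats::sd, na.rm = TRUE)
  for (i in seq_len(n - 1)) {
    if (is.na(sds[i]) || sds[i] == 0) next
    js <- (i + 1):min(i + window, n)
    js <- js[!is.na(sds[js]) & sds[js] > 0]
    if (length(js) == 0) next
    r <- suppressWarnings(cor(dosage[i, ], t(dosage[js, , drop = FALSE]),
                              use = "pairwise.complete.obs"))
    ok <- is.finite(r)
    res_i <- c(res_i, rep(i, sum(ok)))
    res_j <- c(res_j, js[ok])
    res_r2 <- c(res_r2, r[ok]^2)
  }
  pairs <- data.frame(i = res_i, j = res_j,
                      distance = positions[res_j] - positions[res_i],
                      r2 = res_r2)
  if (nrow(pairs) == 0)
    return(list(pairs = pairs, curve = NULL, decay_distance = NA_real_))
  breaks <- seq(0, max(pairs$distance), length.out = n_bins + 1)
  bin <- cut(pairs$distance, breaks, include.lowest = TRUE)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  mean_r2 <- tapply(pairs$r2, bin, mean)
  keep <- !is.na(mean_r2)
  curve <- data.frame(distance = mid[keep], mean_r2 = as.numeric(mean_r2[keep]))
  iso <- isoreg(curve$distance, -curve$mean_r2)
  curve$smoothed <- -iso$yf
  decay <- NA_real_
  below <- which(curve$smoothed <= threshold)
  if (length(below) > 0) {
    b <- below[1]
    if (b == 1) decay <- curve$distance[1]
    else {
      x0 <- curve$distance[b - 1]; y0 <- curve$smoothed[b - 1]
      x1 <- curve$distance[b]; y1 <- curve$smoothed[b]
      decay <- if (y0 == y1) x1 else
        x0 + (y0 - threshold) / (y0 - y1) * (x1 - x0)
    }
  }
  list(pairs = pairs, curve = curve, decay_distance = decay)
}
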