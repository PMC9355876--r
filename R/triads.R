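#' Build the concatenated triad expression matrix
#'
#' One row per retained homoeolog triad; columns concatenate the A, C and D
#' homoeolog expression vectors over organs (`A.organ1..A.organK, C..., D...`).
#' Triads with all-zero expression across all homoeologs and organs are
#' excluded with a logged count (the "expressed at least one homolog"
#' retention rule).
#'
#' @param tpm numeric matrix, genes x organs.
#' @param triads data.frame with `triad_id`, `gene_A`, `gene_C`, `gene_D`.
#' @return list: `mat` (triads x (3 * organs)), `triads` (retained rows of
#'   the input table), `n_excluded`.
#' @export
build_triad_matrix <- function(tpm, triads) {
  genes <- c(triads$gene_A, triads$gene_C, triads$gene_D)
  missing <- !(genes %in% rownames(tpm))
  if (any(missing)) {
    bad <- triads$triad_id[((which(missing) - 1) %% nrow(triads)) + 1][1]
    sg_error("sg_validation_error", "gene id missing from tpm for triad ", bad)
  }
  organs <- colnames(tpm)
  block <- function(g) {
    m <- tpm[g, , drop = FALSE]
    rownames(m) <- triads$triad_id
    m
  }
  mat <- cbind(block(triads$gene_A), block(triads$gene_C),
               block(triads$gene_D))
  colnames(mat) <- paste(rep(c("A", "C", "D"), each = length(organs)),
                         rep(organs, 3), sep = ".")
  keep <- rowSums(mat) > 0
  if (any(!keep))
    sg_log(sum(!keep), " all-zero triads excluded from the triad matrix")
  list(mat = mat[keep, , drop = FALSE],
       triads = triads[keep, , drop = FALSE],
       n_excluded = sum(!keep))
}

#' Log-transform an expression matrix
#'
#' Elementwise `log10(x + 1)`; negative input is an error.
#'
#' @param mat non-negative numeric matrix.
#' @return transformed matrix.
#' @export
log_transform <- function(mat) {
  if (any(mat < 0, na.rm = TRUE))
    sg_error("sg_validation_error", "log_transform requires non-negative input")
  log10(mat + 1)
}

#' Average-linkage clustering under correlation distance
#'
#' Distance is `1 - Pearson correlation` between item profiles; constant
#' profiles (undefined correlation) are placed at the maximum distance 1.
#' Agglomeration is average linkage (UPGMA) via `stats::hclust`.
#'
#' @param mat numeric matrix; items are rows (`axis = "rows"`) or columns.
#' @param axis `"rows"` or `"columns"`.
#' @return list: `order` (leaf order), `heights`, `merge`, `hclust`.
#' @export
hierarchical_cluster <- function(mat, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- if (axis == "columns") t(mat) else mat
  if (nrow(m) < 2)
    sg_error("sg_validation_error", "clustering needs at least 2 items")
  cc <- suppressWarnings(cor(t(m)))
  cc[!is.finite(cc)] <- 0 # constant rows: distance 1
  d <- as.dist(1 - cc)
  hc <- hclust(d, method = "average")
  list(order = hc$order, heights = hc$height, merge = hc$merge, hclust = hc)
}

#' Pairwise homoeolog log2 fold changes
#'
#' `log2((x + eps) / (y + eps))` for the pairs A/C, A/D and D/C; the
#' pseudocount bounds fold changes for zero cells and makes the measure
#' antisymmetric.
#'
#' @param a,c_,d TPM values for the A, C and D homoeologs (vectors over
#'   organs are fine).
#' @param epsilon pseudocount in TPM units.
#' @return data.frame with columns `log2fc_AC`, `log2fc_AD`, `log2fc_DC`.
#' @export
triad_fold_changes <- function(a, c_, d, epsilon = 0.5) {
  fc <- function(x, y) log2((x + epsilon) / (y + epsilon))
  data.frame(log2fc_AC = fc(a, c_), log2fc_AD = fc(a, d),
             log2fc_DC = fc(d, c_))
}

#' One-tailed Fisher test for homoeolog expression bias
#'
#' Exact hypergeometric tail on the 2x2 table
#' `[[counts_x, lib_x - counts_x], [counts_y, lib_y - counts_y]]`, testing
#' whether homoeolog x's share of its library exceeds homoeolog y's.
#' Vectorized over records.
#'
#' @param counts_x,counts_y raw read counts of the two homoeologs.
#' @param lib_x,lib_y library sizes of the corresponding samples.
#' @return one-tailed p-values (P(X >= counts_x) under the hypergeometric
#'   null with fixed margins).
#' @export
triad_bias_test <- function(counts_x, counts_y, lib_x, lib_y) {
  if (any(counts_x > lib_x) || any(counts_y > lib_y))
    sg_error("sg_validation_error", "counts exceed library size")
  phyper(counts_x - 1, lib_x, lib_y, counts_x + counts_y,
         lower.tail = FALSE)
}

#' Per-organ homoeolog bias calls for triads
#'
#' For every triad and organ, each homoeolog is tested one-tailed
#' ([triad_bias_test()]) against both others; p-values are BH-adjusted
#' within the organ family. A homoeolog is called dominant when both of its
#' tests are significant at `alpha` and both fold changes clear `fc_gate`;
#' otherwise the triad is balanced in that organ. The triad-level consensus
#' call applies the same rule to counts pooled across organs (planted bias
#' is a consistent shift, so pooling maximizes power for weakly expressed
#' triads).
#'
#' @param counts raw count matrix, genes x organs (genes named
#'   `<triad>_<A|C|D>` as in [simulate_triads()], or use `triads` mapping).
#' @param lib_sizes per-organ library sizes (defaults to column sums).
#' @param triads data.frame with `triad_id`, `gene_A`, `gene_C`, `gene_D`.
#' @param alpha significance level after BH adjustment.
#' @param fc_gate minimum |log2 fold change| (on count shares) for a call.
#' @param epsilon pseudocount for the fold-change gate.
#' @return list: `calls` (triads x organs character matrix), `consensus`
#'   (named vector), `p_adj` (array of adjusted p-values).
#' @export
call_triad_bias <- function(counts, triads, lib_sizes = colSums(counts),
                            alpha = 0.05, fc_gate = 0.5, epsilon = 0.5) {
  organs <- colnames(counts)
  homs <- c("A", "C", "D")
  getm <- function(h) counts[triads[[paste0("gene_", h)]], , drop = FALSE]
  cnt <- lapply(setNames(nm = homs), getm)
  n <- nrow(triads)
  if (n == 0)
    return(list(calls = matrix(character(0), 0, length(organs),
                               dimnames = list(NULL, organs)),
                consensus = setNames(character(0), character(0))))
  calls <- matrix("balanced", n, length(organs),
                  dimnames = list(triads$triad_id, organs))
  ordered_pairs <- list(c("A", "C"), c("A", "D"), c("C", "A"), c("C", "D"),
                        c("D", "A"), c("D", "C"))
  for (o in seq_along(organs)) {
    lib <- lib_sizes[o]
    p <- sapply(ordered_pairs, function(pr)
      triad_bias_test(cnt[[pr[1]]][, o], cnt[[pr[2]]][, o], lib, lib))
    p_adj <- matrix(p.adjust(p, method = "BH"), nrow = n)
    # fold changes on library-share scale (libraries equal within organ)
    fc <- sapply(ordered_pairs, function(pr)
      log2((cnt[[pr[1]]][, o] + epsilon) / (cnt[[pr[2]]][, o] + epsilon)))
    fc <- matrix(fc, nrow = n)
    for (h in seq_along(homs)) {
      cols <- which(vapply(ordered_pairs, function(pr) pr[1] == homs[h],
                           logical(1)))
      dom <- p_adj[, cols[1]] < alpha & p_adj[, cols[2]] < alpha &
        fc[, cols[1]] > fc_gate & fc[, cols[2]] > fc_gate
      calls[dom, o] <- homs[h]
    }
  }
  # triad-level consensus: pool counts across organs (planted bias is a
  # consistent per-triad shift, so pooling maximizes power for weakly
  # expressed triads) and re-test the aggregate with the same rule
  agg <- lapply(cnt, rowSums)
  lib_tot <- sum(lib_sizes)
  p <- sapply(ordered_pairs, function(pr)
    triad_bias_test(agg[[pr[1]]], agg[[pr[2]]], lib_tot, lib_tot))
  p_adj <- matrix(p.adjust(p, method = "BH"), nrow = n)
  fc <- sapply(ordered_pairs, function(pr)
    log2((agg[[pr[1]]] + epsilon) / (agg[[pr[2]]] + epsilon)))
  fc <- matrix(fc, nrow = n)
  consensus <- setNames(rep("balanced", n), triads$triad_id)
  for (h in seq_along(homs)) {
    cols <- which(vapply(ordered_pairs, function(pr) pr[1] == homs[h],
                         logical(1)))
    dom <- p_adj[, cols[1]] < alpha & p_adj[, cols[2]] < alpha &
      fc[, cols[1]] > fc_gate & fc[, cols[2]] > fc_gate
    consensus[dom] <- homs[h]
  }
  list(calls = calls, consensus = consensus)
}

#' Subgenome expression-dominance summary
#'
#' Counts triads preferentially expressed in each subgenome (consensus bias
#' calls) and compares homoeolog expression distributions pairwise with the
#' Wilcoxon rank-sum test (exact for small samples, normal approximation
#' with tie correction otherwise), BH-adjusted.
#'
#' @param bias result of [call_triad_bias()]; may cover zero triads.
#' @param tpm TPM matrix, genes x organs.
#' @param triads triad table matching `bias`.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (x = first
#'   subgenome of the pair).
#' @return list: `counts` (dominant triads per subgenome),
#'   `fraction_biased` (share of triads with a consensus call), `wilcoxon`
#'   (pair, p, p_adj).
#' @export
dominance_summary <- function(bias, tpm, triads,
                              alternative = "two.sided") {
  homs <- c("A", "C", "D")
  if (length(bias$consensus) == 0)
    return(list(counts = setNames(rep(0L, 3), homs), fraction_biased = NA_real_,
                wilcoxon = data.frame(pair = character(0), p = numeric(0),
                                      p_adj = numeric(0))))
  counts <- vapply(homs, function(h) sum(bias$consensus == h), integer(1))
  expr <- lapply(setNames(nm = homs), function(h)
    as.vector(log_transform(tpm[triads[[paste0("gene_", h)]], , drop = FALSE])))
  pairs <- utils::combn(homs, 2)
  w <- apply(pairs, 2, function(pr) {
    p <- suppressWarnings(wilcox.test(expr[[pr[1]]], expr[[pr[2]]],
                                      alternative = alternative)$p.value)
    data.frame(pair = paste(pr, collapse = " vs "), p = p,
               stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, w)
  w$p_adj <- p.adjust(w$p, method = "BH")
  rownames(w) <- NULL
  list(counts = counts,
       fraction_biased = sum(bias$consensus != "balanced") /
         length(bias$consensus),
       wilcoxon = w)
}
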