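#' Count ortholog losses per subgenome
#'
#' For a conserved one-to-one ortholog table (rows = diploid anchors,
#' columns = polyploid subgenomes, cells 1 = present, 0 = absent, NA =
#' unknown), counts the rows absent in each subgenome. Rows absent in every
#' subgenome are also reported separately. Unknown cells are excluded.
#'
#' @param pav 0/1/NA matrix, genes x subgenomes.
#' @return list with `losses` (named integer per subgenome), `lost_everywhere`
#'   (count) and `n_genes`.
#' @export
pav_counts <- function(pav) {
  if (is.null(dim(pav)))
    sg_error("sg_validation_error", "pav must be a matrix")
  losses <- apply(pav, 2, function(x) sum(x == 0, na.rm = TRUE))
  all_absent <- sum(apply(pav, 1, function(x) all(!is.na(x)) && all(x == 0)))
  list(losses = losses, lost_everywhere = all_absent, n_genes = nrow(pav))
}

#' Two-cell chi-squared bias test
#'
#' Tests observed counts (a, b) against expectations split by
#' `expected_ratio` (default 1:1): `chi2 = sum((obs - exp)^2 / exp)` with
#' df = 1 and no continuity correction. The expectation model is an explicit
#' parameter because a 1:1 split is an assumption, not a given.
#'
#' @param a,b non-negative observed counts, `a + b > 0`.
#' @param expected_ratio length-2 positive weights for the expected split.
#' @return list of class `sg_bias_test`: counts, expected, chi2, df, p.
#' @export
chisq_two_cell <- function(a, b, expected_ratio = c(1, 1)) {
  if (a < 0 || b < 0) sg_error("sg_validation_error", "counts must be >= 0")
  if (a + b == 0) sg_error("sg_validation_error", "a + b must be > 0")
  w <- expected_ratio / sum(expected_ratio)
  e <- (a + b) * w
  chi2 <- sum((c(a, b) - e)^2 / e)
  structure(list(counts = c(a = a, b = b), expected = e, chi2 = chi2,
                 df = 1L, p = pchisq(chi2, df = 1, lower.tail = FALSE)),
            class = "sg_bias_test")
}

#' @export
print.sg_bias_test <- function(x, ...) {
  cat(sprintf("two-cell chi-squared test: %d vs %d (expected %.1f : %.1f)\n",
              x$counts[1], x$counts[2], x$expected[1], x$expected[2]))
  cat(sprintf("  chi2 = %.4g, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Pairwise bias tests on per-subgenome counts
#'
#' Applies [chisq_two_cell()] to every unordered pair of subgenome counts
#' (e.g. pseudogene or loss counts) with Benjamini-Hochberg adjustment
#' across the pair family.
#'
#' @param counts named non-negative counts per subgenome.
#' @param expected_ratio forwarded to [chisq_two_cell()].
#' @return data.frame: pair, a, b, chi2, p, p_adj.
#' @export
pseudogene_bias <- function(counts, expected_ratio = c(1, 1)) {
  nm <- names(counts)
  pairs <- utils::combn(nm, 2)
  rows <- apply(pairs, 2, function(pr) {
    t <- chisq_two_cell(counts[[pr[1]]], counts[[pr[2]]], expected_ratio)
    data.frame(pair = paste(pr, collapse = " vs "),
               a = counts[[pr[1]]], b = counts[[pr[2]]],
               chi2 = t$chi2, p = t$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
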