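# Nei-Gojobori (1986) counting estimator of Ka and Ks with Jukes-Cantor
# correction. Site fractions are computed per codon over the three
# alternative bases at each position (changes producing a stop codon count
# as nonsynonymous, so syn + nonsyn sites always sum to 3 per codon) and
# averaged over the two sequences. Multi-substitution codons average the
# synonymous/nonsynonymous step counts over all minimal substitution orders
# with equal weight, discarding orders that pass through a stop codon
# whenever at least one stop-free order exists.

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

.ng86_env <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_env$aa)) return(.ng86_env)
  .ng86_env$aa <- codon_table()
  codons <- names(.ng86_env$aa)
  syn_sites <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    aa0 <- .ng86_env$aa[[cd]]
    s <- 0
    for (pos in 1:3) for (b in BASES) {
      if (substr(cd, pos, pos) == b) next
      alt <- cd
      substr(alt, pos, pos) <- b
      if (.ng86_env$aa[[alt]] == aa0 && aa0 != "*") s <- s + 1 / 3
    }
    syn_sites[cd] <- s
  }
  .ng86_env$syn_sites <- syn_sites
  .ng86_env
}

# all permutations of a short integer vector
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# pathway-averaged (syn, nonsyn) difference counts for one codon pair
codon_pair_diffs <- function(c1, c2, tab) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  paths <- perms(pos)
  counts <- matrix(NA_real_, length(paths), 2)
  through_stop <- logical(length(paths))
  for (k in seq_along(paths)) {
    cur <- c1
    sd <- nd <- 0
    stopped <- FALSE
    for (p in paths[[k]]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (tab$aa[[nxt]] == "*" && nxt != c2) stopped <- TRUE
      if (tab$aa[[nxt]] == tab$aa[[cur]] && tab$aa[[cur]] != "*")
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    counts[k, ] <- c(sd, nd)
    through_stop[k] <- stopped
  }
  use <- if (any(!through_stop)) !through_stop else rep(TRUE, length(paths))
  colMeans(counts[use, , drop = FALSE])
}

#' Nei-Gojobori (1986) Ka/Ks for one aligned CDS pair
#'
#' @param seq1,seq2 aligned coding sequences: equal length, length divisible
#'   by 3. Codons containing gaps, N or a stop codon in either sequence are
#'   dropped pairwise before counting.
#' @param ks_floor estimates with `Ks < ks_floor` carry `excluded = TRUE`.
#' @return list of class `sg_kaks`: `ka`, `ks`, `ratio` (NA when Ks is 0 or
#'   unavailable), `syn_sites`, `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`,
#'   `n_codons` (used), `saturated` (JC correction undefined, p >= 3/4),
#'   `excluded`.
#' @export
ng86_kaks <- function(seq1, seq2, ks_floor = 0.01) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2))
    sg_error("sg_validation_error", "aligned sequences differ in length")
  if (nchar(seq1) %% 3 != 0)
    sg_error("sg_validation_error", "alignment length not divisible by 3")
  tab <- ng86_tables()
  n <- nchar(seq1) / 3
  starts <- 3 * (seq_len(n) - 1) + 1
  c1 <- substring(seq1, starts, starts + 2)
  c2 <- substring(seq2, starts, starts + 2)
  clean <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2)
  clean[clean] <- tab$aa[c1[clean]] != "*" & tab$aa[c2[clean]] != "*"
  c1 <- c1[clean]; c2 <- c2[clean]
  S <- (sum(tab$syn_sites[c1]) + sum(tab$syn_sites[c2])) / 2
  N <- 3 * length(c1) - S
  sd <- nd <- 0
  for (i in which(c1 != c2)) {
    d <- codon_pair_diffs(c1[i], c2[i], tab)
    sd <- sd + d[1]; nd <- nd + d[2]
  }
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(ps); ka <- jc(pn)
  saturated <- ps >= 0.75 || pn >= 0.75
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  structure(list(ka = ka, ks = ks, ratio = ratio,
                 syn_sites = S, nonsyn_sites = N,
                 syn_diffs = sd, nonsyn_diffs = nd,
                 n_codons = length(c1), saturated = saturated,
                 excluded = isTRUE(!is.na(ks) && ks < ks_floor) ||
                   is.na(ks)),
            class = "sg_kaks")
}

#' @export
print.sg_kaks <- function(x, ...) {
  cat(sprintf(
    "NG86: Ka = %.4g, Ks = %.4g, Ka/Ks = %.4g (%d codons%s%s)\n",
    x$ka, x$ks, x$ratio, x$n_codons,
    if (x$saturated) ", saturated" else "",
    if (x$excluded) ", excluded" else ""))
  invisible(x)
}

#' Filter Ka/Ks estimates and compare group distributions
#'
#' Drops excluded (`Ks < ks_floor`) and saturated estimates with logged
#' counts, summarizes Ka/Ks per group and runs two-tailed Wilcoxon rank-sum
#' tests between all group pairs with BH adjustment. Groups with fewer than
#' three retained values are skipped with a warning.
#'
#' @param results list of `sg_kaks` objects.
#' @param groups character group label per result (e.g. subgenome).
#' @return list: `table` (per-pair values with retention flags), `summary`
#'   (per-group n and medians), `tests` (pair, p, p_adj), `n_excluded`,
#'   `n_saturated`.
#' @export
filter_and_summarize <- function(results, groups) {
  stopifnot(length(results) == length(groups))
  tab <- data.frame(
    group = groups,
    ka = vapply(results, `[[`, numeric(1), "ka"),
    ks = vapply(results, `[[`, numeric(1), "ks"),
    ratio = vapply(results, `[[`, numeric(1), "ratio"),
    saturated = vapply(results, `[[`, logical(1), "saturated"),
    excluded = vapply(results, `[[`, logical(1), "excluded"),
    stringsAsFactors = FALSE)
  n_exc <- sum(tab$excluded & !tab$saturated)
  n_sat <- sum(tab$saturated)
  keep <- tab[!tab$excluded & !tab$saturated & !is.na(tab$ratio), ,
              drop = FALSE]
  if (n_exc + n_sat > 0)
    sg_log(n_exc, " excluded (Ks below floor) and ", n_sat,
           " saturated estimates dropped")
  sizes <- table(keep$group)
  small <- names(sizes)[sizes < 3]
  if (length(small) > 0) {
    warning("group(s) skipped with < 3 retained values: ",
            paste(small, collapse = ", "))
    keep <- keep[!(keep$group %in% small), , drop = FALSE]
  }
  gs <- sort(unique(keep$group))
  summary <- do.call(rbind, lapply(gs, function(g) {
    v <- keep$ratio[keep$group == g]
    data.frame(group = g, n = length(v), median_ratio = median(v),
               median_ka = median(keep$ka[keep$group == g]),
               median_ks = median(keep$ks[keep$group == g]),
               stringsAsFactors = FALSE)
  }))
  tests <- NULL
  if (length(gs) >= 2) {
    pr <- utils::combn(gs, 2)
    tests <- do.call(rbind, apply(pr, 2, function(p2) {
      p <- suppressWarnings(
        wilcox.test(keep$ratio[keep$group == p2[1]],
                    keep$ratio[keep$group == p2[2]],
                    alternative = "two.sided")$p.value)
      data.frame(pair = paste(p2, collapse = " vs "), p = p,
                 stringsAsFactors = FALSE)
    }))
    tests$p_adj <- p.adjust(tests$p, method = "BH")
    rownames(tests) <- NULL
  }
  list(table = tab, summary = summary, tests = tests,
       n_excluded = n_exc, n_saturated = n_sat)
}
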