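# Independent oracles used to cross-check the package implementations.
# These deliberately use brute force / enumeration / quadrature, never the
# code paths they validate.

# All-positions Hamming scan over both strands; returns every placement
# achieving the minimum mismatch count <= max_mm.
brute_hamming_scan <- function(frag, target, max_mm) {
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  f <- nchar(frag)
  hits <- NULL
  for (cn in names(target)) {
    tv <- strsplit(target[[cn]], "")[[1]]
    for (strand in c("+", "-")) {
      fv <- strsplit(if (strand == "+") frag else rc(frag), "")[[1]]
      L <- length(tv)
      if (L < f) next
      for (s in 0:(L - f)) {
        tt <- tv[(s + 1):(s + f)]
        mm <- sum(tt != fv | tt == "N")
        if (mm <= max_mm)
          hits <- rbind(hits, data.frame(chrom = cn, start = s,
                                         strand = strand, mismatches = mm,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(hits)) return(hits)
  hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
}

# naive per-window sorted-median oracle
naive_window_medians <- function(depth, size, step) {
  starts <- seq(0, length(depth) - 1, by = step)
  starts <- starts[starts < length(depth)]
  vapply(starts, function(s) {
    w <- sort(depth[(s + 1):min(s + size, length(depth))])
    n <- length(w)
    if (n %% 2 == 1) w[(n + 1) / 2] else (w[n / 2] + w[n / 2 + 1]) / 2
  }, numeric(1))
}

# chi-squared(1) survival function by adaptive quadrature on the density,
# written out explicitly (gamma(1/2) = sqrt(pi))
chisq1_sf_quad <- function(x) {
  dens <- function(t) t^(-0.5) * exp(-t / 2) / sqrt(2 * pi)
  vapply(x, function(xi) {
    if (xi <= 0) return(1)
    stats::integrate(dens, xi, Inf, rel.tol = 1e-13,
                     abs.tol = 0)$value
  }, numeric(1))
}

# one-tailed Fisher p by explicit enumeration of the hypergeometric tail
fisher_one_tail_enum <- function(cx, cy, lx, ly) {
  k <- cx + cy
  support <- max(0, k - ly):min(k, lx)
  logp <- lchoose(lx, support) + lchoose(ly, k - support) -
    lchoose(lx + ly, k)
  sum(exp(logp[support >= cx]))
}

# exact Wilcoxon rank-sum p by full enumeration of group assignments
wilcox_perm_enum <- function(x, y, alternative = "greater") {
  all <- c(x, y)
  n <- length(all); nx <- length(x)
  r <- rank(all)
  W_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  W_all <- apply(combs, 2, function(id) sum(r[id]) - nx * (nx + 1) / 2)
  pg <- mean(W_all >= W_obs)
  pl <- mean(W_all <= W_obs)
  switch(alternative,
         greater = pg,
         less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

# brute-force average-linkage (UPGMA) merge heights from a distance matrix
upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (j <= i) next
      if (d[active[i], active[j]] < bh) {
        bh <- d[active[i], active[j]]
        best <- c(active[i], active[j])
      }
    }
    heights <- c(heights, bh)
    a <- best[1]; b <- best[2]
    for (k in setdiff(active, best)) {
      nv <- (d[a, k] * sizes[a] + d[b, k] * sizes[b]) / (sizes[a] + sizes[b])
      d[a, k] <- d[k, a] <- nv
    }
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  sort(heights)
}

# enumeration of maximal valid syntenic runs: every window of placements on
# one (target, strand) with monotone coordinates and bounded index gaps,
# kept only if not extendable
enum_max_runs <- function(pl, min_frag, max_gap) {
  pl <- pl[pl$unique, , drop = FALSE]
  out <- NULL
  for (tc in unique(pl$chrom)) for (st in c("+", "-")) {
    sub <- pl[pl$chrom == tc & pl$strand == st, , drop = FALSE]
    sub <- sub[order(sub$index), , drop = FALSE]
    m <- nrow(sub)
    if (m == 0) next
    valid <- function(i, j) {
      if (j < i) return(FALSE)
      if (j == i) return(TRUE)
      idx <- sub$index[i:j]; ts <- sub$tstart[i:j]
      gaps <- diff(idx) - 1
      mono <- if (st == "+") all(diff(ts) > 0) else all(diff(ts) < 0)
      all(gaps <= max_gap) && mono
    }
    for (i in seq_len(m)) for (j in i:m) {
      if (!valid(i, j)) next
      if (i > 1 && valid(i - 1, j)) next
      if (j < m && valid(i, j + 1)) next
      if (j - i + 1 < min_frag) next
      out <- rbind(out, data.frame(target_chrom = tc, orientation = st,
                                   fragment_count = j - i + 1,
                                   target_start = min(sub$tstart[i:j]),
                                   target_end = max(sub$tend[i:j]),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}
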