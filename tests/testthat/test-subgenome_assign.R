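test_that("fragmenting tiles chromosomes and drops the remainder", {
  g <- c(c1 = strrep("ACGTT", 50)) # 250 bp
  fr <- fragment_genome(g, 100)
  expect_equal(nrow(fr), 2)
  expect_equal(fr$start, c(0, 100))
  expect_equal(fr$end, c(100, 200))
  # reassembly: fragments plus remainder reconstruct the chromosome
  expect_identical(paste0(paste(fr$seq, collapse = ""),
                          substr(g[[1]], 201, 250)), g[[1]])
  expect_warning(fragment_genome(c(tiny = "ACGTACGTACGTACGTACGTACG"), 100),
                 "shorter")
})

test_that("the seeded mapper agrees with a brute-force Hamming scan", {
  set.seed(41)
  hx <- small_hexaploid(seed = 11, chrom_length = 1.5e3)
  target <- hx$hex$genome[c("1A", "1C", "1D")] # ~4.5 kb total
  frags <- fragment_genome(hx$anc$root["1R"], 100)
  pick <- sample(nrow(frags), 12)
  for (max_mm in c(0, 2, 5)) {
    pl <- map_fragments(frags[pick, ], target, max_mm)
    for (k in seq_along(pick)) {
      oracle <- brute_hamming_scan(frags$seq[pick[k]], target, max_mm)
      got <- pl[pl$index == frags$index[pick[k]], , drop = FALSE]
      if (is.null(oracle)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(nrow(got), nrow(oracle))
        o <- oracle[order(oracle$chrom, oracle$start, oracle$strand), ]
        g2 <- got[order(got$chrom, got$tstart, got$strand), ]
        expect_equal(g2$chrom, o$chrom)
        expect_equal(g2$tstart, o$start)
        expect_equal(g2$strand, o$strand)
        expect_equal(g2$mismatches, o$mismatches)
      }
    }
  }
})

test_that("mapper: self-mapping identity, N fragments, strand symmetry", {
  hx <- small_hexaploid(seed = 5, chrom_length = 2e3)
  g <- hx$anc$A
  fr <- fragment_genome(g, 100)
  pl <- map_fragments(fr, g, 0)
  expect_equal(sum(pl$mismatches), 0)
  # uniqueness fraction equals exhaustive substring occurrence count
  n_unique_true <- sum(vapply(fr$seq, function(s) {
    fwd <- sum(vapply(names(g), function(cn)
      length(gregexpr(s, g[[cn]], fixed = TRUE)[[1]]) *
        (gregexpr(s, g[[cn]], fixed = TRUE)[[1]][1] != -1), numeric(1)))
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                       collapse = ""))
    rev_n <- sum(vapply(names(g), function(cn)
      length(gregexpr(rc, g[[cn]], fixed = TRUE)[[1]]) *
        (gregexpr(rc, g[[cn]], fixed = TRUE)[[1]][1] != -1), numeric(1)))
    (fwd + rev_n) == 1
  }, logical(1)))
  expect_equal(sum(pl$unique), n_unique_true)

  allN <- data.frame(source_chrom = "x", index = 1, start = 0, end = 100,
                     seq = strrep("N", 100), stringsAsFactors = FALSE)
  expect_equal(nrow(map_fragments(allN, g, 5)), 0)

  # reverse-complemented target flips orientation and mirrors coordinates
  rc_target <- setNames(chartr("ACGT", "TGCA",
                               vapply(strsplit(g, ""), function(x)
                                 paste(rev(x), collapse = ""), "")),
                        names(g))
  a <- map_fragments(fr[1:20, ], g, 2)
  b <- map_fragments(fr[1:20, ], rc_target, 2)
  a <- a[order(a$index), ]; b <- b[order(b$index), ]
  expect_equal(a$index, b$index)
  expect_true(all(a$strand != b$strand))
  expect_equal(b$tstart, nchar(g[a$chrom]) - a$tend, ignore_attr = TRUE)
  expect_equal(a$mismatches, b$mismatches)
})

test_that("syntenic block calling enforces the five-fragment threshold", {
  mk <- function(idx, tstart, chrom = "1X", strand = "+", unique = TRUE)
    data.frame(source_chrom = "1R", index = idx, start = (idx - 1) * 100,
               end = idx * 100, chrom = chrom, tstart = tstart,
               tend = tstart + 100, strand = strand, mismatches = 0,
               n_best_locations = 1, unique = unique,
               stringsAsFactors = FALSE)
  four <- mk(1:4, (1:4) * 100)
  expect_equal(nrow(call_syntenic_blocks(four, 5, 1)$blocks), 0)
  six <- mk(1:6, (1:6) * 100)
  b6 <- call_syntenic_blocks(six, 5, 1)$blocks
  expect_equal(nrow(b6), 1)
  expect_equal(b6$fragment_count, 6)
  expect_equal(b6$target_start, 100)
  expect_equal(b6$target_end, 700)
  expect_equal(b6$source_start, 0)
  expect_equal(b6$source_end, 600)
})

test_that("block boundaries match exhaustive run enumeration", {
  # a 7-run with one interleaved off-chromosome placement (gap tolerance 1)
  pl <- data.frame(
    source_chrom = "1R",
    index = c(1, 2, 3, 4, 5, 6, 7, 8),
    start = c(0, 100, 200, 300, 400, 500, 600, 700),
    end = c(100, 200, 300, 400, 500, 600, 700, 800),
    chrom = c("1X", "1X", "1X", "2X", "1X", "1X", "1X", "1X"),
    tstart = c(10, 120, 230, 5000, 450, 560, 670, 780),
    tend = c(110, 220, 330, 5100, 550, 660, 770, 880),
    strand = "+", mismatches = 0, n_best_locations = 1, unique = TRUE,
    stringsAsFactors = FALSE)
  got <- call_syntenic_blocks(pl, 5, 1)$blocks
  oracle <- enum_max_runs(pl, 5, 1)
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$fragment_count, oracle$fragment_count)
  expect_equal(got$target_start, oracle$target_start)
  expect_equal(got$target_end, oracle$target_end)

  # random placement lists against the oracle
  set.seed(7)
  for (rep in 1:5) {
    n <- 30
    rnd <- data.frame(
      source_chrom = "1R", index = sort(sample(1:45, n)),
      chrom = sample(c("1X", "2X"), n, TRUE),
      strand = sample(c("+", "-"), n, TRUE),
      mismatches = 0, n_best_locations = 1, unique = TRUE,
      stringsAsFactors = FALSE)
    rnd$start <- (rnd$index - 1) * 100; rnd$end <- rnd$index * 100
    rnd$tstart <- sample(1:5000, n); rnd$tend <- rnd$tstart + 100
    got <- call_syntenic_blocks(rnd, 4, 1)$blocks
    oracle <- enum_max_runs(rnd, 4, 1)
    n_oracle <- if (is.null(oracle)) 0 else nrow(oracle)
    expect_equal(nrow(got), n_oracle)
    if (n_oracle > 0) {
      key <- function(d) sort(paste(d$fragment_count, d$target_start,
                                    d$target_end))
      expect_equal(key(got), key(oracle))
    }
  }
})

test_that("similarity ranking assigns A/C/D by tercile with planted truth", {
  mk <- function(chrom, covered_frac, ident, L = 1000) {
    n <- round(covered_frac * L / 100)
    if (n == 0) return(NULL)
    data.frame(source_chrom = "1R", index = seq_len(n),
               start = 0, end = 100, chrom = chrom,
               tstart = (seq_len(n) - 1) * 100, tend = seq_len(n) * 100,
               strand = "+", mismatches = round((1 - ident) * 100),
               n_best_locations = 1, unique = TRUE, stringsAsFactors = FALSE)
  }
  target <- c(x = strrep("A", 1000), y = strrep("A", 1000),
              z = strrep("A", 1000))
  pl <- rbind(mk("x", 0.9, 1), mk("y", 0.5, 1), mk("z", 0.7, 1))
  asg <- assign_subgenomes(pl, target)
  expect_equal(unname(asg$assignment[c("x", "y", "z")]), c("A", "C", "D"))

  hx <- small_hexaploid(seed = 2, chrom_length = 1e5)
  frags <- fragment_genome(hx$anc$root, 100)
  pl <- map_fragments(frags, hx$hex$genome, 5)
  asg <- assign_subgenomes(pl, hx$hex$genome)
  truth <- hx$hex$truth$subgenome_of_chromosome
  expect_equal(unname(asg$assignment[names(truth)]), unname(truth))
})

test_that("diagnostic satellite motifs are densest in their own subgenome", {
  model <- small_model(chrom_length = 1e5, satellite_density = 80)
  anc <- simulate_ancestors(model, seed = 6)
  hex <- simulate_allohexaploid(anc, default_rearrangements(1e5)[0, ])
  frags <- fragment_genome(anc$root, 100)
  pl <- map_fragments(frags, hex$genome, 5)
  asg <- assign_subgenomes(pl, hex$genome)
  motifs <- model$satellite_motifs
  dens <- sapply(c("A", "C", "D"), function(lab) {
    chroms <- names(asg$assignment)[asg$assignment == lab]
    sapply(names(motifs), function(m) {
      hits <- sum(vapply(chroms, function(cn) {
        r <- gregexpr(motifs[[m]], hex$genome[[cn]], fixed = TRUE)[[1]]
        if (r[1] == -1) 0L else length(r)
      }, integer(1)))
      hits / sum(nchar(hex$genome[chroms]))
    })
  })
  # rows: motif owner; cols: assigned label; diagonal must dominate rows
  for (m in c("A", "C", "D"))
    expect_equal(names(which.max(dens[m, ])), m)
})

test_that("C-lineage divergence cannot raise C-chromosome similarity", {
  score_C <- function(dC) {
    model <- ancestor_model(n_chromosomes = 3, chrom_length = 5e4,
                            divergence = c(A = 0.02, C = dC, D = 0.05),
                            satellite_density = 0)
    anc <- simulate_ancestors(model, seed = 9)
    hex <- simulate_allohexaploid(anc, default_rearrangements(5e4)[0, ])
    pl <- map_fragments(fragment_genome(anc$root, 100), hex$genome, 5)
    asg <- assign_subgenomes(pl, hex$genome)
    mean(asg$report$similarity_score[grepl("C$", asg$report$target_chrom)])
  }
  s <- vapply(c(0.08, 0.12, 0.2), score_C, numeric(1))
  expect_true(all(diff(s) <= 0))
})

test_that("depth validation flags consistent ancestor affinity", {
  asg <- c(`1A` = "A", `1C` = "C", `1D` = "D")
  tab <- validate_by_depth(c(`1A` = 5, `1C` = 0.2, `1D` = 0.4), asg, "A")
  expect_true(attr(tab, "consistent"))
  expect_warning(z <- validate_by_depth(c(`1A` = 0, `1C` = 0, `1D` = 0),
                                        asg, "A"), "no depth")
  expect_false(attr(z, "consistent"))
  expect_warning(t2 <- validate_by_depth(c(`1A` = 1, `1C` = 1, `1D` = 1),
                                         asg, "A"), "tie")
  expect_false(attr(t2, "consistent"))
})
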