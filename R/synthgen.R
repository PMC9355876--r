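#' Ancestor model for the synthetic allohexaploid generator
#'
#' Describes three diverged ancestral genomes (A, C, D) derived from one
#' root sequence by i.i.d. substitutions, following the divergence hierarchy
#' ((A,D),C): the C lineage must be more diverged than A and D. Each
#' subgenome carries a diagnostic satellite motif overwritten at
#' Poisson-distributed positions (analogue of genome-specific tandem
#' repeats used to validate subgenome identity).
#'
#' @param n_chromosomes chromosomes per subgenome.
#' @param chrom_length chromosome length in bp.
#' @param divergence named numeric: per-site substitution proportion from the
#'   root for A, C and D. C must exceed A and D.
#' @param satellite_motifs named character: one diagnostic motif per
#'   subgenome (must be distinct).
#' @param satellite_density motif placements per Mb.
#' @return list of class `sg_ancestor_model`.
#' @export
ancestor_model <- function(n_chromosomes = 3,
                           chrom_length = 1e6,
                           divergence = c(A = 0.02, C = 0.15, D = 0.05),
                           satellite_motifs = c(
                             A = "ATTTAGGGATCGATTTAGGG",
                             C = "GGCCAATTGGCCAATTGGCC",
                             D = "CACGTGTTCACGTGTTCACG"),
                           satellite_density = 50) {
  if (any(divergence < 0) || any(divergence >= 0.75))
    sg_error("sg_config_error", "divergence must lie in [0, 0.75)")
  if (!all(c("A", "C", "D") %in% names(divergence)))
    sg_error("sg_config_error", "divergence needs names A, C, D")
  if (divergence["C"] < max(divergence[c("A", "D")]))
    sg_error("sg_config_error",
             "divergence ordering violated: C must be the most diverged lineage")
  if (anyDuplicated(satellite_motifs))
    sg_error("sg_config_error", "satellite motifs must be unique per subgenome")
  structure(list(n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length,
                 divergence = divergence,
                 satellite_motifs = satellite_motifs,
                 satellite_density = satellite_density),
            class = "sg_ancestor_model")
}

BASES <- c("A", "C", "G", "T")

# integer codes 1..4 -> DNA string
codes_to_seq <- function(x) paste(BASES[x], collapse = "")

#' Simulate diverged A/C/D ancestor genomes
#'
#' All three subgenomes descend from a single random root by i.i.d.
#' substitutions, uniform over the three alternative bases (Jukes-Cantor
#' style, no indels). Chromosomes are named `1A..nA`, `1C..nC`, `1D..nD`.
#'
#' @param model an [ancestor_model()].
#' @param seed integer RNG seed (the generator is a pure function of
#'   (model, seed)).
#' @return list with elements `A`, `C`, `D` (named character vectors of
#'   chromosome sequences) and `root` (the shared root genome).
#' @export
simulate_ancestors <- function(model, seed = 1L) {
  stopifnot(inherits(model, "sg_ancestor_model"))
  with_seed(seed, {
    L <- model$chrom_length
    n <- model$n_chromosomes
    root <- lapply(seq_len(n), function(i) sample.int(4L, L, replace = TRUE))
    out <- list()
    for (g in c("A", "C", "D")) {
      d <- model$divergence[[g]]
      chroms <- vapply(root, function(rc) {
        x <- rc
        if (d > 0) {
          idx <- which(runif(L) < d)
          if (length(idx) > 0) {
            shift <- sample.int(3L, length(idx), replace = TRUE)
            x[idx] <- ((x[idx] - 1L + shift) %% 4L) + 1L
          }
        }
        codes_to_seq(x)
      }, "")
      names(chroms) <- paste0(seq_len(n), g)
      motif <- model$satellite_motifs[[g]]
      n_sat <- rpois(n, model$satellite_density * L / 1e6)
      for (i in seq_len(n)) {
        if (n_sat[i] == 0) next
        pos <- sample.int(L - nchar(motif), n_sat[i])
        s <- chroms[i]
        for (p in pos) substr(s, p, p + nchar(motif) - 1L) <- motif
        chroms[i] <- s
      }
      out[[g]] <- chroms
    }
    out$root <- setNames(vapply(root, codes_to_seq, ""),
                         paste0(seq_len(n), "R"))
    out
  })
}

#' Default rearrangement event set
#'
#' The generator-scale analogue of the study system's inventory: two D-to-C
#' and four C-to-D translocations at the tetraploid stage (one of them
#' non-homoeologous), then one C-to-A translocation and one inversion on a C
#' chromosome at the hexaploid stage. Positions are fixed fractions of the
#' chromosome length; each event spans 5% of a chromosome.
#'
#' @param chrom_length chromosome length in bp (events scale with it).
#' @return data.frame of rearrangement events (kind, donor, src_chrom,
#'   src_start, src_end, dst_chrom, dst_start, dst_end, stage).
#' @export
default_rearrangements <- function(chrom_length = 1e6) {
  L <- chrom_length
  f <- function(x) round(x * L)
  ev <- function(kind, donor, sc, ss, se, dc, ds, de, stage)
    data.frame(kind = kind, donor = donor, src_chrom = sc,
               src_start = f(ss), src_end = f(se), dst_chrom = dc,
               dst_start = f(ds), dst_end = f(de), stage = stage,
               stringsAsFactors = FALSE)
  rbind(
    ev("translocation", "D", "1D", 0.10, 0.15, "1C", 0.10, 0.15, "tetraploid"),
    ev("translocation", "D", "2D", 0.30, 0.35, "2C", 0.30, 0.35, "tetraploid"),
    ev("translocation", "C", "1C", 0.50, 0.55, "1D", 0.50, 0.55, "tetraploid"),
    ev("translocation", "C", "2C", 0.60, 0.65, "2D", 0.60, 0.65, "tetraploid"),
    ev("translocation", "C", "3C", 0.20, 0.25, "3D", 0.20, 0.25, "tetraploid"),
    ev("translocation", "C", "3C", 0.70, 0.75, "2D", 0.80, 0.85, "tetraploid"),
    ev("translocation", "C", "1C", 0.80, 0.85, "1A", 0.80, 0.85, "hexaploid"),
    ev("inversion",     "C", "3C", 0.40, 0.50, "3C", 0.40, 0.50, "hexaploid"))
}

#' Assemble a synthetic allohexaploid genome with planted rearrangements
#'
#' The hexaploid is the union of the A, C and D ancestor chromosomes with
#' events applied in stage order (tetraploid before hexaploid). A
#' translocation copies the source ancestor segment onto the destination
#' interval (replacement; the destination sequence equals the source
#' ancestor segment exactly); an inversion reverse-complements its interval
#' in place. The truth table records the final coordinates of every event
#' and the subgenome of every chromosome.
#'
#' @param ancestors output of [simulate_ancestors()].
#' @param events data.frame as from [default_rearrangements()]; may be empty.
#' @return list with `genome` (named character vector) and `truth` (list:
#'   `events`, `subgenome_of_chromosome`).
#' @export
simulate_allohexaploid <- function(ancestors,
                                   events = default_rearrangements(
                                     nchar(ancestors$A[[1]]))) {
  genome <- c(ancestors$A, ancestors$C, ancestors$D)
  subg <- setNames(chrom_subgenome(names(genome)), names(genome))
  src_pool <- genome # pristine ancestor content, sources always read from here
  if (nrow(events) > 0) {
    lens <- nchar(genome)
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      if (!(e$src_chrom %in% names(genome)) ||
          !(e$dst_chrom %in% names(genome)))
        sg_error("sg_validation_error", "event ", i,
                 " references unknown chromosome")
      if (e$src_end > lens[[e$src_chrom]] || e$dst_end > lens[[e$dst_chrom]] ||
          e$src_start < 0 || e$dst_start < 0)
        sg_error("sg_validation_error", "event ", i, " out of bounds")
      if ((e$src_end - e$src_start) != (e$dst_end - e$dst_start))
        sg_error("sg_validation_error", "event ", i,
                 " source/destination lengths differ")
    }
    for (i in seq_len(nrow(events))) for (j in seq_len(nrow(events))) {
      if (j <= i) next
      a <- events[i, ]; b <- events[j, ]
      if (a$dst_chrom == b$dst_chrom &&
          a$dst_start < b$dst_end && b$dst_start < a$dst_end)
        sg_error("sg_validation_error",
                 "overlapping destinations for events ", i, " and ", j)
    }
    events <- events[order(match(events$stage, c("tetraploid", "hexaploid"))), ]
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      if (e$kind == "translocation") {
        seg <- substr(src_pool[[e$src_chrom]], e$src_start + 1L, e$src_end)
        s <- genome[[e$dst_chrom]]
        substr(s, e$dst_start + 1L, e$dst_end) <- seg
        genome[[e$dst_chrom]] <- s
      } else if (e$kind == "inversion") {
        s <- genome[[e$dst_chrom]]
        seg <- revcomp(substr(s, e$dst_start + 1L, e$dst_end))
        substr(s, e$dst_start + 1L, e$dst_end) <- seg
        genome[[e$dst_chrom]] <- s
      } else sg_error("sg_validation_error", "unknown event kind: ", e$kind)
    }
  }
  list(genome = genome,
       truth = list(events = events,
                    subgenome_of_chromosome = subg))
}

#' Simulate uniform shotgun reads with substitution errors
#'
#' Read count is `round(coverage * genome_length / read_length)`; start
#' positions are uniform over valid positions, strands random, substitution
#' errors i.i.d. per base. Read names encode the origin
#' (`r<i>|<chrom>|<start0>|<strand>`), which downstream recovery scoring may
#' parse from the emitted FASTQ.
#'
#' @param genome named character vector of chromosome sequences.
#' @param coverage fold coverage (> 0).
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error probability.
#' @param seed integer RNG seed.
#' @return data.frame with `id`, `seq`, `qual`, plus origin columns
#'   `chrom`, `start`, `strand`.
#' @export
simulate_reads <- function(genome, coverage, read_length = 100,
                           error_rate = 0.01, seed = 1L) {
  if (coverage <= 0) sg_error("sg_config_error", "coverage must be > 0")
  lens <- nchar(genome)
  if (read_length > min(lens))
    sg_error("sg_config_error",
             "read_length exceeds the shortest chromosome")
  with_seed(seed, {
    total <- sum(lens)
    n <- round(coverage * total / read_length)
    chrom <- sample(names(genome), n, replace = TRUE, prob = lens)
    start <- floor(runif(n) * (lens[chrom] - read_length + 1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- character(n)
    for (cn in unique(chrom)) {
      sel <- chrom == cn
      seqs[sel] <- substring(genome[[cn]], start[sel] + 1,
                             start[sel] + read_length)
    }
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
    if (error_rate > 0) {
      k <- rbinom(n, read_length, error_rate)
      for (i in which(k > 0)) {
        pos <- sample.int(read_length, k[i])
        s <- seqs[i]
        for (p in pos) {
          old <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(BASES, old), 1L)
        }
        seqs[i] <- s
      }
    }
    data.frame(id = sprintf("r%07d|%s|%d|%s", seq_len(n), chrom, start, strand),
               seq = seqs,
               qual = strrep("I", read_length),
               chrom = chrom, start = start, strand = strand,
               stringsAsFactors = FALSE)
  })
}

#' Simulate homoeolog-triad expression with planted bias
#'
#' Unbiased triads share a common organ-specific mean across the three
#' homoeologs; a planted fraction shifts one homoeolog (the triad's
#' direction) by `bias_log2fc` in every organ. Counts are negative binomial
#' with variance `mu + dispersion * mu^2`, converted to TPM assuming equal
#' gene lengths.
#'
#' @param n_triads number of triads.
#' @param n_organs number of organs (libraries).
#' @param bias_fraction fraction of triads with planted bias (0..1).
#' @param bias_log2fc log2 fold shift applied to the biased homoeolog.
#' @param dispersion negative-binomial dispersion phi (0 gives Poisson).
#' @param mean_tpm_meanlog,mean_tpm_sdlog lognormal parameters for the
#'   per-triad baseline expression mean.
#' @param seed integer RNG seed.
#' @return list with `tpm` and `counts` (gene x organ matrices), `lib_sizes`,
#'   `triads` (triad_id, gene_A, gene_C, gene_D) and `truth`
#'   (triad_id, biased, direction).
#' @export
simulate_triads <- function(n_triads = 1000, n_organs = 3,
                            bias_fraction = 0.2, bias_log2fc = 2,
                            dispersion = 0.01,
                            mean_tpm_meanlog = log(30), mean_tpm_sdlog = 1,
                            seed = 1L) {
  if (bias_fraction < 0 || bias_fraction > 1)
    sg_error("sg_config_error", "bias_fraction must lie in [0, 1]")
  with_seed(seed, {
    ids <- sprintf("T%05d", seq_len(n_triads))
    genes <- as.vector(t(outer(ids, c("A", "C", "D"), paste, sep = "_")))
    n_biased <- round(n_triads * bias_fraction)
    biased <- rep(FALSE, n_triads)
    biased[sample.int(n_triads, n_biased)] <- TRUE
    direction <- rep(NA_character_, n_triads)
    direction[biased] <- sample(c("A", "C", "D"), n_biased, replace = TRUE)
    base_mu <- exp(rnorm(n_triads, mean_tpm_meanlog, mean_tpm_sdlog))
    organ_eff <- exp(rnorm(n_organs, 0, 0.5))
    counts <- matrix(0, nrow = 3 * n_triads, ncol = n_organs,
                     dimnames = list(genes, paste0("organ", seq_len(n_organs))))
    for (o in seq_len(n_organs)) {
      mu <- rep(base_mu * organ_eff[o], each = 3) # A, C, D per triad
      if (n_biased > 0) {
        hom <- match(direction, c("A", "C", "D"))
        idx <- (which(biased) - 1) * 3 + hom[biased]
        mu[idx] <- mu[idx] * 2^bias_log2fc
      }
      counts[, o] <- if (dispersion > 0)
        rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      else rpois(length(mu), mu)
    }
    lib <- colSums(counts)
    tpm <- sweep(counts, 2, lib, "/") * 1e6
    list(tpm = tpm, counts = counts, lib_sizes = lib,
         triads = data.frame(triad_id = ids,
                             gene_A = paste0(ids, "_A"),
                             gene_C = paste0(ids, "_C"),
                             gene_D = paste0(ids, "_D"),
                             stringsAsFactors = FALSE),
         truth = data.frame(triad_id = ids, biased = biased,
                            direction = direction, stringsAsFactors = FALSE))
  })
}

#' Simulate ortholog presence/absence with subgenome-specific loss
#'
#' Independent Bernoulli loss per gene per subgenome at the stated rates.
#'
#' @param n_genes number of conserved ortholog anchors.
#' @param loss_rate named numeric loss probability per subgenome.
#' @param seed integer RNG seed.
#' @return list with `pav` (gene x subgenome 0/1 presence matrix) and
#'   `truth` (list of lost gene ids per subgenome).
#' @export
simulate_pav <- function(n_genes = 10000,
                         loss_rate = c(A = 0.1, C = 0.2, D = 0.1),
                         seed = 1L) {
  if (any(loss_rate < 0) || any(loss_rate > 1))
    sg_error("sg_config_error", "loss rates must lie in [0, 1]")
  with_seed(seed, {
    genes <- sprintf("G%06d", seq_len(n_genes))
    pav <- sapply(names(loss_rate), function(g)
      1L - rbinom(n_genes, 1L, loss_rate[[g]]))
    rownames(pav) <- genes
    list(pav = pav,
         truth = lapply(setNames(nm = colnames(pav)),
                        function(g) genes[pav[, g] == 0]))
  })
}

#' Simulate genotypes with exponential LD decay and a binary trait
#'
#' SNPs sit on one coordinate axis; haplotype alleles follow a copying chain
#' in which the allele at a SNP copies the previous SNP's allele with
#' probability `exp(-d / ld_block_length)` (d = inter-SNP distance), so
#' adjacent-allele correlation decays exponentially and pairwise r-squared
#' approximately follows `exp(-2 d / ld_block_length)`. Samples are drawn
#' from a predominantly selfing population: with probability `inbreeding`
#' a sample is homozygous at every locus (its two haplotypes are one
#' haplotype doubled), matching the low heterozygosity of inbred crop
#' panels. A binary trait is determined by the trait-locus genotype plus
#' symmetric noise.
#'
#' @param n_samples diploid samples (>= 20).
#' @param n_snps SNP count.
#' @param maf_range uniform range for per-SNP allele frequencies.
#' @param ld_block_length correlation length scale in bp (0 gives
#'   independent SNPs).
#' @param region_length total axis length in bp.
#' @param trait_locus index of the causal SNP (default: middle SNP).
#' @param inbreeding probability that a sample is fully homozygous (selfed
#'   lineage).
#' @param penetrance P(case | carrier of the alternate allele); non-carriers
#'   are cases with probability 1 - penetrance.
#' @param seed integer RNG seed.
#' @return list with `variants`, `gt` (character matrix variants x samples),
#'   `dosage` (numeric matrix), `positions`, `phenotype` (data.frame) and
#'   `truth` (trait locus index).
#' @export
simulate_genotypes <- function(n_samples = 100, n_snps = 500,
                               maf_range = c(0.2, 0.5),
                               ld_block_length = 1e5,
                               region_length = 5e6,
                               trait_locus = NULL, inbreeding = 0.95,
                               penetrance = 0.8, seed = 1L) {
  if (n_samples < 20) sg_error("sg_config_error", "n_samples must be >= 20")
  with_seed(seed, {
    pos <- sort(sample.int(region_length, n_snps))
    p <- runif(n_snps, maf_range[1], maf_range[2])
    H <- matrix(0L, nrow = n_snps, ncol = 2 * n_samples)
    H[1, ] <- rbinom(2 * n_samples, 1L, p[1])
    for (j in 2:n_snps) {
      rho <- if (ld_block_length > 0)
        exp(-(pos[j] - pos[j - 1]) / ld_block_length) else 0
      copy <- runif(2 * n_samples) < rho
      fresh <- rbinom(2 * n_samples, 1L, p[j])
      H[j, ] <- ifelse(copy, H[j - 1, ], fresh)
    }
    h1 <- H[, seq(1, 2 * n_samples, by = 2), drop = FALSE]
    h2 <- H[, seq(2, 2 * n_samples, by = 2), drop = FALSE]
    selfed <- runif(n_samples) < inbreeding
    h2[, selfed] <- h1[, selfed]
    dosage <- h1 + h2
    samples <- sprintf("S%03d", seq_len(n_samples))
    colnames(dosage) <- samples
    if (is.null(trait_locus)) trait_locus <- ceiling(n_snps / 2)
    carrier <- dosage[trait_locus, ] >= 1
    pheno <- rbinom(n_samples, 1L, ifelse(carrier, penetrance, 1 - penetrance))
    gt <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L], nrow = n_snps,
                 dimnames = list(NULL, samples))
    variants <- data.frame(chrom = "1A", pos = pos,
                           ref = "A", alt = "G",
                           qual = 100, qd = 25, fs = 1, mq = 60,
                           stringsAsFactors = FALSE)
    list(variants = variants, gt = gt, dosage = dosage, positions = pos,
         phenotype = data.frame(sample = samples, trait = pheno,
                                stringsAsFactors = FALSE),
         truth = list(trait_locus = trait_locus))
  })
}

#' Toy gene models on a regular grid
#'
#' Places single-exon gene/mRNA/CDS triples at regular intervals along each
#' chromosome — enough structure to exercise GFF3 I/O and gene-keyed tables
#' without modeling real gene architecture.
#'
#' @param genome named character vector of chromosome sequences.
#' @param gene_length gene span in bp.
#' @param spacing distance between gene starts in bp.
#' @return data.frame in the [read_gff3_lite()] layout.
#' @export
gene_grid <- function(genome, gene_length = 3000, spacing = 10000) {
  out <- lapply(names(genome), function(cn) {
    L <- nchar(genome[[cn]])
    starts <- seq(0, L - gene_length, by = spacing)
    if (length(starts) == 0) return(NULL)
    ids <- sprintf("%s.g%04d", cn, seq_along(starts))
    do.call(rbind, lapply(seq_along(starts), function(i)
      data.frame(chrom = cn,
                 start = starts[i], end = starts[i] + gene_length,
                 strand = c("+", "-")[1 + i %% 2],
                 type = c("gene", "mRNA", "CDS"),
                 id = paste0(ids[i], c("", ".m1", ".m1.cds")),
                 parent = c(NA, ids[i], paste0(ids[i], ".m1")),
                 stringsAsFactors = FALSE)))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
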