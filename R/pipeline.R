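#' Truth translocation segments from a generator truth table
#'
#' Converts planted translocation events into the segment representation
#' used by [call_segments()] (destination coordinates, donor and host
#' subgenomes, homoeologous class from the group indices). Inversions are
#' omitted: they move no donor content between subgenomes.
#'
#' @param truth truth list from [simulate_allohexaploid()].
#' @return data.frame of segments.
#' @export
truth_translocation_segments <- function(truth) {
  ev <- truth$events
  ev <- ev[ev$kind == "translocation", , drop = FALSE]
  data.frame(chrom = ev$dst_chrom,
             start = ev$dst_start, end = ev$dst_end,
             donor_subgenome = ev$donor,
             host_subgenome = chrom_subgenome(ev$dst_chrom),
             donor_chrom = ev$src_chrom,
             class = ifelse(chrom_group(ev$src_chrom) ==
                              chrom_group(ev$dst_chrom),
                            "homoeologous", "non-homoeologous"),
             stringsAsFactors = FALSE)
}

#' Recovery metrics for predicted segments against planted truth
#'
#' A predicted segment matches a truth segment when they overlap on the
#' same chromosome and agree on the donor subgenome (when both carry one).
#' Boundary error per matched event is the larger of the start and end
#' offsets.
#'
#' @param predicted data.frame of called segments.
#' @param truth data.frame of truth segments
#'   ([truth_translocation_segments()]).
#' @return list: recall, precision (NA when nothing was predicted),
#'   boundary_error (per matched truth event), n_truth, n_predicted.
#' @export
recovery_metrics <- function(predicted, truth) {
  n_t <- nrow(truth); n_p <- nrow(predicted)
  if (n_t == 0)
    return(list(recall = NA_real_,
                precision = if (n_p == 0) NA_real_ else 0,
                boundary_error = numeric(0), n_truth = 0, n_predicted = n_p))
  matched_t <- logical(n_t)
  matched_p <- logical(n_p)
  berr <- rep(NA_real_, n_t)
  for (i in seq_len(n_t)) {
    for (j in seq_len(n_p)) {
      if (predicted$chrom[j] != truth$chrom[i]) next
      if (!is.null(predicted$donor_subgenome) &&
          !is.null(truth$donor_subgenome) &&
          predicted$donor_subgenome[j] != truth$donor_subgenome[i]) next
      if (predicted$start[j] < truth$end[i] &&
          truth$start[i] < predicted$end[j]) {
        e <- max(abs(predicted$start[j] - truth$start[i]),
                 abs(predicted$end[j] - truth$end[i]))
        if (!matched_t[i] || e < berr[i]) berr[i] <- e
        matched_t[i] <- TRUE
        matched_p[j] <- TRUE
      }
    }
  }
  list(recall = mean(matched_t),
       precision = if (n_p == 0) NA_real_ else mean(matched_p),
       boundary_error = berr[matched_t],
       n_truth = n_t, n_predicted = n_p)
}

#' Run the full synthetic study end to end
#'
#' Simulates an allohexaploid dataset (ancestors, rearranged hexaploid,
#' ancestor reads, triad expression, PAV table, genotypes), runs every
#' analysis stage and scores recovery against the truth tables. Stage
#' outputs are optionally written as plain TSV/BED/FASTA files with an MD5
#' manifest.
#'
#' @param config [pipeline_config()]; generator-scale depth windows
#'   (10 kb / 5 kb) are the natural choice at the default genome scale.
#' @param model [ancestor_model()] for the genome stage.
#' @param seed integer master seed; stage seeds derive from it.
#' @param coverage fold coverage for the ancestor read sets.
#' @param out_dir optional output directory.
#' @return list of class `sg_run`: per-stage results, `report` (named
#'   numeric summary metrics) and `manifest`.
#' @export
run_all <- function(config = pipeline_config(window_size = 1e4,
                                             window_step = 5e3),
                    model = ancestor_model(),
                    seed = 1L, coverage = 5, out_dir = NULL) {
  seed <- as.integer(seed)
  t0 <- Sys.time()
  anc <- simulate_ancestors(model, seed = seed)
  hex <- simulate_allohexaploid(anc)
  genome <- hex$genome

  # stage: subgenome assignment from root-reference fragments
  frags <- fragment_genome(anc$root, config$fragment_length)
  pl <- map_fragments(frags, genome, config$max_mismatches)
  blocks <- call_syntenic_blocks(pl, config$min_block_fragments,
                                 config$max_gap_fragments)
  asg <- assign_subgenomes(pl, genome)
  truth_sub <- hex$truth$subgenome_of_chromosome
  acc <- mean(asg$assignment[names(truth_sub)] == truth_sub) * 100

  # stage: depth-based translocation detection (C and D ancestor reads)
  segs <- NULL
  depth_means <- list()
  for (donor in c("C", "D")) {
    reads <- simulate_reads(anc[[donor]], coverage = coverage,
                            error_rate = 0.01, seed = seed + match(donor, LETTERS))
    rp <- map_fragments(reads[, c("id", "seq", "chrom", "start")],
                        genome, config$max_mismatches)
    prof <- compute_depth(rp, genome)
    depth_means[[donor]] <- vapply(prof, mean, numeric(1))
    win <- window_medians(prof, config$window_size, config$window_step)
    sg <- call_segments(win, asg$assignment, donor,
                        high_frac = config$high_frac,
                        max_gap_windows = 1, placements = rp)
    segs <- rbind(segs, sg)
  }
  truth_segs <- truth_translocation_segments(hex$truth)
  rec <- recovery_metrics(segs, truth_segs)
  depth_check <- validate_by_depth(depth_means[["C"]], asg$assignment, "C")

  # stage: triad expression bias
  tri <- simulate_triads(seed = seed + 11L)
  tm <- build_triad_matrix(tri$tpm, tri$triads)
  bias <- call_triad_bias(tri$counts, tri$triads,
                          fc_gate = config$fc_gate,
                          epsilon = config$epsilon_tpm)
  dom <- dominance_summary(bias, tri$tpm, tri$triads)
  planted_frac <- mean(tri$truth$biased)

  # stage: gene fractionation
  pav <- simulate_pav(seed = seed + 12L)
  losses <- pav_counts(pav$pav)
  frac_test <- chisq_two_cell(losses$losses[["C"]], losses$losses[["A"]])

  # stage: variants, LD, association threshold
  gen <- simulate_genotypes(seed = seed + 13L)
  gbs <- filter_gbs_snps(list(variants = cbind(gen$variants,
                                               allele_count = 2,
                                               is_indel = FALSE),
                              gt = gen$gt))
  ld <- ld_r2_decay(gen$dosage, gen$positions, window = config$ld_window,
                    threshold = config$ld_r2_threshold)
  thr <- bonferroni_neglog_threshold(config$alpha, nrow(gen$variants))
  ctg <- contig_stats(unname(nchar(genome)))

  report <- c(assignment_accuracy_pct = acc,
              transloc_recall = rec$recall,
              transloc_precision = rec$precision,
              transloc_boundary_error_bp = if (length(rec$boundary_error))
                max(rec$boundary_error) else NA_real_,
              depth_validation_consistent = as.numeric(attr(depth_check,
                                                            "consistent")),
              triad_fraction_planted = planted_frac,
              triad_fraction_estimated = dom$fraction_biased,
              pav_chi2_C_vs_A = frac_test$chi2,
              gbs_retained = gbs$report$retained,
              ld_decay_bp = ld$decay_distance,
              assoc_threshold = thr,
              n50_bp = ctg$n50)

  run <- list(config = config, seed = seed,
              assignment = asg, blocks = blocks,
              segments = segs, truth = hex$truth,
              recovery = rec, depth_check = depth_check,
              triads = list(matrix = tm, bias = bias, dominance = dom,
                            truth = tri$truth),
              fractionation = list(losses = losses, test = frac_test),
              variants = list(gbs_report = gbs$report, ld = ld,
                              threshold = thr, contig = ctg),
              report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome, file.path(out_dir, "hexaploid.fa"))
    write.table(asg$report, file.path(out_dir, "similarity_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(segs) > 0)
      write_bed(segs[, c("chrom", "start", "end", "donor_subgenome",
                         "host_subgenome", "class")],
                file.path(out_dir, "segments.bed"))
    write.table(data.frame(metric = names(report), value = unname(report)),
                file.path(out_dir, "report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    run$manifest <- data.frame(file = basename(files),
                               md5 = unname(tools::md5sum(files)),
                               stringsAsFactors = FALSE)
  }
  run$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(run) <- "sg_run"
  run
}

#' @export
print.sg_run <- function(x, ...) {
  cat("synthetic allohexaploid study (seed ", x$seed, ")\n", sep = "")
  m <- x$report
  for (k in names(m))
    cat(sprintf("  %-32s %s\n", k, format(m[[k]], digits = 4)))
  invisible(x)
}
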