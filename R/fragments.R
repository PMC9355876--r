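#' Tile a genome into non-overlapping fragments
#'
#' Each chromosome yields `floor(L / fragment_length)` fragments at offsets
#' 0, f, 2f, ...; the trailing remainder shorter than `fragment_length` is
#' dropped and counted in the log. Chromosomes shorter than one fragment
#' yield zero fragments with a warning.
#'
#' @param genome named character vector of chromosome sequences.
#' @param fragment_length fragment size in bp (>= 20).
#' @return data.frame with columns `source_chrom`, `index` (1-based within
#'   chromosome), `start`, `end` (0-based half-open) and `seq`.
#' @export
fragment_genome <- function(genome, fragment_length = 100) {
  if (fragment_length < 20)
    sg_error("sg_config_error", "fragment_length must be >= 20")
  lens <- nchar(genome)
  short <- lens < fragment_length
  if (any(short))
    warning("chromosome(s) shorter than fragment_length yield no fragments: ",
            paste(names(genome)[short], collapse = ", "))
  dropped <- sum(lens %% fragment_length)
  if (dropped > 0)
    sg_log(dropped, " trailing bp dropped while fragmenting")
  out <- lapply(names(genome), function(cn) {
    nfrag <- lens[[cn]] %/% fragment_length
    if (nfrag == 0) return(NULL)
    start <- (seq_len(nfrag) - 1) * fragment_length
    data.frame(source_chrom = cn, index = seq_len(nfrag),
               start = start, end = start + fragment_length,
               seq = substring(genome[[cn]], start + 1,
                               start + fragment_length),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Map fragments (or reads) onto a target genome
#'
#' Exact-seed, Hamming-verified placement on both strands. For every
#' fragment all placements achieving the minimum mismatch count (at most
#' `max_mismatches`) are reported; `n_best_locations` counts them, and a
#' placement is `unique` iff that count is 1. The seed length defaults to
#' `min(31, floor(len / (max_mismatches + 1)))`, which by the pigeonhole
#' principle makes the search equivalent to an all-positions Hamming scan.
#'
#' @param fragments data.frame with a `seq` column (e.g. from
#'   [fragment_genome()] or [simulate_reads()]); other columns are carried
#'   through.
#' @param target named character vector of target chromosome sequences.
#' @param max_mismatches maximum Hamming distance for a reported placement.
#' @param seed_length optional override of the seed length.
#' @return data.frame: carried-through fragment columns plus `chrom`,
#'   `tstart`, `tend`, `strand`, `mismatches`, `n_best_locations`, `unique`.
#' @export
map_fragments <- function(fragments, target, max_mismatches = 5,
                          seed_length = NULL) {
  stopifnot(is.data.frame(fragments), "seq" %in% colnames(fragments))
  lens <- nchar(fragments$seq)
  if (is.null(seed_length))
    seed_length <- max(1L, min(31L, min(lens) %/% (max_mismatches + 1L)))
  hits <- cpp_map_fragments(unname(target), fragments$seq,
                            as.integer(max_mismatches),
                            as.integer(seed_length))
  keep_cols <- setdiff(colnames(fragments), "seq")
  carried <- fragments[, keep_cols, drop = FALSE]
  clash <- intersect(colnames(carried),
                     c("chrom", "tstart", "tend", "strand", "mismatches",
                       "n_best_locations", "unique"))
  colnames(carried)[match(clash, colnames(carried))] <-
    paste0(clash, ".orig")
  out <- cbind(carried[hits$fragment, , drop = FALSE],
               data.frame(chrom = names(target)[hits$chrom_index],
                          tstart = hits$start,
                          tend = hits$start + lens[hits$fragment],
                          strand = hits$strand,
                          mismatches = hits$mismatches,
                          n_best_locations = hits$n_best_locations,
                          stringsAsFactors = FALSE))
  out$unique <- out$n_best_locations == 1L
  rownames(out) <- NULL
  out
}
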