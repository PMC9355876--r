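#' Pipeline configuration
#'
#' Central container for the tunable constants shared across the analysis
#' stages. Defaults follow the study-scale procedure: 100-bp non-overlapping
#' reference fragments, syntenic blocks of at least five fragments, 1 Mb /
#' 0.5 Mb depth windows (generator-scale runs pass 10 kb / 5 kb), a Ks floor
#' of 0.01, a 50-SNP LD window with an r-squared decay threshold of 0.2 and
#' alpha = 0.01 for the Bonferroni-style association threshold.
#'
#' @param fragment_length fragment size in bp used to tile the ancestor
#'   reference before mapping.
#' @param min_block_fragments minimum colinear fragments in a syntenic block.
#' @param max_mismatches maximum Hamming mismatches for a fragment placement.
#' @param max_gap_fragments tolerated missing/interrupting fragments inside a
#'   syntenic block run.
#' @param window_size,window_step sliding-window geometry (bp) for depth
#'   profiling.
#' @param high_frac fraction of the donor's home-subgenome baseline median at
#'   or above which a window counts as donor-present.
#' @param ks_floor Ka/Ks estimates with Ks below this value are excluded.
#' @param ld_window number of downstream SNPs paired with each SNP for LD.
#' @param ld_r2_threshold r-squared level defining the LD decay distance.
#' @param alpha significance level for the association threshold.
#' @param epsilon_tpm pseudocount (TPM) added to both sides of homoeolog
#'   fold changes.
#' @param fc_gate minimum absolute log2 fold change for a bias call.
#' @param rng_seed integer seed recorded with the run.
#' @return a list of class `sg_config`.
#' @export
pipeline_config <- function(fragment_length = 100,
                            min_block_fragments = 5,
                            max_mismatches = 5,
                            max_gap_fragments = 1,
                            window_size = 1e6,
                            window_step = 5e5,
                            high_frac = 0.5,
                            ks_floor = 0.01,
                            ld_window = 50,
                            ld_r2_threshold = 0.2,
                            alpha = 0.01,
                            epsilon_tpm = 0.5,
                            fc_gate = 0.5,
                            rng_seed = 1L) {
  cfg <- list(fragment_length = fragment_length,
              min_block_fragments = min_block_fragments,
              max_mismatches = max_mismatches,
              max_gap_fragments = max_gap_fragments,
              window_size = window_size,
              window_step = window_step,
              high_frac = high_frac,
              ks_floor = ks_floor,
              ld_window = ld_window,
              ld_r2_threshold = ld_r2_threshold,
              alpha = alpha,
              epsilon_tpm = epsilon_tpm,
              fc_gate = fc_gate,
              rng_seed = as.integer(rng_seed))
  sizes <- c("fragment_length", "min_block_fragments", "window_size",
             "window_step", "ld_window")
  for (s in sizes)
    if (cfg[[s]] <= 0) sg_error("sg_config_error", s, " must be positive")
  if (cfg$window_step > cfg$window_size)
    sg_error("sg_config_error", "window_step must be <= window_size")
  if (cfg$ld_r2_threshold <= 0 || cfg$ld_r2_threshold >= 1)
    sg_error("sg_config_error", "ld_r2_threshold must lie in (0, 1)")
  class(cfg) <- "sg_config"
  cfg
}

#' Read a flat key=value configuration file
#'
#' Values are coerced to numeric where possible; explicit arguments passed in
#' `...` override file values (mirrors CLI-flag-over-config precedence).
#'
#' @param path path to a key=value text file (one pair per line, `#` comments).
#' @param ... overrides forwarded to [pipeline_config()].
#' @return a `sg_config` list.
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad))
    sg_error("sg_format_error", "malformed config line: ", lines[which(bad)[1]])
  vals <- lapply(kv, function(p) {
    v <- trimws(p[2])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, function(p) trimws(p[1]), "")
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}
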