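#' Simulation configuration for the synthetic three-group dataset
#'
#' Builds and validates the parameter set driving [simulate_dataset()] and the
#' individual generators. The defaults describe a desk-scale version of the
#' study design this package targets: three treatment groups (low glucose,
#' high glucose, high glucose + TTR) with three replicates each, planted
#' differential expression at a 4-fold effect, planted trend-reversal
#' transcripts whose two contrast fold changes have opposite sign, planted
#' co-expression modules tied to binary glucose/TTR traits, planted cis
#' neighbours around a 10 kb window, and planted lncRNA/miRNA/mRNA seed-site
#' triads.
#'
#' @param n_coding,n_lncrna Numbers of coding and lncRNA transcripts.
#' @param n_replicates_per_group Replicates per group (>= 2).
#' @param groups Ordered group labels; the second and third label define the
#'   two contrasts (group2 vs group1, group3 vs group2).
#' @param n_de_up,n_de_down Planted up-/down-regulated transcripts per
#'   contrast.
#' @param n_trend_reversal Transcripts planted with opposite-signed effects in
#'   the two contrasts (must satisfy
#'   `ceiling(n_trend_reversal/2) <= min(n_de_up, n_de_down)`).
#' @param log2fc_effect Planted effect magnitude on the log2(FPKM+1) scale.
#' @param noise_sd Standard deviation of log2-scale replicate noise.
#' @param n_modules,module_size Planted co-expression modules and their size.
#' @param module_trait_cor Target Pearson correlation between each module's
#'   latent factor and its trait (glucose for odd modules, TTR for even ones).
#' @param cis_window_bp Cis proximity window in base pairs.
#' @param n_cis_pairs Planted lncRNA/mRNA proximity placements; gaps cycle
#'   through overlapping (antisense), strictly inside the window, exactly at
#'   the boundary, and outside it (decoys).
#' @param n_mirnas Number of simulated miRNAs.
#' @param seed_length Length of the seed region (miRNA positions 2 onwards;
#'   default 7, i.e. positions 2-8).
#' @param n_cerna_triads Planted lncRNA/miRNA/mRNA triads sharing seed sites.
#' @param seq_length Unused for transcripts (sequence length follows the
#'   annotated span); retained as the minimum span length.
#' @param baseline_log2_range Range of baseline log2(FPKM+1) means.
#' @param rng_seed Integer seed; one seed drives every stage.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_coding = 400L, n_lncrna = 50L,
                       n_replicates_per_group = 3L,
                       groups = c("LG", "HG", "HG_TTR"),
                       n_de_up = 40L, n_de_down = 40L,
                       n_trend_reversal = 30L,
                       log2fc_effect = 2.0, noise_sd = 0.25,
                       n_modules = 2L, module_size = 50L,
                       module_trait_cor = 0.85,
                       cis_window_bp = 10000L, n_cis_pairs = 8L,
                       n_mirnas = 8L, seed_length = 7L,
                       n_cerna_triads = 5L,
                       seq_length = 500L,
                       baseline_log2_range = c(3, 8),
                       rng_seed = 1L) {
  config <- list(
    n_coding = as.integer(n_coding), n_lncrna = as.integer(n_lncrna),
    n_replicates_per_group = as.integer(n_replicates_per_group),
    groups = as.character(groups),
    n_de_up = as.integer(n_de_up), n_de_down = as.integer(n_de_down),
    n_trend_reversal = as.integer(n_trend_reversal),
    log2fc_effect = as.numeric(log2fc_effect), noise_sd = as.numeric(noise_sd),
    n_modules = as.integer(n_modules), module_size = as.integer(module_size),
    module_trait_cor = as.numeric(module_trait_cor),
    cis_window_bp = as.integer(cis_window_bp),
    n_cis_pairs = as.integer(n_cis_pairs),
    n_mirnas = as.integer(n_mirnas), seed_length = as.integer(seed_length),
    n_cerna_triads = as.integer(n_cerna_triads),
    seq_length = as.integer(seq_length),
    baseline_log2_range = as.numeric(baseline_log2_range),
    rng_seed = as.integer(rng_seed)
  )
  class(config) <- "sim_config"
  validate_sim_config(config)
  config
}

validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fail <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  counts <- c("n_coding", "n_lncrna", "n_replicates_per_group", "n_de_up",
              "n_de_down", "n_trend_reversal", "n_modules", "module_size",
              "n_cis_pairs", "n_mirnas", "n_cerna_triads")
  for (f in counts) {
    v <- config[[f]]
    if (length(v) != 1L || is.na(v) || v < 0L) {
      fail(sprintf("count '%s' must be a single non-negative integer", f))
    }
  }
  n_total <- config$n_coding + config$n_lncrna
  if (config$n_replicates_per_group < 2L) {
    fail("n_replicates_per_group must be >= 2 (contrasts need >= 2 samples per group)")
  }
  if (length(config$groups) != 3L || anyDuplicated(config$groups)) {
    fail("groups must be three distinct labels")
  }
  if (config$n_trend_reversal > config$n_de_up + config$n_de_down) {
    fail("n_trend_reversal must be <= n_de_up + n_de_down")
  }
  if (ceiling(config$n_trend_reversal / 2) > min(config$n_de_up, config$n_de_down) &&
      config$n_trend_reversal > 0L) {
    fail("ceiling(n_trend_reversal/2) must be <= min(n_de_up, n_de_down)")
  }
  if (config$noise_sd <= 0) fail("noise_sd must be > 0")
  if (config$log2fc_effect < 0) fail("log2fc_effect must be >= 0")
  if (abs(config$module_trait_cor) >= 1) {
    fail("module_trait_cor must lie in (-1, 1)")
  }
  if (config$n_modules * config$module_size > n_total) {
    fail("module_size * n_modules must be <= n_coding + n_lncrna")
  }
  n_de_total <- 2L * (config$n_de_up + config$n_de_down) - config$n_trend_reversal
  if (n_de_total + config$n_modules * config$module_size > n_total) {
    fail("planted DE transcripts plus module members exceed the transcript universe")
  }
  if (config$n_cis_pairs > min(config$n_lncrna, config$n_coding)) {
    fail("n_cis_pairs must be <= min(n_lncrna, n_coding)")
  }
  if (config$n_cerna_triads > min(config$n_mirnas, config$n_lncrna, config$n_coding)) {
    fail("n_cerna_triads must be <= min(n_mirnas, n_lncrna, n_coding)")
  }
  if (config$seed_length < 6L || config$seed_length > 8L) {
    fail("seed_length must be 6, 7 or 8")
  }
  if (config$cis_window_bp <= 0L) fail("cis_window_bp must be > 0")
  if (config$seq_length < 50L) fail("seq_length must be >= 50")
  if (length(config$baseline_log2_range) != 2L ||
      diff(config$baseline_log2_range) <= 0 ||
      config$baseline_log2_range[1] <= 1) {
    fail("baseline_log2_range must be an increasing range above 1")
  }
  invisible(config)
}
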