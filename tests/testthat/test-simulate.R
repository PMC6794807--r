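test_that("config validation names the violated constraint", {
  expect_error(sim_config(n_coding = -1), "n_coding")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_de_up = 2, n_de_down = 2, n_trend_reversal = 10),
               "n_trend_reversal")
  expect_error(sim_config(n_coding = 10, n_lncrna = 0, n_modules = 4,
                          module_size = 5, n_cis_pairs = 0, n_mirnas = 0,
                          n_cerna_triads = 0, n_de_up = 0, n_de_down = 0,
                          n_trend_reversal = 0),
               "module_size")
  expect_error(sim_config(module_trait_cor = 1.2), "module_trait_cor")
})

test_that("same seed gives bit-identical output, different seed differs", {
  cfg <- sim_config(n_coding = 60L, n_lncrna = 10L, n_de_up = 6L,
                    n_de_down = 6L, n_trend_reversal = 4L, n_modules = 0L,
                    module_size = 0L, n_cis_pairs = 2L, n_mirnas = 3L,
                    n_cerna_triads = 2L, rng_seed = 7L)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_annotation(cfg), generate_annotation(cfg))
  ann <- generate_annotation(cfg)
  expect_identical(generate_sequences(ann, cfg)$sequences,
                   generate_sequences(ann, cfg)$sequences)
  cfg2 <- sim_config(n_coding = 60L, n_lncrna = 10L, n_de_up = 6L,
                     n_de_down = 6L, n_trend_reversal = 4L, n_modules = 0L,
                     module_size = 0L, n_cis_pairs = 2L, n_mirnas = 3L,
                     n_cerna_triads = 2L, rng_seed = 8L)
  expect_false(identical(a$matrix, generate_expression(cfg2)$matrix))
})

test_that("planted truth is internally consistent", {
  cfg <- sim_config(rng_seed = 11L)
  ds <- generate_expression(cfg)
  tr <- ds$truth
  ## every reversal transcript sits in both DE maps with opposite direction
  expect_length(tr$trend_reversal_set, cfg$n_trend_reversal)
  for (t in tr$trend_reversal_set) {
    expect_true(t %in% names(tr$de_hg_vs_lg))
    expect_true(t %in% names(tr$de_ttr_vs_hg))
    expect_true(tr$de_hg_vs_lg[[t]] != tr$de_ttr_vs_hg[[t]])
  }
  expect_equal(sum(tr$de_hg_vs_lg == "up"), cfg$n_de_up)
  expect_equal(sum(tr$de_hg_vs_lg == "down"), cfg$n_de_down)
  expect_equal(sum(tr$de_ttr_vs_hg == "up"), cfg$n_de_up)
  expect_true(all(ds$matrix > 0))
})

test_that("planted group-mean effects are exact before noise", {
  ## with noise averaged over many datasets the realised pseudocounted
  ## log2 fold change centres on the planted effect
  cfg0 <- sim_config(n_coding = 60L, n_lncrna = 0L, n_de_up = 10L,
                     n_de_down = 10L, n_trend_reversal = 0L, n_modules = 0L,
                     module_size = 0L, n_cis_pairs = 0L, n_mirnas = 0L,
                     n_cerna_triads = 0L)
  real_up <- real_dn <- c()
  for (seed in 1:100) {
    cfg <- cfg0; cfg$rng_seed <- seed
    ds <- generate_expression(cfg)
    hg <- ds$design$sample[ds$design$group == "HG"]
    lg <- ds$design$sample[ds$design$group == "LG"]
    lfc <- log2((rowMeans(ds$matrix[, hg]) + 1) / (rowMeans(ds$matrix[, lg]) + 1))
    up <- names(ds$truth$de_hg_vs_lg)[ds$truth$de_hg_vs_lg == "up"]
    dn <- names(ds$truth$de_hg_vs_lg)[ds$truth$de_hg_vs_lg == "down"]
    real_up <- c(real_up, lfc[up])
    real_dn <- c(real_dn, lfc[dn])
  }
  expect_lt(abs(mean(real_up) - 2), 0.05)
  expect_lt(abs(mean(real_dn) + 2), 0.05)
})

test_that("null simulations are calibrated and call nothing", {
  cfg <- null_config(n = 500L, seed = 3L)
  ds <- generate_expression(cfg)
  expect_length(ds$truth$de_hg_vs_lg, 0)
  expect_length(ds$truth$trend_reversal_set, 0)
  c1 <- run_contrast(ds$matrix, ds$design, "HG", "LG")
  c2 <- run_contrast(ds$matrix, ds$design, "HG_TTR", "HG")
  ## raw p uniformity at the 5% point
  frac <- mean(c(c1$p_value, c2$p_value) <= 0.05)
  expect_lt(abs(frac - 0.05), 0.02)
  ## joint FC/p/FDR gates call essentially nothing
  expect_lte(sum(c1$status != "ns") + sum(c2$status != "ns"), 1)
})

test_that("strict trend filter has type-I control on null data", {
  zero_runs <- 0L
  n_runs <- 30L
  for (seed in seq_len(n_runs)) {
    ds <- generate_expression(null_config(n = 150L, seed = seed))
    ann <- generate_annotation(null_config(n = 150L, seed = seed))
    c1 <- run_contrast(ds$matrix, ds$design, "HG", "LG")
    c2 <- run_contrast(ds$matrix, ds$design, "HG_TTR", "HG")
    ttr <- ttr_trend_filter(c1, c2, ann, mode = "strict")
    if (nrow(ttr$table) == 0L) zero_runs <- zero_runs + 1L
  }
  expect_gte(zero_runs / n_runs, 0.95)
})

test_that("annotation places cis pairs at controlled gaps", {
  cfg <- sim_config(rng_seed = 5L)
  ann <- generate_annotation(cfg)
  ds <- generate_expression(cfg)
  expect_equal(sort(ann$transcript_id), sort(rownames(ds$matrix)))
  expect_true(all(ann$start < ann$end))
  expect_true(all(ann$strand %in% c("+", "-")))
  expect_setequal(unique(ann$biotype), c("coding", "lncRNA", "novel_lncRNA"))

  gap_of <- function(pair) {
    li <- ann[ann$transcript_id == pair$lncrna_id, ]
    mi <- ann[ann$transcript_id == pair$mrna_id, ]
    expect_equal(li$chrom, mi$chrom)
    if (li$start <= mi$end && mi$start <= li$end) return(0L)
    if (mi$start > li$end) mi$start - li$end else li$start - mi$end
  }
  truth <- ds$truth
  for (i in seq_len(nrow(truth$cis_pairs))) {
    expect_equal(gap_of(truth$cis_pairs[i, ]), truth$cis_pairs$gap_bp[i])
  }
  ## overlapping pair intersects on opposite strands (antisense)
  ov <- truth$cis_pairs[truth$cis_pairs$relation == "overlapping", ][1, ]
  li <- ann[ann$transcript_id == ov$lncrna_id, ]
  mi <- ann[ann$transcript_id == ov$mrna_id, ]
  expect_true(li$start <= mi$end && mi$start <= li$end)
  expect_true(li$strand != mi$strand)
  ## a boundary pair sits exactly at the window, a decoy just outside
  expect_true(any(truth$cis_pairs$gap_bp == cfg$cis_window_bp))
  expect_true(any(truth$cis_decoys$gap_bp == cfg$cis_window_bp + 1L))
})

test_that("with no cis placements nothing is near anything", {
  cfg <- sim_config(n_cis_pairs = 0L, rng_seed = 2L)
  ann <- generate_annotation(cfg)
  lnc <- ann$transcript_id[ann$biotype != "coding"]
  mrna <- ann$transcript_id[ann$biotype == "coding"]
  hits <- cis_pairs(ann, lnc, mrna, window_bp = cfg$cis_window_bp)
  expect_equal(nrow(hits), 0L)
})

test_that("planted seed sites exist, unplanted sequences carry none", {
  cfg <- sim_config(n_coding = 40L, n_lncrna = 12L, n_de_up = 4L,
                    n_de_down = 4L, n_trend_reversal = 2L, n_modules = 0L,
                    module_size = 0L, n_cis_pairs = 0L, n_mirnas = 4L,
                    n_cerna_triads = 3L, rng_seed = 13L)
  ann <- generate_annotation(cfg)
  sq <- generate_sequences(ann, cfg)
  triads <- sq$truth$planted_triads
  expect_equal(nrow(triads), 3L)
  for (i in seq_len(nrow(triads))) {
    seed <- sq$mirnas$seed_7mer[sq$mirnas$mirna_id == triads$mirna_id[i]]
    ## hand reverse complement of the seed, as planted on the sense strand
    site <- revcomp_oracle(seed)
    expect_true(grepl(site, sq$sequences[[triads$lncrna_id[i]]], fixed = TRUE))
    expect_true(grepl(site, sq$sequences[[triads$mrna_id[i]]], fixed = TRUE))
  }
  ## every non-owner sequence is free of every 6mer core
  cores <- vapply(substr(sq$mirnas$seed_7mer, 1, 6), revcomp_oracle, character(1))
  names(cores) <- sq$mirnas$mirna_id
  for (id in names(sq$sequences)) {
    own <- triads$mirna_id[triads$lncrna_id == id | triads$mrna_id == id]
    for (mir in setdiff(names(cores), own)) {
      expect_false(grepl(cores[[mir]], sq$sequences[[id]], fixed = TRUE))
    }
  }
})

test_that("sequence lengths follow the annotation", {
  cfg <- sim_config(n_coding = 20L, n_lncrna = 5L, n_de_up = 0L, n_de_down = 0L,
                    n_trend_reversal = 0L, n_modules = 0L, module_size = 0L,
                    n_cis_pairs = 0L, n_mirnas = 2L, n_cerna_triads = 1L,
                    rng_seed = 4L)
  ann <- generate_annotation(cfg)
  sq <- generate_sequences(ann, cfg)
  lens <- setNames(ann$end - ann$start + 1L, ann$transcript_id)
  expect_equal(nchar(sq$sequences[names(lens)]), lens)
})
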