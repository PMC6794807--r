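toy_annotation <- function() {
  data.frame(
    transcript_id = c("lncA", "mA", "mB", "mC", "lncB", "mD"),
    gene_id = paste0("g", 1:6), gene_name = paste0("g", 1:6),
    biotype = c("lncRNA", rep("coding", 3), "lncRNA", "coding"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    start = c(20000L, 25000L, 5000L, 1000L, 1500L, 40000L),
    end = c(21000L, 26000L, 9999L, 2000L, 2600L, 41000L),
    strand = c("+", "+", "-", "+", "-", "+"),
    stringsAsFactors = FALSE
  )
}

test_that("cis caller applies the inclusive end-to-start window rule", {
  ann <- toy_annotation()
  res <- cis_pairs(ann, c("lncA", "lncB"), c("mA", "mB", "mC", "mD"),
                   window_bp = 10000)
  ## lncA chr1:20000-21000 vs mA chr1:25000-26000: gap 4000, downstream
  row <- res[res$lncrna_id == "lncA" & res$mrna_id == "mA", ]
  expect_equal(row$relation, "downstream")
  expect_equal(row$gap_bp, 4000L)
  ## lncA vs mB (end 9999): gap 20000 - 9999 = 10001 -> excluded
  expect_false(any(res$lncrna_id == "lncA" & res$mrna_id == "mB"))
  ## gap exactly the window is included
  res2 <- cis_pairs(ann, "lncA", "mB", window_bp = 10001)
  expect_equal(res2$gap_bp, 10001L)
  expect_equal(res2$relation, "upstream")
  ## lncB overlaps mC on the opposite strand
  ov <- res[res$lncrna_id == "lncB" & res$mrna_id == "mC", ]
  expect_equal(ov$relation, "overlapping")
  expect_equal(ov$gap_bp, 0L)
  expect_true(ov$antisense)
  ## different chromosomes never pair
  expect_false(any(res$lncrna_id == "lncA" & res$mrna_id %in% c("mC", "mD")))
})

test_that("cis caller equals the brute-force all-pairs scan on synthetic data", {
  cfg <- sim_config(rng_seed = 17L)
  ann <- generate_annotation(cfg)
  lnc <- ann$transcript_id[ann$biotype != "coding"]
  mrna <- ann$transcript_id[ann$biotype == "coding"]
  got <- cis_pairs(ann, lnc, mrna, window_bp = 10000)
  want <- cis_oracle(ann, lnc, mrna, window_bp = 10000)
  expect_equal(got[, c("lncrna_id", "mrna_id", "relation", "gap_bp")], want)
  ## the boundary placement is picked up, the gap+1 decoy is not
  truth <- generate_expression(cfg)$truth
  boundary <- truth$cis_pairs[truth$cis_pairs$gap_bp == 10000, ]
  expect_true(all(paste(boundary$lncrna_id, boundary$mrna_id) %in%
                  paste(got$lncrna_id, got$mrna_id)))
  decoy <- truth$cis_decoys
  expect_false(any(paste(decoy$lncrna_id, decoy$mrna_id) %in%
                   paste(got$lncrna_id, got$mrna_id)))
})

test_that("cis relation inverts when the roles are swapped", {
  ann <- toy_annotation()
  fwd <- cis_pairs(ann, "lncA", "mA", window_bp = 10000)
  rev <- cis_pairs(ann, "mA", "lncA", window_bp = 10000)
  expect_equal(fwd$relation, "downstream")
  expect_equal(rev$relation, "upstream")
  expect_equal(fwd$gap_bp, rev$gap_bp)
})

test_that("trans caller thresholds correlation and matches the oracle", {
  samples <- sprintf("s%d", 1:9)
  base <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  set.seed(9)
  m <- rbind(
    lnc1 = base,
    lnc2 = rnorm(9, 5),
    m1 = base * 2,              # r = 1 with lnc1 on the log scale? no: use raw
    m2 = 10 - base,             # strongly negative
    m3 = rnorm(9, 5)
  )
  colnames(m) <- samples
  m <- pmax(m, 0)
  res <- trans_pairs(m, c("lnc1", "lnc2"), c("m1", "m2", "m3"),
                     r_threshold = 0.95, log_transform = FALSE)
  expect_true(all(c("positive", "negative") %in%
                  res$sign[res$lncrna_id == "lnc1"]))
  r11 <- res[res$lncrna_id == "lnc1" & res$mrna_id == "m1", ]
  expect_equal(r11$pearson_r, 1)
  r12 <- res[res$lncrna_id == "lnc1" & res$mrna_id == "m2", ]
  expect_equal(r12$pearson_r, -1)
  expect_false(any(res$mrna_id == "m3"))

  ## synthetic data: equality with the brute-force scan + monotonicity
  ds <- generate_expression(sim_config(rng_seed = 9L))
  lnc <- grep("^LNC", rownames(ds$matrix), value = TRUE)[1:25]
  mrna <- grep("^MRNA", rownames(ds$matrix), value = TRUE)[1:60]
  got <- trans_pairs(ds$matrix, lnc, mrna, r_threshold = 0.95)
  want <- trans_oracle(ds$matrix, lnc, mrna, r_threshold = 0.95)
  expect_equal(got[, c("lncrna_id", "mrna_id", "pearson_r")], want)
  tighter <- trans_pairs(ds$matrix, lnc, mrna, r_threshold = 0.97)
  expect_true(all(paste(tighter$lncrna_id, tighter$mrna_id) %in%
                  paste(got$lncrna_id, got$mrna_id)))
})

test_that("seed matcher classifies canonical site types", {
  ## no complement at all
  expect_equal(nrow(seed_match_sites("GGGGGGGGGGGG", "UGAGGUAGUAGGUUGUAUAGUU")), 0)
  ## let-7 family example: CTACCTCA is the 8mer site for seed GAGGUAG
  hit <- seed_match_sites("GGGGCTACCTCAGGGG", "UGAGGUAGUAGGUUGUAUAGUU")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$match_type, "8mer")
  expect_equal(hit$start, 5L)
  expect_equal(hit$end, 12L)
  ## same site without the trailing A: 7mer-m8
  hit2 <- seed_match_sites("GGGGCTACCTCGGGGG", "UGAGGUAGUAGGUUGUAUAGUU")
  expect_equal(hit2$match_type, "7mer-m8")
  ## core + A but wrong m8 base: 7mer-A1
  hit3 <- seed_match_sites("GGGGGTACCTCAGGGG", "UGAGGUAGUAGGUUGUAUAGUU")
  expect_equal(hit3$match_type, "7mer-A1")
  ## bare core: 6mer
  hit4 <- seed_match_sites("GGGGGTACCTCGGGGG", "UGAGGUAGUAGGUUGUAUAGUU")
  expect_equal(hit4$match_type, "6mer")
  ## restricting rules drops weaker classes
  expect_equal(nrow(seed_match_sites("GGGGGTACCTCGGGGG", "UGAGGUAGUAGGUUGUAUAGUU",
                                     rules = c("8mer", "7mer-m8"))), 0)
  ## a 7mer seed input (positions 2-8) behaves like the full miRNA
  hit5 <- seed_match_sites("GGGGCTACCTCAGGGG", "GAGGUAG")
  expect_equal(hit5$match_type, "8mer")
  ## T/U equivalence on both sides
  hit6 <- seed_match_sites("ggggctacctcagggg", "TGAGGTAGTAGGTTGTATAGTT")
  expect_equal(hit6$match_type, "8mer")
  expect_error(seed_match_sites("ACGTN", "GAGGUAG"), "invalid character")
})

test_that("two planted non-overlapping sites are both reported", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  target <- paste0("GGGG", "CTACCTCA", "GGGGGGGG", "CTACCTCA", "GG")
  hits <- seed_match_sites(target, mir)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$start, c(5L, 21L))
  expect_equal(hits$match_type, rep("8mer", 2))
})

test_that("seed matcher equals the exhaustive substring oracle", {
  set.seed(77)
  for (i in 1:300) {
    target <- random_seq(sample(30:120, 1))
    mir <- random_seq(22, alphabet = c("A", "C", "G", "U"))
    got <- seed_match_sites(target, mir)
    want <- seed_scan_oracle(target, mir)
    expect_equal(got, want)
  }
})

test_that("ceRNA triads require shared miRNA sites on both members", {
  lnc_sites <- data.frame(mirna_id = c("mirX", "mirX", "mirY"),
                          target_id = c("lnc1", "lnc1", "lnc2"),
                          start = c(5L, 40L, 7L), end = c(12L, 47L, 14L),
                          match_type = "8mer", stringsAsFactors = FALSE)
  mrna_sites <- data.frame(mirna_id = c("mirX", "mirZ"),
                           target_id = c("m1", "m2"),
                           start = c(9L, 9L), end = c(16L, 16L),
                           match_type = "8mer", stringsAsFactors = FALSE)
  tri <- cerna_triads(lnc_sites, mrna_sites)
  expect_equal(nrow(tri), 1)
  expect_equal(tri$lncrna_id, "lnc1")
  expect_equal(tri$mirna_id, "mirX")
  expect_equal(tri$lnc_site_count, 2L)
  expect_equal(tri$mrna_site_count, 1L)
  ## min_sites gates the lncRNA side
  expect_equal(nrow(cerna_triads(lnc_sites, mrna_sites, min_sites = 2L)), 0)
  expect_equal(nrow(cerna_triads(lnc_sites[0, ], mrna_sites)), 0)
})

test_that("planted triads are recovered perfectly on scrubbed sequences", {
  cfg <- sim_config(n_coding = 40L, n_lncrna = 12L, n_de_up = 4L,
                    n_de_down = 4L, n_trend_reversal = 2L, n_modules = 0L,
                    module_size = 0L, n_cis_pairs = 0L, n_mirnas = 5L,
                    n_cerna_triads = 5L, rng_seed = 19L)
  ann <- generate_annotation(cfg)
  sq <- generate_sequences(ann, cfg)
  lnc <- ann$transcript_id[ann$biotype != "coding"]
  mrna <- ann$transcript_id[ann$biotype == "coding"]
  lnc_sites <- site_table(sq$sequences[lnc], sq$mirnas)
  mrna_sites <- site_table(sq$sequences[mrna], sq$mirnas)
  got <- cerna_triads(lnc_sites, mrna_sites)
  want <- sq$truth$planted_triads
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$lncrna_id, got$mirna_id, got$mrna_id),
                  paste(want$lncrna_id, want$mirna_id, want$mrna_id))
  ## planted 8mer site positions are reported exactly
  for (i in seq_len(nrow(want))) {
    s <- lnc_sites[lnc_sites$mirna_id == want$mirna_id[i] &
                   lnc_sites$target_id == want$lncrna_id[i], ]
    expect_true(want$lnc_site_pos[i] %in% s$start)
  }
})

test_that("hub ranking counts unique partners with lexicographic ties", {
  edges <- data.frame(
    lncrna_id = c(rep("lncL", 5), "lncA", "lncB"),
    mrna_id = c(paste0("m", 1:5), "m1", "m1"),
    pearson_r = 0.99, sign = "positive", stringsAsFactors = FALSE
  )
  rk <- hub_rank(edges, top_n = 10)
  expect_equal(rk$lncrna_id[1], "lncL")
  expect_equal(rk$degree[1], 5L)
  expect_equal(rk$lncrna_id[2:3], c("lncA", "lncB"))
  ## duplicated edges do not inflate the degree
  dup <- rbind(edges, edges[1, ])
  expect_equal(hub_rank(dup, 1)$degree, 5L)
  expect_equal(nrow(hub_rank(edges[0, ], 3)), 0)
  ## synthetic network equals brute-force counting
  ds <- generate_expression(sim_config(rng_seed = 13L))
  lnc <- grep("^LNC", rownames(ds$matrix), value = TRUE)
  mrna <- grep("^MRNA", rownames(ds$matrix), value = TRUE)
  tr <- trans_pairs(ds$matrix, lnc, mrna, r_threshold = 0.95)
  rk2 <- hub_rank(tr, top_n = 10)
  brute <- sort(table(unique(tr[, 1:2])$lncrna_id), decreasing = TRUE)
  expect_equal(rk2$degree[1], unname(brute[1]))
  expect_equal(sum(rk2$degree), sum(sort(brute, decreasing = TRUE)[seq_len(nrow(rk2))]))
})

test_that("merged graph integrates the three edge types around the focus", {
  cis <- data.frame(lncrna_id = "lnc1", mrna_id = "m1",
                    relation = "upstream", gap_bp = 500L, antisense = FALSE,
                    stringsAsFactors = FALSE)
  trans <- data.frame(lncrna_id = c("lnc1", "lnc2"), mrna_id = c("m2", "m3"),
                      pearson_r = c(0.99, -0.98),
                      sign = c("positive", "negative"), stringsAsFactors = FALSE)
  triads <- data.frame(lncrna_id = "lnc1", mirna_id = "mir1", mrna_id = "m3",
                       lnc_site_count = 1L, mrna_site_count = 2L,
                       stringsAsFactors = FALSE)
  g <- merge_networks(cis, trans, triads, focus_lncrnas = "lnc1")
  expect_setequal(igraph::V(g)$name, c("lnc1", "m1", "m2", "mir1", "m3"))
  expect_setequal(igraph::E(g)$edge_type, c("cis", "trans", "cerna"))
  expect_equal(igraph::ecount(g), 4)   # cis + trans + lnc-mir + mir-mrna
  expect_equal(igraph::V(g)$type[igraph::V(g)$name == "mir1"], "miRNA")
  ## lnc2 edges are excluded, absent focus nodes stay isolated with warning
  expect_false("lnc2" %in% igraph::V(g)$name)
  expect_warning(g2 <- merge_networks(cis, trans, triads,
                                      focus_lncrnas = c("lnc1", "ghost")),
                 "absent")
  expect_true("ghost" %in% igraph::V(g2)$name)
  expect_equal(igraph::degree(g2)[["ghost"]], 0)
})
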