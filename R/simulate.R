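## Synthetic three-group dataset with planted ground truth.
##
## One RNG, seeded once from the config, drives every stage: the planted sets
## are drawn first (simulate_truth), then per-stage sub-seeds are derived so
## that generate_expression / generate_annotation / generate_sequences are
## individually reproducible yet mutually consistent.

transcript_ids <- function(config) {
  list(
    coding = if (config$n_coding > 0) sprintf("MRNA_%04d", seq_len(config$n_coding)) else character(),
    lncrna = if (config$n_lncrna > 0) sprintf("LNC_%04d", seq_len(config$n_lncrna)) else character()
  )
}

sample_ids <- function(config) {
  as.vector(vapply(config$groups, function(g) {
    sprintf("%s_%d", g, seq_len(config$n_replicates_per_group))
  }, character(config$n_replicates_per_group)))
}

#' @keywords internal
sim_design <- function(config) {
  data.frame(
    sample = sample_ids(config),
    group = rep(config$groups, each = config$n_replicates_per_group),
    stringsAsFactors = FALSE
  )
}

## Binary trait encodings over the sample vector: glucose marks the two
## high-glucose groups, ttr marks the TTR co-treatment group.
sim_traits <- function(config) {
  design <- sim_design(config)
  data.frame(
    row.names = design$sample,
    glucose = as.numeric(design$group %in% config$groups[2:3]),
    ttr = as.numeric(design$group == config$groups[3])
  )
}

## Draw every planted set. Deterministic in config$rng_seed.
simulate_truth <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$rng_seed, {
    ids <- transcript_ids(config)
    all_ids <- c(ids$coding, ids$lncrna)

    ## gene map: a few coding genes carry two transcripts so that gene-level
    ## aggregation rules are exercised; everything else is one-to-one
    n_paired_genes <- min(10L, config$n_coding %/% 4L)
    gene_of_coding <- character(config$n_coding)
    i <- seq_len(config$n_coding)
    paired <- i <= 2L * n_paired_genes
    gene_of_coding[paired] <- sprintf("GCOD_%04d", ceiling(i[paired] / 2))
    gene_of_coding[!paired] <- sprintf("GCOD_%04d", n_paired_genes + (i[!paired] - 2L * n_paired_genes))
    gene_map <- c(
      stats::setNames(gene_of_coding, ids$coding),
      stats::setNames(sprintf("GLNC_%04d", seq_len(config$n_lncrna)), ids$lncrna)
    )

    ## trend-reversal transcripts, stratified so lncRNAs are represented
    ntr <- config$n_trend_reversal
    n_rev_lnc <- 0L
    if (ntr > 0L && config$n_lncrna > 0L) {
      n_rev_lnc <- round(ntr * config$n_lncrna / length(all_ids))
      n_rev_lnc <- min(config$n_lncrna, max(min(2L, ntr), n_rev_lnc))
    }
    n_rev_cod <- ntr - n_rev_lnc
    reversal <- c(
      if (n_rev_lnc > 0L) sample(ids$lncrna, n_rev_lnc) else character(),
      if (n_rev_cod > 0L) sample(ids$coding, n_rev_cod) else character()
    )
    reversal <- if (length(reversal)) sample(reversal) else character()
    r_u <- ceiling(ntr / 2)
    rev_up <- reversal[seq_len(r_u)]          # up in contrast 1, down in 2
    rev_dn <- setdiff(reversal, rev_up)       # down in contrast 1, up in 2
    r_d <- length(rev_dn)

    pool <- setdiff(all_ids, reversal)
    take <- function(n) {
      if (n == 0L) return(character())
      picked <- sample(pool, n)
      pool <<- setdiff(pool, picked)
      picked
    }
    up1_only <- take(config$n_de_up - r_u)
    dn1_only <- take(config$n_de_down - r_d)
    up2_only <- take(config$n_de_up - r_d)
    dn2_only <- take(config$n_de_down - r_u)

    de1 <- c(stats::setNames(rep("up", length(c(rev_up, up1_only))), c(rev_up, up1_only)),
             stats::setNames(rep("down", length(c(rev_dn, dn1_only))), c(rev_dn, dn1_only)))
    de2 <- c(stats::setNames(rep("up", length(c(rev_dn, up2_only))), c(rev_dn, up2_only)),
             stats::setNames(rep("down", length(c(rev_up, dn2_only))), c(rev_up, dn2_only)))

    ## module memberships from the untouched pool
    module_labels <- character()
    module_traits <- character()
    if (config$n_modules > 0L && config$module_size > 0L) {
      members <- take(config$n_modules * config$module_size)
      module_labels <- stats::setNames(
        rep(sprintf("M%d", seq_len(config$n_modules)), each = config$module_size),
        members
      )
      module_traits <- stats::setNames(
        rep(c("glucose", "ttr"), length.out = config$n_modules),
        sprintf("M%d", seq_len(config$n_modules))
      )
    }

    ## cis placements: prefer trend-reversal transcripts as pair members so
    ## that downstream TTR-DEG networks are populated
    cis_layout <- NULL
    if (config$n_cis_pairs > 0L) {
      prefer <- function(universe) {
        pref <- intersect(reversal, universe)
        c(sample(pref), sample(setdiff(universe, pref)))
      }
      lncs <- prefer(ids$lncrna)[seq_len(config$n_cis_pairs)]
      mrnas <- prefer(ids$coding)[seq_len(config$n_cis_pairs)]
      n <- config$n_cis_pairs
      n_overlap <- min(1L, n)
      rem <- n - n_overlap
      n_inside <- ceiling(rem / 2)
      remn <- rem - n_inside
      n_boundary <- ceiling(remn / 2)
      n_outside <- remn - n_boundary
      kind <- c(rep("overlapping", n_overlap), rep("inside", n_inside),
                rep("boundary", n_boundary), rep("outside", n_outside))
      gap <- integer(n)
      gap[kind == "inside"] <- sample.int(config$cis_window_bp - 1L,
                                          sum(kind == "inside"), replace = TRUE)
      gap[kind == "boundary"] <- config$cis_window_bp
      out_idx <- which(kind == "outside")
      if (length(out_idx)) {
        gap[out_idx[1]] <- config$cis_window_bp + 1L   # strict-boundary decoy
        if (length(out_idx) > 1L) {
          gap[out_idx[-1]] <- config$cis_window_bp +
            sample(500:5000, length(out_idx) - 1L, replace = TRUE)
        }
      }
      relation <- ifelse(kind == "overlapping", "overlapping",
                         sample(c("upstream", "downstream"), n, replace = TRUE))
      cis_layout <- data.frame(
        lncrna_id = lncs, mrna_id = mrnas, kind = kind,
        relation = relation, gap_bp = gap, stringsAsFactors = FALSE
      )
    }

    ## ceRNA triads: distinct members, preferring trend-reversal transcripts
    triads <- NULL
    if (config$n_cerna_triads > 0L) {
      prefer <- function(universe) {
        pref <- intersect(reversal, universe)
        c(sample(pref), sample(setdiff(universe, pref)))
      }
      triads <- data.frame(
        lncrna_id = prefer(ids$lncrna)[seq_len(config$n_cerna_triads)],
        mirna_id = sprintf("MIR_%02d", seq_len(config$n_cerna_triads)),
        mrna_id = prefer(ids$coding)[seq_len(config$n_cerna_triads)],
        stringsAsFactors = FALSE
      )
    }

    stage_seeds <- sample.int(.Machine$integer.max, 4L)

    list(
      ids = ids, all_ids = all_ids, gene_map = gene_map,
      de_hg_vs_lg = de1, de_ttr_vs_hg = de2,
      trend_reversal = reversal,
      module_labels = module_labels, module_traits = module_traits,
      cis_layout = cis_layout, triads = triads,
      stage_seeds = stage_seeds
    )
  })
}

## Public ground-truth view (what write_dataset serialises).
ground_truth <- function(truth, config) {
  cis_pairs <- cis_decoys <- data.frame(
    lncrna_id = character(), mrna_id = character(),
    relation = character(), gap_bp = integer(), stringsAsFactors = FALSE
  )
  if (!is.null(truth$cis_layout)) {
    lay <- truth$cis_layout
    keep <- lay$kind != "outside"
    cis_pairs <- lay[keep, c("lncrna_id", "mrna_id", "relation", "gap_bp")]
    cis_pairs$gap_bp[lay$kind[keep] == "overlapping"] <- 0L
    cis_decoys <- lay[!keep, c("lncrna_id", "mrna_id", "relation", "gap_bp")]
    rownames(cis_pairs) <- rownames(cis_decoys) <- NULL
  }
  planted_triads <- if (is.null(truth$triads)) {
    data.frame(lncrna_id = character(), mirna_id = character(),
               mrna_id = character(), stringsAsFactors = FALSE)
  } else truth$triads
  list(
    de_hg_vs_lg = truth$de_hg_vs_lg,
    de_ttr_vs_hg = truth$de_ttr_vs_hg,
    trend_reversal_set = truth$trend_reversal,
    module_labels = truth$module_labels,
    module_traits = truth$module_traits,
    cis_pairs = cis_pairs,
    cis_decoys = cis_decoys,
    planted_triads = planted_triads
  )
}

#' Simulate the FPKM expression matrix with planted effects
#'
#' Expression is modelled on the log2(FPKM+1) scale: each transcript draws a
#' baseline mean, group effects of exactly `log2fc_effect` are added for
#' planted DE transcripts (trend-reversal transcripts receive opposite-signed
#' effects in the two contrasts), module members share a per-sample latent
#' factor whose sample correlation with the module's trait equals
#' `module_trait_cor` by construction, and i.i.d. normal noise of sd
#' `noise_sd` is added before back-transforming (`FPKM = 2^x - 1`). Because
#' the back-transform inverts the +1 pseudocount used downstream, planted
#' group-mean log2 ratios equal the effect exactly before noise.
#'
#' @param config A [sim_config()].
#' @return A list with `matrix` (transcripts x samples, strictly positive
#'   FPKM), `design` (sample/group data frame) and `truth` (planted ground
#'   truth: DE direction maps per contrast, trend-reversal set, module labels
#'   and traits, cis pairs/decoys, planted triads).
#' @export
generate_expression <- function(config) {
  truth <- simulate_truth(config)
  design <- sim_design(config)
  traits <- sim_traits(config)
  n_tx <- length(truth$all_ids)
  n_smp <- nrow(design)

  withr::with_seed(truth$stage_seeds[1], {
    baseline <- stats::runif(n_tx, config$baseline_log2_range[1],
                             config$baseline_log2_range[2])
    mu <- matrix(baseline, n_tx, n_smp, dimnames = list(truth$all_ids, design$sample))

    eff <- config$log2fc_effect
    g2 <- design$group == config$groups[2]
    g3 <- design$group == config$groups[3]
    d1 <- stats::setNames(numeric(n_tx), truth$all_ids)
    d1[names(truth$de_hg_vs_lg)] <- ifelse(truth$de_hg_vs_lg == "up", eff, -eff)
    d2 <- stats::setNames(numeric(n_tx), truth$all_ids)
    d2[names(truth$de_ttr_vs_hg)] <- ifelse(truth$de_ttr_vs_hg == "up", eff, -eff)
    mu[, g2] <- mu[, g2] + d1[truth$all_ids]
    mu[, g3] <- mu[, g3] + d1[truth$all_ids] + d2[truth$all_ids]

    ## module latent factors: exact sample correlation with the trait
    if (length(truth$module_labels)) {
      alpha <- 3 * config$noise_sd   # within-module correlation ~ 0.9
      prev_z <- NULL                 # in-sample orthogonal latent residuals
      for (m in unique(truth$module_labels)) {
        trait <- traits[[truth$module_traits[[m]]]]
        t_std <- as.numeric(scale(trait))
        eta <- stats::rnorm(n_smp)
        basis <- cbind(t_std, prev_z)
        eta <- stats::residuals(stats::lm(eta ~ basis))
        eta <- as.numeric(scale(eta))
        r <- config$module_trait_cor
        z <- r * t_std + sqrt(1 - r^2) * eta
        prev_z <- cbind(prev_z, eta)
        members <- names(truth$module_labels)[truth$module_labels == m]
        mu[members, ] <- sweep(mu[members, , drop = FALSE], 2, alpha * z, "+")
      }
    }

    x <- mu + matrix(stats::rnorm(n_tx * n_smp, sd = config$noise_sd), n_tx, n_smp)
    fpkm <- pmax(2^x - 1, 1e-4)
  })

  list(matrix = fpkm, design = design, truth = ground_truth(truth, config))
}

#' Simulate the transcript annotation (GTF-style, 1-based inclusive)
#'
#' Background transcripts are laid out along chromosomes with inter-feature
#' gaps always exceeding the cis window, so no unplanted lncRNA/mRNA pair can
#' fall within it. Planted cis placements sit at controlled gaps: one
#' antisense-overlapping pair, half strictly inside the window, some exactly
#' at the boundary (gap == window, included by the caller's inclusive rule)
#' and some outside (decoys, the first at gap == window + 1). The gap between
#' two spans is measured end-to-start (`start2 - end1`; 0 when overlapping).
#'
#' @param config A [sim_config()].
#' @return A data frame with columns transcript_id, gene_id, gene_name,
#'   biotype (`coding`, `lncRNA` or `novel_lncRNA`), chrom, start, end,
#'   strand, ordered like the expression matrix.
#' @export
generate_annotation <- function(config) {
  truth <- simulate_truth(config)
  if (!length(truth$all_ids)) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      gene_name = character(), biotype = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  lay <- truth$cis_layout

  withr::with_seed(truth$stage_seeds[2], {
    paired_ids <- if (is.null(lay)) character() else c(lay$lncrna_id, lay$mrna_id)
    singles <- setdiff(truth$all_ids, paired_ids)

    ## placement units: single transcripts, or a pair at a controlled gap
    units <- c(as.list(singles),
               if (!is.null(lay)) split(lay, seq_len(nrow(lay))))
    units <- units[sample(length(units))]

    n_chrom <- max(1L, ceiling(length(units) / 40L))
    chroms <- sprintf("chr%d", seq_len(n_chrom))
    cursor <- stats::setNames(rep(10000L, n_chrom), chroms)
    big_gap <- function() config$cis_window_bp + sample(2000:8000, 1L)
    span_len <- function() sample(config$seq_length:2000L, 1L)

    rows <- vector("list", length(truth$all_ids))
    names(rows) <- truth$all_ids
    put <- function(id, chrom, start, end, strand) {
      rows[[id]] <<- data.frame(transcript_id = id, chrom = chrom,
                                start = start, end = end, strand = strand,
                                stringsAsFactors = FALSE)
    }

    for (k in seq_along(units)) {
      u <- units[[k]]
      chrom <- chroms[((k - 1L) %% n_chrom) + 1L]
      at <- cursor[[chrom]]
      if (is.character(u)) {
        len <- span_len()
        put(u, chrom, at, at + len - 1L, sample(c("+", "-"), 1L))
        cursor[[chrom]] <- at + len - 1L + big_gap()
      } else {
        len_l <- span_len(); len_m <- span_len()
        if (u$kind == "overlapping") {
          ## antisense overlap: lncRNA on the opposite strand, spans intersect
          m_start <- at; m_end <- at + len_m - 1L
          l_start <- at + len_m %/% 2L; l_end <- l_start + len_l - 1L
          put(u$mrna_id, chrom, m_start, m_end, "+")
          put(u$lncrna_id, chrom, l_start, l_end, "-")
        } else if (u$relation == "upstream") {
          ## mRNA at lower coordinates than the lncRNA
          m_start <- at; m_end <- at + len_m - 1L
          l_start <- m_end + u$gap_bp; l_end <- l_start + len_l - 1L
          put(u$mrna_id, chrom, m_start, m_end, sample(c("+", "-"), 1L))
          put(u$lncrna_id, chrom, l_start, l_end, sample(c("+", "-"), 1L))
        } else {
          l_start <- at; l_end <- at + len_l - 1L
          m_start <- l_end + u$gap_bp; m_end <- m_start + len_m - 1L
          put(u$lncrna_id, chrom, l_start, l_end, sample(c("+", "-"), 1L))
          put(u$mrna_id, chrom, m_start, m_end, sample(c("+", "-"), 1L))
        }
        cursor[[chrom]] <- max(l_end, m_end) + big_gap()
      }
    }

    ann <- do.call(rbind, rows[truth$all_ids])
    biotype <- ifelse(ann$transcript_id %in% truth$ids$coding, "coding", "lncRNA")
    ## every fifth lncRNA is flagged as a novel assembly product
    novel <- truth$ids$lncrna[seq_along(truth$ids$lncrna) %% 5L == 0L]
    biotype[ann$transcript_id %in% novel] <- "novel_lncRNA"
    ann$biotype <- biotype
    ann$gene_id <- unname(truth$gene_map[ann$transcript_id])
    ann$gene_name <- ann$gene_id
    rownames(ann) <- NULL
    ann[, c("transcript_id", "gene_id", "gene_name", "biotype",
            "chrom", "start", "end", "strand")]
  })
}

## DNA/RNA helpers --------------------------------------------------------

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("Uu", "Tt", x))
  ))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

count_fixed <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

## Remove every occurrence of the given cores by mutating one base inside
## each match; exact re-check afterwards (capped targeted resampling).
scrub_cores <- function(seq, cores, max_iter = 200L) {
  bases <- c("A", "C", "G", "T")
  for (iter in seq_len(max_iter)) {
    hit <- FALSE
    for (core in cores) {
      m <- gregexpr(core, seq, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      hit <- TRUE
      for (pos in m) {
        at <- pos + sample.int(nchar(core), 1L) - 1L
        old <- substr(seq, at, at)
        substr(seq, at, at) <- sample(setdiff(bases, old), 1L)
      }
    }
    if (!hit) return(seq)
  }
  stop("seed-site scrubbing failed to converge; use longer sequences or a shorter seed",
       call. = FALSE)
}

#' Simulate transcript sequences and the miRNA seed table
#'
#' Transcript sequences are random-composition DNA of the annotated span
#' length. Each planted triad's lncRNA and mRNA carry one exact 8mer site for
#' the triad's miRNA (reverse complement of seed positions 2-8 followed by an
#' A opposite position 1, on the target's sense strand written 5'-3'). All
#' other sequence/miRNA combinations are scrubbed of 6mer-core seed
#' complements by capped targeted resampling, so the seed matcher finds
#' planted sites and nothing else.
#'
#' @param annotation Output of [generate_annotation()] (same config).
#' @param config The same [sim_config()].
#' @return A list with `sequences` (named character, DNA), `mirnas` (data
#'   frame: mirna_id, seed_7mer, sequence (RNA)), and `truth` (planted triads
#'   with 1-based site start positions).
#' @export
generate_sequences <- function(annotation, config) {
  truth <- simulate_truth(config)
  if (!setequal(annotation$transcript_id, truth$all_ids)) {
    stop("annotation does not match the configured transcript universe", call. = FALSE)
  }

  withr::with_seed(truth$stage_seeds[3], {
    ## miRNAs with mutually distinct seed regions
    mirnas <- NULL
    if (config$n_mirnas > 0L) {
      repeat {
        seqs <- vapply(seq_len(config$n_mirnas), function(i) {
          paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE), collapse = "")
        }, character(1))
        seeds <- substr(seqs, 2L, 1L + config$seed_length)
        if (!anyDuplicated(seeds)) break
      }
      mirnas <- data.frame(
        mirna_id = sprintf("MIR_%02d", seq_len(config$n_mirnas)),
        seed_7mer = seeds, sequence = seqs, stringsAsFactors = FALSE
      )
    }
    cores <- character()
    if (!is.null(mirnas)) {
      cores <- vapply(substr(mirnas$seed_7mer, 1L, 6L), revcomp_dna, character(1))
      names(cores) <- mirnas$mirna_id
    }

    lens <- stats::setNames(annotation$end - annotation$start + 1L,
                            annotation$transcript_id)
    triads <- truth$triads
    sequences <- stats::setNames(character(length(truth$all_ids)), truth$all_ids)
    site_pos <- list()

    for (id in truth$all_ids) {
      len <- lens[[id]]
      own <- if (!is.null(triads)) triads$mirna_id[triads$lncrna_id == id | triads$mrna_id == id] else character()
      foreign <- setdiff(names(cores), own)
      seq <- scrub_cores(random_dna(len), cores)
      if (length(own)) {
        ## insert one 8mer site per owning miRNA, keeping foreign cores absent
        for (attempt in seq_len(200L)) {
          cand <- seq
          pos <- integer(length(own))
          ok <- TRUE
          for (j in seq_along(own)) {
            mir <- own[j]
            seed <- mirnas$seed_7mer[mirnas$mirna_id == mir]
            site <- paste0(revcomp_dna(seed), "A")
            at <- sample.int(len - nchar(site) + 1L, 1L)
            substr(cand, at, at + nchar(site) - 1L) <- site
            pos[j] <- at
          }
          n_foreign <- sum(vapply(cores[foreign], function(p) count_fixed(cand, p), integer(1)))
          n_own <- all(vapply(cores[own], function(p) count_fixed(cand, p) >= 1L, logical(1)))
          if (n_foreign == 0L && n_own) {
            seq <- cand
            for (j in seq_along(own)) site_pos[[paste(own[j], id)]] <- pos[j]
            ok <- TRUE
            break
          }
          ok <- FALSE
        }
        if (!ok) stop("planted-site insertion failed; use longer sequences or a shorter seed",
                      call. = FALSE)
      }
      sequences[[id]] <- seq
    }

    gt <- ground_truth(truth, config)
    if (nrow(gt$planted_triads)) {
      gt$planted_triads$lnc_site_pos <- vapply(seq_len(nrow(gt$planted_triads)), function(i) {
        site_pos[[paste(gt$planted_triads$mirna_id[i], gt$planted_triads$lncrna_id[i])]]
      }, integer(1))
      gt$planted_triads$mrna_site_pos <- vapply(seq_len(nrow(gt$planted_triads)), function(i) {
        site_pos[[paste(gt$planted_triads$mirna_id[i], gt$planted_triads$mrna_id[i])]]
      }, integer(1))
    }
    if (is.null(mirnas)) {
      mirnas <- data.frame(mirna_id = character(), seed_7mer = character(),
                           sequence = character(), stringsAsFactors = FALSE)
    }
    list(sequences = sequences, mirnas = mirnas, truth = gt)
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [generate_expression()],
#' [generate_annotation()] and [generate_sequences()] under one config.
#'
#' @param config A [sim_config()].
#' @return A list of class `lncreg_dataset`: `matrix`, `design`, `annotation`,
#'   `sequences`, `mirnas`, `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  expr <- generate_expression(config)
  ann <- generate_annotation(config)
  seqs <- generate_sequences(ann, config)
  out <- list(matrix = expr$matrix, design = expr$design, annotation = ann,
              sequences = seqs$sequences, mirnas = seqs$mirnas,
              truth = seqs$truth, config = config)
  class(out) <- "lncreg_dataset"
  out
}
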