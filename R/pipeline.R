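## End-to-end orchestration: simulate (or load) -> contrasts -> converse-trend
## filter -> co-expression modules -> cis/trans/ceRNA networks -> hub ranking
## -> merged regulatory graph. Fully deterministic for a given config.

#' Pipeline configuration
#'
#' All stage thresholds in one validated object. Unknown fields are rejected
#' (they would be silently ignored otherwise). Either `sim` (a
#' [sim_config()]; the default) or `input_dir` (a directory written by
#' [write_dataset()]) supplies the data.
#'
#' @param sim A [sim_config()] for synthetic input, or NULL when
#'   `input_dir` is given.
#' @param input_dir Optional dataset directory.
#' @param fc_threshold,p_max,q_max,pseudocount Differential-expression gates.
#' @param trend_mode `"strict"` or `"lenient"` converse-trend mode.
#' @param beta_candidates,r2_target,fallback_power Soft-threshold scan.
#' @param cut_height,min_module_size Module detection.
#' @param cis_window_bp Cis proximity window.
#' @param r_threshold Trans correlation threshold.
#' @param seed_rules Seed-match classes to report.
#' @param min_sites Minimum seed sites per ceRNA triad member.
#' @param top_n Hub lncRNAs to rank.
#' @param n_focus Top hubs used as the merged-network focus set.
#' @param ppi_path Optional interaction edge-list TSV; enables the MCODE
#'   stage.
#' @param mcode_node_score_cutoff,mcode_haircut,mcode_min_size MCODE
#'   parameters.
#' @param rng_seed Integer seed propagated to every stochastic stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            fc_threshold = 2, p_max = 0.05, q_max = 0.05,
                            pseudocount = 1,
                            trend_mode = "strict",
                            beta_candidates = 1:20, r2_target = 0.8,
                            fallback_power = 10,
                            cut_height = 0.95, min_module_size = 30L,
                            cis_window_bp = 10000L, r_threshold = 0.95,
                            seed_rules = c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                            min_sites = 1L,
                            top_n = 10L, n_focus = 3L,
                            ppi_path = NULL,
                            mcode_node_score_cutoff = 0.2,
                            mcode_haircut = TRUE, mcode_min_size = 3L,
                            rng_seed = 1L) {
  config <- list(
    sim = sim, input_dir = input_dir,
    fc_threshold = as.numeric(fc_threshold), p_max = as.numeric(p_max),
    q_max = as.numeric(q_max), pseudocount = as.numeric(pseudocount),
    trend_mode = trend_mode,
    beta_candidates = as.integer(beta_candidates),
    r2_target = as.numeric(r2_target),
    fallback_power = as.numeric(fallback_power),
    cut_height = as.numeric(cut_height),
    min_module_size = as.integer(min_module_size),
    cis_window_bp = as.integer(cis_window_bp),
    r_threshold = as.numeric(r_threshold),
    seed_rules = seed_rules, min_sites = as.integer(min_sites),
    top_n = as.integer(top_n), n_focus = as.integer(n_focus),
    ppi_path = ppi_path,
    mcode_node_score_cutoff = as.numeric(mcode_node_score_cutoff),
    mcode_haircut = isTRUE(mcode_haircut),
    mcode_min_size = as.integer(mcode_min_size),
    rng_seed = as.integer(rng_seed)
  )
  fail <- function(msg) stop("invalid pipeline_config: ", msg, call. = FALSE)
  if (is.null(config$sim) && is.null(config$input_dir)) {
    fail("either 'sim' or 'input_dir' must be given")
  }
  if (!is.null(config$sim)) validate_sim_config(config$sim)
  in01 <- function(field) {
    v <- config[[field]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      fail(sprintf("'%s' must lie in [0, 1]", field))
    }
  }
  in01("p_max"); in01("q_max"); in01("r2_target")
  if (config$fc_threshold < 1) fail("'fc_threshold' must be >= 1")
  if (config$pseudocount < 0) fail("'pseudocount' must be >= 0")
  if (!config$trend_mode %in% c("strict", "lenient")) {
    fail("'trend_mode' must be 'strict' or 'lenient'")
  }
  if (config$r_threshold <= 0 || config$r_threshold > 1) {
    fail("'r_threshold' must lie in (0, 1]")
  }
  if (config$mcode_node_score_cutoff < 0 || config$mcode_node_score_cutoff >= 1) {
    fail("'mcode_node_score_cutoff' must lie in [0, 1)")
  }
  bad <- setdiff(config$seed_rules, c("8mer", "7mer-m8", "7mer-A1", "6mer"))
  if (length(bad)) fail(paste("unknown seed rule:", bad[1]))
  if (config$top_n < 1L || config$n_focus < 1L) {
    fail("'top_n' and 'n_focus' must be >= 1")
  }
  class(config) <- "pipeline_config"
  config
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full inference pipeline
#'
#' Executes: synthetic generation (or dataset loading), the two treatment
#' contrasts, the converse-trend (TTR-DEG) filter, soft-threshold selection
#' and module detection with trait correlation, cis/trans/ceRNA target
#' networks over the TTR-DEG sets, hub ranking by trans degree, and the
#' merged regulatory graph around the top hubs. Optionally runs MCODE on a
#' supplied interaction edge list. All tables are written to `out_dir`
#' (byte-identical across runs of one config) together with a manifest
#' recording the package version, config and config hash.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress per-stage messages (default FALSE).
#' @return A list bundle with every stage result (invisibly also written to
#'   `out_dir`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  say <- function(...) if (!quiet) message("[lncreg] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  say("stage: input")
  data <- stage("input", {
    if (!is.null(config$input_dir)) {
      read_dataset(config$input_dir)
    } else {
      ds <- simulate_dataset(config$sim)
      write_dataset(ds, file.path(out_dir, "dataset"))
      ds
    }
  })
  groups <- unique(data$design$group)

  say("stage: contrasts")
  contrasts <- stage("contrasts", {
    run1 <- function(test, ctrl) {
      run_contrast(data$matrix, data$design, test, ctrl,
                   fc_threshold = config$fc_threshold, p_max = config$p_max,
                   q_max = config$q_max, pseudocount = config$pseudocount,
                   annotation = data$annotation)
    }
    list(hg_vs_lg = run1(groups[2], groups[1]),
         ttr_vs_hg = run1(groups[3], groups[2]))
  })
  write_tsv(contrasts$hg_vs_lg, file.path(out_dir, "contrast_hg_vs_lg.tsv"))
  write_tsv(contrasts$ttr_vs_hg, file.path(out_dir, "contrast_ttr_vs_hg.tsv"))

  say("stage: trend filter")
  ttr <- stage("trend filter", {
    ttr_trend_filter(contrasts$hg_vs_lg, contrasts$ttr_vs_hg,
                     data$annotation, mode = config$trend_mode)
  })
  write_tsv(ttr$table, file.path(out_dir, "ttr_degs.tsv"))

  say("stage: modules")
  modules <- stage("modules", {
    sft <- pick_soft_threshold(data$matrix,
                               candidate_powers = config$beta_candidates,
                               r2_target = config$r2_target,
                               fallback_power = config$fallback_power)
    adj <- adjacency_matrix(data$matrix, power = sft$power)
    tom <- topological_overlap(adj)
    labels <- detect_modules(tom, min_module_size = config$min_module_size,
                             cut_height = config$cut_height)
    res <- list(soft_threshold = sft, labels = labels,
                eigengenes = NULL, trait_cor = NULL)
    if (any(labels != "grey")) {
      me <- module_eigengene(data$matrix, labels)
      traits <- default_traits(data$design, groups)
      res$eigengenes <- me
      res$trait_cor <- module_trait_correlation(me$eigengenes, traits)
    }
    res
  })
  write_tsv(modules$soft_threshold$scan, file.path(out_dir, "soft_threshold.tsv"))
  write_tsv(data.frame(transcript_id = names(modules$labels),
                       module = unname(modules$labels),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "modules.tsv"))
  if (!is.null(modules$trait_cor)) {
    write_tsv(modules$trait_cor$correlations,
              file.path(out_dir, "module_trait.tsv"))
    me_df <- data.frame(module = rownames(modules$eigengenes$eigengenes),
                        modules$eigengenes$eigengenes, check.names = FALSE,
                        stringsAsFactors = FALSE)
    write_tsv(me_df, file.path(out_dir, "eigengenes.tsv"))
  }

  say("stage: cis/trans/ceRNA networks")
  networks <- stage("networks", {
    cis <- cis_pairs(data$annotation, ttr$ttr_lncrna, ttr$ttr_mrna,
                     window_bp = config$cis_window_bp)
    trans <- trans_pairs(data$matrix, ttr$ttr_lncrna, ttr$ttr_mrna,
                         r_threshold = config$r_threshold)
    lnc_sites <- site_table(data$sequences[intersect(ttr$ttr_lncrna,
                                                     names(data$sequences))],
                            data$mirnas, rules = config$seed_rules)
    mrna_sites <- site_table(data$sequences[intersect(ttr$ttr_mrna,
                                                      names(data$sequences))],
                             data$mirnas, rules = config$seed_rules)
    triads <- cerna_triads(lnc_sites, mrna_sites, min_sites = config$min_sites)
    list(cis = cis, trans = trans, lnc_sites = lnc_sites,
         mrna_sites = mrna_sites, triads = triads)
  })
  write_tsv(networks$cis, file.path(out_dir, "cis.tsv"))
  write_tsv(networks$trans, file.path(out_dir, "trans.tsv"))
  write_tsv(networks$triads, file.path(out_dir, "cerna.tsv"))

  say("stage: hubs")
  hubs <- stage("hubs", hub_rank(networks$trans, top_n = config$top_n))
  write_tsv(hubs, file.path(out_dir, "hubs.tsv"))

  say("stage: merged graph")
  merged <- stage("merged graph", {
    focus <- if (nrow(hubs)) {
      utils::head(hubs$lncrna_id, config$n_focus)
    } else {
      utils::head(ttr$ttr_lncrna, config$n_focus)
    }
    if (!length(focus)) NULL else {
      suppressWarnings(merge_networks(networks$cis, networks$trans,
                                      networks$triads, focus,
                                      annotation = data$annotation,
                                      hg_vs_lg = contrasts$hg_vs_lg,
                                      ttr_vs_hg = contrasts$ttr_vs_hg))
    }
  })
  if (!is.null(merged)) {
    write_sif(merged, file.path(out_dir, "merged.sif"))
    igraph::write_graph(merged, file.path(out_dir, "merged.graphml"),
                        format = "graphml")
  }

  mcode <- NULL
  if (!is.null(config$ppi_path)) {
    say("stage: mcode")
    mcode <- stage("mcode", {
      g <- suppressMessages(load_interactions(config$ppi_path))
      list(graph = g,
           complexes = mcode_complexes(
             g, node_score_cutoff = config$mcode_node_score_cutoff,
             haircut = config$mcode_haircut, min_size = config$mcode_min_size),
           degrees = degree_table(g))
    })
    write_tsv(mcode$degrees, file.path(out_dir, "ppi_degrees.tsv"))
    cx <- mcode$complexes
    cx_df <- if (length(cx)) {
      data.frame(
        complex_id = seq_along(cx),
        seed = vapply(cx, `[[`, character(1), "seed"),
        size = vapply(cx, `[[`, integer(1), "size"),
        density = vapply(cx, `[[`, numeric(1), "density"),
        mcode_score = vapply(cx, `[[`, numeric(1), "mcode_score"),
        members = vapply(cx, function(x) paste(x$members, collapse = ","),
                         character(1)),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(complex_id = integer(), seed = character(), size = integer(),
                 density = numeric(), mcode_score = numeric(),
                 members = character(), stringsAsFactors = FALSE)
    }
    write_tsv(cx_df, file.path(out_dir, "ppi_complexes.tsv"))
  }

  manifest <- list(
    package = "lncreg",
    version = as.character(utils::packageVersion("lncreg")),
    rng_seed = config$rng_seed,
    config = unclass(config),
    config_md5 = config_hash(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)

  invisible(list(data = data, contrasts = contrasts, ttr = ttr,
                 modules = modules, networks = networks, hubs = hubs,
                 merged = merged, mcode = mcode, manifest = manifest))
}
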