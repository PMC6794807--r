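## LncRNA target networks: cis (genomic proximity), trans (expression
## correlation), ceRNA (shared miRNA seed sites) and degree-ranked hubs.

annotation_granges <- function(annotation, ids) {
  idx <- match(ids, annotation$transcript_id)
  missing <- ids[is.na(idx)]
  if (length(missing)) {
    warning("transcript(s) without coordinates skipped: ",
            paste(utils::head(missing, 3), collapse = ", "))
    idx <- idx[!is.na(idx)]
  }
  ann <- annotation[idx, , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand,
    transcript_id = ann$transcript_id
  )
}

#' Cis lncRNA/mRNA pairs by genomic proximity
#'
#' A pair is emitted iff both transcripts lie on the same chromosome and
#' either their spans intersect (relation `overlapping`, gap 0) or the
#' end-to-start gap (`start2 - end1`) is at most `window_bp`, boundary
#' included. The relation is the strand-agnostic genomic order of the mRNA
#' relative to the lncRNA (`upstream` = mRNA at lower coordinates). Opposite
#' strandedness of overlapping pairs is reported via `antisense`.
#'
#' @param annotation Annotation data frame (1-based inclusive coordinates).
#' @param lncrna_set,mrna_set Transcript id vectors to pair.
#' @param window_bp Proximity window in bp (default 10000).
#' @return Data frame: lncrna_id, mrna_id, relation, gap_bp, antisense.
#' @export
cis_pairs <- function(annotation, lncrna_set, mrna_set, window_bp = 10000) {
  if (window_bp <= 0) stop("window_bp must be > 0", call. = FALSE)
  empty <- data.frame(lncrna_id = character(), mrna_id = character(),
                      relation = character(), gap_bp = integer(),
                      antisense = logical(), stringsAsFactors = FALSE)
  if (!length(lncrna_set) || !length(mrna_set)) return(empty)
  lnc_gr <- annotation_granges(annotation, lncrna_set)
  mrna_gr <- annotation_granges(annotation, mrna_set)
  if (!length(lnc_gr) || !length(mrna_gr)) return(empty)

  ## candidate pairs: maxgap uses the between-span distance (= gap - 1), so
  ## scan one base wider and apply the exact end-to-start rule afterwards
  hits <- GenomicRanges::findOverlaps(lnc_gr, mrna_gr,
                                      maxgap = window_bp, ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  l <- lnc_gr[S4Vectors::queryHits(hits)]
  m <- mrna_gr[S4Vectors::subjectHits(hits)]
  overlap <- IRanges::poverlaps(IRanges::ranges(l), IRanges::ranges(m))
  gap <- ifelse(as.logical(overlap), 0L,
                ifelse(GenomicRanges::start(m) > GenomicRanges::end(l),
                       GenomicRanges::start(m) - GenomicRanges::end(l),
                       GenomicRanges::start(l) - GenomicRanges::end(m)))
  keep <- gap <= window_bp
  relation <- ifelse(as.logical(overlap), "overlapping",
                     ifelse(GenomicRanges::end(m) < GenomicRanges::start(l),
                            "upstream", "downstream"))
  out <- data.frame(
    lncrna_id = l$transcript_id, mrna_id = m$transcript_id,
    relation = relation, gap_bp = as.integer(gap),
    antisense = as.character(GenomicRanges::strand(l)) !=
      as.character(GenomicRanges::strand(m)),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  out <- out[order(out$lncrna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trans lncRNA/mRNA pairs by expression correlation
#'
#' Pearson correlation across all samples on `log2(FPKM + 1)` (raw FPKM
#' optional); an edge is emitted iff `|r| >= r_threshold`. Constant-profile
#' transcripts are skipped with a warning.
#'
#' @param matrix Transcripts x samples FPKM matrix.
#' @param lncrna_set,mrna_set Transcript id vectors.
#' @param r_threshold Absolute correlation threshold in (0, 1\] (default
#'   0.95).
#' @param log_transform Correlate log2(FPKM+1) (default TRUE).
#' @return Data frame: lncrna_id, mrna_id, pearson_r, sign.
#' @export
trans_pairs <- function(matrix, lncrna_set, mrna_set, r_threshold = 0.95,
                        log_transform = TRUE) {
  if (r_threshold <= 0 || r_threshold > 1) {
    stop("r_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (ncol(matrix) < 3L) stop(">= 3 samples required", call. = FALSE)
  empty <- data.frame(lncrna_id = character(), mrna_id = character(),
                      pearson_r = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  lncrna_set <- intersect(lncrna_set, rownames(matrix))
  mrna_set <- intersect(mrna_set, rownames(matrix))
  if (!length(lncrna_set) || !length(mrna_set)) return(empty)
  x <- if (log_transform) log2(matrix + 1) else matrix
  drop_const <- function(ids) {
    constant <- ids[apply(x[ids, , drop = FALSE], 1, stats::sd) == 0]
    if (length(constant)) {
      warning(length(constant), " constant-profile transcript(s) skipped")
    }
    setdiff(ids, constant)
  }
  lncrna_set <- drop_const(lncrna_set)
  mrna_set <- drop_const(mrna_set)
  if (!length(lncrna_set) || !length(mrna_set)) return(empty)
  r <- stats::cor(t(x[lncrna_set, , drop = FALSE]),
                  t(x[mrna_set, , drop = FALSE]))
  idx <- which(abs(r) >= r_threshold, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  out <- data.frame(
    lncrna_id = lncrna_set[idx[, 1]], mrna_id = mrna_set[idx[, 2]],
    pearson_r = r[idx],
    sign = ifelse(r[idx] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  out <- out[out$lncrna_id != out$mrna_id, , drop = FALSE]
  out <- out[order(out$lncrna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Canonical miRNA seed-match sites on a target sequence
#'
#' Scans the target (sense strand, 5'-3') for exact reverse complements of
#' the miRNA 6mer core (positions 2-7), then classifies each location by m8
#' complementarity (target base 5' of the core matches miRNA position 8) and
#' a target `A` opposite miRNA position 1: `8mer` (m8 + A1) > `7mer-m8` >
#' `7mer-A1` > `6mer`. The strongest class allowed by `rules` is reported
#' per location. T and U are equivalent on input.
#'
#' @param target_sequence Target nucleotide sequence (character scalar).
#' @param mirna_sequence miRNA sequence 5'-3' (>= 8 nt), or a 7mer seed
#'   (positions 2-8).
#' @param rules Site classes to report (default all four).
#' @return Data frame: start, end (1-based on the target, spanning the
#'   reported site), match_type.
#' @export
seed_match_sites <- function(target_sequence, mirna_sequence,
                             rules = c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
  rules <- match.arg(rules, several.ok = TRUE)
  target <- toupper(chartr("Uu", "Tt", target_sequence))
  mir <- toupper(chartr("Tt", "Uu", mirna_sequence))
  if (grepl("[^ACGT]", target)) stop("invalid character in target sequence", call. = FALSE)
  if (grepl("[^ACGU]", mir)) stop("invalid character in miRNA sequence", call. = FALSE)
  if (nchar(mir) == 7L) {
    seed27 <- substr(mir, 1L, 6L)   # positions 2-7 of a supplied 7mer seed
    m8 <- substr(mir, 7L, 7L)
  } else if (nchar(mir) >= 8L) {
    seed27 <- substr(mir, 2L, 7L)
    m8 <- substr(mir, 8L, 8L)
  } else {
    stop("miRNA sequence must be >= 8 nt (or a 7mer seed)", call. = FALSE)
  }
  core <- revcomp_dna(seed27)
  m8_comp <- revcomp_dna(m8)

  hits <- gregexpr(core, target, fixed = TRUE)[[1]]
  empty <- data.frame(start = integer(), end = integer(),
                      match_type = character(), stringsAsFactors = FALSE)
  if (hits[1] == -1L) return(empty)
  rows <- lapply(as.integer(hits), function(s) {
    e <- s + 5L
    has_m8 <- s > 1L && substr(target, s - 1L, s - 1L) == m8_comp
    has_a1 <- e < nchar(target) && substr(target, e + 1L, e + 1L) == "A"
    candidates <- rbind(
      c("8mer", has_m8 && has_a1, -1L, 1L),
      c("7mer-m8", has_m8, -1L, 0L),
      c("7mer-A1", has_a1, 0L, 1L),
      c("6mer", TRUE, 0L, 0L)
    )
    for (i in seq_len(nrow(candidates))) {
      if (as.logical(candidates[i, 2]) && candidates[i, 1] %in% rules) {
        return(data.frame(start = s + as.integer(candidates[i, 3]),
                          end = e + as.integer(candidates[i, 4]),
                          match_type = candidates[i, 1],
                          stringsAsFactors = FALSE))
      }
    }
    NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Seed-site table over target and miRNA sets
#'
#' Applies [seed_match_sites()] to every (miRNA, target) combination.
#'
#' @param sequences Named character vector of target sequences.
#' @param mirnas Data frame with `mirna_id` and `sequence` (or `seed_7mer`).
#' @param rules Site classes, see [seed_match_sites()].
#' @return Data frame: mirna_id, target_id, start, end, match_type.
#' @export
site_table <- function(sequences, mirnas,
                       rules = c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
  mir_seq <- if ("sequence" %in% names(mirnas)) mirnas$sequence else mirnas$seed_7mer
  rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    for (id in names(sequences)) {
      sites <- seed_match_sites(sequences[[id]], mir_seq[i], rules = rules)
      if (nrow(sites)) {
        sites$mirna_id <- mirnas$mirna_id[i]
        sites$target_id <- id
        rows[[length(rows) + 1L]] <- sites
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(), target_id = character(),
                      start = integer(), end = integer(),
                      match_type = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)[, c("mirna_id", "target_id", "start", "end", "match_type")]
  rownames(out) <- NULL
  out
}

#' Competing-endogenous-RNA triads from shared seed sites
#'
#' A triad (lncRNA, miRNA, mRNA) is emitted iff the lncRNA and the mRNA each
#' carry at least `min_sites` seed sites for that miRNA.
#'
#' @param lnc_sites,mrna_sites Site tables ([site_table()]) for the lncRNA
#'   and mRNA universes.
#' @param min_sites Minimum sites on each member (default 1).
#' @return Data frame: lncrna_id, mirna_id, mrna_id, lnc_site_count,
#'   mrna_site_count (deduplicated, sorted).
#' @export
cerna_triads <- function(lnc_sites, mrna_sites, min_sites = 1L) {
  if (min_sites < 1L) stop("min_sites must be >= 1", call. = FALSE)
  empty <- data.frame(lncrna_id = character(), mirna_id = character(),
                      mrna_id = character(), lnc_site_count = integer(),
                      mrna_site_count = integer(), stringsAsFactors = FALSE)
  if (!nrow(lnc_sites) || !nrow(mrna_sites)) return(empty)
  count <- function(sites) {
    agg <- stats::aggregate(list(n = sites$start),
                            by = list(mirna_id = sites$mirna_id,
                                      target_id = sites$target_id),
                            FUN = length)
    agg[agg$n >= min_sites, , drop = FALSE]
  }
  lc <- count(lnc_sites)
  mc <- count(mrna_sites)
  merged <- merge(lc, mc, by = "mirna_id", suffixes = c("_lnc", "_mrna"))
  if (!nrow(merged)) return(empty)
  out <- data.frame(
    lncrna_id = merged$target_id_lnc, mirna_id = merged$mirna_id,
    mrna_id = merged$target_id_mrna,
    lnc_site_count = merged$n_lnc, mrna_site_count = merged$n_mrna,
    stringsAsFactors = FALSE
  )
  out <- out[out$lncrna_id != out$mrna_id, , drop = FALSE]
  out <- unique(out)
  out <- out[order(out$lncrna_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hub lncRNAs ranked by trans-network degree
#'
#' Degree counts unique mRNA partners in the trans network; ties are broken
#' lexicographically by lncRNA id.
#'
#' @param trans_edges Data frame from [trans_pairs()].
#' @param top_n Number of hubs to return (default 10).
#' @return Data frame: rank, lncrna_id, degree.
#' @export
hub_rank <- function(trans_edges, top_n = 10L) {
  if (top_n < 1L) stop("top_n must be >= 1", call. = FALSE)
  if (!nrow(trans_edges)) {
    return(data.frame(rank = integer(), lncrna_id = character(),
                      degree = integer(), stringsAsFactors = FALSE))
  }
  uniq <- unique(trans_edges[, c("lncrna_id", "mrna_id")])
  deg <- table(uniq$lncrna_id)
  ord <- order(-as.integer(deg), names(deg))
  n <- min(top_n, length(deg))
  data.frame(
    rank = seq_len(n),
    lncrna_id = names(deg)[ord][seq_len(n)],
    degree = as.integer(deg)[ord][seq_len(n)],
    stringsAsFactors = FALSE
  )
}

#' Merge cis, trans and ceRNA relations into one typed regulatory graph
#'
#' Builds an igraph multigraph restricted to edges incident to the focus
#' lncRNAs, plus the miRNA bridge edges of their triads. Node attributes:
#' `type` (lncRNA/mRNA/miRNA), `biotype`, and DE direction per contrast when
#' contrast results are supplied. Edge attributes: `edge_type`
#' (cis/trans/cerna), `relation`, `sign`, `weight` (|r| for trans, site
#' count for ceRNA, 1 for cis).
#'
#' @param cis,trans,triads Outputs of [cis_pairs()], [trans_pairs()],
#'   [cerna_triads()] (any may be empty).
#' @param focus_lncrnas Non-empty character vector of lncRNAs of interest.
#' @param annotation Optional annotation (biotypes).
#' @param hg_vs_lg,ttr_vs_hg Optional contrast results (DE direction
#'   attributes).
#' @return An igraph object.
#' @export
merge_networks <- function(cis, trans, triads, focus_lncrnas,
                           annotation = NULL, hg_vs_lg = NULL,
                           ttr_vs_hg = NULL) {
  if (!length(focus_lncrnas)) stop("focus set must be non-empty", call. = FALSE)
  cis_f <- cis[cis$lncrna_id %in% focus_lncrnas, , drop = FALSE]
  trans_f <- trans[trans$lncrna_id %in% focus_lncrnas, , drop = FALSE]
  triads_f <- triads[triads$lncrna_id %in% focus_lncrnas, , drop = FALSE]

  seen <- unique(c(cis$lncrna_id, trans$lncrna_id, triads$lncrna_id))
  absent <- setdiff(focus_lncrnas, seen)
  if (length(absent)) {
    warning("focus lncRNA(s) absent from all networks: ",
            paste(absent, collapse = ", "))
  }

  edges <- list()
  if (nrow(cis_f)) {
    edges$cis <- data.frame(from = cis_f$lncrna_id, to = cis_f$mrna_id,
                            edge_type = "cis", relation = cis_f$relation,
                            sign = NA_character_, weight = 1,
                            stringsAsFactors = FALSE)
  }
  if (nrow(trans_f)) {
    edges$trans <- data.frame(from = trans_f$lncrna_id, to = trans_f$mrna_id,
                              edge_type = "trans", relation = NA_character_,
                              sign = trans_f$sign,
                              weight = abs(trans_f$pearson_r),
                              stringsAsFactors = FALSE)
  }
  if (nrow(triads_f)) {
    edges$cerna <- rbind(
      data.frame(from = triads_f$lncrna_id, to = triads_f$mirna_id,
                 edge_type = "cerna", relation = NA_character_,
                 sign = NA_character_, weight = triads_f$lnc_site_count,
                 stringsAsFactors = FALSE),
      data.frame(from = triads_f$mirna_id, to = triads_f$mrna_id,
                 edge_type = "cerna", relation = NA_character_,
                 sign = NA_character_, weight = triads_f$mrna_site_count,
                 stringsAsFactors = FALSE)
    )
  }
  edge_df <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), edge_type = character(),
               relation = character(), sign = character(), weight = numeric(),
               stringsAsFactors = FALSE)
  rownames(edge_df) <- NULL

  mir_nodes <- unique(triads_f$mirna_id)
  nodes <- unique(c(focus_lncrnas, edge_df$from, edge_df$to))
  node_df <- data.frame(name = nodes, stringsAsFactors = FALSE)
  node_df$type <- ifelse(nodes %in% mir_nodes, "miRNA",
                         ifelse(nodes %in% c(focus_lncrnas, triads$lncrna_id,
                                             cis$lncrna_id, trans$lncrna_id),
                                "lncRNA", "mRNA"))
  if (!is.null(annotation)) {
    node_df$biotype <- annotation$biotype[match(nodes, annotation$transcript_id)]
  }
  attach_dir <- function(contrast, col) {
    if (is.null(contrast)) return(NULL)
    node_df[[col]] <<- contrast$status[match(nodes, contrast$transcript_id)]
  }
  attach_dir(hg_vs_lg, "de_hg_vs_lg")
  attach_dir(ttr_vs_hg, "de_ttr_vs_hg")

  igraph::graph_from_data_frame(edge_df, directed = FALSE, vertices = node_df)
}
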