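## Transcript-level two-group differential expression, gene-level
## aggregation, and the converse-trend (TTR-DEG) filter.

#' Log2 fold change between two groups of FPKM values
#'
#' `log2((mean(test) + pseudocount) / (mean(control) + pseudocount))`. A
#' positive pseudocount is required whenever either group mean is zero.
#'
#' @param test_values,control_values Non-negative numeric vectors.
#' @param pseudocount Non-negative constant added to both means (default 1).
#' @return The log2 fold change (scalar).
#' @export
log2_fold_change <- function(test_values, control_values, pseudocount = 1) {
  if (!length(test_values) || !length(control_values)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  m_t <- mean(test_values)
  m_c <- mean(control_values)
  if (pseudocount == 0 && (m_t == 0 || m_c == 0)) {
    stop("undefined ratio: zero group mean with pseudocount 0", call. = FALSE)
  }
  log2((m_t + pseudocount) / (m_c + pseudocount))
}

#' Two-group t test
#'
#' Two-sided t test with the sign convention `t ~ mean(a) - mean(b)`.
#' The equal-variance (Student) form is the default; Welch is available.
#' When both groups are constant the test degenerates: equal means give
#' `t = 0, p = 1`; unequal means give `p = 0` with a degeneracy flag.
#'
#' @param group_a,group_b Numeric vectors with >= 2 values each.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return A list with `t_stat`, `p_value`, `df`, `degenerate`.
#' @export
two_group_t_test <- function(group_a, group_b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t_stat = 0, p_value = 1,
                  df = length(group_a) + length(group_b) - 2, degenerate = TRUE))
    }
    return(list(t_stat = sign(mean(group_a) - mean(group_b)) * Inf,
                p_value = 0, df = length(group_a) + length(group_b) - 2,
                degenerate = TRUE))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = (variant == "student"))
  list(t_stat = unname(fit$statistic), p_value = fit$p.value,
       df = unname(fit$parameter), degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p values
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @return Adjusted q values, order-preserving with respect to input
#'   positions and capped at 1.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Run one two-group contrast over an expression matrix
#'
#' For every transcript: group-mean log2 fold change with pseudocount, a
#' two-group t test, and BH adjustment computed jointly across all
#' transcripts of the contrast (coding and non-coding together). A
#' transcript is called `up` when `fc >= fc_threshold`, `p <= p_max` and
#' `q <= q_max`; `down` when `fc <= 1/fc_threshold` at the same gates;
#' otherwise `ns`. The published gates are FC >= 2, P <= 0.05, FDR <= 0.05.
#'
#' @param matrix Transcripts x samples non-negative FPKM matrix with unique
#'   dimnames.
#' @param design Data frame with columns `sample`, `group` covering the
#'   matrix columns.
#' @param test_group,control_group Group labels to contrast (test vs control).
#' @param fc_threshold,p_max,q_max,pseudocount Significance gates.
#' @param variant t-test variant, see [two_group_t_test()].
#' @param annotation Optional annotation data frame; attaches gene_id and
#'   biotype columns.
#' @return A data frame (one row per transcript): transcript_id, log2fc, fc,
#'   t_stat, p_value, q_value, status; with attributes `test_group`,
#'   `control_group`.
#' @export
run_contrast <- function(matrix, design, test_group, control_group,
                         fc_threshold = 2, p_max = 0.05, q_max = 0.05,
                         pseudocount = 1, variant = "student",
                         annotation = NULL) {
  validate_expression(matrix, design)
  for (g in c(test_group, control_group)) {
    n <- sum(design$group == g)
    if (n < 2L) stop(sprintf("group '%s' has %d sample(s); >= 2 required", g, n),
                     call. = FALSE)
  }
  t_cols <- design$sample[design$group == test_group]
  c_cols <- design$sample[design$group == control_group]

  n_tx <- nrow(matrix)
  log2fc <- t_stat <- p_value <- numeric(n_tx)
  for (i in seq_len(n_tx)) {
    a <- matrix[i, t_cols]
    b <- matrix[i, c_cols]
    log2fc[i] <- log2_fold_change(a, b, pseudocount)
    tt <- two_group_t_test(log2(a + pseudocount), log2(b + pseudocount),
                           variant = variant)
    t_stat[i] <- tt$t_stat
    p_value[i] <- tt$p_value
  }
  q_value <- bh_fdr(p_value)
  fc <- 2^log2fc
  sig <- p_value <= p_max & q_value <= q_max
  status <- rep("ns", n_tx)
  status[sig & fc >= fc_threshold] <- "up"
  status[sig & fc <= 1 / fc_threshold] <- "down"

  out <- data.frame(
    transcript_id = rownames(matrix), log2fc = log2fc, fc = fc,
    t_stat = t_stat, p_value = p_value, q_value = q_value, status = status,
    stringsAsFactors = FALSE
  )
  if (!is.null(annotation)) {
    idx <- match(out$transcript_id, annotation$transcript_id)
    out$gene_id <- annotation$gene_id[idx]
    out$biotype <- annotation$biotype[idx]
  }
  attr(out, "test_group") <- test_group
  attr(out, "control_group") <- control_group
  attr(out, "thresholds") <- list(fc_threshold = fc_threshold, p_max = p_max,
                                  q_max = q_max, pseudocount = pseudocount)
  out
}

validate_expression <- function(matrix, design) {
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix))) {
    stop("expression matrix needs unique transcript ids as rownames", call. = FALSE)
  }
  if (is.null(colnames(matrix)) || anyDuplicated(colnames(matrix))) {
    stop("expression matrix needs unique sample ids as colnames", call. = FALSE)
  }
  if (any(matrix < 0)) stop("FPKM values must be non-negative", call. = FALSE)
  if (!all(c("sample", "group") %in% names(design))) {
    stop("design needs 'sample' and 'group' columns", call. = FALSE)
  }
  if (!all(colnames(matrix) %in% design$sample)) {
    stop("every matrix column must appear in the design", call. = FALSE)
  }
  invisible(TRUE)
}

#' Aggregate transcript calls to gene level
#'
#' A gene is `de` when, per the chosen rule, at least one
#' (`"any_transcript"`, default) or at least two (`"at_least_two"`) of its
#' transcripts are significant in the contrast. Genes whose significant
#' transcripts disagree in direction are flagged.
#'
#' @param contrast Output of [run_contrast()].
#' @param annotation Annotation data frame mapping transcripts to genes.
#' @param rule `"any_transcript"` or `"at_least_two"`.
#' @return Data frame: gene_id, call (`de`/`ns`), n_sig, direction_conflict.
#' @export
gene_level_calls <- function(contrast, annotation,
                             rule = c("any_transcript", "at_least_two")) {
  rule <- match.arg(rule)
  idx <- match(contrast$transcript_id, annotation$transcript_id)
  if (anyNA(idx)) {
    stop("transcript(s) missing from annotation: ",
         paste(utils::head(contrast$transcript_id[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  }
  gene <- annotation$gene_id[idx]
  need <- if (rule == "any_transcript") 1L else 2L
  split_status <- split(contrast$status, gene)
  n_sig <- vapply(split_status, function(s) sum(s != "ns"), integer(1))
  conflict <- vapply(split_status, function(s) {
    any(s == "up") && any(s == "down")
  }, logical(1))
  data.frame(
    gene_id = names(split_status),
    call = ifelse(n_sig >= need, "de", "ns"),
    n_sig = n_sig, direction_conflict = conflict,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Converse-trend (TTR-DEG) filter between the two treatment contrasts
#'
#' A transcript is TTR-related when its log2 fold changes in (HG vs LG) and
#' (HG+TTR vs HG) have opposite sign and the mode's significance requirement
#' holds: `strict` (default) demands a non-`ns` status in both contrasts,
#' `lenient` only in the TTR contrast. The result is split by biotype into
#' TTR-mRNAs and TTR-lncRNAs.
#'
#' @param hg_vs_lg,ttr_vs_hg [run_contrast()] results over the same
#'   transcript universe.
#' @param annotation Annotation data frame (for biotypes and gene ids).
#' @param mode `"strict"` or `"lenient"`.
#' @return A list of class `ttr_deg_set`: `table` (per-member rows with both
#'   contrasts' statistics), `ttr_mrna`, `ttr_lncrna` (transcript id
#'   vectors), `mode`.
#' @export
ttr_trend_filter <- function(hg_vs_lg, ttr_vs_hg, annotation,
                             mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (!setequal(hg_vs_lg$transcript_id, ttr_vs_hg$transcript_id)) {
    stop("the two contrasts cover different transcript universes", call. = FALSE)
  }
  c2 <- ttr_vs_hg[match(hg_vs_lg$transcript_id, ttr_vs_hg$transcript_id), ]
  opposite <- sign(hg_vs_lg$log2fc) * sign(c2$log2fc) < 0
  sig <- if (mode == "strict") {
    hg_vs_lg$status != "ns" & c2$status != "ns"
  } else {
    c2$status != "ns"
  }
  member <- opposite & sig
  idx <- match(hg_vs_lg$transcript_id[member], annotation$transcript_id)
  tab <- data.frame(
    transcript_id = hg_vs_lg$transcript_id[member],
    gene_id = annotation$gene_id[idx],
    biotype = annotation$biotype[idx],
    log2fc_hg_vs_lg = hg_vs_lg$log2fc[member],
    p_hg_vs_lg = hg_vs_lg$p_value[member],
    fdr_hg_vs_lg = hg_vs_lg$q_value[member],
    status_hg_vs_lg = hg_vs_lg$status[member],
    log2fc_ttr_vs_hg = c2$log2fc[member],
    p_ttr_vs_hg = c2$p_value[member],
    fdr_ttr_vs_hg = c2$q_value[member],
    status_ttr_vs_hg = c2$status[member],
    stringsAsFactors = FALSE
  )
  out <- list(
    table = tab,
    ttr_mrna = tab$transcript_id[tab$biotype == "coding"],
    ttr_lncrna = tab$transcript_id[tab$biotype %in% c("lncRNA", "novel_lncRNA")],
    mode = mode
  )
  class(out) <- "ttr_deg_set"
  out
}

#' Relative expression by the comparative Ct method (2^-ddCt)
#'
#' `dCt = Ct_target - Ct_reference` per condition; `ddCt = dCt_test -
#' dCt_control`; fold = `2^-ddCt`.
#'
#' @param ct_target_test,ct_ref_test,ct_target_ctrl,ct_ref_ctrl Finite Ct
#'   values (scalars or equal-length vectors, averaged first).
#' @return Fold change relative to the control condition.
#' @export
ddct_relative_expression <- function(ct_target_test, ct_ref_test,
                                     ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(cts))) stop("all Ct values must be finite", call. = FALSE)
  ddct <- (mean(ct_target_test) - mean(ct_ref_test)) -
    (mean(ct_target_ctrl) - mean(ct_ref_ctrl))
  2^(-ddct)
}

#' Ratio of group means
#'
#' @param group_a_values,group_b_values Numeric vectors (numerator /
#'   denominator groups).
#' @param digits Decimal places for the returned ratio (default 2, as
#'   printed in area-ratio summaries); use `NULL` for full precision.
#' @return `mean(a) / mean(b)`, rounded to `digits`.
#' @export
mean_ratio <- function(group_a_values, group_b_values, digits = 2) {
  m_b <- mean(group_b_values)
  if (!is.finite(m_b) || m_b <= 0) {
    stop("undefined ratio: denominator mean must be > 0", call. = FALSE)
  }
  r <- mean(group_a_values) / m_b
  if (is.null(digits)) r else round(r, digits)
}
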