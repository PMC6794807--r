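## Weighted co-expression analysis: soft-threshold scan, adjacency,
## topological overlap, static-cut module detection, module eigengenes and
## module-trait correlation.

## Standard module colour palette, assigned in decreasing size order.
module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue"
)

#' Co-expression adjacency matrix
#'
#' Pairwise Pearson correlation of transcripts across samples (computed on
#' `log2(FPKM + 1)` when `log_transform` is TRUE), raised to the soft
#' threshold: unsigned `|r|^power` (default) or signed `((1 + r)/2)^power`.
#' Constant transcripts are dropped with a warning.
#'
#' @param matrix Transcripts x samples expression matrix.
#' @param power Soft threshold beta (>= 1).
#' @param type `"unsigned"` or `"signed"`.
#' @param log_transform Work on log2(FPKM+1) (default TRUE).
#' @return Symmetric adjacency matrix with zero diagonal.
#' @export
adjacency_matrix <- function(matrix, power = 6,
                             type = c("unsigned", "signed"),
                             log_transform = TRUE) {
  type <- match.arg(type)
  if (power < 1) stop("power must be >= 1", call. = FALSE)
  x <- if (log_transform) log2(matrix + 1) else matrix
  keep <- apply(x, 1, stats::sd) > 0
  if (any(!keep)) {
    warning(sum(!keep), " constant transcript(s) dropped before correlation")
    x <- x[keep, , drop = FALSE]
  }
  r <- stats::cor(t(x))
  if (!all(is.finite(r))) stop("non-finite correlations", call. = FALSE)
  a <- if (type == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 0
  a
}

#' Soft-threshold selection by scale-free topology fit
#'
#' For each candidate power the connectivity distribution is binned and the
#' signed R-squared of the log10(p(k)) ~ log10(k) regression is recorded
#' (sign flipped when the slope is positive, as in standard scale-free fit
#' indices). The chosen power is the smallest reaching `r2_target`; when
#' none does, `fallback_power` is returned with a warning flag.
#'
#' @param matrix Transcripts x samples expression matrix.
#' @param candidate_powers Positive integer powers to scan (default 1:20).
#' @param r2_target Fit threshold (default 0.8).
#' @param fallback_power Power used when no candidate reaches the target
#'   (default 10).
#' @param type,log_transform Passed to [adjacency_matrix()].
#' @return A list: `scan` (data frame power / scale_free_fit_r2 /
#'   mean_connectivity), `power`, `fallback_used`.
#' @export
pick_soft_threshold <- function(matrix, candidate_powers = 1:20,
                                r2_target = 0.8, fallback_power = 10,
                                type = "unsigned", log_transform = TRUE) {
  if (!length(candidate_powers) || any(candidate_powers < 1)) {
    stop("candidate_powers must be positive", call. = FALSE)
  }
  if (ncol(matrix) < 4L) stop(">= 4 samples required", call. = FALSE)
  x <- if (log_transform) log2(matrix + 1) else matrix
  keep <- apply(x, 1, stats::sd) > 0
  if (any(!keep)) {
    message(sum(!keep), " constant transcript(s) dropped before correlation")
    x <- x[keep, , drop = FALSE]
  }
  r <- stats::cor(t(x))
  base <- if (type == "unsigned") abs(r) else (1 + r) / 2
  diag(base) <- 0

  scan <- do.call(rbind, lapply(candidate_powers, function(beta) {
    a <- base^beta
    diag(a) <- 0
    k <- rowSums(a)
    data.frame(power = beta,
               scale_free_fit_r2 = scale_free_fit(k),
               mean_connectivity = mean(k))
  }))
  ok <- scan$scale_free_fit_r2 >= r2_target
  if (any(ok)) {
    list(scan = scan, power = scan$power[which(ok)[1]], fallback_used = FALSE)
  } else {
    list(scan = scan, power = fallback_power, fallback_used = TRUE)
  }
}

## Signed R^2 of the log-log degree-distribution regression (10 bins).
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < 2L || stats::sd(k) == 0) return(0)
  bins <- cut(k, breaks = n_bins)
  k_mean <- tapply(k, bins, mean)
  p_k <- tabulate(bins, nbins = n_bins) / length(k)
  keep <- !is.na(k_mean) & p_k > 0
  if (sum(keep) < 3L) return(0)
  fit <- stats::lm(log10(p_k[keep]) ~ log10(k_mean[keep]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `TOM_ii = 1`; entries lie in \[0, 1\] for any adjacency in \[0, 1\].
#'
#' @param adjacency Symmetric adjacency matrix in \[0, 1\] with zero
#'   diagonal, e.g. from [adjacency_matrix()].
#' @return The TOM matrix.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-10) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (!all(is.finite(a)) || any(a < 0 | a > 1)) {
    stop("adjacency entries must be finite and in [0, 1]", call. = FALSE)
  }
  diag(a) <- 0
  shared <- a %*% a
  k <- rowSums(a)
  min_k <- outer(k, k, pmin)
  tom <- (shared + a) / (min_k + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Module detection by average-linkage clustering of TOM dissimilarity
#'
#' Hierarchical clustering (average linkage) on `1 - TOM`, cut statically at
#' `cut_height`; clusters smaller than `min_module_size` are set to
#' `"grey"`. Surviving modules are named from a fixed colour list in
#' decreasing size order (ties broken by first member position).
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param min_module_size Minimum members per module (default 30).
#' @param cut_height Static tree-cut height on the dissimilarity scale
#'   (default 0.95).
#' @return Named character vector transcript -> module colour.
#' @export
detect_modules <- function(tom, min_module_size = 30L, cut_height = 0.95) {
  if (!nrow(tom)) stop("empty TOM", call. = FALSE)
  if (min_module_size < 2L) stop("min_module_size must be >= 2", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", nrow(tom))
  names(labels) <- rownames(tom)
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) {
      color <- if (i <= length(module_colors)) module_colors[i] else sprintf("module%d", i)
      labels[raw == as.integer(ord[i])] <- color
    }
  }
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component (unit-norm
#' sample scores) of the row-standardised member x sample submatrix, with
#' its sign fixed so that it correlates positively with the module's mean
#' standardised profile. Constant member rows are dropped with a warning;
#' a module with no variable members is an error.
#'
#' @param matrix Transcripts x samples expression matrix (FPKM).
#' @param labels Module assignment from [detect_modules()] (`"grey"` is
#'   ignored).
#' @param log_transform Standardise log2(FPKM+1) rows (default TRUE).
#' @return A list: `eigengenes` (module x sample matrix) and
#'   `variance_explained` (named vector).
#' @export
module_eigengene <- function(matrix, labels, log_transform = TRUE) {
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) stop("no non-grey modules", call. = FALSE)
  x <- if (log_transform) log2(matrix + 1) else matrix
  me <- matrix(NA_real_, length(mods), ncol(x),
               dimnames = list(mods, colnames(x)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    members <- names(labels)[labels == m]
    if (length(members) < 2L) stop("module '", m, "' has < 2 members", call. = FALSE)
    sub <- x[members, , drop = FALSE]
    variable <- apply(sub, 1, stats::sd) > 0
    if (!any(variable)) stop("module '", m, "' is degenerate (all constant)", call. = FALSE)
    if (any(!variable)) {
      warning(sum(!variable), " constant member(s) dropped from module '", m, "'")
      sub <- sub[variable, , drop = FALSE]
    }
    s <- t(scale(t(sub)))
    sv <- svd(s)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(s)) < 0) e <- -e
    me[m, ] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, variance_explained = ve)
}

#' Default binary traits for the three-group design
#'
#' `glucose` marks the two high-glucose groups; `ttr` marks the TTR
#' co-treatment group.
#'
#' @param design Sample/group data frame.
#' @param groups Ordered group labels (default LG, HG, HG_TTR).
#' @return Data frame of numeric trait vectors, rownames = samples.
#' @export
default_traits <- function(design, groups = c("LG", "HG", "HG_TTR")) {
  data.frame(
    row.names = design$sample,
    glucose = as.numeric(design$group %in% groups[2:3]),
    ttr = as.numeric(design$group == groups[3])
  )
}

#' Module-trait correlation and hub-module nomination
#'
#' Pearson correlation (with two-sided p) between each module eigengene and
#' each numeric trait. The hub module maximises `min(|r|)` across traits,
#' formalising "highest correlation with both" traits; `mean(|r|)` is
#' available as an alternative.
#'
#' @param eigengenes Module x sample matrix from [module_eigengene()].
#' @param traits Data frame of numeric sample traits (rows = samples, in
#'   matrix column order).
#' @param criterion `"min_abs"` (default) or `"mean_abs"`.
#' @return A list: `correlations` (long data frame module/trait/r/p),
#'   `hub_module`, `hub_score`.
#' @export
module_trait_correlation <- function(eigengenes, traits,
                                     criterion = c("min_abs", "mean_abs")) {
  criterion <- match.arg(criterion)
  traits <- as.data.frame(traits)
  if (any(vapply(traits, function(v) stats::sd(v) == 0, logical(1)))) {
    stop("constant trait: correlation undefined", call. = FALSE)
  }
  rows <- list()
  for (m in rownames(eigengenes)) {
    for (tr in names(traits)) {
      ct <- stats::cor.test(eigengenes[m, ], traits[[tr]])
      rows[[paste(m, tr)]] <- data.frame(
        module = m, trait = tr, r = unname(ct$estimate), p = ct$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  correlations <- do.call(rbind, rows)
  rownames(correlations) <- NULL
  agg <- vapply(rownames(eigengenes), function(m) {
    rs <- abs(correlations$r[correlations$module == m])
    if (criterion == "min_abs") min(rs) else mean(rs)
  }, numeric(1))
  list(correlations = correlations,
       hub_module = names(agg)[which.max(agg)],
       hub_score = max(agg))
}
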