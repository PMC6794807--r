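## Independent brute-force oracles used to cross-check the implementation.
## These deliberately avoid the package's own code paths.

## Benjamini-Hochberg step-up, written directly from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  if (!n) return(numeric())
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  if (n >= 2) {
    for (i in (n - 1):1) {
      q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
    }
  }
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

## Reverse complement without Biostrings.
revcomp_oracle <- function(x) {
  x <- chartr("Uu", "Tt", x)
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

## Exhaustive seed-site scan: slide over every target position, compare
## substrings to the expected core/m8/A1 layout, report the strongest class.
seed_scan_oracle <- function(target, mir) {
  target <- toupper(chartr("Uu", "Tt", target))
  mir <- toupper(chartr("Tt", "Uu", mir))
  if (nchar(mir) == 7) {
    core <- revcomp_oracle(substr(mir, 1, 6))
    m8c <- revcomp_oracle(substr(mir, 7, 7))
  } else {
    core <- revcomp_oracle(substr(mir, 2, 7))
    m8c <- revcomp_oracle(substr(mir, 8, 8))
  }
  n <- nchar(target)
  out <- NULL
  for (s in seq_len(max(0, n - 5))) {
    if (substr(target, s, s + 5) != core) next
    has_m8 <- s > 1 && substr(target, s - 1, s - 1) == m8c
    has_a1 <- s + 6 <= n && substr(target, s + 6, s + 6) == "A"
    if (has_m8 && has_a1) {
      row <- c(s - 1, s + 6, "8mer")
    } else if (has_m8) {
      row <- c(s - 1, s + 5, "7mer-m8")
    } else if (has_a1) {
      row <- c(s, s + 6, "7mer-A1")
    } else {
      row <- c(s, s + 5, "6mer")
    }
    out <- rbind(out, row)
  }
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(),
                      match_type = character(), stringsAsFactors = FALSE))
  }
  data.frame(start = as.integer(out[, 1]), end = as.integer(out[, 2]),
             match_type = out[, 3], row.names = NULL, stringsAsFactors = FALSE)
}

## All-pairs interval scan with the end-to-start gap convention.
cis_oracle <- function(annotation, lnc_ids, mrna_ids, window_bp) {
  rows <- NULL
  ann <- annotation
  for (l in lnc_ids) {
    li <- ann[ann$transcript_id == l, ]
    if (!nrow(li)) next
    for (m in mrna_ids) {
      mi <- ann[ann$transcript_id == m, ]
      if (!nrow(mi) || li$chrom != mi$chrom) next
      overlap <- li$start <= mi$end && mi$start <= li$end
      if (overlap) {
        rows <- rbind(rows, data.frame(lncrna_id = l, mrna_id = m,
                                       relation = "overlapping", gap_bp = 0L,
                                       stringsAsFactors = FALSE))
      } else {
        gap <- if (mi$start > li$end) mi$start - li$end else li$start - mi$end
        if (gap <= window_bp) {
          rel <- if (mi$end < li$start) "upstream" else "downstream"
          rows <- rbind(rows, data.frame(lncrna_id = l, mrna_id = m,
                                         relation = rel, gap_bp = as.integer(gap),
                                         stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(rows)) {
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      relation = character(), gap_bp = integer(),
                      stringsAsFactors = FALSE))
  }
  rows <- rows[order(rows$lncrna_id, rows$mrna_id), ]
  rownames(rows) <- NULL
  rows
}

## All-pairs Pearson scan on log2(FPKM + 1).
trans_oracle <- function(matrix, lnc_ids, mrna_ids, r_threshold) {
  x <- log2(matrix + 1)
  rows <- NULL
  for (l in intersect(lnc_ids, rownames(x))) {
    for (m in intersect(mrna_ids, rownames(x))) {
      if (l == m) next
      r <- suppressWarnings(stats::cor(x[l, ], x[m, ]))
      if (!is.na(r) && abs(r) >= r_threshold) {
        rows <- rbind(rows, data.frame(lncrna_id = l, mrna_id = m,
                                       pearson_r = r, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(rows)) {
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      pearson_r = numeric(), stringsAsFactors = FALSE))
  }
  rows <- rows[order(rows$lncrna_id, rows$mrna_id), ]
  rownames(rows) <- NULL
  rows
}

## Small null config reused across tests: no planted structure at all.
null_config <- function(n = 200L, seed = 1L) {
  sim_config(n_coding = n, n_lncrna = 0L, n_de_up = 0L, n_de_down = 0L,
             n_trend_reversal = 0L, n_modules = 0L, module_size = 0L,
             n_cis_pairs = 0L, n_mirnas = 0L, n_cerna_triads = 0L,
             rng_seed = seed)
}

## Two planted 50-transcript blocks, nothing else (between-block r ~ 0).
two_block_config <- function(seed) {
  sim_config(n_coding = 100L, n_lncrna = 0L, n_de_up = 0L, n_de_down = 0L,
             n_trend_reversal = 0L, n_modules = 2L, module_size = 50L,
             module_trait_cor = 0.2, n_cis_pairs = 0L, n_mirnas = 0L,
             n_cerna_triads = 0L, rng_seed = seed)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
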