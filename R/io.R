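## File round-tripping: TSV expression/design/seed tables, GTF annotation,
## FASTA sequences, JSON truth manifest, SIF edge lists. Numeric columns are
## written with 17 significant digits so write -> read reproduces objects
## exactly.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}

#' Read an expression matrix TSV
#'
#' First column `transcript_id`, remaining columns one per sample.
#'
#' @param path TSV path.
#' @return Numeric matrix (transcripts x samples).
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "transcript_id") {
    stop("expression TSV must start with a 'transcript_id' column", call. = FALSE)
  }
  if (anyDuplicated(df$transcript_id)) {
    stop("duplicate transcript id: ",
         df$transcript_id[duplicated(df$transcript_id)][1], call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$transcript_id
  m
}

#' Read a two-column design TSV (sample, group)
#' @param path TSV path.
#' @return Data frame with `sample` and `group`.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df))) {
    stop("design TSV needs 'sample' and 'group' columns", call. = FALSE)
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample id", call. = FALSE)
  df
}

#' Write annotation as GTF (gene + transcript features)
#' @param annotation Annotation data frame.
#' @param path Output path.
#' @export
write_gtf_annotation <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  genes <- split(annotation, annotation$gene_id)
  ## stable order: first appearance in the annotation
  gene_order <- unique(annotation$gene_id)
  for (g in gene_order) {
    tx <- genes[[g]]
    attrs <- sprintf('gene_id "%s"; gene_name "%s";', g, tx$gene_name[1])
    writeLines(paste(tx$chrom[1], "lncreg_sim", "gene", min(tx$start),
                     max(tx$end), ".", tx$strand[1], ".", attrs,
                     sep = "\t"), con)
    for (i in seq_len(nrow(tx))) {
      attrs <- sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_name "%s"; transcript_biotype "%s";',
        g, tx$transcript_id[i], tx$gene_name[i], tx$biotype[i]
      )
      writeLines(paste(tx$chrom[i], "lncreg_sim", "transcript", tx$start[i],
                       tx$end[i], ".", tx$strand[i], ".", attrs,
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a GTF annotation
#'
#' Parses transcript features (via rtracklayer) into the annotation data
#' frame used throughout the package. Lines with start > end are rejected
#' with their line number.
#'
#' @param path GTF path.
#' @return Annotation data frame (transcript_id, gene_id, gene_name,
#'   biotype, chrom, start, end, strand).
#' @export
read_gtf_annotation <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  starts <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 4)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 5)))
  bad <- which(is.na(starts) | is.na(ends) | starts > ends)
  if (length(bad)) {
    stop("GTF parse error at line ", bad[1], ": start > end or non-numeric",
         call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "transcript"]
  if (anyDuplicated(gr$transcript_id)) {
    stop("duplicate transcript id in GTF: ",
         gr$transcript_id[duplicated(gr$transcript_id)][1], call. = FALSE)
  }
  data.frame(
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    gene_name = gr$gene_name,
    biotype = gr$transcript_biotype,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Read transcript sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(set))) {
    stop("duplicate sequence id in FASTA: ",
         names(set)[duplicated(names(set))][1], call. = FALSE)
  }
  stats::setNames(as.character(set), names(set))
}

#' Read a miRNA seed table TSV (mirna_id, seed_7mer[, sequence])
#' @param path TSV path.
#' @return Data frame.
#' @export
read_seed_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "seed_7mer") %in% names(df))) {
    stop("seed table needs 'mirna_id' and 'seed_7mer' columns", call. = FALSE)
  }
  if (anyDuplicated(df$mirna_id)) stop("duplicate miRNA id", call. = FALSE)
  bad <- grepl("[^ACGUTacgut]", df$seed_7mer)
  if (any(bad)) stop("non-nucleotide characters in seed: ",
                     df$mirna_id[bad][1], call. = FALSE)
  df
}

#' Write a simulated dataset to a directory
#'
#' Emits `expression.tsv`, `design.tsv`, `annotation.gtf`, `transcripts.fa`,
#' `mirnas.tsv` and `truth.json`; [read_dataset()] reproduces the objects
#' exactly.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  missing <- setdiff(rownames(dataset$matrix), dataset$annotation$transcript_id)
  if (length(missing)) {
    stop("transcript in matrix missing from annotation: ", missing[1],
         call. = FALSE)
  }
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  expr <- data.frame(transcript_id = rownames(dataset$matrix),
                     dataset$matrix, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv(expr, file.path(out_dir, "expression.tsv"))
  write_tsv(dataset$design, file.path(out_dir, "design.tsv"))
  write_gtf_annotation(dataset$annotation, file.path(out_dir, "annotation.gtf"))
  if (length(dataset$sequences)) {
    set <- Biostrings::DNAStringSet(dataset$sequences)
    Biostrings::writeXStringSet(set, file.path(out_dir, "transcripts.fa"))
  } else {
    file.create(file.path(out_dir, "transcripts.fa"))
  }
  write_tsv(dataset$mirnas, file.path(out_dir, "mirnas.tsv"))
  ## named atomic vectors lose their names as JSON arrays; store as objects
  truth_out <- dataset$truth
  for (f in c("de_hg_vs_lg", "de_ttr_vs_hg", "module_labels", "module_traits")) {
    truth_out[[f]] <- as.list(truth_out[[f]])
  }
  jsonlite::write_json(truth_out, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

empty_or_df <- function(x, template) {
  if (is.null(x) || (is.list(x) && !length(x))) return(template)
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  df[, names(template), drop = FALSE]
}

named_chr <- function(x) {
  if (is.null(x) || !length(x)) return(stats::setNames(character(), character()))
  unlist(x)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir Dataset directory.
#' @return A list mirroring [simulate_dataset()] output (without `config`).
#' @export
read_dataset <- function(dir) {
  matrix <- read_expression(file.path(dir, "expression.tsv"))
  design <- read_design(file.path(dir, "design.tsv"))
  annotation <- read_gtf_annotation(file.path(dir, "annotation.gtf"))
  fa <- file.path(dir, "transcripts.fa")
  sequences <- if (file.size(fa) > 0) read_fasta_sequences(fa) else
    stats::setNames(character(), character())
  mirnas <- utils::read.delim(file.path(dir, "mirnas.tsv"),
                              stringsAsFactors = FALSE,
                              colClasses = "character")
  raw <- jsonlite::fromJSON(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  cis_template <- data.frame(lncrna_id = character(), mrna_id = character(),
                             relation = character(), gap_bp = integer(),
                             stringsAsFactors = FALSE)
  triad_template <- data.frame(lncrna_id = character(), mirna_id = character(),
                               mrna_id = character(),
                               lnc_site_pos = integer(),
                               mrna_site_pos = integer(),
                               stringsAsFactors = FALSE)
  truth <- list(
    de_hg_vs_lg = named_chr(raw$de_hg_vs_lg),
    de_ttr_vs_hg = named_chr(raw$de_ttr_vs_hg),
    trend_reversal_set = as.character(unlist(raw$trend_reversal_set)),
    module_labels = named_chr(raw$module_labels),
    module_traits = named_chr(raw$module_traits),
    cis_pairs = empty_or_df(raw$cis_pairs, cis_template),
    cis_decoys = empty_or_df(raw$cis_decoys, cis_template),
    planted_triads = if (is.null(raw$planted_triads) ||
                         (is.list(raw$planted_triads) && !length(raw$planted_triads))) {
      triad_template
    } else as.data.frame(raw$planted_triads, stringsAsFactors = FALSE)
  )
  ## annotation rows in matrix order, as the generator emits them
  annotation <- annotation[match(rownames(matrix), annotation$transcript_id), ]
  rownames(annotation) <- NULL
  list(matrix = matrix, design = design, annotation = annotation,
       sequences = sequences, mirnas = mirnas, truth = truth)
}

#' Write network edges as SIF
#'
#' One line per edge: `source<TAB>interaction<TAB>target`.
#'
#' @param graph An igraph object with an `edge_type` edge attribute (e.g.
#'   from [merge_networks()]), or a data frame with columns `from`,
#'   `edge_type`, `to`.
#' @param path Output path.
#' @export
write_sif <- function(graph, path) {
  if (inherits(graph, "igraph")) {
    if (igraph::ecount(graph) == 0L) {
      writeLines(character(), path)
      return(invisible(path))
    }
    ends <- igraph::as_edgelist(graph)
    type <- igraph::E(graph)$edge_type
    if (is.null(type)) type <- "interacts"
    df <- data.frame(from = ends[, 1], edge_type = type, to = ends[, 2],
                     stringsAsFactors = FALSE)
  } else {
    df <- graph[, c("from", "edge_type", "to")]
  }
  writeLines(paste(df$from, df$edge_type, df$to, sep = "\t"), path)
  invisible(path)
}
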