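## Dense sub-network (molecular complex) detection and degree statistics on
## an undirected interaction graph.

#' Load an interaction edge list
#'
#' Reads a tab-separated table `node_a<TAB>node_b[<TAB>score]` (a data frame
#' may be passed directly). Edges with a confidence score are kept only when
#' `score > min_score` (strict, the "medium confidence" export convention).
#' Self-loops and duplicate edges are dropped with a message.
#'
#' @param edge_table Path to a TSV file, or a 2-3 column data frame.
#' @param min_score Strict lower bound on the score (default 0.4).
#' @param header Whether the file has a header row (default FALSE).
#' @return A simple undirected igraph object.
#' @export
load_interactions <- function(edge_table, min_score = 0.4, header = FALSE) {
  if (is.character(edge_table)) {
    if (file.exists(edge_table) && file.size(edge_table) == 0) {
      return(igraph::make_empty_graph(directed = FALSE))
    }
    df <- tryCatch(
      utils::read.delim(edge_table, header = header, stringsAsFactors = FALSE,
                        colClasses = "character"),
      error = function(e) stop("cannot parse edge table: ", conditionMessage(e),
                               call. = FALSE)
    )
  } else {
    df <- as.data.frame(edge_table, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) return(igraph::make_empty_graph(directed = FALSE))
  if (ncol(df) < 2L) stop("edge table needs at least two columns", call. = FALSE)
  bad <- which(is.na(df[[1]]) | is.na(df[[2]]) | df[[1]] == "" | df[[2]] == "")
  if (length(bad)) {
    stop("malformed edge table row(s): line ", paste(utils::head(bad, 3), collapse = ", "),
         call. = FALSE)
  }
  if (ncol(df) >= 3L) {
    score <- suppressWarnings(as.numeric(df[[3]]))
    if (anyNA(score)) {
      stop("non-numeric score at line ", which(is.na(score))[1], call. = FALSE)
    }
    keep <- score > min_score
    message(sum(!keep), " edge(s) dropped at score <= ", min_score)
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0L) return(igraph::make_empty_graph(directed = FALSE))
  loops <- df[[1]] == df[[2]]
  if (any(loops)) message(sum(loops), " self-loop(s) dropped")
  df <- df[!loops, , drop = FALSE]
  key <- paste(pmin(df[[1]], df[[2]]), pmax(df[[1]], df[[2]]))
  dup <- duplicated(key)
  if (any(dup)) message(sum(dup), " duplicate edge(s) dropped")
  df <- df[!dup, , drop = FALSE]
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  igraph::simplify(g)
}

#' MCODE vertex weights
#'
#' The weight of a vertex is `k * density` of the highest k-core of its
#' closed neighbourhood (the vertex plus its neighbours); the density term
#' is the core-clustering coefficient. Isolated vertices weigh 0.
#'
#' @param graph An undirected igraph object.
#' @return Named numeric vector of vertex weights.
#' @export
mcode_vertex_weights <- function(graph) {
  graph <- ensure_named(graph)
  vs <- igraph::V(graph)$name
  w <- stats::setNames(numeric(length(vs)), vs)
  for (v in vs) {
    nb <- igraph::neighbors(graph, v)$name
    if (!length(nb)) next
    sub <- igraph::induced_subgraph(graph, c(v, nb))
    cores <- igraph::coreness(sub)
    k <- max(cores)
    core_nodes <- names(cores)[cores >= k]
    core_sub <- igraph::induced_subgraph(sub, core_nodes)
    n <- igraph::vcount(core_sub)
    dens <- if (n < 2L) 0 else
      2 * igraph::ecount(core_sub) / (n * (n - 1))
    w[v] <- k * dens
  }
  w
}

#' MCODE-style molecular complex detection
#'
#' Seed-and-grow from the highest-weight unassigned vertex (ties broken by
#' vertex id): a neighbour is admitted when its weight is at least
#' `seed_weight * (1 - node_score_cutoff)` and, once the complex has two or
#' more members, it attaches to at least two of them (density-preserving
#' growth, which keeps single-edge bridges from merging dense regions).
#' With `haircut`, members not in the 2-core of the complex are removed.
#' Complexes smaller than `min_size` are discarded; each vertex belongs to
#' at most one complex; results are sorted by `mcode_score = density *
#' size` descending.
#'
#' @param graph An undirected igraph object.
#' @param node_score_cutoff Admission slack relative to the seed weight
#'   (default 0.2).
#' @param haircut Remove singly-connected members (default TRUE).
#' @param min_size Minimum complex size (default 3).
#' @return A list of complexes, each a list with `seed`, `members`, `size`,
#'   `density`, `mcode_score`.
#' @export
mcode_complexes <- function(graph, node_score_cutoff = 0.2, haircut = TRUE,
                            min_size = 3L) {
  if (node_score_cutoff < 0 || node_score_cutoff >= 1) {
    stop("node_score_cutoff must lie in [0, 1)", call. = FALSE)
  }
  if (igraph::ecount(graph) == 0L) return(list())
  graph <- ensure_named(graph)
  w <- mcode_vertex_weights(graph)
  order_ids <- names(w)[order(-w, names(w))]
  assigned <- character()
  complexes <- list()

  for (seed in order_ids) {
    if (seed %in% assigned) next
    threshold <- w[seed] * (1 - node_score_cutoff)
    members <- seed
    repeat {
      nb <- unique(unlist(lapply(members, function(v) {
        igraph::neighbors(graph, v)$name
      })))
      cand <- setdiff(nb, c(members, assigned))
      cand <- cand[w[cand] >= threshold]
      if (length(members) >= 2L) {
        links <- vapply(cand, function(v) {
          sum(igraph::neighbors(graph, v)$name %in% members)
        }, integer(1))
        cand <- cand[links >= 2L]
      }
      if (!length(cand)) break
      cand <- cand[order(-w[cand], cand)]
      members <- c(members, cand[1])
    }
    if (haircut) members <- haircut_members(graph, members)
    if (length(members) >= min_size) {
      sub <- igraph::induced_subgraph(graph, members)
      n <- igraph::vcount(sub)
      dens <- 2 * igraph::ecount(sub) / (n * (n - 1))
      complexes[[length(complexes) + 1L]] <- list(
        seed = seed, members = sort(members), size = as.integer(n),
        density = dens, mcode_score = dens * n
      )
      assigned <- c(assigned, members)
    } else {
      assigned <- c(assigned, seed)
    }
  }
  scores <- vapply(complexes, `[[`, numeric(1), "mcode_score")
  complexes[order(-scores)]
}

ensure_named <- function(graph) {
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  graph
}

## 2-core of the induced subgraph: iteratively drop degree-<2 members.
haircut_members <- function(graph, members) {
  repeat {
    sub <- igraph::induced_subgraph(graph, members)
    deg <- igraph::degree(sub)
    drop <- names(deg)[deg < 2L]
    if (!length(drop) || length(members) <= 1L) return(setdiff(members, drop))
    members <- setdiff(members, drop)
    if (!length(members)) return(members)
  }
}

#' Degree table of an interaction graph
#'
#' @param graph An undirected igraph object.
#' @return Data frame (node, degree) sorted by degree descending, node id
#'   ascending.
#' @export
degree_table <- function(graph) {
  if (igraph::vcount(graph) == 0L) {
    return(data.frame(node = character(), degree = integer(),
                      stringsAsFactors = FALSE))
  }
  deg <- igraph::degree(graph)
  nm <- names(deg)
  if (is.null(nm)) nm <- as.character(seq_along(deg))
  out <- data.frame(node = nm, degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}
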