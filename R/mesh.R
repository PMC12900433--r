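#' Build the MeSH TreeNumber ancestor DAG
#'
#' Every TreeNumber code of every disease is expanded into its full
#' ancestor chain by repeatedly truncating the last dotted segment; the
#' resulting codes become graph nodes with one parent->child edge per
#' truncation adjacency. A disease with several codes is carried by a
#' single node holding all of them (no vector averaging is needed later),
#' named by its `disease_id`; ancestor codes not claimed by any catalogue
#' disease become code-named nodes. The graph is acyclic by construction.
#'
#' @param diseases Disease tibble (`disease_id`, `tree_numbers`
#'   list-column), e.g. from [read_disease_table()].
#' @return An object of class `mesh_graph`: tibbles `nodes` (`node`,
#'   `disease_id`, `codes` list-column) and `edges` (`from`, `to`, plus the
#'   underlying `parent_code`/`child_code`), and an igraph handle `graph`.
#' @export
build_mesh_dag <- function(diseases) {
  stopifnot(all(c("disease_id", "tree_numbers") %in% names(diseases)))
  codes <- diseases$tree_numbers
  ok <- vapply(codes, function(cc) length(cc) > 0 && all(tree_number_valid(cc)),
               logical(1))
  if (!all(ok)) {
    bad <- unlist(codes[!ok])
    abort(paste0("malformed tree number(s): ",
                 paste(bad[!tree_number_valid(bad)], collapse = ", ")))
  }
  owner <- stats::setNames(rep(diseases$disease_id, lengths(codes)), unlist(codes))
  if (anyDuplicated(names(owner)))
    abort(paste0("tree number assigned to more than one disease: ",
                 paste(unique(names(owner)[duplicated(names(owner))]), collapse = ", ")))
  all_codes <- unique(unlist(lapply(unlist(codes), code_ancestry)))
  node_of <- function(code) {
    hit <- owner[code]
    ifelse(is.na(hit), code, hit)
  }
  parent <- parent_code(all_codes)
  has_parent <- !is.na(parent)
  edges <- tibble::tibble(parent_code = parent[has_parent],
                          child_code = all_codes[has_parent])
  edges$from <- unname(node_of(edges$parent_code))
  edges$to <- unname(node_of(edges$child_code))
  edges <- edges[edges$from != edges$to, c("from", "to", "parent_code", "child_code")]
  edges <- dplyr::distinct(edges, .data$from, .data$to, .keep_all = TRUE)
  node_ids <- unique(c(unname(node_of(all_codes))))
  nodes <- tibble::tibble(
    node = node_ids,
    disease_id = ifelse(node_ids %in% diseases$disease_id, node_ids, NA_character_),
    codes = lapply(node_ids, function(nd) {
      if (nd %in% diseases$disease_id)
        diseases$tree_numbers[[match(nd, diseases$disease_id)]]
      else nd
    }))
  g <- igraph::graph_from_data_frame(edges[c("from", "to")], directed = TRUE,
                                     vertices = nodes["node"])
  if (!igraph::is_dag(g)) abort("truncation graph is not acyclic")
  structure(list(nodes = nodes, edges = edges, graph = g), class = "mesh_graph")
}

code_ancestry <- function(code) {
  segs <- strsplit(code, ".", fixed = TRUE)[[1]]
  vapply(seq_along(segs), function(k) paste(segs[1:k], collapse = "."), character(1))
}

parent_code <- function(codes) {
  out <- sub("\\.[^.]+$", "", codes)
  out[!grepl(".", codes, fixed = TRUE)] <- NA_character_
  out
}

#' @export
print.mesh_graph <- function(x, ...) {
  cat("<mesh_graph> ", nrow(x$nodes), " nodes (",
      sum(!is.na(x$nodes$disease_id)), " diseases), ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Uniform truncated random walks over the disease DAG
#'
#' Starts `walks_per_node` walks from every node and extends each for up
#' to `walk_length` steps, choosing the next node uniformly from the
#' *undirected* neighbourhood (edges are stored parent->child, but walks
#' may move both up and down the hierarchy so leaves do not trap them).
#' Isolated nodes yield length-1 walks.
#'
#' @param graph A `mesh_graph`.
#' @param walks_per_node Walks started per node (default 10).
#' @param walk_length Maximum walk length in nodes (default 40).
#' @param seed Integer seed.
#' @return List of character vectors of node names.
#' @export
random_walks <- function(graph, walks_per_node = 10, walk_length = 40, seed = 42) {
  stopifnot(inherits(graph, "mesh_graph"), walk_length >= 1)
  ug <- igraph::as_undirected(graph$graph, mode = "collapse")
  nodes <- igraph::V(ug)$name
  nbrs <- lapply(igraph::adjacent_vertices(ug, nodes), function(v) v$name)
  names(nbrs) <- nodes
  walks <- vector("list", length(nodes) * walks_per_node)
  local_seed(seed, {
    w <- 0L
    for (rep in seq_len(walks_per_node)) {
      for (start in nodes) {
        walk <- character(walk_length)
        walk[1] <- start
        len <- 1L
        while (len < walk_length) {
          nb <- nbrs[[walk[len]]]
          if (length(nb) == 0) break
          walk[len + 1L] <- nb[sample.int(length(nb), 1L)]
          len <- len + 1L
        }
        w <- w + 1L
        walks[[w]] <- walk[seq_len(len)]
      }
    }
  })
  walks
}

#' Train DeepWalk-style node embeddings from random walks
#'
#' Feeds walk sequences to the skip-gram trainer, mapping every walked
#' node to a dense vector (default dimension 64) in which hierarchically
#' related diseases land close together.
#'
#' @param walks List of node-name sequences from [random_walks()].
#' @param dim Embedding dimension (default 64).
#' @param window Skip-gram context window (default 5).
#' @param epochs,negative,lr Training settings.
#' @param seed Integer seed.
#' @return Embedding tibble (`id` = node name, `V1..Vd`).
#' @export
train_deepwalk <- function(walks, dim = 64, window = 5, epochs = 5,
                           negative = 5, lr = 0.025, seed = 42) {
  if (length(walks) == 0) abort("empty walk set")
  counts <- table(unlist(walks))
  vec <- train_sgns(walks, names(counts), as.numeric(counts), dim = dim,
                    window = window, epochs = epochs, negative = negative,
                    lr = lr, seed = seed)
  as_embedding_table(vec, rownames(vec))
}

#' Embed a disease catalogue end to end
#'
#' Convenience wrapper: builds the ancestor DAG, walks it, trains the
#' embedding and returns vectors keyed by `disease_id`. Ancestor-only
#' nodes receive embeddings during training but are excluded from the
#' output unless `include_ancestors = TRUE`.
#'
#' @param diseases Disease tibble.
#' @param dim,walks_per_node,walk_length,window,epochs,seed Walk and
#'   training settings (see [random_walks()], [train_deepwalk()]).
#' @param include_ancestors Keep ancestor-only nodes in the output table.
#' @return Embedding tibble.
#' @export
embed_diseases <- function(diseases, dim = 64, walks_per_node = 10,
                           walk_length = 40, window = 5, epochs = 5,
                           seed = 42, include_ancestors = FALSE) {
  graph <- build_mesh_dag(diseases)
  walks <- random_walks(graph, walks_per_node, walk_length, seed = seed)
  emb <- train_deepwalk(walks, dim = dim, window = window, epochs = epochs,
                        seed = seed)
  if (!include_ancestors)
    emb <- emb[emb$id %in% diseases$disease_id, ]
  emb
}
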