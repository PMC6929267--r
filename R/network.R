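#' Build a simple undirected network from an edge table
#'
#' Constructs the undirected, unweighted network object that every
#' quantity in this package is computed on.  Self-loops and duplicate
#' edges are dropped at construction (with a message reporting how many),
#' so the result is always a simple graph.  Node identifiers are treated
#' as opaque, case-sensitive tokens.
#'
#' @param edges A two-column matrix or data frame of node-identifier
#'   pairs, one edge per row.  Columns beyond the second are ignored.
#' @param nodes Optional character vector of node identifiers to include
#'   even if they carry no edge (isolated nodes).
#'
#' @return An undirected [igraph::igraph] object with named vertices.
#'   The edge count `igraph::gsize()` is the quantity `L` used by all
#'   quality functions.
#' @export
#' @examples
#' g <- mr_network(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' igraph::gsize(g)
mr_network <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(dim(edges)) || ncol(edges) < 2L) {
    stop("'edges' must have two columns (node, node)")
  }
  el <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
  if (any(is.na(el)) || any(!nzchar(el))) {
    stop("edge list contains missing or empty node identifiers")
  }
  n_loops <- sum(el[, 1L] == el[, 2L])
  el <- el[el[, 1L] != el[, 2L], , drop = FALSE]
  key <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  el <- el[!dup, , drop = FALSE]
  if (n_loops + n_dup > 0L) {
    message(sprintf("dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_loops, n_dup))
  }
  vnames <- unique(c(as.vector(t(el)), as.character(nodes)))
  g <- igraph::make_empty_graph(n = length(vnames), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vnames)
  if (nrow(el) > 0L) g <- igraph::add_edges(g, t(el))
  g
}

#' Coerce to a network object
#'
#' Accepts an igraph graph (simplified and made undirected as needed) or
#' an edge table, and returns the simple undirected graph used by the
#' rest of the package.
#'
#' @param x An igraph object, two-column matrix, or data frame.
#' @return An undirected simple [igraph::igraph] with named vertices.
#' @export
as_network <- function(x) {
  if (igraph::is_igraph(x)) {
    if (igraph::is_directed(x)) x <- igraph::as_undirected(x, mode = "collapse")
    if (igraph::any_loop(x) || igraph::any_multiple(x)) {
      x <- igraph::simplify(x)
    }
    if (is.null(igraph::V(x)$name)) {
      igraph::V(x)$name <- as.character(seq_len(igraph::vcount(x)))
    }
    return(x)
  }
  mr_network(x)
}

#' Read a whitespace-delimited edge list
#'
#' Reads a two-column edge list (one edge per line, columns separated by
#' any whitespace).  Lines starting with `#` are skipped.  A third
#' column, if present, is ignored with a warning (weights are not
#' supported: the model is unweighted).
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple [igraph::igraph], as from [mr_network()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("no edges in file: ", path)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(toks)
  if (any(nf < 2L)) {
    bad <- keep[which(nf < 2L)[1L]]
    stop(sprintf("malformed edge list line %d in %s: fewer than two fields",
                 bad, path))
  }
  if (any(nf > 2L)) {
    warning("third and later columns (e.g. edge weights) ignored: ",
            "the network model is unweighted")
  }
  el <- cbind(vapply(toks, `[[`, "", 1L), vapply(toks, `[[`, "", 2L))
  mr_network(el)
}

#' Write a network as an edge list
#'
#' @param network A network (see [as_network()]).
#' @param path Output file path.
#' @param header Logical; write a `#`-prefixed header line.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(network, path, header = TRUE) {
  g <- as_network(network)
  el <- igraph::as_edgelist(g, names = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("# node_a\tnode_b", con)
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
  invisible(path)
}

#' Coerce to a partition
#'
#' A partition assigns every node to exactly one module.  It is
#' represented as a named character vector: names are node identifiers,
#' values are module labels.  Accepted inputs: a named vector, a
#' two-column data frame `(node, module)`, an [igraph::communities]
#' object, or a list of disjoint node sets (list names become labels).
#'
#' @param x Object to coerce.
#' @return Named character vector of module labels.
#' @export
as_partition <- function(x) {
  if (inherits(x, "communities")) {
    m <- igraph::membership(x)
    out <- as.character(m)
    names(out) <- names(m)
    x <- out
  } else if (is.list(x) && !is.data.frame(x)) {
    labs <- names(x)
    if (is.null(labs) || any(!nzchar(labs))) labs <- as.character(seq_along(x))
    nodes <- unlist(x, use.names = FALSE)
    if (anyDuplicated(nodes)) {
      stop("node '", nodes[duplicated(nodes)][1L],
           "' appears in more than one module")
    }
    out <- rep(labs, lengths(x))
    names(out) <- as.character(nodes)
    x <- out
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("partition data frame needs (node, module) columns")
    out <- as.character(x[[2L]])
    names(out) <- as.character(x[[1L]])
    x <- out
  } else {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("partition must carry node identifiers as names")
  }
  if (anyDuplicated(names(x))) {
    stop("node '", names(x)[duplicated(names(x))][1L],
         "' assigned to more than one module")
  }
  if (any(is.na(x))) stop("partition contains missing module labels")
  x
}

#' Validate a partition against a network
#'
#' Checks the defining invariants: every network node appears exactly
#' once, and the partition mentions no unknown nodes.
#'
#' @param network A network.
#' @param partition A partition (see [as_partition()]).
#' @return Invisibly, the validated partition aligned to
#'   `igraph::V(network)$name` order.
#' @export
validate_partition <- function(network, partition) {
  g <- as_network(network)
  p <- as_partition(partition)
  vn <- igraph::V(g)$name
  missing <- setdiff(vn, names(p))
  if (length(missing) > 0L) {
    stop("node '", missing[1L], "' is not assigned to any module")
  }
  extra <- setdiff(names(p), vn)
  if (length(extra) > 0L) {
    stop("node '", extra[1L], "' in partition is not a network node")
  }
  invisible(p[vn])
}

#' Split a partition into its modules
#'
#' @param partition A partition.
#' @return Named list of character vectors (module label -> node set).
#' @export
partition_modules <- function(partition) {
  p <- as_partition(partition)
  split(names(p), p)
}

#' Write / read a partition as a tab-delimited table
#'
#' Two tab-separated columns: node identifier, module label.  Lines
#' starting with `#` are treated as comments.  Tab is the only field
#' separator, so module labels may contain spaces.
#'
#' @param partition A partition.
#' @param path File path.
#' @param header Logical; write a `#`-prefixed header line.
#' @return `write_partition()` returns `path` invisibly;
#'   `read_partition()` returns a named character vector.
#' @export
write_partition <- function(partition, path, header = TRUE) {
  p <- as_partition(partition)
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("# node\tmodule", con)
  writeLines(paste(names(p), p, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("empty partition file: ", path)
  toks <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(toks) < 2L)) {
    stop("partition line without a tab-separated module label in ", path)
  }
  p <- vapply(toks, `[[`, "", 2L)
  names(p) <- vapply(toks, `[[`, "", 1L)
  as_partition(p)
}
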