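#' Detector specification
#'
#' Describes a base community detector used for initial modularization
#' and for the incremental re-modularization step of [refine_modules()].
#' The refinement engine depends only on this contract, so any
#' modularity-based backend can be swapped in.
#'
#' @param method One of `"louvain"` (multi-level modularity
#'   optimization), `"greedy"` (Clauset-Newman-Moore style agglomeration,
#'   deterministic), or `"label_propagation"` (majority label updates;
#'   ignores `gamma`).
#' @param gamma Positive resolution parameter passed to the modularity
#'   objective of the backend.
#' @param seed Optional integer seed controlling the backend's
#'   stochastic choices; with a fixed seed, repeated calls on the same
#'   network return identical partitions.
#' @return A list of class `"detector_spec"`.
#' @export
detector_spec <- function(method = c("louvain", "greedy", "label_propagation"),
                          gamma = 1, seed = NULL) {
  method <- match.arg(method)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("'gamma' must be a single positive number")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(method = method, gamma = gamma, seed = seed),
            class = "detector_spec")
}

#' @export
print.detector_spec <- function(x, ...) {
  cat(sprintf("detector: %s (gamma=%g, seed=%s)\n", x$method, x$gamma,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Run a base community detector
#'
#' Applies the detector described by `spec` to the network and returns a
#' full partition (every node assigned to exactly one module).
#' Disconnected networks are allowed; isolated nodes end up in singleton
#' modules.
#'
#' @param network A network (see [as_network()]).
#' @param spec A [detector_spec()].
#' @return A partition: named character vector of module labels.
#' @export
#' @examples
#' rc <- generate_ring_of_cliques(4, 5)
#' p <- detect_modules(rc$network, detector_spec("louvain", seed = 1))
#' length(partition_modules(p))
detect_modules <- function(network, spec = detector_spec()) {
  g <- as_network(network)
  if (igraph::vcount(g) < 1L) stop("network must have at least one node")
  if (!inherits(spec, "detector_spec")) {
    stop("'spec' must be a detector_spec object")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  memb <- switch(spec$method,
    louvain = {
      if (igraph::gsize(g) == 0L) {
        stats::setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
      } else {
        igraph::membership(igraph::cluster_louvain(g, resolution = spec$gamma))
      }
    },
    greedy = greedy_modularity_membership(g, gamma = spec$gamma),
    label_propagation = igraph::membership(igraph::cluster_label_prop(g)),
    stop("unsupported detector method: ", spec$method)
  )
  out <- as.character(as.integer(memb))
  names(out) <- igraph::V(g)$name
  out
}

# Clauset-Newman-Moore style greedy agglomeration with a resolution
# parameter.  Starts from singletons and repeatedly merges the connected
# pair of communities with the largest modularity increase
#   dQ = w_ij / L - 2 * gamma * theta_i * theta_j / (2L)^2,
# stopping when no merge increases Q.  Deterministic: ties are broken by
# the first pair in (i, j) order.
greedy_modularity_membership <- function(g, gamma = 1) {
  n <- igraph::vcount(g)
  comm <- seq_len(n)
  L <- igraph::gsize(g)
  if (L == 0L) return(stats::setNames(comm, igraph::V(g)$name))
  theta <- as.numeric(igraph::degree(g))
  el <- igraph::as_edgelist(g, names = FALSE)
  pi_ <- pmin(el[, 1L], el[, 2L])
  pj <- pmax(el[, 1L], el[, 2L])
  key <- pi_ * (n + 1) + pj
  agg <- rowsum(rep(1, length(key)), key)
  keys <- as.numeric(rownames(agg))
  pairs <- data.frame(i = floor(keys / (n + 1)), j = keys %% (n + 1),
                      w = agg[, 1L])
  repeat {
    if (nrow(pairs) == 0L) break
    dq <- pairs$w / L - 2 * gamma * theta[pairs$i] * theta[pairs$j] / (2 * L)^2
    best <- which.max(dq)
    if (dq[best] <= 0) break
    i <- pairs$i[best]; j <- pairs$j[best]
    comm[comm == j] <- i
    theta[i] <- theta[i] + theta[j]
    theta[j] <- 0
    # redirect j's pairs to i, re-aggregate, drop the merged self-pair
    pi2 <- ifelse(pairs$i == j, i, pairs$i)
    pj2 <- ifelse(pairs$j == j, i, pairs$j)
    lo <- pmin(pi2, pj2); hi <- pmax(pi2, pj2)
    keep <- lo != hi
    if (!any(keep)) break
    key2 <- lo[keep] * (n + 1) + hi[keep]
    agg2 <- rowsum(pairs$w[keep], key2)
    keys2 <- as.numeric(rownames(agg2))
    pairs <- data.frame(i = floor(keys2 / (n + 1)), j = keys2 %% (n + 1),
                        w = agg2[, 1L])
  }
  stats::setNames(match(comm, unique(comm)), igraph::V(g)$name)
}
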