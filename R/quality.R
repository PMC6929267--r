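#' Per-module counts and quality
#'
#' Computes the counts that drive every topological criterion in the
#' package: node count `n_m`, intra-module edge count `l_m`, edges to
#' the rest of the network `l_out`, total degree `theta_m = 2*l_m +
#' l_out`, its internal (`theta_in = 2*l_m`) and external (`theta_out =
#' l_out`) parts, the ratio `a = l_out / l_m`, and the module quality
#'
#' \deqn{Q_m = \frac{l_m}{L} - \gamma \left(\frac{\theta_m}{2L}\right)^2}
#'
#' where `L` is the total edge count of `network` and `gamma` the
#' resolution parameter (`gamma = 1` gives classical modularity;
#' larger values favour smaller modules).
#'
#' @param network A network (see [as_network()]).
#' @param members Character vector of node identifiers, non-empty, all
#'   present in the network.
#' @param gamma Positive resolution parameter.
#' @return A list of class `"module_stats"` with fields `n_m`, `l_m`,
#'   `l_out`, `theta_m`, `theta_in`, `theta_out`, `a` (NA when
#'   `l_m = 0`), `Q_m`, and `gamma`.
#' @export
#' @examples
#' g <- generate_ring_of_cliques(3, 4)$network
#' module_stats(g, partition_modules(generate_ring_of_cliques(3, 4)$partition)[[1]])
module_stats <- function(network, members, gamma = 1) {
  g <- as_network(network)
  L <- igraph::gsize(g)
  if (L == 0L) stop("module quality is undefined on a network with no edges")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("'gamma' must be a single positive number")
  }
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("'members' must be a non-empty node set")
  unknown <- setdiff(members, igraph::V(g)$name)
  if (length(unknown) > 0L) {
    stop("unknown node in 'members': '", unknown[1L], "'")
  }
  l_m <- igraph::gsize(igraph::induced_subgraph(g, members))
  theta_m <- sum(igraph::degree(g, v = members))
  theta_in <- 2 * l_m
  theta_out <- theta_m - theta_in
  structure(list(
    n_m = length(members),
    l_m = l_m,
    l_out = theta_out,
    theta_m = theta_m,
    theta_in = theta_in,
    theta_out = theta_out,
    a = if (l_m > 0) theta_out / l_m else NA_real_,
    Q_m = l_m / L - gamma * (theta_m / (2 * L))^2,
    gamma = gamma
  ), class = "module_stats")
}

#' @export
print.module_stats <- function(x, ...) {
  cat(sprintf(
    "module: n_m=%d l_m=%d l_out=%d theta_in=%d theta_out=%d Q_m=%.6f (gamma=%g)\n",
    x$n_m, x$l_m, x$l_out, x$theta_in, x$theta_out, x$Q_m, x$gamma))
  invisible(x)
}

#' Modularity of a partition
#'
#' Sums the per-module qualities of [module_stats()] over all modules:
#' \deqn{Q = \sum_m \left[\frac{l_m}{L} -
#'   \gamma\left(\frac{\theta_m}{2L}\right)^2\right].}
#' At `gamma = 1` this is the classical Newman-Girvan modularity; the
#' whole-network partition then scores exactly 0.
#'
#' @inheritParams module_stats
#' @param partition A partition of the network (see [as_partition()]).
#' @return A single numeric value.
#' @export
network_modularity <- function(network, partition, gamma = 1) {
  g <- as_network(network)
  L <- igraph::gsize(g)
  if (L == 0L) stop("modularity is undefined on a network with no edges")
  p <- validate_partition(g, partition)
  memb <- factor(p)
  el <- igraph::as_edgelist(g, names = TRUE)
  m1 <- memb[match(el[, 1L], names(p))]
  m2 <- memb[match(el[, 2L], names(p))]
  intra <- m1 == m2
  l_m <- tabulate(m1[intra], nbins = nlevels(memb))
  deg <- igraph::degree(g)
  theta <- vapply(split(deg[names(p)], memb), sum, 0)
  sum(l_m) / L - gamma * sum((theta / (2 * L))^2)
}

#' Sufficient-condition test for being a module
#'
#' A node set qualifies as a module when (i) its quality is positive,
#' `Q_m > 0`, and (ii) its total internal degree exceeds its external
#' degree, `theta_in > theta_out` (equivalently `a = l_out / l_m < 2`).
#' Both inequalities are strict; a set sitting exactly on either
#' boundary does not qualify.
#'
#' @inheritParams module_stats
#' @return A list of class `"module_qualification"` with logical fields
#'   `qualifies`, `q_positive`, `internal_exceeds_external`, and the
#'   underlying `stats` ([module_stats()]).
#' @export
qualifies_as_module <- function(network, members, gamma = 1) {
  s <- module_stats(network, members, gamma = gamma)
  q_pos <- s$Q_m > 0
  in_gt_out <- s$theta_in > s$theta_out
  structure(list(
    qualifies = q_pos && in_gt_out,
    q_positive = q_pos,
    internal_exceeds_external = in_gt_out,
    stats = s
  ), class = "module_qualification")
}

#' @export
print.module_qualification <- function(x, ...) {
  cat(sprintf("qualifies as module: %s (Q_m > 0: %s; theta_in > theta_out: %s)\n",
              x$qualifies, x$q_positive, x$internal_exceeds_external))
  invisible(x)
}

#' Resolution-limit scales of modularity
#'
#' For a network with `L` edges, modularity maximization cannot resolve
#' modules below an intrinsic scale of order `sqrt(L)`:
#' * `l_min = sqrt(L / 2)` — best case, modules joined by single links;
#' * `l_max = L / 4` — worst case, intra- and inter-module edges balanced;
#' * `refinable_threshold = sqrt(2 * L)` — a module with more than this
#'   many intra-module edges can hold two or more valid sub-modules and
#'   is a candidate for refinement.
#'
#' @param L Total edge count, a positive integer.
#' @return List with fields `l_min`, `l_max`, `refinable_threshold`.
#' @export
#' @examples
#' resolution_limits(800)  # l_min = 20, l_max = 200, refinable = 40
resolution_limits <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 1 ||
      L != floor(L)) {
    stop("'L' must be a single integer >= 1")
  }
  list(l_min = sqrt(L / 2), l_max = L / 4, refinable_threshold = sqrt(2 * L))
}

#' Partition density
#'
#' A resolution-limit-free local quality: the normalized link density of
#' each module, weighted by that module's share of edges,
#' \deqn{PD = \frac{1}{L} \sum_m l_m\,
#'   \frac{l_m - (n_m - 1)}{n_m(n_m-1)/2 - (n_m - 1)}.}
#' A module that is a tree (`l_m = n_m - 1`) contributes 0 and a clique
#' contributes its full edge weight, so `PD = 1` exactly when every
#' module is a clique of at least 3 nodes and no edges run between
#' modules.  Modules with 2 or fewer nodes contribute 0 (the normalizing
#' denominator vanishes below 3 nodes).
#'
#' @inheritParams network_modularity
#' @return A single numeric value, at most 1.
#' @export
partition_density <- function(network, partition) {
  g <- as_network(network)
  L <- igraph::gsize(g)
  if (L == 0L) stop("partition density is undefined on a network with no edges")
  p <- validate_partition(g, partition)
  mods <- split(names(p), p)
  contrib <- vapply(mods, function(m) {
    n_m <- length(m)
    if (n_m <= 2L) return(0)
    l_m <- igraph::gsize(igraph::induced_subgraph(g, m))
    denom <- n_m * (n_m - 1) / 2 - (n_m - 1)
    l_m * (l_m - (n_m - 1)) / denom
  }, 0)
  sum(contrib) / L
}

#' Composite quality score
#'
#' Combines the global quality (modularity `Q`) with the local,
#' resolution-limit-free quality (partition density `PD`) as their sum.
#' Both terms are bounded above by 1 and the score is used ordinally:
#' higher is better.
#'
#' @param Q Modularity value.
#' @param PD Partition-density value.
#' @return `Q + PD`.
#' @export
composite_score <- function(Q, PD) {
  Q + PD
}
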