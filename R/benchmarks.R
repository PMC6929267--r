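# Synthetic benchmark networks with planted community structure.
#
# The LFR-style generator follows the standard recipe: power-law node
# degrees and community sizes, assignment of nodes to communities under
# the feasibility constraint (a node's internal degree must fit in its
# community), and stub matching of internal and external half-edges
# with rejection of self-loops and duplicates.

# inverse-CDF sample from a continuous power law p(x) ~ x^-exponent on
# [xmin, xmax]
rpowerlaw <- function(n, xmin, xmax, exponent) {
  a <- 1 - exponent
  u <- stats::runif(n)
  if (abs(a) < 1e-12) {
    exp(log(xmin) + u * (log(xmax) - log(xmin)))
  } else {
    (xmin^a + u * (xmax^a - xmin^a))^(1 / a)
  }
}

# mean of the continuous power law on [xmin, xmax]
powerlaw_mean <- function(xmin, xmax, exponent) {
  stats::integrate(function(x) x^(1 - exponent), xmin, xmax)$value /
    stats::integrate(function(x) x^(-exponent), xmin, xmax)$value
}

# pair stubs at random into simple edges; endpoints of rejected pairs
# are re-shuffled for a few passes, then dropped
match_stubs <- function(stubs, forbidden_same = NULL, max_pass = 8L) {
  edges <- matrix(integer(0), ncol = 2L)
  seen <- numeric(0)
  offset <- max(stubs, 1L) + 1
  for (pass in seq_len(max_pass)) {
    if (length(stubs) < 2L) break
    if (length(stubs) %% 2L == 1L) stubs <- stubs[-length(stubs)]
    stubs <- sample(stubs)
    a <- stubs[c(TRUE, FALSE)]
    b <- stubs[c(FALSE, TRUE)]
    key <- pmin(a, b) * offset + pmax(a, b)
    bad <- a == b | key %in% seen | duplicated(key)
    if (!is.null(forbidden_same)) bad <- bad | forbidden_same[a] == forbidden_same[b]
    if (any(!bad)) {
      edges <- rbind(edges, cbind(a[!bad], b[!bad]))
      seen <- c(seen, key[!bad])
    }
    stubs <- c(a[bad], b[bad])
  }
  edges
}

#' Generate an LFR-style benchmark network with planted communities
#'
#' Synthetic networks with power-law degree and community-size
#' distributions and a tunable mixing parameter, mimicking the
#' heterogeneity of molecular networks.  Each node receives a target
#' degree from a power law (exponent `degree_exponent`, calibrated so
#' the realized mean is close to `avg_degree`, capped at `max_degree`).
#' Community sizes are drawn from a power law (exponent
#' `module_size_exponent`) on `[min_module_size, max_module_size]`.
#' A fraction `1 - mixing` of each node's edges is placed inside its
#' community and the rest across communities, by stub matching with
#' rejection of self-loops and duplicate edges.
#'
#' @param n Number of nodes.
#' @param mixing Mixing parameter in (0, 1): the fraction of each
#'   node's edges that leave its planted community.
#' @param avg_degree Target mean degree.
#' @param max_degree Degree cap; defaults to `0.1 * n`.
#' @param min_module_size,max_module_size Community-size bounds;
#'   `max_module_size` defaults to `0.1 * n`.
#' @param degree_exponent,module_size_exponent Power-law exponents
#'   (must be > 1).
#' @param seed Integer seed; the generator is fully reproducible from
#'   it.
#' @param max_retries Re-seeds attempted when a draw produces an
#'   infeasible configuration.
#' @return List with `network` (igraph) and `partition` (the planted
#'   ground truth as a named character vector).
#' @export
#' @examples
#' lfr <- generate_lfr(300, mixing = 0.3, min_module_size = 20,
#'                     max_module_size = 60, seed = 1)
#' range(lengths(partition_modules(lfr$partition)))
generate_lfr <- function(n, mixing, avg_degree = 20,
                         max_degree = ceiling(0.1 * n),
                         min_module_size = 30,
                         max_module_size = ceiling(0.1 * n),
                         degree_exponent = 2, module_size_exponent = 2,
                         seed = NULL, max_retries = 20L) {
  if (mixing <= 0 || mixing >= 1) stop("'mixing' must be in (0, 1)")
  if (min_module_size > max_module_size) {
    stop("min_module_size must not exceed max_module_size")
  }
  if (degree_exponent <= 1 || module_size_exponent <= 1) {
    stop("power-law exponents must be > 1")
  }
  if (max_degree <= avg_degree) stop("'max_degree' must exceed 'avg_degree'")
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (attempt in seq_len(max_retries)) {
    out <- tryCatch(lfr_draw(n, mixing, avg_degree, max_degree,
                             min_module_size, max_module_size,
                             degree_exponent, module_size_exponent),
                    error = function(e) e)
    if (!inherits(out, "error")) return(out)
  }
  stop(sprintf(paste0("LFR generation failed after %d attempts ",
                      "(n=%d, mixing=%.2f, min_module_size=%d): %s"),
               max_retries, n, mixing, min_module_size,
               conditionMessage(out)))
}

# shrink/grow community sizes within [smin, smax] until they sum to n
adjust_community_sizes <- function(sizes, n, smin, smax) {
  for (iter in seq_len(1000L)) {
    diffn <- sum(sizes) - n
    if (diffn == 0L) return(sizes)
    if (diffn > 0L) {
      i <- which(sizes > smin)
      if (length(i) == 0L) {
        sizes <- sizes[-length(sizes)]
        next
      }
      room <- sizes[i] - smin
      take <- pmin(room, diff(c(0, pmin(cumsum(room), diffn))))
      sizes[i] <- sizes[i] - take
    } else {
      i <- which(sizes < smax)
      if (length(i) == 0L) {
        sizes <- c(sizes, smin)
      } else {
        room <- smax - sizes[i]
        add <- pmin(room, diff(c(0, pmin(cumsum(room), -diffn))))
        sizes[i] <- sizes[i] + add
      }
    }
  }
  stop("could not adjust community sizes to cover the node count")
}

lfr_draw <- function(n, mixing, avg_degree, max_degree, smin, smax,
                     tau1, tau2) {
  # degree sequence: calibrate the lower cutoff so the continuous mean
  # matches avg_degree, then sample and round
  kmin <- stats::uniroot(function(x) powerlaw_mean(x, max_degree, tau1) -
                           avg_degree,
                         lower = 1, upper = max_degree - 1)$root
  deg <- pmin(round(rpowerlaw(n, kmin, max_degree, tau1)), max_degree)
  deg <- pmax(deg, 1L)

  # community sizes: draw until the total covers n, then adjust within
  # bounds so the sizes sum exactly to n
  sizes <- integer(0)
  while (sum(sizes) < n) {
    need <- max(200L, ceiling((n - sum(sizes)) / smin))
    sizes <- c(sizes, pmin(pmax(round(rpowerlaw(need, smin, smax, tau2)),
                                smin), smax))
    sizes <- sizes[cumsum(sizes) <= n + smax]
  }
  sizes <- adjust_community_sizes(sizes, n, smin, smax)
  n_comm <- length(sizes)
  if (n_comm < 2L) stop("fewer than two communities drawn")

  # internal degrees and assignment: nodes with large internal degree
  # first, into communities that can host them, weighted by free slots
  d_int <- round((1 - mixing) * deg)
  ord <- order(d_int, decreasing = TRUE)
  slots <- sizes
  comm_of <- integer(n)
  for (v in ord) {
    elig <- which(slots > 0L & sizes - 1L >= d_int[v])
    if (length(elig) == 0L) elig <- which(slots > 0L)
    c_sel <- if (length(elig) == 1L) elig else
      sample(elig, 1L, prob = slots[elig])
    comm_of[v] <- c_sel
    slots[c_sel] <- slots[c_sel] - 1L
    d_int[v] <- min(d_int[v], sizes[c_sel] - 1L)
  }

  # intra-community wiring, one community at a time
  intra_edges <- vector("list", n_comm)
  for (cix in seq_len(n_comm)) {
    members <- which(comm_of == cix)
    stubs <- rep(members, d_int[members])
    intra_edges[[cix]] <- match_stubs(stubs)
  }
  intra <- do.call(rbind, intra_edges)

  # inter-community wiring on the remaining stubs; pairs falling inside
  # a community are rejected (they cannot duplicate intra edges, which
  # are always within one community)
  d_ext <- deg - d_int
  ext_stubs <- rep(seq_len(n), d_ext)
  inter <- match_stubs(ext_stubs, forbidden_same = comm_of)

  edges <- rbind(intra, inter)
  if (nrow(edges) < n) stop("degenerate draw: too few edges realized")
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1L]),
               to = as.character(edges[, 2L])),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  part <- stats::setNames(as.character(comm_of), as.character(seq_len(n)))
  list(network = g, partition = part)
}

#' Generate a planted-partition (stochastic block) network
#'
#' Bernoulli edges with probability `p_in` within blocks and `p_out`
#' between blocks; the planted block labels are returned as ground
#' truth.
#'
#' @param blocks Number of blocks (>= 2).
#' @param block_size Nodes per block (>= 2).
#' @param p_in,p_out Within-/between-block edge probabilities with
#'   `0 <= p_out < p_in <= 1`.
#' @param seed Integer seed.
#' @return List with `network` and `partition`.
#' @export
generate_planted_partition <- function(blocks, block_size, p_in, p_out,
                                       seed = NULL) {
  blocks <- as.integer(blocks); block_size <- as.integer(block_size)
  if (is.na(blocks) || blocks < 2L || is.na(block_size) || block_size < 2L) {
    stop("need at least 2 blocks of at least 2 nodes")
  }
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- blocks * block_size
  pref <- matrix(p_out, blocks, blocks)
  diag(pref) <- p_in
  g <- igraph::sample_sbm(n, pref.matrix = pref,
                          block.sizes = rep(block_size, blocks))
  igraph::V(g)$name <- as.character(seq_len(n))
  part <- stats::setNames(as.character(rep(seq_len(blocks),
                                           each = block_size)),
                          as.character(seq_len(n)))
  list(network = g, partition = part)
}

#' Generate a ring of cliques
#'
#' The canonical resolution-limit construction: `n_cliques` cliques of
#' `clique_size` nodes, consecutive cliques joined by exactly one edge.
#' Deterministic.
#'
#' @param n_cliques Number of cliques (>= 3).
#' @param clique_size Nodes per clique (>= 3).
#' @return List with `network` and `partition` (the cliques).
#' @export
generate_ring_of_cliques <- function(n_cliques, clique_size) {
  n_cliques <- as.integer(n_cliques); clique_size <- as.integer(clique_size)
  if (is.na(n_cliques) || n_cliques < 3L) stop("'n_cliques' must be >= 3")
  if (is.na(clique_size) || clique_size < 3L) stop("'clique_size' must be >= 3")
  pairs <- t(utils::combn(clique_size, 2L))
  edges <- do.call(rbind, lapply(seq_len(n_cliques), function(c) {
    (c - 1L) * clique_size + pairs
  }))
  # one bridge per consecutive clique pair; distinct endpoints so every
  # node carries at most one bridge
  from <- (seq_len(n_cliques) - 1L) * clique_size + 1L
  to <- (seq_len(n_cliques) %% n_cliques) * clique_size + 2L
  edges <- rbind(edges, cbind(from, to))
  n <- n_cliques * clique_size
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1L]),
               to = as.character(edges[, 2L])),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  part <- stats::setNames(as.character(rep(seq_len(n_cliques),
                                           each = clique_size)),
                          as.character(seq_len(n)))
  list(network = g, partition = part)
}

#' Run the LFR benchmark experiment
#'
#' For each combination of network size, mixing parameter and replicate:
#' generate an LFR benchmark (the minimum module size is drawn uniformly
#' from `min_module_sizes` per replicate), run the base detector alone
#' and the detector followed by refinement, and score both partitions
#' against the planted ground truth.
#'
#' @param sizes Integer vector of network sizes.
#' @param mixings Numeric vector of mixing parameters.
#' @param n_replicates Replicates per (size, mixing) cell.
#' @param detector A [detector_spec()] for the initial modularization.
#' @param refine_config A [refinement_config()]; per-replicate seeds are
#'   derived from the experiment seed.
#' @param seed Master seed: the experiment is fully reproducible from it
#'   and the parameter grid.
#' @param min_module_sizes Candidate minimum module sizes, one drawn per
#'   replicate.
#' @param avg_degree Target mean degree of the benchmarks.
#' @return Data frame with one row per (size, mixing, replicate, method)
#'   and columns `n`, `mu`, `min_module_size`, `replicate`, `method`
#'   (`"louvain"` or `"louvain+refinement"`, named after the detector),
#'   `nmi`, `modularity`, `n_modules`, `mean_module_size`,
#'   `max_module_size`, `runtime` (seconds).  Generator failures are
#'   reported as warnings and the replicate is skipped.
#' @export
run_lfr_experiment <- function(sizes, mixings, n_replicates,
                               detector = detector_spec("louvain"),
                               refine_config = refinement_config(),
                               seed = 1L,
                               min_module_sizes = c(30, 40, 50, 60, 70),
                               avg_degree = 20) {
  seed <- as.integer(seed)
  records <- list()
  counter <- 0L
  for (n in sizes) {
    for (mu in mixings) {
      for (rep_i in seq_len(n_replicates)) {
        counter <- counter + 1L
        rep_seed <- (seed + 7919L * counter) %% 2000000000L
        set.seed(rep_seed)
        smin <- sample(min_module_sizes, 1L)
        gen <- tryCatch(
          generate_lfr(n, mixing = mu, avg_degree = avg_degree,
                       min_module_size = smin, seed = rep_seed + 1L),
          error = function(e) e)
        if (inherits(gen, "error")) {
          warning(sprintf("replicate skipped (n=%d, mu=%.2f, rep=%d): %s",
                          n, mu, rep_i, conditionMessage(gen)))
          next
        }
        g <- gen$network
        truth <- gen$partition

        det <- detector
        det$seed <- rep_seed + 2L
        t0 <- proc.time()[["elapsed"]]
        p_base <- detect_modules(g, det)
        t_base <- proc.time()[["elapsed"]] - t0

        rc <- refine_config
        rc$seed <- rep_seed + 3L
        t0 <- proc.time()[["elapsed"]]
        refined <- refine_modules(g, p_base, rc)
        t_ref <- t_base + proc.time()[["elapsed"]] - t0

        rec <- function(p, method, runtime) {
          sz <- lengths(partition_modules(p))
          data.frame(n = n, mu = mu, min_module_size = smin,
                     replicate = rep_i, method = method,
                     nmi = nmi(p, truth),
                     modularity = network_modularity(g, p, detector$gamma),
                     n_modules = length(sz),
                     mean_module_size = mean(sz),
                     max_module_size = max(sz),
                     runtime = runtime)
        }
        records[[length(records) + 1L]] <-
          rec(p_base, detector$method, t_base)
        records[[length(records) + 1L]] <-
          rec(refined$partition,
              paste0(detector$method, "+refinement"), t_ref)
      }
    }
  }
  do.call(rbind, records)
}
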