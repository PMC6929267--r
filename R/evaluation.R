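#' Normalized mutual information between two partitions
#'
#' Mutual information of the joint module-label distribution, normalized
#' by the arithmetic mean of the two label entropies:
#' \deqn{\mathrm{NMI}(P, Q) = \frac{2 I(P; Q)}{H(P) + H(Q)}.}
#' Identical partitions score 1.  By convention the value is 0 when
#' either partition consists of a single module (zero entropy carries no
#' information).
#'
#' @param p,q Partitions covering the same node set (see
#'   [as_partition()]).
#' @return A number in `[0, 1]`.
#' @export
nmi <- function(p, q) {
  p <- as_partition(p)
  q <- as_partition(q)
  if (length(p) != length(q) || !setequal(names(p), names(q))) {
    stop("partitions cover different node sets")
  }
  q <- q[names(p)]
  n <- length(p)
  tab <- table(p, q)
  pi_ <- rowSums(tab) / n
  pj <- colSums(tab) / n
  hx <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hy <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (hx == 0 || hy == 0) return(0)
  pij <- tab / n
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / (pi_[row(pij)[nz]] * pj[col(pij)[nz]])))
  min(max(2 * mi / (hx + hy), 0), 1)
}

#' Stability of a detector as mean pairwise NMI
#'
#' Runs the detector (optionally followed by refinement) `n_iter` times
#' with distinct derived seeds and returns the mean NMI over all
#' unordered pairs of resulting partitions.
#'
#' @param network A network.
#' @param spec A [detector_spec()]; its `seed` (default 1 if unset) is
#'   the base from which per-iteration seeds are derived.
#' @param n_iter Number of iterations, at least 2.
#' @param refine_config Optional [refinement_config()]; when given, each
#'   detected partition is refined before comparison.
#' @return Mean pairwise NMI in `[0, 1]`.
#' @export
pairwise_stability <- function(network, spec = detector_spec(), n_iter = 25L,
                               refine_config = NULL) {
  g <- as_network(network)
  n_iter <- as.integer(n_iter)
  if (is.na(n_iter) || n_iter < 2L) stop("'n_iter' must be at least 2")
  base <- if (is.null(spec$seed)) 1L else spec$seed
  parts <- lapply(seq_len(n_iter), function(i) {
    s <- spec
    s$seed <- base + i
    p <- detect_modules(g, s)
    if (!is.null(refine_config)) {
      rc <- refine_config
      rc$seed <- base + 1000L * i
      p <- refine_modules(g, p, rc)$partition
    }
    p
  })
  pairs <- utils::combn(n_iter, 2L)
  mean(apply(pairs, 2L, function(ij) nmi(parts[[ij[1L]]], parts[[ij[2L]]])))
}

#' Degree-preserving random networks
#'
#' Generates configuration-model null networks by degree-preserving edge
#' swaps (double-edge swaps that forbid self-loops and multi-edges), so
#' each null network is simple and has exactly the original degree
#' sequence.  Each network is produced with `20 * L` attempted swaps.
#'
#' @param network A network with at least 2 edges.
#' @param n_networks Number of null networks, at least 1.
#' @param seed Integer seed.
#' @return List of igraph networks.
#' @export
degree_preserving_null <- function(network, n_networks = 100L, seed = 1L) {
  g <- as_network(network)
  if (igraph::gsize(g) < 2L) {
    stop("degree-preserving rewiring needs a network with at least 2 edges")
  }
  n_networks <- as.integer(n_networks)
  if (is.na(n_networks) || n_networks < 1L) stop("'n_networks' must be >= 1")
  set.seed(as.integer(seed))
  niter <- 20L * igraph::gsize(g)
  lapply(seq_len(n_networks), function(i) {
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = niter))
  })
}

#' Significance of modularity against degree-preserving nulls
#'
#' Compares the modularity achieved on the real network (mean over
#' `n_iter` detector runs) with the modularity achieved on `n_null`
#' degree-preserving random networks (one detector run each):
#' `z = (mean real Q - mean null Q) / sd(null Q)` and the empirical p
#' value is the fraction of null modularities at least as large as the
#' real mean.
#'
#' @inheritParams pairwise_stability
#' @param n_null Number of null networks, at least 2.
#' @param seed Integer seed for null generation and detector runs.
#' @return List with `z_score`, `empirical_p`, `real_q` (vector),
#'   `null_q` (vector).
#' @export
modularity_significance <- function(network, spec = detector_spec(),
                                    n_iter = 25L, n_null = 100L, seed = 1L) {
  g <- as_network(network)
  n_iter <- as.integer(n_iter); n_null <- as.integer(n_null)
  if (is.na(n_iter) || n_iter < 2L) stop("'n_iter' must be at least 2")
  if (is.na(n_null) || n_null < 2L) stop("'n_null' must be at least 2")
  seed <- as.integer(seed)
  real_q <- vapply(seq_len(n_iter), function(i) {
    s <- spec; s$seed <- seed + i
    network_modularity(g, detect_modules(g, s), gamma = spec$gamma)
  }, 0)
  nulls <- degree_preserving_null(g, n_null, seed = seed + 10000L)
  null_q <- vapply(seq_along(nulls), function(i) {
    s <- spec; s$seed <- seed + 20000L + i
    network_modularity(nulls[[i]], detect_modules(nulls[[i]], s),
                       gamma = spec$gamma)
  }, 0)
  sd_null <- stats::sd(null_q)
  if (sd_null == 0) {
    warning("null modularity variance is zero; z-score reported as Inf")
    z <- Inf * sign(mean(real_q) - mean(null_q))
    if (is.nan(z)) z <- 0
  } else {
    z <- (mean(real_q) - mean(null_q)) / sd_null
  }
  list(z_score = z, empirical_p = mean(null_q >= mean(real_q)),
       real_q = real_q, null_q = null_q)
}

#' Select the resolution parameter by stability and significance
#'
#' Sweeps a grid of resolution parameters.  For each value the detector
#' is run `n_iter` times (stability = mean pairwise NMI; mean
#' modularity, module count and size are recorded) and its modularity is
#' compared with `n_null` degree-preserving null networks.  Among grid
#' values whose empirical p-value passes `alpha`, the one with the
#' highest stability is selected; ties are broken toward the larger mean
#' module count.  When no value passes, the maximum-stability value is
#' returned with a warning flag.
#'
#' @inheritParams modularity_significance
#' @param gamma_grid Numeric vector of candidate resolution parameters.
#' @param alpha Significance cutoff on the empirical p-value.
#' @return List with `gamma_star`, `report` (one data-frame row per grid
#'   value), and `all_failed_significance` (logical flag).
#' @export
select_resolution <- function(network, gamma_grid, spec = detector_spec(),
                              n_iter = 25L, n_null = 100L, seed = 1L,
                              alpha = 0.05) {
  g <- as_network(network)
  if (length(gamma_grid) == 0L) stop("'gamma_grid' must be non-empty")
  seed <- as.integer(seed)
  nulls <- degree_preserving_null(g, n_null, seed = seed + 10000L)
  rows <- lapply(seq_along(gamma_grid), function(k) {
    gam <- gamma_grid[[k]]
    s <- spec; s$gamma <- gam
    parts <- lapply(seq_len(n_iter), function(i) {
      si <- s; si$seed <- seed + 100L * k + i
      detect_modules(g, si)
    })
    qs <- vapply(parts, function(p) network_modularity(g, p, gam), 0)
    sizes <- lapply(parts, function(p) lengths(partition_modules(p)))
    pr <- utils::combn(n_iter, 2L)
    stab <- mean(apply(pr, 2L, function(ij) nmi(parts[[ij[1L]]],
                                                parts[[ij[2L]]])))
    null_q <- vapply(seq_along(nulls), function(i) {
      si <- s; si$seed <- seed + 20000L + 100L * k + i
      network_modularity(nulls[[i]], detect_modules(nulls[[i]], si), gam)
    }, 0)
    sd_null <- stats::sd(null_q)
    data.frame(
      gamma = gam,
      stability = stab,
      mean_q = mean(qs),
      mean_n_modules = mean(vapply(sizes, length, 0L)),
      mean_module_size = mean(vapply(sizes, mean, 0)),
      null_q_mean = mean(null_q),
      null_q_sd = sd_null,
      z_score = if (sd_null > 0) (mean(qs) - mean(null_q)) / sd_null else Inf,
      empirical_p = mean(null_q >= mean(qs))
    )
  })
  report <- do.call(rbind, rows)
  passing <- which(report$empirical_p < alpha)
  all_failed <- length(passing) == 0L
  if (all_failed) {
    warning("no resolution parameter passed the significance cutoff; ",
            "returning the most stable value")
    passing <- seq_len(nrow(report))
  }
  cand <- report[passing, ]
  best <- passing[order(-cand$stability, -cand$mean_n_modules)][1L]
  list(gamma_star = report$gamma[best], report = report,
       all_failed_significance = all_failed)
}

#' Complementary cumulative distribution of module sizes
#'
#' @param partition A partition.
#' @return Data frame with columns `size` (1 to max size + 1) and
#'   `fraction`: the fraction of modules of at least that size.  The
#'   fraction at size 1 is 1 and the sequence is non-increasing.
#' @export
size_ccdf <- function(partition) {
  sizes <- lengths(partition_modules(partition))
  grid <- seq_len(max(sizes) + 1L)
  data.frame(size = grid,
             fraction = vapply(grid, function(s) mean(sizes >= s), 0))
}
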