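#' Refinement configuration
#'
#' @param gamma Positive resolution parameter used for the modularity
#'   bookkeeping and (by default) by the incremental detector.
#' @param rho Non-negative modularity-loss budget: the cumulative loss
#'   `Q_init - Q_current` is never allowed to exceed `rho`; a split that
#'   would exceed it is reverted and the module frozen.  When `NULL`
#'   (default), `rho = 0.2 * max(Q_init, 0)` is used at run time: a
#'   relative default that keeps the budget scale-free.
#' @param detector A [detector_spec()] used to re-modularize refinable
#'   modules as individual graphs.  Its `gamma` defaults to the
#'   configuration's `gamma`.
#' @param max_rounds Positive integer safety cap on the number of
#'   incremental-modularization rounds.
#' @param seed Integer seed; each round's detector call derives its own
#'   seed deterministically from it.
#' @param filter_scope Either `"module"` (default) or `"network"`.
#'   Controls which graph the sub-module qualification test
#'   ([qualifies_as_module()]) is evaluated against: the refinable
#'   module treated as an individual graph, or the whole original
#'   network.  See the methods vignette for why module-local filtering
#'   is the default.
#' @return A list of class `"refinement_config"`.
#' @export
refinement_config <- function(gamma = 1, rho = NULL, detector = NULL,
                              max_rounds = 10000L, seed = NULL,
                              filter_scope = c("module", "network")) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("'gamma' must be a single positive number")
  }
  if (!is.null(rho) && (!is.numeric(rho) || length(rho) != 1L || rho < 0)) {
    stop("'rho' must be a single non-negative number (or NULL)")
  }
  if (is.null(detector)) detector <- detector_spec("louvain", gamma = gamma)
  if (!inherits(detector, "detector_spec")) {
    stop("'detector' must be a detector_spec object")
  }
  max_rounds <- as.integer(max_rounds)
  if (is.na(max_rounds) || max_rounds < 1L) stop("'max_rounds' must be >= 1")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(gamma = gamma, rho = rho, detector = detector,
                 max_rounds = max_rounds, seed = seed,
                 filter_scope = match.arg(filter_scope)),
            class = "refinement_config")
}

#' Is a module refinable?
#'
#' A module is refinable when it can club two or more valid sub-modules,
#' which requires more than `sqrt(2 * L)` intra-module edges, with `L`
#' the total edge count of the original network.  The comparison is
#' strict.
#'
#' @inheritParams module_stats
#' @return Logical.
#' @export
is_refinable <- function(network, members) {
  g <- as_network(network)
  L <- igraph::gsize(g)
  if (L == 0L) return(FALSE)
  members <- unique(as.character(members))
  l_m <- igraph::gsize(igraph::induced_subgraph(g, members))
  l_m > sqrt(2 * L)
}

#' Split a module by re-modularizing it as an individual graph
#'
#' Runs the configured detector on the subgraph induced by `members`
#' and returns the resulting sub-module node sets (a partition of
#' `members`).
#'
#' @inheritParams module_stats
#' @param config A [refinement_config()]; its `detector` is used.
#' @return List of character vectors, pairwise disjoint, covering
#'   `members`.
#' @export
split_module <- function(network, members, config = refinement_config()) {
  g <- as_network(network)
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("'members' must be a non-empty node set")
  sub <- igraph::induced_subgraph(g, members)
  p <- detect_modules(sub, config$detector)
  unname(partition_modules(p))
}

#' Filter sub-modules by the topological qualification test
#'
#' Each sub-module is tested with [qualifies_as_module()] against
#' `network`: its quality must be positive and its internal degree must
#' exceed its external degree.  Sub-modules that fail are grouped into a
#' single rejected set.
#'
#' Pass the refinable module's induced subgraph as `network` to filter
#' module-locally (each sub-module judged within the module being
#' refined), or the whole original network to filter globally.
#'
#' @param network The graph the qualification test is evaluated against.
#' @param submodules List of disjoint node sets.
#' @param gamma Positive resolution parameter for the quality test.
#' @return List with `accepted` (list of node sets) and `rejected_group`
#'   (single character vector, possibly empty).
#' @export
filter_submodules <- function(network, submodules, gamma = 1) {
  g <- as_network(network)
  ok <- vapply(submodules, function(m) {
    qualifies_as_module(g, m, gamma = gamma)$qualifies
  }, NA)
  list(accepted = submodules[ok],
       rejected_group = as.character(unlist(submodules[!ok], use.names = FALSE)))
}

#' Refine a partition by incremental re-modularization
#'
#' The core algorithm.  Starting from `initial` (a partition from any
#' modularity-based detector), modules with more than `sqrt(2 * L)`
#' intra-module edges are queued as *refinable* (largest `l_m` first)
#' and processed one per round:
#'
#' 1. the module is re-modularized as an individual graph by the
#'    configured detector ([split_module()]);
#' 2. sub-modules are filtered by the topological qualification test
#'    ([filter_submodules()]); failures are grouped into a single
#'    rejected set;
#' 3. accepted sub-modules join the final modularization as they stand;
#'    the rejected group replaces what is left of the parent and is
#'    submitted again for incremental modularization when it is itself
#'    refinable;
#' 4. a round whose cumulative modularity loss `Q_init - Q_current`
#'    would exceed the budget `rho` is reverted and the parent frozen.
#'
#' Non-refinable modules are never touched.  The run terminates when the
#' queue is empty or `max_rounds` is reached.
#'
#' @inheritParams network_modularity
#' @param initial A valid partition of the network.
#' @param config A [refinement_config()].
#' @return A list of class `"refinement_result"`: `partition` (the final
#'   partition), `Q_init`, `Q_final`, `genealogy` (final-module label ->
#'   character vector of ancestor labels, nearest first),
#'   `n_refinable_initial`, `rounds`, `converged_by` (one of
#'   `"no_refinable_left"`, `"loss_budget"`, `"max_rounds"`), and a
#'   per-round `log` data frame.
#' @export
#' @examples
#' pp <- generate_planted_partition(4, 20, 0.6, 0.02, seed = 1)
#' merged <- ifelse(as.integer(pp$partition) <= 2, "A", "B")
#' names(merged) <- names(pp$partition)
#' res <- refine_modules(pp$network, merged,
#'                       refinement_config(seed = 1, rho = 1))
#' res$converged_by
refine_modules <- function(network, initial, config = refinement_config()) {
  g <- as_network(network)
  L <- igraph::gsize(g)
  if (L == 0L) stop("refinement is undefined on a network with no edges")
  p <- validate_partition(g, initial)
  gamma <- config$gamma
  thr <- sqrt(2 * L)

  mods <- split(names(p), p)
  intra <- function(m) igraph::gsize(igraph::induced_subgraph(g, m))
  l_m <- vapply(mods, intra, 0)
  Q_m <- vapply(mods, function(m) module_stats(g, m, gamma)$Q_m, 0)
  Q_init <- sum(Q_m)
  Q_cur <- Q_init
  rho <- if (is.null(config$rho)) 0.2 * max(Q_init, 0) else config$rho
  base_seed <- if (is.null(config$seed)) NULL else config$seed

  refinable <- l_m > thr
  n_refinable_initial <- sum(refinable)
  queue <- names(mods)[refinable]          # labels still to process
  frozen <- character(0)
  parent_of <- character(0)                # child label -> parent label
  budget_hit <- FALSE
  rounds <- 0L
  log <- list()

  while (length(queue) > 0L && rounds < config$max_rounds) {
    # largest intra-edge count first: front-loads the biggest losses so
    # the budget binds deterministically
    lab <- queue[which.max(l_m[queue])]
    queue <- setdiff(queue, lab)
    rounds <- rounds + 1L
    members <- mods[[lab]]
    parent_lm <- l_m[[lab]]

    det <- config$detector
    if (!is.null(base_seed)) det$seed <- base_seed + rounds
    sub_sets <- split_module(g, members, refinement_config(
      gamma = gamma, detector = det, seed = det$seed))

    if (length(sub_sets) <= 1L) {
      # no internal structure found: mark non-refinable
      frozen <- c(frozen, lab)
      log[[rounds]] <- data.frame(round = rounds, module = lab,
                                  l_m = parent_lm, n_sub = 1L,
                                  delta_q = 0, cum_loss = Q_init - Q_cur,
                                  action = "frozen_single")
      next
    }

    filter_graph <- if (config$filter_scope == "module") {
      igraph::induced_subgraph(g, members)
    } else g
    flt <- filter_submodules(filter_graph, sub_sets, gamma = gamma)
    children <- flt$accepted
    if (length(flt$rejected_group) > 0L) {
      children <- c(children, list(flt$rejected_group))
    }
    if (length(children) <= 1L) {
      # every sub-module failed the test: no net change, freeze
      frozen <- c(frozen, lab)
      log[[rounds]] <- data.frame(round = rounds, module = lab,
                                  l_m = parent_lm, n_sub = length(sub_sets),
                                  delta_q = 0, cum_loss = Q_init - Q_cur,
                                  action = "frozen_all_rejected")
      next
    }

    child_q <- vapply(children, function(m) module_stats(g, m, gamma)$Q_m, 0)
    delta_q <- sum(child_q) - Q_m[[lab]]
    loss_after <- Q_init - (Q_cur + delta_q)
    if (loss_after > rho + 1e-12) {
      frozen <- c(frozen, lab)
      budget_hit <- TRUE
      log[[rounds]] <- data.frame(round = rounds, module = lab,
                                  l_m = parent_lm, n_sub = length(sub_sets),
                                  delta_q = delta_q,
                                  cum_loss = Q_init - Q_cur,
                                  action = "reverted_budget")
      next
    }

    # commit the split: accepted sub-modules are final as they stand;
    # only the rejected group is submitted again (if itself refinable)
    child_labs <- paste(lab, seq_along(children), sep = ".")
    has_rejected <- length(flt$rejected_group) > 0L
    mods[[lab]] <- NULL
    l_m <- l_m[names(l_m) != lab]
    Q_m <- Q_m[names(Q_m) != lab]
    for (k in seq_along(children)) {
      cl <- child_labs[[k]]
      mods[[cl]] <- children[[k]]
      l_m[[cl]] <- intra(children[[k]])
      Q_m[[cl]] <- child_q[[k]]
      parent_of[[cl]] <- lab
      is_rejected_group <- has_rejected && k == length(children)
      if (is_rejected_group && l_m[[cl]] > thr) queue <- c(queue, cl)
    }
    Q_cur <- Q_cur + delta_q
    log[[rounds]] <- data.frame(round = rounds, module = lab,
                                l_m = parent_lm, n_sub = length(sub_sets),
                                delta_q = delta_q, cum_loss = Q_init - Q_cur,
                                action = "split")
  }

  converged_by <- if (length(queue) > 0L) "max_rounds"
                  else if (budget_hit) "loss_budget"
                  else "no_refinable_left"

  out <- character(0)
  for (lab in names(mods)) out[mods[[lab]]] <- lab
  out <- out[igraph::V(g)$name]
  genealogy <- lapply(names(mods), function(lab) {
    chain <- character(0)
    while (!is.na(parent_of[lab] %||% NA_character_)) {
      lab <- parent_of[[lab]]
      chain <- c(chain, lab)
    }
    chain
  })
  names(genealogy) <- names(mods)

  structure(list(
    partition = out,
    Q_init = Q_init,
    Q_final = network_modularity(g, out, gamma),
    genealogy = genealogy,
    n_refinable_initial = n_refinable_initial,
    rounds = rounds,
    converged_by = converged_by,
    rho = rho,
    log = if (length(log)) do.call(rbind, log) else
      data.frame(round = integer(0), module = character(0), l_m = numeric(0),
                 n_sub = integer(0), delta_q = numeric(0),
                 cum_loss = numeric(0), action = character(0))
  ), class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf(
    paste0("module refinement: %d round(s), %d refinable initially, ",
           "%d final module(s)\n  Q: %.5f -> %.5f (loss %.5f, budget %.5f); ",
           "converged by %s\n"),
    x$rounds, x$n_refinable_initial, length(unique(x$partition)),
    x$Q_init, x$Q_final, x$Q_init - x$Q_final, x$rho, x$converged_by))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
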