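#' Read a GMT gene-set collection
#'
#' Tab-delimited GMT: one set per line as `name <tab> description <tab>
#' gene1 <tab> gene2 ...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (set name -> gene set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(toks) < 3L)) {
    stop("malformed GMT line: need name, description and at least one gene")
  }
  sets <- lapply(toks, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(toks, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in ", path)
  sets
}

#' Read / build a gene -> term annotation table
#'
#' `read_annotations()` reads a two-column delimited file (gene, term);
#' `annotation_table()` builds the same structure from vectors.
#'
#' @param path Two-column whitespace/tab-delimited file, `#` comments
#'   allowed.
#' @return A list of class `"annotation_table"` with `gene2term` (gene
#'   -> character vector of terms) and `term2gene` (term -> character
#'   vector of genes).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty annotation file: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(toks) < 2L)) {
    stop("annotation line with fewer than two fields in ", path)
  }
  annotation_table(vapply(toks, `[[`, "", 1L), vapply(toks, `[[`, "", 2L))
}

#' @rdname read_annotations
#' @param gene,term Character vectors of equal length: one (gene, term)
#'   pair per element.
#' @export
annotation_table <- function(gene, term) {
  gene <- as.character(gene); term <- as.character(term)
  if (length(gene) != length(term) || length(gene) == 0L) {
    stop("'gene' and 'term' must be non-empty vectors of equal length")
  }
  keep <- !duplicated(paste(gene, term, sep = "\r"))
  gene <- gene[keep]; term <- term[keep]
  structure(list(gene2term = split(term, gene),
                 term2gene = split(gene, term)),
            class = "annotation_table")
}

#' Hypergeometric enrichment of a module
#'
#' For every annotation term, tests over-representation of the term's
#' genes in the module with the one-sided hypergeometric tail
#' `p = P(X >= k)`, where `k` is the module/term overlap, drawn from a
#' universe of `|universe|` genes of which `|term|` carry the term.
#' Terms passing `alpha` are ranked by ascending p-value and the top
#' `top_k` retained.  The enriched fraction is the fraction of module
#' genes annotated to at least one retained term.
#'
#' @param members Character vector of gene identifiers (the module).
#' @param annotations An [annotation_table()].
#' @param universe Background gene set; defaults to all annotated genes.
#'   Module genes outside the universe are ignored with a warning.
#' @param alpha Significance cutoff on the (optionally adjusted)
#'   p-value.
#' @param top_k Number of top enriched terms retained (10, matching the
#'   "top ten enriched functions" convention).
#' @param adjust `"none"` (raw p-values, the default) or `"BH"` for
#'   Benjamini-Hochberg adjustment before thresholding.
#' @return List of class `"module_enrichment"`: `table` (all terms with
#'   `k`, `K`, `p`), `top_terms` (character vector, at most `top_k`),
#'   `enriched_fraction`, `n_tested`.
#' @export
enrich_module <- function(members, annotations, universe = NULL,
                          alpha = 0.05, top_k = 10L,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!inherits(annotations, "annotation_table")) {
    stop("'annotations' must be an annotation_table")
  }
  if (is.null(universe)) universe <- names(annotations$gene2term)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("empty module")
  outside <- setdiff(members, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " module gene(s) outside the universe ignored")
    members <- intersect(members, universe)
    if (length(members) == 0L) stop("no module genes in the universe")
  }
  N <- length(universe)
  nm <- length(members)
  terms <- names(annotations$term2gene)
  tab <- do.call(rbind, lapply(terms, function(t) {
    tg <- intersect(annotations$term2gene[[t]], universe)
    K <- length(tg)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, tg))
    data.frame(term = t, k = k, K = K,
               p = stats::phyper(k - 1, K, N - K, nm, lower.tail = FALSE))
  }))
  if (is.null(tab)) {
    tab <- data.frame(term = character(0), k = integer(0), K = integer(0),
                      p = numeric(0))
  }
  p_use <- if (adjust == "BH") stats::p.adjust(tab$p, "BH") else tab$p
  sig <- which(p_use < alpha)
  sig <- sig[order(tab$p[sig])]
  top <- utils::head(tab$term[sig], top_k)
  covered <- unique(unlist(annotations$term2gene[top], use.names = FALSE))
  structure(list(
    table = tab[order(tab$p), , drop = FALSE],
    top_terms = top,
    enriched_fraction = if (length(top)) {
      length(intersect(members, covered)) / nm
    } else 0,
    n_tested = nrow(tab)
  ), class = "module_enrichment")
}

#' Mean enriched fraction over meso-modules
#'
#' Averages the enriched fraction of [enrich_module()] over
#' *meso-modules* — modules with more than 10 nodes (`min_size = 11`),
#' the scale at which functional enrichment is meaningfully assessed.
#' Smaller modules are excluded.
#'
#' @inheritParams enrich_module
#' @param partition A partition whose node identifiers are gene
#'   identifiers.
#' @param min_size Minimum module size included (default 11, i.e. size
#'   > 10).
#' @return Mean enriched fraction in `[0, 1]`; 0 with a warning when no
#'   module reaches `min_size`.
#' @export
enrichment_fraction_summary <- function(partition, annotations,
                                        universe = NULL, alpha = 0.05,
                                        min_size = 11L,
                                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  mods <- partition_modules(partition)
  mods <- mods[lengths(mods) >= min_size]
  if (length(mods) == 0L) {
    warning("no meso-modules (size >= ", min_size, "); returning 0")
    return(0)
  }
  if (is.null(universe)) universe <- names(annotations$gene2term)
  fr <- vapply(mods, function(m) {
    if (length(intersect(m, universe)) == 0L) return(0)
    suppressWarnings(
      enrich_module(m, annotations, universe = universe, alpha = alpha,
                    adjust = adjust)$enriched_fraction)
  }, 0)
  mean(fr)
}

#' Functional coverage of a partition by known gene sets
#'
#' For each known gene set, the best Jaccard coefficient over all
#' predicted modules is found; the coverage is the mean of these
#' per-set maxima.  Gene sets are used as given; set
#' `restrict_to_network = TRUE` to first intersect each set with the
#' partition's node universe.
#'
#' @param partition A partition whose nodes are gene identifiers.
#' @param gene_sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param restrict_to_network Logical; intersect gene sets with the
#'   partitioned nodes before computing overlaps.
#' @return Mean best-Jaccard coverage in `[0, 1]`.
#' @export
functional_coverage <- function(partition, gene_sets,
                                restrict_to_network = FALSE) {
  if (length(gene_sets) == 0L) stop("'gene_sets' must be non-empty")
  mods <- partition_modules(partition)
  if (restrict_to_network) {
    nodes <- unlist(mods, use.names = FALSE)
    gene_sets <- lapply(gene_sets, intersect, y = nodes)
    gene_sets <- gene_sets[lengths(gene_sets) > 0L]
    if (length(gene_sets) == 0L) return(0)
  }
  best <- vapply(gene_sets, function(gs) {
    max(vapply(mods, function(m) {
      length(intersect(gs, m)) / length(union(gs, m))
    }, 0))
  }, 0)
  mean(best)
}

#' Generate synthetic annotations aligned with a partition
#'
#' Fixture generator for enrichment experiments without external data:
#' each module is assigned a designated term; each gene receives its
#' module's term with probability `coherence` and a uniformly random
#' term otherwise.  At `coherence = 1` every module is perfectly
#' enriched in its own term; at `coherence = 0` terms are uniform noise.
#'
#' @param partition A partition.
#' @param n_terms Number of distinct terms (at least the number of
#'   modules is not required; terms are recycled over modules).
#' @param coherence Probability in `[0, 1]` that a gene is annotated
#'   with its module's designated term.
#' @param seed Integer seed; the table is reproducible from it.
#' @return An [annotation_table()].
#' @export
generate_synthetic_annotations <- function(partition, n_terms, coherence,
                                           seed = 1L) {
  if (coherence < 0 || coherence > 1) stop("'coherence' must be in [0, 1]")
  n_terms <- as.integer(n_terms)
  if (is.na(n_terms) || n_terms < 1L) stop("'n_terms' must be >= 1")
  set.seed(as.integer(seed))
  p <- as_partition(partition)
  labs <- unique(p)
  term_of_module <- stats::setNames(
    paste0("T", ((seq_along(labs) - 1L) %% n_terms) + 1L), labs)
  all_terms <- paste0("T", seq_len(n_terms))
  own <- stats::runif(length(p)) < coherence
  term <- ifelse(own, term_of_module[p],
                 sample(all_terms, length(p), replace = TRUE))
  annotation_table(names(p), term)
}
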