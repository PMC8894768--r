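#' Simulate a small DAG-structured GO universe with planted enrichment
#'
#' Builds a rooted acyclic ontology (term 1 is the root; every later term
#' draws one or two parents among earlier terms, so the edge list is
#' acyclic by construction, which is asserted before returning), annotates
#' every gene directly to at least one non-root term, and plants enriched
#' terms by over-sampling their annotated genes into a designated study
#' set.
#'
#' @param config A [sim_config()]; uses `go_terms`, `go_enriched_terms`,
#'   `n_genes`.
#' @param study_size Number of genes in the designated study set (default
#'   one tenth of the gene universe, at least 10).
#' @param enrich_prob Probability that a gene annotated to a planted term
#'   enters the study set (background genes enter with the complementary
#'   rate needed to reach `study_size` on average).
#' @return A list with `annotations` (data frame `gene`, `term`; direct
#'   annotations), `edges` (data frame `child`, `parent`), `study`
#'   (character vector), and `truth` (with `enriched_terms`).
#' @examples
#' sim <- simulate_go_universe(sim_config(seed = 1, n_genes = 200,
#'                                        go_terms = 10))
#' head(sim$edges)
#' @export
simulate_go_universe <- function(config, study_size = NULL,
                                 enrich_prob = 0.5) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  nt <- config$go_terms
  ng <- config$n_genes
  terms <- sprintf("TERM:%04d", seq_len(nt))
  genes <- sprintf("gene%05d", seq_len(ng))

  ## parents only among earlier-indexed terms -> acyclic by construction
  edges <- NULL
  if (nt > 1) {
    child <- character(0); parent <- character(0)
    for (i in 2:nt) {
      k <- if (i == 2) 1L else sample(1:2, 1)
      pa <- sample.int(i - 1L, min(k, i - 1L))
      child <- c(child, rep(terms[i], length(pa)))
      parent <- c(parent, terms[pa])
    }
    edges <- data.frame(child = child, parent = parent,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(child = character(0), parent = character(0))
  }
  ## generator-bug guard: the DAG must be acyclic
  stopifnot(is_acyclic_edges(edges))

  ## direct annotation: each gene to 1-3 non-root terms (or the root if the
  ## ontology is a single term)
  ann_terms <- if (nt > 1) terms[-1] else terms
  ann_gene <- character(0); ann_term <- character(0)
  for (g in genes) {
    k <- sample(1:min(3, length(ann_terms)), 1)
    tm <- sample(ann_terms, k)
    ann_gene <- c(ann_gene, rep(g, k))
    ann_term <- c(ann_term, tm)
  }
  annotations <- data.frame(gene = ann_gene, term = ann_term,
                            stringsAsFactors = FALSE)

  ## plant enriched terms among the leaves (terms that are never parents)
  leaves <- setdiff(terms, unique(edges$parent))
  n_enr <- min(config$go_enriched_terms, length(leaves))
  enriched <- if (n_enr > 0) sort(sample(leaves, n_enr)) else character(0)

  if (is.null(study_size)) study_size <- max(10L, round(ng / 10))
  in_enr <- genes %in% annotations$gene[annotations$term %in% enriched]
  p_bg <- max(0, (study_size - enrich_prob * sum(in_enr)) /
                max(1, sum(!in_enr)))
  take <- ifelse(in_enr, stats::runif(ng) < enrich_prob,
                 stats::runif(ng) < p_bg)
  study <- genes[take]
  if (length(study) < 2) study <- sample(genes, max(2, study_size))

  truth <- structure(list(enriched_terms = enriched),
                     class = "sim_truth")
  list(annotations = annotations, edges = edges, study = study,
       truth = truth)
}

## acyclicity check by iterated leaf stripping (Kahn)
is_acyclic_edges <- function(edges) {
  if (nrow(edges) == 0) return(TRUE)
  nodes <- unique(c(edges$child, edges$parent))
  e <- edges
  repeat {
    ## "leaves" here: nodes that are never a parent (no incoming child edge)
    leaves <- setdiff(nodes, unique(e$parent))
    if (length(leaves) == 0) return(FALSE)
    nodes <- setdiff(nodes, leaves)
    e <- e[!(e$child %in% leaves), , drop = FALSE]
    if (length(nodes) == 0 || nrow(e) == 0) return(TRUE)
  }
}
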