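#' GO DAG container
#'
#' Holds an acyclic is-a term graph (child -> parent edges), direct
#' annotations, and, after [propagate_true_path()], propagated annotation
#' sets obeying the true-path rule (a gene annotated to a term is
#' annotated to all its ancestors).
#'
#' @param annotations Data frame with columns `gene`, `term` (direct
#'   annotations).
#' @param edges Data frame with columns `child`, `parent`.
#' @return Object of class `"go_dag"`.
#' @export
go_dag <- function(annotations, edges) {
  stopifnot(all(c("gene", "term") %in% names(annotations)),
            all(c("child", "parent") %in% names(edges)))
  terms <- sort(unique(c(annotations$term, edges$child, edges$parent)))
  if (!is_acyclic_edges(edges)) {
    stop("cycle detected in term graph", call. = FALSE)
  }
  direct <- split(annotations$gene, factor(annotations$term,
                                           levels = terms))
  direct <- lapply(direct, unique)
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  children <- split(edges$child, factor(edges$parent, levels = terms))
  structure(list(terms = terms, edges = edges, direct = direct,
                 parents = parents, children = children,
                 propagated = NULL),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat("go_dag: ", length(x$terms), " terms, ", nrow(x$edges), " edges, ",
      length(unique(unlist(x$direct))), " annotated genes",
      if (!is.null(x$propagated)) " (propagated)", "\n", sep = "")
  invisible(x)
}

## longest-path depth from the root(s); roots have depth 0
dag_depths <- function(dag) {
  depth <- stats::setNames(rep(0L, length(dag$terms)), dag$terms)
  ## iterate until fixpoint (bounded by number of terms)
  for (i in seq_along(dag$terms)) {
    changed <- FALSE
    for (tm in dag$terms) {
      pa <- dag$parents[[tm]]
      if (length(pa)) {
        d <- max(depth[pa]) + 1L
        if (d > depth[tm]) { depth[tm] <- d; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  depth
}

## all strict descendants of every term (via reverse reachability)
dag_descendants <- function(dag) {
  desc <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  order <- names(sort(dag_depths(dag), decreasing = TRUE))  # deepest first
  for (tm in order) {
    ch <- dag$children[[tm]]
    desc[[tm]] <- unique(c(ch, unlist(desc[ch], use.names = FALSE)))
  }
  desc
}

#' Propagate annotations up the DAG (true-path rule)
#'
#' Computes `propagated(term) = direct(term) U union(propagated(children))`
#' bottom-up. Idempotent; fails with the offending structure if the edge
#' list contains a cycle.
#'
#' @param dag A [go_dag()].
#' @return The dag with `propagated` filled.
#' @export
propagate_true_path <- function(dag) {
  stopifnot(inherits(dag, "go_dag"))
  order <- names(sort(dag_depths(dag), decreasing = TRUE))
  prop <- dag$direct
  for (tm in order) {
    ch <- dag$children[[tm]]
    if (length(ch)) {
      prop[[tm]] <- unique(c(prop[[tm]],
                             unlist(prop[ch], use.names = FALSE)))
    }
  }
  dag$propagated <- prop
  dag
}

## weighted one-sided hypergeometric test used by weight01; weights scale
## the contribution of each annotated gene and counts are rounded back to
## integers before the tail sum
weighted_term_p <- function(ann_genes, w, study, n_pop, n_study) {
  sig <- round(sum(w[ann_genes %in% study]))
  n_ann <- round(sum(w))
  if (n_ann == 0) return(1)
  sig <- min(sig, n_ann)
  stats::phyper(sig - 1, n_ann, n_pop - n_ann, n_study,
                lower.tail = FALSE)
}

#' DAG-aware GO term enrichment (classic and weight01 Fisher)
#'
#' `classic` tests every term independently with the one-sided
#' hypergeometric (Fisher) test on (study hits in term, study size, term
#' size, population size). `weight01` decorrelates parent-child tests:
#' terms are visited bottom-up (deepest first, ties in lexicographic id
#' order) and when a child is more significant than its parent, the
#' child's genes are down-weighted in the parent and all higher ancestors
#' by the log-p significance ratio `log(p_parent) / log(p_child)` (in
#' [0, 1]), after which the parent's p-value is recomputed with weighted
#' counts. Leaves are never reweighted, so leaf p-values coincide with
#' classic ones. BH FDRs are computed over the returned p-values.
#'
#' @param dag A [go_dag()] (propagated automatically if needed).
#' @param study Character vector of study genes (must be annotated).
#' @param mode `"classic"` or `"weight01"`.
#' @return Data frame `term`, `study_count`, `pop_count`, `p`, `fdr`,
#'   ordered by `fdr` then term id.
#' @export
term_enrichment <- function(dag, study, mode = c("weight01", "classic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dag, "go_dag"))
  if (is.null(dag$propagated)) dag <- propagate_true_path(dag)
  population <- unique(unlist(dag$propagated, use.names = FALSE))
  study <- unique(study)
  if (!length(study)) stop("empty study set", call. = FALSE)
  extra <- setdiff(study, population)
  if (length(extra)) {
    stop("study genes not in annotated population: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  n_pop <- length(population)
  n_study <- length(study)
  prop <- dag$propagated

  classic_p <- vapply(dag$terms, function(tm) {
    ann <- prop[[tm]]
    k <- length(intersect(ann, study))
    stats::phyper(k - 1, length(ann), n_pop - length(ann), n_study,
                  lower.tail = FALSE)
  }, 1.0)

  if (mode == "classic") {
    p <- classic_p
  } else {
    depth <- dag_depths(dag)
    order <- dag$terms[order(-depth, dag$terms)]   # deepest first, then id
    desc <- dag_descendants(dag)
    ## down-weight events: term at which they were raised, affected genes,
    ## multiplicative factor; an event applies to all strict ancestors of
    ## its term, i.e. to any later-visited term having it as descendant
    events <- list()
    p <- stats::setNames(rep(NA_real_, length(dag$terms)), dag$terms)
    for (tm in order) {
      ann <- prop[[tm]]
      w <- stats::setNames(rep(1, length(ann)), ann)
      for (e in events) {
        if (e$term %in% desc[[tm]]) {
          hit <- names(w) %in% e$genes
          w[hit] <- w[hit] * e$factor
        }
      }
      p_tm <- weighted_term_p(ann, w, study, n_pop, n_study)
      ch <- intersect(dag$children[[tm]], names(p)[!is.na(p)])
      sig_ch <- ch[p[ch] < p_tm]
      if (length(sig_ch)) {
        for (cterm in sort(sig_ch)) {
          ## ratio of log p-values in [0, 1]; p_child < p_tm <= 1
          factor <- if (p[cterm] >= 1) 1 else
            log(max(p_tm, .Machine$double.xmin)) /
            log(max(p[cterm], .Machine$double.xmin))
          factor <- min(max(factor, 0), 1)
          genes_c <- prop[[cterm]]
          events[[length(events) + 1L]] <-
            list(term = cterm, genes = genes_c, factor = factor)
          hit <- names(w) %in% genes_c
          w[hit] <- w[hit] * factor
        }
        p_tm <- weighted_term_p(ann, w, study, n_pop, n_study)
      }
      p[tm] <- p_tm
    }
    p <- p[dag$terms]
  }

  out <- data.frame(
    term = dag$terms,
    study_count = vapply(dag$terms, function(tm)
      length(intersect(prop[[tm]], study)), 1L),
    pop_count = vapply(dag$terms, function(tm) length(prop[[tm]]), 1L),
    p = unname(p),
    stringsAsFactors = FALSE, row.names = NULL)
  out$fdr <- bh_adjust(out$p)
  out[order(out$fdr, out$p, out$term), ]
}
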