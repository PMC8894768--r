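## Independent brute-force oracles used to cross-check the implementation.
## These deliberately re-derive each quantity from first principles and
## never call the code paths they verify.

## step-up BH by direct evaluation of min_{j >= i} p_(j) * m / j
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(ranked[i:m] * m / (i:m))
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

## one-sided hypergeometric upper tail P(X >= a) by explicit summation of
## the probability mass function
hyper_tail_enum <- function(a, n_pred, universe, n_det) {
  ks <- a:min(n_pred, n_det)
  sum(choose(n_pred, ks) * choose(universe - n_pred, n_det - ks) /
        choose(universe, n_det))
}

## TMM factors by direct evaluation of the trimmed weighted mean of
## M-values (30% trim on M, 5% on A, inverse-variance weights), reference
## column chosen by upper quartile, factors rescaled to geometric mean 1
brute_force_tmm <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  one_factor <- function(j) {
    y_j <- counts[, j]; y_r <- counts[, ref]
    n_j <- lib[j]; n_r <- lib[ref]
    keep0 <- y_j > 0 & y_r > 0
    y_j <- y_j[keep0]; y_r <- y_r[keep0]
    m <- log2((y_j / n_j) / (y_r / n_r))
    a <- 0.5 * log2((y_j / n_j) * (y_r / n_r))
    w <- 1 / ((n_j - y_j) / (n_j * y_j) + (n_r - y_r) / (n_r * y_r))
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * sum_trim) + 1;      hi_a <- n + 1 - lo_a
    keep <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    f <- 2^(sum(w[keep] * m[keep]) / sum(w[keep]))
    if (!is.finite(f)) f <- 1
    f
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, 1.0)
  f / exp(mean(log(f)))
}

## transitive-closure propagation: a gene annotated to term t belongs to
## every term that t can reach via child -> parent edges (including t)
closure_propagation <- function(annotations, edges) {
  terms <- sort(unique(c(annotations$term, edges$child, edges$parent)))
  ## reachability by iterated matrix-style relaxation
  reach <- stats::setNames(lapply(terms, function(t) t), terms)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      ch <- edges$child[i]; pa <- edges$parent[i]
      add <- setdiff(reach[[ch]], character(0))
      new <- union(reach[[ch]], reach[[pa]])
      if (length(new) > length(reach[[ch]])) {
        reach[[ch]] <- new; changed <- TRUE
      }
      invisible(add)
    }
    if (!changed) break
  }
  out <- stats::setNames(lapply(terms, function(t) character(0)), terms)
  for (i in seq_len(nrow(annotations))) {
    g <- annotations$gene[i]
    for (t in reach[[annotations$term[i]]]) {
      out[[t]] <- union(out[[t]], g)
    }
  }
  out
}

## Pearson correlation from the definition
hand_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

## small paired count fixture: b blocks of AL+ST at one timepoint
make_paired_counts <- function(seed, n_genes = 300, blocks = 3,
                               timepoint = 18, ...) {
  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    n_replicates_per_tissue = blocks,
                    timepoints = timepoint, ...)
  simulate_rnaseq_counts(cfg)
}
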