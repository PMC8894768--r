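#' Paired design specification
#'
#' Builds the model matrix for the paired AL-vs-ST contrast: an additive
#' replicate-block factor plus the tissue factor, with the reported
#' coefficient being AL relative to ST. Every block must contain both
#' tissues exactly once.
#'
#' @param samples Sample sheet (columns `sample`, `tissue`,
#'   `replicate_block`), typically one timepoint of a [count_matrix()].
#' @return A list of class `"design_spec"` with `design` (model matrix),
#'   `coef` (name of the tissue coefficient) and the sheet.
#' @export
design_spec <- function(samples) {
  tab <- table(samples$replicate_block, samples$tissue)
  if (!all(tab == 1) || ncol(tab) != 2 ||
      !all(colnames(tab) %in% c("AL", "ST"))) {
    stop("each replicate block must pair one AL with one ST sample",
         call. = FALSE)
  }
  block <- factor(samples$replicate_block)
  tissue <- factor(samples$tissue, levels = c("ST", "AL"))  # AL vs ST
  design <- if (nlevels(block) > 1) {
    stats::model.matrix(~ block + tissue)
  } else {
    stats::model.matrix(~ tissue)   # one block: absorbed by the intercept
  }
  rownames(design) <- samples$sample
  if (qr(design)$rank < ncol(design)) {
    stop("design matrix is not full rank", call. = FALSE)
  }
  structure(list(design = design, coef = "tissueAL", samples = samples),
            class = "design_spec")
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Per-sample scaling factors correcting for library composition bias,
#' computed by the TMM procedure (reference column chosen by upper
#' quartile, 30% trim on log-ratios, 5% on log-abundance,
#' precision-weighted mean of retained M values) and rescaled to geometric
#' mean 1. The effective library size of a sample is its raw size times
#' its factor.
#'
#' @param counts A [count_matrix()] or plain counts matrix.
#' @return A data frame of class `"norm_factors"` with `sample`, `factor`,
#'   `lib_size`, `effective_lib_size`.
#' @export
tmm_factors <- function(counts) {
  cm <- if (inherits(counts, "count_matrix")) counts$counts else
    as.matrix(counts)
  if (ncol(cm) < 2) stop("need >= 2 samples", call. = FALSE)
  lib <- colSums(cm)
  if (any(lib == 0)) {
    stop("all-zero sample: ", colnames(cm)[which(lib == 0)[1]],
         call. = FALSE)
  }
  f <- edgeR::calcNormFactors(cm, method = "TMM")
  out <- data.frame(sample = colnames(cm), factor = f, lib_size = lib,
                    effective_lib_size = lib * f, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("norm_factors", "data.frame")
  out
}

#' Negative-binomial dispersion estimation (common, trended, tagwise)
#'
#' Fits the quadratic mean-variance model `var = mu + phi * mu^2`: a common
#' dispersion maximizing the adjusted profile likelihood over all genes, a
#' mean-dependent trend, and per-gene (tagwise) estimates shrunk toward the
#' trend by empirical Bayes.
#'
#' @param counts A [count_matrix()] (one timepoint) or counts matrix.
#' @param design A [design_spec()] or model matrix.
#' @param factors Optional [tmm_factors()] result; computed if missing.
#' @return A list with `common`, `trended`, `tagwise` dispersions and the
#'   underlying `DGEList`.
#' @export
estimate_dispersion <- function(counts, design, factors = NULL) {
  cm <- if (inherits(counts, "count_matrix")) counts$counts else
    as.matrix(counts)
  dm <- if (inherits(design, "design_spec")) design$design else design
  if (nrow(dm) >= ncol(dm) && nrow(dm) - ncol(dm) < 1) {
    stop("zero residual degrees of freedom; pool the design", call. = FALSE)
  }
  dge <- edgeR::DGEList(cm)
  dge$samples$norm.factors <- if (is.null(factors)) {
    edgeR::calcNormFactors(cm, method = "TMM")
  } else factors$factor
  dge <- edgeR::estimateDisp(dge, dm)
  list(common = dge$common.dispersion,
       trended = dge$trended.dispersion,
       tagwise = dge$tagwise.dispersion,
       dge = dge)
}

#' Negative-binomial GLM likelihood-ratio test (path 1)
#'
#' Per-gene NB log-link GLM with `log(effective library size)` offsets,
#' dispersion held fixed at the tagwise estimate. The full model carries
#' block and tissue effects; the likelihood-ratio statistic against the
#' reduced (no tissue) model is referred to chi-square with 1 df. The
#' reported log2 fold change is the AL-vs-ST coefficient.
#'
#' @param counts A [count_matrix()] restricted to one timepoint, or matrix.
#' @param design A [design_spec()].
#' @param dispersion Result of [estimate_dispersion()] (tagwise values are
#'   used), or a numeric dispersion (scalar or per gene); estimated when
#'   missing.
#' @param factors Optional [tmm_factors()] result.
#' @return Data frame `gene`, `log2fc`, `lr_stat`, `p_nb`, `dispersion`.
#' @export
nb_glm_lrt <- function(counts, design, dispersion = NULL, factors = NULL) {
  cm <- if (inherits(counts, "count_matrix")) counts$counts else
    as.matrix(counts)
  dm <- if (inherits(design, "design_spec")) design$design else design
  cf <- if (inherits(design, "design_spec")) design$coef else ncol(dm)
  if (is.null(factors)) factors <- tmm_factors(cm)
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(cm, dm, factors)
  }
  disp_vec <- if (is.list(dispersion)) dispersion$tagwise else dispersion
  dge <- edgeR::DGEList(cm)
  dge$samples$norm.factors <- factors$factor
  fit <- edgeR::glmFit(dge, dm, dispersion = disp_vec)
  lrt <- edgeR::glmLRT(fit, coef = cf)
  tab <- lrt$table
  data.frame(gene = rownames(tab), log2fc = tab$logFC, lr_stat = tab$LR,
             p_nb = tab$PValue,
             dispersion = if (length(disp_vec) == 1)
               rep(disp_vec, nrow(tab)) else disp_vec,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Variance-stabilizing log-CPM transform with precision weights (path 2)
#'
#' Transforms counts to `log2((count + 0.5) / (effective libsize + 1) *
#' 1e6)`, fits gene-wise linear models, smooths the sqrt-residual-SD vs
#' mean trend, and assigns each observation the inverse predicted variance
#' as weight, removing the count-data mean-variance dependence before
#' linear modelling.
#'
#' @inheritParams nb_glm_lrt
#' @return A list with `logcpm` (matrix), `weights` (matrix), and the
#'   underlying `EList`.
#' @export
voom_transform <- function(counts, design, factors = NULL) {
  cm <- if (inherits(counts, "count_matrix")) counts$counts else
    as.matrix(counts)
  dm <- if (inherits(design, "design_spec")) design$design else design
  if (is.null(factors)) factors <- tmm_factors(cm)
  dge <- edgeR::DGEList(cm)
  dge$samples$norm.factors <- factors$factor
  v <- limma::voom(dge, dm)
  list(logcpm = v$E, weights = v$weights, elist = v)
}

#' Precision-weighted moderated t-test (path 2)
#'
#' Weighted least squares per gene followed by empirical Bayes moderation:
#' gene-wise residual variances are shrunk toward a common prior estimated
#' across all genes, and the moderated t-statistic gains the prior degrees
#' of freedom. Reports the AL-vs-ST coefficient and its two-sided p-value.
#'
#' @param voom A [voom_transform()] result (or a list with `logcpm` and
#'   `weights`).
#' @param design A [design_spec()].
#' @return Data frame `gene`, `log2fc`, `t`, `p_lm`, `s2_post`, plus
#'   attributes `df_prior` and `s2_prior`.
#' @export
moderated_t_test <- function(voom, design) {
  dm <- if (inherits(design, "design_spec")) design$design else design
  cf <- if (inherits(design, "design_spec")) design$coef else ncol(dm)
  obj <- if (!is.null(voom$elist)) voom$elist else voom$logcpm
  fit <- limma::lmFit(obj, dm,
                      weights = if (is.null(voom$elist)) voom$weights)
  fit <- limma::eBayes(fit)
  out <- data.frame(gene = rownames(fit$coefficients),
                    log2fc = fit$coefficients[, cf],
                    t = fit$t[, cf],
                    p_lm = fit$p.value[, cf],
                    s2_post = fit$s2.post,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "df_prior") <- fit$df.prior
  attr(out, "s2_prior") <- fit$s2.prior
  attr(out, "sigma") <- fit$sigma
  attr(out, "df_residual") <- fit$df.residual
  out
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment returned in input order; NA p-values pass through
#' untouched. An optional Storey-type null-proportion estimate scales the
#' adjusted values (`pi0 = 1` is plain BH and the default).
#'
#' @param pvalues Numeric vector of p-values in [0, 1] (NA allowed).
#' @param pi0 Null proportion in (0, 1]; use
#'   [estimate_pi0()] for a data-driven value.
#' @return Vector of FDR-adjusted p-values.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.05))
#' @export
bh_adjust <- function(pvalues, pi0 = 1) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must be in (0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  pmin(out * pi0, 1)
}

#' Storey-type estimate of the null proportion
#'
#' `pi0 = min(1, mean(p > lambda) / (1 - lambda))`; with the default
#' `lambda = 0.5` this is twice the fraction of p-values above one half.
#'
#' @param pvalues Numeric p-values.
#' @param lambda Tuning threshold in (0, 1).
#' @return Scalar in (0, 1].
#' @export
estimate_pi0 <- function(pvalues, lambda = 0.5) {
  p <- pvalues[!is.na(pvalues)]
  max(min(1, mean(p > lambda) / (1 - lambda)), .Machine$double.eps)
}

#' Consensus differential-expression calls with the zero-TPM elimination
#'
#' A gene is a consensus DEG when both testing paths call it at
#' `FDR <= alpha`, both estimate `|log2FC| > log2(min_fold)`, and the fold
#' changes agree in sign. Consensus genes whose group-mean TPM is zero in
#' either tissue at the tested timepoint are then eliminated
#' (`eliminated_zero_tpm`), removing calls driven by transcripts the
#' expressed rule already judged undetectable.
#'
#' @param nb_results [nb_glm_lrt()] output.
#' @param lm_results [moderated_t_test()] output.
#' @param tpm Optional summarized `tpm_table` for the elimination rule.
#' @param timepoint Timepoint the tests were run at (needed with `tpm`).
#' @param alpha FDR cutoff (default 0.05).
#' @param min_fold Fold-change cutoff (default 2).
#' @param eliminate_on `"mean_tpm"` (default: zero group-mean after the
#'   expressed rule) or `"any_replicate"` (any single replicate TPM zero).
#' @return Data frame of class `"deg_table"`: per-gene fold changes,
#'   p-values and FDRs from both paths, `direction` (up_AL / up_ST),
#'   `consensus`, `eliminated_zero_tpm`, and `deg` (final call); attribute
#'   `summary` holds up/down counts.
#' @export
call_consensus_degs <- function(nb_results, lm_results, tpm = NULL,
                                timepoint = NULL, alpha = 0.05,
                                min_fold = 2,
                                eliminate_on = c("mean_tpm",
                                                 "any_replicate")) {
  eliminate_on <- match.arg(eliminate_on)
  if (!identical(sort(nb_results$gene), sort(lm_results$gene))) {
    stop("the two paths cover different gene sets", call. = FALSE)
  }
  lm_results <- lm_results[match(nb_results$gene, lm_results$gene), ]
  res <- data.frame(
    gene = nb_results$gene,
    log2fc_nb = nb_results$log2fc,
    log2fc_lm = lm_results$log2fc,
    p_nb = nb_results$p_nb,
    p_lm = lm_results$p_lm,
    fdr_nb = bh_adjust(nb_results$p_nb),
    fdr_lm = bh_adjust(lm_results$p_lm),
    stringsAsFactors = FALSE)
  thr <- log2(min_fold)
  res$direction <- ifelse(res$log2fc_nb > 0, "up_AL", "up_ST")
  res$consensus <- !is.na(res$p_nb) & !is.na(res$p_lm) &
    res$fdr_nb <= alpha & res$fdr_lm <= alpha &
    abs(res$log2fc_nb) > thr & abs(res$log2fc_lm) > thr &
    sign(res$log2fc_nb) == sign(res$log2fc_lm)

  res$eliminated_zero_tpm <- FALSE
  if (!is.null(tpm)) {
    if (is.null(tpm$mean_tpm)) tpm <- summarize_expression(tpm)
    if (is.null(timepoint)) {
      stop("'timepoint' needed for the zero-TPM elimination", call. = FALSE)
    }
    g <- tpm$groups
    if (eliminate_on == "mean_tpm") {
      al <- tpm$mean_tpm[res$gene,
                         g$key[g$tissue == "AL" & g$timepoint == timepoint]]
      st <- tpm$mean_tpm[res$gene,
                         g$key[g$tissue == "ST" & g$timepoint == timepoint]]
      zero <- al == 0 | st == 0
    } else {
      s <- tpm$samples
      cols <- s$timepoint == timepoint
      sub <- tpm$tpm[res$gene, cols, drop = FALSE]
      zero <- rowSums(sub == 0) > 0
    }
    res$eliminated_zero_tpm <- res$consensus & zero
  }
  res$deg <- res$consensus & !res$eliminated_zero_tpm
  class(res) <- c("deg_table", "data.frame")
  attr(res, "summary") <- data.frame(
    up_AL = sum(res$deg & res$direction == "up_AL"),
    up_ST = sum(res$deg & res$direction == "up_ST"),
    consensus = sum(res$consensus),
    eliminated = sum(res$eliminated_zero_tpm))
  res
}

#' Cross-timepoint DEG overlap (Venn counts)
#'
#' @param deg_list Named list of `deg_table`s, one per timepoint.
#' @return Data frame with per-timepoint DEG counts, the shared set size,
#'   and each timepoint's unique count.
#' @export
deg_overlap_summary <- function(deg_list) {
  sets <- lapply(deg_list, function(d) d$gene[d$deg])
  shared <- Reduce(intersect, sets)
  data.frame(
    timepoint = c(names(sets), "shared"),
    n_deg = c(vapply(sets, length, 1L), length(shared)),
    n_unique = c(vapply(seq_along(sets), function(i) {
      length(setdiff(sets[[i]], unlist(sets[-i])))
    }, 1L), NA_integer_),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Run both testing paths on one timepoint
#'
#' Convenience wrapper: subsets the count matrix to a timepoint, builds the
#' paired design, computes TMM factors, runs the NB GLM LRT and the
#' precision-weighted moderated t-test, and combines them with
#' [call_consensus_degs()].
#'
#' @param counts A [count_matrix()].
#' @param timepoint Timepoint (DAP) to test.
#' @param tpm Optional summarized `tpm_table` for the elimination rule.
#' @inheritParams call_consensus_degs
#' @return A `deg_table`.
#' @export
run_deg_timepoint <- function(counts, timepoint, tpm = NULL, alpha = 0.05,
                              min_fold = 2) {
  sub <- subset_timepoint(counts, timepoint)
  des <- design_spec(sub$samples)
  fac <- tmm_factors(sub)
  disp <- estimate_dispersion(sub, des, fac)
  nb <- nb_glm_lrt(sub, des, disp, fac)
  v <- voom_transform(sub, des, fac)
  lm <- moderated_t_test(v, des)
  call_consensus_degs(nb, lm, tpm = tpm, timepoint = timepoint,
                      alpha = alpha, min_fold = min_fold)
}
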