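#' Simulate triplicate qPCR Ct values with a reference gene
#'
#' Generates cycle-threshold (Ct) tables for target genes with known true
#' AL/ST expression ratios plus a reference gene (`Ubc9`) expressed equally
#' in both tissues. Ct values follow `base - log2(expression) + noise`, so
#' perfect amplification efficiency (doubling per cycle) inverts exactly to
#' the true ratio under the comparative-Ct method.
#'
#' @param config A [sim_config()]; uses `qpcr_genes`, `qpcr_log2_ratios`,
#'   `ct_noise_sd`, `n_bio_reps`, `n_tech_reps`.
#' @return A list with `ct` (data frame `gene`, `tissue`, `bio_rep`,
#'   `tech_rep`, `ct`), `reference` (gene id), and `truth` (named vector of
#'   true AL/ST fold changes).
#' @examples
#' sim <- simulate_qpcr_ct(sim_config(seed = 1, ct_noise_sd = 0))
#' ddct_fold_change(sim$ct, target = names(sim$truth$fold_changes)[1],
#'                  reference = sim$reference)
#' @export
simulate_qpcr_ct <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 5L)
  ngene <- config$qpcr_genes
  ratios <- config$qpcr_log2_ratios
  if (is.null(ratios)) {
    ratios <- seq(3, -3, length.out = ngene)
  }
  ratios <- rep_len(ratios, ngene)
  genes <- sprintf("target%02d", seq_len(ngene))
  names(ratios) <- genes
  reference <- "Ubc9"

  ## per-gene baseline expression in ST; AL = ST * 2^ratio
  base_expr <- stats::setNames(stats::rlnorm(ngene, log(100), 0.5), genes)
  ref_expr <- 100
  base_ct <- 28   # cycles at unit expression

  rows <- list()
  for (b in seq_len(config$n_bio_reps)) {
    ## biological variation shared by all genes of a replicate
    bio_eff <- stats::rnorm(1, 0, 0.1)
    for (tissue in c("AL", "ST")) {
      for (g in c(genes, reference)) {
        expr <- if (g == reference) {
          ref_expr
        } else if (tissue == "AL") {
          base_expr[g] * 2^ratios[g]
        } else {
          base_expr[g]
        }
        for (tr in seq_len(config$n_tech_reps)) {
          ct <- base_ct - log2(expr) + bio_eff +
            stats::rnorm(1, 0, config$ct_noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, tissue = tissue, bio_rep = b, tech_rep = tr,
            ct = ct, stringsAsFactors = FALSE)
        }
      }
    }
  }
  ct <- do.call(rbind, rows)
  rownames(ct) <- NULL
  truth <- structure(list(fold_changes = stats::setNames(2^ratios, genes)),
                     class = "sim_truth")
  list(ct = ct, reference = reference, truth = truth)
}
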