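#' Comparative-Ct (delta-delta-Ct) relative quantification
#'
#' Technical replicates are averaged per (gene, tissue, biological
#' replicate); `dCt = Ct_target - Ct_reference` within each tissue and
#' replicate; `ddCt = dCt_a - dCt_b`; the per-replicate fold change is
#' `efficiency^(-ddCt)` (efficiency 2 assumes perfect doubling each
#' cycle). The summary is the mean of the per-replicate fold changes
#' (the fold of the mean ddCt is also reported).
#'
#' @param records Data frame with columns `gene`, `tissue`, `bio_rep`,
#'   `tech_rep`, `ct`.
#' @param target Target gene id.
#' @param reference Reference gene id (e.g. `Ubc9`).
#' @param tissue_a,tissue_b Tissues compared; the fold is a relative to b
#'   (default AL vs ST).
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return List with `per_replicate` (data frame `bio_rep`, `ddct`,
#'   `fold`), `mean_fold` (mean of replicate folds) and
#'   `fold_of_mean_ddct`.
#' @examples
#' ct <- expand.grid(gene = c("g", "ref"), tissue = c("AL", "ST"),
#'                   bio_rep = 1, tech_rep = 1:2)
#' ct$ct <- ifelse(ct$gene == "ref", 15, ifelse(ct$tissue == "AL", 20, 22))
#' ddct_fold_change(ct, "g", "ref")$mean_fold   # 4
#' @export
ddct_fold_change <- function(records, target, reference,
                             tissue_a = "AL", tissue_b = "ST",
                             efficiency = 2) {
  req <- c("gene", "tissue", "bio_rep", "tech_rep", "ct")
  stopifnot(all(req %in% names(records)))
  if (any(!is.finite(records$ct))) stop("non-finite Ct", call. = FALSE)
  sub <- records[records$gene %in% c(target, reference) &
                   records$tissue %in% c(tissue_a, tissue_b), ]
  if (!any(sub$gene == target)) stop("target gene absent", call. = FALSE)
  ## mean over technical replicates
  agg <- stats::aggregate(ct ~ gene + tissue + bio_rep, data = sub,
                          FUN = mean)
  reps <- sort(unique(agg$bio_rep))
  per <- lapply(reps, function(b) {
    get_ct <- function(g, tis) {
      v <- agg$ct[agg$gene == g & agg$tissue == tis & agg$bio_rep == b]
      if (length(v) != 1) {
        stop("missing ", if (g == reference) "reference " else "",
             "Ct for gene '", g, "' in tissue ", tis, ", replicate ", b,
             call. = FALSE)
      }
      v
    }
    dct_a <- get_ct(target, tissue_a) - get_ct(reference, tissue_a)
    dct_b <- get_ct(target, tissue_b) - get_ct(reference, tissue_b)
    ddct <- dct_a - dct_b
    data.frame(bio_rep = b, ddct = ddct, fold = efficiency^(-ddct))
  })
  per <- do.call(rbind, per)
  list(per_replicate = per,
       mean_fold = mean(per$fold),
       fold_of_mean_ddct = efficiency^(-mean(per$ddct)))
}

#' Comparative-Ct fold changes for every target gene in a Ct table
#'
#' @param records Ct data frame (see [ddct_fold_change()]).
#' @param reference Reference gene id.
#' @inheritParams ddct_fold_change
#' @return Data frame `gene`, `mean_fold`, `fold_of_mean_ddct`.
#' @export
qpcr_fold_table <- function(records, reference, tissue_a = "AL",
                            tissue_b = "ST", efficiency = 2) {
  targets <- setdiff(unique(records$gene), reference)
  out <- lapply(targets, function(g) {
    fc <- ddct_fold_change(records, g, reference, tissue_a, tissue_b,
                           efficiency)
    data.frame(gene = g, mean_fold = fc$mean_fold,
               fold_of_mean_ddct = fc$fold_of_mean_ddct,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
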