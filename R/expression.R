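#' Compute transcripts per million
#'
#' TPM for gene g in sample i is
#' `1e6 * (count_gi / length_g) / sum_h(count_hi / length_h)`: counts are
#' first length-normalized, then scaled so each sample sums to one million.
#' An all-zero sample yields an all-zero column with a warning.
#'
#' @param counts A [count_matrix()].
#' @return An object of class `"tpm_table"`: list with `tpm` (genes x
#'   samples), the `samples` sheet, and empty `mean_tpm` / `expressed`
#'   slots filled by [summarize_expression()].
#' @examples
#' sim <- simulate_rnaseq_counts(sim_config(seed = 1, n_genes = 100,
#'                                          timepoints = 18))
#' tpm <- compute_tpm(sim$counts)
#' colSums(tpm$tpm)
#' @export
compute_tpm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  cm <- counts$counts
  if (any(cm < 0)) stop("negative counts", call. = FALSE)
  len <- counts$gene_length[rownames(cm)]
  if (anyNA(len)) {
    stop("missing length for gene ",
         rownames(cm)[which(is.na(len))[1]], call. = FALSE)
  }
  rate <- cm / len
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("all-zero sample(s): ",
            paste(colnames(cm)[zero], collapse = ", "))
    denom[zero] <- 1   # leaves the column all-zero
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  structure(list(tpm = tpm, samples = counts$samples,
                 mean_tpm = NULL, expressed = NULL),
            class = "tpm_table")
}

#' @export
print.tpm_table <- function(x, ...) {
  cat("tpm_table: ", nrow(x$tpm), " genes x ", ncol(x$tpm), " samples",
      if (!is.null(x$mean_tpm)) " (summarized)", "\n", sep = "")
  invisible(x)
}

#' Summarize TPM over biological replicates with the strict expressed rule
#'
#' A gene is called expressed in a (tissue, timepoint) group if and only if
#' every biological replicate has TPM > 0; its group value is then the mean
#' replicate TPM. Otherwise the gene is treated as not expressed and its
#' group mean is set to 0. This all-replicates rule deliberately discards
#' genes detected in only part of the replicates.
#'
#' @param tpm A `tpm_table` from [compute_tpm()].
#' @return The same object with `mean_tpm` and `expressed` matrices filled
#'   (genes x "tissue_timepoint" groups) and a `groups` data frame mapping
#'   columns to (tissue, timepoint).
#' @export
summarize_expression <- function(tpm) {
  stopifnot(inherits(tpm, "tpm_table"))
  s <- tpm$samples
  key <- paste(s$tissue, s$timepoint, sep = "_")
  groups <- unique(data.frame(key = key, tissue = s$tissue,
                              timepoint = s$timepoint,
                              stringsAsFactors = FALSE))
  mean_tpm <- matrix(0, nrow(tpm$tpm), nrow(groups),
                     dimnames = list(rownames(tpm$tpm), groups$key))
  expressed <- matrix(FALSE, nrow(tpm$tpm), nrow(groups),
                      dimnames = list(rownames(tpm$tpm), groups$key))
  for (j in seq_len(nrow(groups))) {
    cols <- which(key == groups$key[j])
    sub <- tpm$tpm[, cols, drop = FALSE]
    all_pos <- rowSums(sub > 0) == length(cols)
    expressed[, j] <- all_pos
    m <- rowMeans(sub)
    m[!all_pos] <- 0
    mean_tpm[, j] <- m
  }
  tpm$mean_tpm <- mean_tpm
  tpm$expressed <- expressed
  tpm$groups <- groups
  tpm
}

#' Compartment (CS) score: tissue share of summed expression
#'
#' The CS score of a gene for tissue ST is the sum of its group-mean TPM in
#' ST over the selected timepoints divided by the summed mean TPM in ST and
#' AL together; `cs_al = 1 - cs_st`. The score lies in [0, 1]: 1 means
#' exclusively ST expression, 0.5 a perfectly tissue-symmetric gene. When
#' all contributing TPM are zero the score is undefined and flagged.
#'
#' @param tpm A summarized `tpm_table` (see [summarize_expression()]).
#' @param gene Gene id(s); defaults to all genes.
#' @param timepoints Timepoints (DAP) to sum over; defaults to all present.
#' @return Data frame with `gene`, `cs_st`, `cs_al`, `defined`.
#' @examples
#' # a tissue-symmetric gene scores exactly 0.5
#' @export
cs_score <- function(tpm, gene = NULL, timepoints = NULL) {
  stopifnot(inherits(tpm, "tpm_table"))
  if (is.null(tpm$mean_tpm)) tpm <- summarize_expression(tpm)
  g <- tpm$groups
  if (is.null(timepoints)) timepoints <- unique(g$timepoint)
  if (is.null(gene)) gene <- rownames(tpm$mean_tpm)
  unknown <- setdiff(gene, rownames(tpm$mean_tpm))
  if (length(unknown)) {
    stop("unknown gene id(s): ", paste(utils::head(unknown, 5),
         collapse = ", "), call. = FALSE)
  }
  st_cols <- g$key[g$tissue == "ST" & g$timepoint %in% timepoints]
  al_cols <- g$key[g$tissue == "AL" & g$timepoint %in% timepoints]
  st_sum <- rowSums(tpm$mean_tpm[gene, st_cols, drop = FALSE])
  al_sum <- rowSums(tpm$mean_tpm[gene, al_cols, drop = FALSE])
  tot <- st_sum + al_sum
  defined <- tot > 0
  cs_st <- ifelse(defined, st_sum / tot, NA_real_)
  data.frame(gene = gene, cs_st = cs_st, cs_al = 1 - cs_st,
             defined = defined, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Transcript-class share of the transcriptome
#'
#' Percentage of total group-mean TPM contributed by each gene class
#' (e.g. prolamin / non-prolamin-storage / other) per tissue and timepoint,
#' plus each class's share within the storage-protein classes combined.
#'
#' @param tpm A summarized `tpm_table`.
#' @param class_map Named character vector gene -> class; unmapped genes
#'   default to "other".
#' @return Data frame with `tissue`, `timepoint`, `class`, `percent`
#'   (of total TPM), `storage_share_percent` (share within the storage
#'   classes, NA for "other"), and `defined`.
#' @export
class_fraction <- function(tpm, class_map) {
  stopifnot(inherits(tpm, "tpm_table"))
  if (is.null(tpm$mean_tpm)) tpm <- summarize_expression(tpm)
  genes <- rownames(tpm$mean_tpm)
  cls <- stats::setNames(rep("other", length(genes)), genes)
  hit <- intersect(genes, names(class_map))
  cls[hit] <- class_map[hit]
  g <- tpm$groups
  storage_classes <- setdiff(unique(cls), "other")
  out <- list()
  for (j in seq_len(nrow(g))) {
    col <- tpm$mean_tpm[, g$key[j]]
    tot <- sum(col)
    storage_tot <- sum(col[cls %in% storage_classes])
    for (cl in sort(unique(cls))) {
      mass <- sum(col[cls == cl])
      out[[length(out) + 1L]] <- data.frame(
        tissue = g$tissue[j], timepoint = g$timepoint[j], class = cl,
        percent = if (tot > 0) 100 * mass / tot else NA_real_,
        storage_share_percent = if (cl %in% storage_classes && storage_tot > 0)
          100 * mass / storage_tot else NA_real_,
        defined = tot > 0, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Replicate and cross-tissue correlation summaries
#'
#' Two modes. `replicate_spearman`: Spearman rho of `log(TPM + 1)` between
#' every pair of replicate columns within each (tissue, timepoint) group, a
#' reproducibility check. `cross_tissue_pcc`: Pearson r of log10 group-mean
#' TPM between AL and ST at each timepoint over a gene subset, dropping
#' genes with zero mean TPM in either tissue (the log of zero is excluded
#' by design; see the methods vignette).
#'
#' @param tpm A summarized `tpm_table`.
#' @param gene_subset Genes to use (default all).
#' @param mode `"replicate_spearman"` or `"cross_tissue_pcc"`.
#' @param log_base Base for the cross-tissue log transform (default 10).
#' @return Data frame of correlations: per column pair (replicate mode) or
#'   per timepoint (cross-tissue mode) with the number of genes used.
#' @export
correlation_suite <- function(tpm, gene_subset = NULL,
                              mode = c("replicate_spearman",
                                       "cross_tissue_pcc"),
                              log_base = 10) {
  stopifnot(inherits(tpm, "tpm_table"))
  mode <- match.arg(mode)
  if (is.null(tpm$mean_tpm)) tpm <- summarize_expression(tpm)
  if (is.null(gene_subset)) gene_subset <- rownames(tpm$tpm)
  if (mode == "replicate_spearman") {
    s <- tpm$samples
    key <- paste(s$tissue, s$timepoint, sep = "_")
    out <- list()
    for (k in unique(key)) {
      cols <- which(key == k)
      if (length(cols) < 2) next
      mat <- log(tpm$tpm[gene_subset, cols, drop = FALSE] + 1)
      if (nrow(mat) < 3) stop("fewer than 3 usable genes", call. = FALSE)
      for (a in seq_along(cols)[-length(cols)]) {
        for (b in (a + 1):length(cols)) {
          out[[length(out) + 1L]] <- data.frame(
            group = k,
            sample_a = colnames(mat)[a], sample_b = colnames(mat)[b],
            rho = stats::cor(mat[, a], mat[, b], method = "spearman"),
            n_genes = nrow(mat), stringsAsFactors = FALSE)
        }
      }
    }
    res <- do.call(rbind, out)
  } else {
    g <- tpm$groups
    out <- list()
    for (tp in unique(g$timepoint)) {
      al <- tpm$mean_tpm[gene_subset, g$key[g$tissue == "AL" &
                                              g$timepoint == tp]]
      st <- tpm$mean_tpm[gene_subset, g$key[g$tissue == "ST" &
                                              g$timepoint == tp]]
      keep <- al > 0 & st > 0
      if (sum(keep) < 3) stop("fewer than 3 usable genes at ", tp, " DAP",
                              call. = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        timepoint = tp,
        pcc = stats::cor(log(al[keep], base = log_base),
                         log(st[keep], base = log_base)),
        n_genes = sum(keep), stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
  }
  rownames(res) <- NULL
  res
}
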