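#' Count-matrix container
#'
#' Light container for gene-level counts plus the metadata the pipeline
#' needs: gene lengths (bases) and a sample sheet giving tissue (AL or ST),
#' timepoint (DAP) and replicate block. Replicate blocks pair one AL with
#' one ST sample at each timepoint, the structure the paired differential
#' tests exploit.
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param gene_length Named positive numeric vector of gene lengths.
#' @param samples Data frame with columns `sample`, `tissue`, `timepoint`,
#'   `replicate_block`, one row per column of `counts`.
#' @return An object of class `"count_matrix"`.
#' @export
count_matrix <- function(counts, gene_length, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' must carry gene and sample dimnames", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  missing_len <- setdiff(rownames(counts), names(gene_length))
  if (length(missing_len)) {
    stop("missing gene length for: ", paste(utils::head(missing_len, 5),
         collapse = ", "), call. = FALSE)
  }
  if (any(gene_length <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  req <- c("sample", "tissue", "timepoint", "replicate_block")
  if (!all(req %in% names(samples))) {
    stop("sample sheet needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(sort(colnames(counts)), sort(as.character(samples$sample)))) {
    stop("sample sheet does not match count columns", call. = FALSE)
  }
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(
    list(counts = counts,
         gene_length = gene_length[rownames(counts)],
         samples = samples),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  tab <- table(x$samples$tissue, x$samples$timepoint)
  cat("samples per tissue x timepoint (DAP):\n")
  print(tab)
  invisible(x)
}

#' Subset a count matrix to one timepoint
#'
#' @param x A [count_matrix()].
#' @param timepoint Timepoint (DAP) to keep.
#' @return A `count_matrix` containing only that timepoint's samples.
#' @export
subset_timepoint <- function(x, timepoint) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- x$samples$timepoint == timepoint
  if (!any(keep)) stop("no samples at timepoint ", timepoint, call. = FALSE)
  count_matrix(x$counts[, keep, drop = FALSE], x$gene_length,
               x$samples[keep, , drop = FALSE])
}

#' Simulate paired aleurone / starchy-endosperm RNA-seq counts
#'
#' Draws negative-binomial gene counts for a paired two-tissue design with
#' planted differential expression and a storage-protein gene class whose
#' share of the ST transcriptome ramps up over development. The mean model
#' is `lib_size * p_g * 2^(s_g * log2fc_effect / 2) * 2^(block effect)`
#' where `p_g` are log-normal relative abundances renormalized per sample
#' and `s_g` is +1/-1 for AL-/ST-up DE genes (the effect is split
#' symmetrically across tissues so the planted AL/ST ratio is
#' `2^log2fc_effect`). Counts are `NB(mu, phi)` with variance
#' `mu + phi * mu^2`; `phi = 0` gives Poisson counts.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (a [count_matrix()]) and `truth`
#'   (a `sim_truth` list with `de_genes`, signed `log2fc`,
#'   `expression_class_map`, and per-sample library sizes).
#' @examples
#' sim <- simulate_rnaseq_counts(sim_config(seed = 1, n_genes = 200,
#'                                          timepoints = 18))
#' sim$counts
#' @export
simulate_rnaseq_counts <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("gene%05d", seq_len(ng))

  gene_length <- stats::setNames(
    pmax(200, round(stats::rlnorm(ng, config$length_meanlog,
                                  config$length_sdlog))), genes)

  ## heavy-tailed relative abundances shared across samples
  base_abund <- stats::rlnorm(ng, meanlog = 0, sdlog = config$abundance_sdlog)

  ## storage-protein class: prolamin / non-prolamin-storage / other
  n_storage <- round(config$storage_fraction * ng)
  storage_idx <- if (n_storage > 0) sample.int(ng, n_storage) else integer(0)
  n_prolamin <- round(config$prolamin_share * n_storage)
  class_map <- stats::setNames(rep("other", ng), genes)
  if (n_storage > 0) {
    class_map[storage_idx[seq_len(n_prolamin)]] <- "prolamin"
    if (n_storage > n_prolamin) {
      class_map[storage_idx[(n_prolamin + 1):n_storage]] <-
        "non-prolamin-storage"
    }
  }

  ## planted DE genes, random sign (positive = up in AL)
  n_de <- round(config$de_fraction * ng)
  de_idx <- if (n_de > 0) sample.int(ng, n_de) else integer(0)
  de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
  log2fc_truth <- stats::setNames(rep(0, ng), genes)
  log2fc_truth[de_idx] <- de_sign * config$log2fc_effect

  tps <- config$timepoints
  nrep <- config$n_replicates_per_tissue
  n_tp <- length(tps)

  sample_rows <- list()
  count_cols <- list()
  lib_sizes <- numeric(0)

  for (ti in seq_len(n_tp)) {
    tp <- tps[ti]
    ## storage-share ramp: ~0 at first timepoint, storage_share at the last
    ramp <- if (n_tp == 1) 1 else (ti - 1) / (n_tp - 1)
    target_share <- config$storage_share * ramp
    for (b in seq_len(nrep)) {
      block <- sprintf("t%d_b%d", tp, b)
      block_eff <- stats::rnorm(1, 0, config$block_sd)   # shared by the pair
      for (tissue in c("AL", "ST")) {
        abund <- base_abund
        ## storage boost in ST rising over development (milder in AL)
        share_target <- if (tissue == "ST") target_share else target_share / 4
        if (n_storage > 0 && share_target > 0 && share_target < 1) {
          s_mass <- sum(abund[storage_idx])
          o_mass <- sum(abund[-storage_idx])
          boost <- share_target / (1 - share_target) * o_mass / s_mass
          abund[storage_idx] <- abund[storage_idx] * boost
        }
        ## DE effect split symmetrically across tissues
        half <- config$log2fc_effect / 2
        if (n_de > 0) {
          shift <- if (tissue == "AL") de_sign * half else -de_sign * half
          abund[de_idx] <- abund[de_idx] * 2^shift
        }
        p <- abund / sum(abund)
        lib <- round(stats::runif(1, config$library_size_range[1],
                                  config$library_size_range[2]))
        mu <- lib * p * 2^block_eff
        y <- if (config$nb_dispersion == 0) {
          stats::rpois(ng, mu)
        } else {
          stats::rnbinom(ng, mu = mu, size = 1 / config$nb_dispersion)
        }
        smp <- sprintf("%s_%d DAP_rep%d", tissue, tp, b)
        count_cols[[smp]] <- y
        lib_sizes[smp] <- lib
        sample_rows[[smp]] <- data.frame(
          sample = smp, tissue = tissue, timepoint = tp,
          replicate_block = block, stringsAsFactors = FALSE)
      }
    }
  }

  counts <- do.call(cbind, count_cols)
  rownames(counts) <- genes
  samples <- do.call(rbind, sample_rows)
  rownames(samples) <- NULL

  truth <- structure(list(
    de_genes = genes[de_idx],
    log2fc = log2fc_truth[de_idx],
    expression_class_map = class_map,
    library_sizes = lib_sizes,
    nb_dispersion = config$nb_dispersion
  ), class = "sim_truth")

  list(counts = count_matrix(counts, gene_length, samples), truth = truth)
}
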