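#' Simulation configuration
#'
#' Builds and validates the single configuration object consumed by every
#' generator in the package ([simulate_rnaseq_counts()],
#' [simulate_proteomics_ip()], [simulate_go_universe()],
#' [simulate_tonoplast_profile()], [simulate_qpcr_ct()]). Defaults emulate
#' the study design the pipeline was built for: paired aleurone (AL) and
#' starchy endosperm (ST) samples at 8, 15, 18 and 22 days after pollination
#' (DAP), a storage-protein gene class that comes to dominate the late
#' starchy-endosperm transcriptome, a triplicate co-IP with a pre-immune
#' control, and fluorescence profiles with a double-membrane engulfment
#' domain.
#'
#' @param seed Integer seed; identical `(seed, config)` pairs give
#'   byte-identical generator output.
#' @param n_genes Number of genes in the RNA-seq universe.
#' @param timepoints Developmental timepoints (DAP) to simulate.
#' @param n_replicates_per_tissue Paired biological replicates per tissue
#'   and timepoint (>= 2; a replicate block holds one AL and one ST sample).
#' @param de_fraction Fraction of genes planted as differentially expressed
#'   between AL and ST.
#' @param log2fc_effect Absolute planted log2 fold change for DE genes.
#' @param nb_dispersion Negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param library_size_range Length-2 integer range library sizes are drawn
#'   from (uniformly).
#' @param abundance_sdlog sdlog of the log-normal gene relative-abundance
#'   distribution (heavy tail mimicking a storage-protein-dominated
#'   transcriptome).
#' @param block_sd SD of the additive replicate-block effect on the log
#'   mean (the pairing structure the paired tests exploit).
#' @param storage_fraction Fraction of genes in the storage-protein class.
#' @param prolamin_share Share of storage-protein genes that are prolamins.
#' @param storage_share Target share of the ST transcriptome occupied by
#'   storage-protein transcripts at the last timepoint (ramps up from near
#'   zero at the first).
#' @param length_meanlog,length_sdlog Log-normal parameters for gene
#'   lengths in bases.
#' @param n_proteins Number of proteins detected in the co-IP experiment.
#' @param tonoplast_fraction Fraction of detected proteins that are true
#'   tonoplast residents.
#' @param ip_enrichment_factor Multiplicative IP/pre-immune abundance ratio
#'   for true tonoplast proteins (> 1 means enriched).
#' @param dropout_rate Probability that any single abundance measurement is
#'   zeroed (stochastic per-replicate detection failure).
#' @param protein_universe_size Size of the protein-coding universe the
#'   tonoplast prediction list is drawn from.
#' @param prediction_sensitivity Fraction of true tonoplast proteins carried
#'   by the prediction list.
#' @param prediction_background Fraction of non-tonoplast universe members
#'   spuriously predicted.
#' @param abundance_cv Log-normal sdlog of replicate-to-replicate abundance
#'   noise in the proteomics generator.
#' @param go_terms Number of GO terms in the synthetic ontology.
#' @param go_enriched_terms Number of planted enriched terms.
#' @param membrane_enrichment_factor Per-membrane accumulation factor of the
#'   tagged protein in the engulfment domain (>= 1; 1 means evenly
#'   distributed, giving the analytic two-fold double-membrane ratio).
#' @param n_positions Number of sampled positions along a traced membrane
#'   profile.
#' @param engulfment_fraction Fraction of profile positions inside the
#'   engulfment domain (0 gives a degenerate profile with no domain).
#' @param baseline_intensity Per-membrane baseline fluorescence (arbitrary
#'   units).
#' @param noise_sd SD of additive Gaussian intensity noise (same units).
#' @param saturation_level Intensity at which the detector clips; clipped
#'   positions are flagged saturated (default 4095, a 12-bit detector).
#' @param qpcr_genes Number of target genes in the qPCR generator.
#' @param qpcr_log2_ratios Optional vector of true AL/ST log2 expression
#'   ratios (recycled/truncated to `qpcr_genes`); default spans strong ST-
#'   to strong AL-preferential genes.
#' @param ct_noise_sd SD of Ct measurement noise in cycles.
#' @param n_bio_reps,n_tech_reps qPCR biological and technical replicates.
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 500)
#' cfg$de_fraction
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       timepoints = c(8L, 15L, 18L, 22L),
                       n_replicates_per_tissue = 2L,
                       de_fraction = 0.1,
                       log2fc_effect = 2,
                       nb_dispersion = 0.1,
                       library_size_range = c(1e6, 2e6),
                       abundance_sdlog = 1.5,
                       block_sd = 0.1,
                       storage_fraction = 0.02,
                       prolamin_share = 0.8,
                       storage_share = 0.6,
                       length_meanlog = log(1500),
                       length_sdlog = 0.4,
                       n_proteins = 800L,
                       tonoplast_fraction = 0.18,
                       ip_enrichment_factor = 10,
                       dropout_rate = 0.15,
                       protein_universe_size = 20000L,
                       prediction_sensitivity = 0.9,
                       prediction_background = 0.02,
                       abundance_cv = 0.25,
                       go_terms = 50L,
                       go_enriched_terms = 3L,
                       membrane_enrichment_factor = 1,
                       n_positions = 400L,
                       engulfment_fraction = 0.25,
                       baseline_intensity = 100,
                       noise_sd = 5,
                       saturation_level = 4095,
                       qpcr_genes = 6L,
                       qpcr_log2_ratios = NULL,
                       ct_noise_sd = 0.2,
                       n_bio_reps = 3L,
                       n_tech_reps = 3L) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    timepoints = as.integer(timepoints),
    n_replicates_per_tissue = as.integer(n_replicates_per_tissue),
    de_fraction = de_fraction,
    log2fc_effect = log2fc_effect,
    nb_dispersion = nb_dispersion,
    library_size_range = as.numeric(library_size_range),
    abundance_sdlog = abundance_sdlog,
    block_sd = block_sd,
    storage_fraction = storage_fraction,
    prolamin_share = prolamin_share,
    storage_share = storage_share,
    length_meanlog = length_meanlog,
    length_sdlog = length_sdlog,
    n_proteins = as.integer(n_proteins),
    tonoplast_fraction = tonoplast_fraction,
    ip_enrichment_factor = ip_enrichment_factor,
    dropout_rate = dropout_rate,
    protein_universe_size = as.integer(protein_universe_size),
    prediction_sensitivity = prediction_sensitivity,
    prediction_background = prediction_background,
    abundance_cv = abundance_cv,
    go_terms = as.integer(go_terms),
    go_enriched_terms = as.integer(go_enriched_terms),
    membrane_enrichment_factor = membrane_enrichment_factor,
    n_positions = as.integer(n_positions),
    engulfment_fraction = engulfment_fraction,
    baseline_intensity = baseline_intensity,
    noise_sd = noise_sd,
    saturation_level = saturation_level,
    qpcr_genes = as.integer(qpcr_genes),
    qpcr_log2_ratios = qpcr_log2_ratios,
    ct_noise_sd = ct_noise_sd,
    n_bio_reps = as.integer(n_bio_reps),
    n_tech_reps = as.integer(n_tech_reps)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk_prop <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop(sprintf("'%s' must be a proportion in [0, 1]", nm), call. = FALSE)
    }
  }
  chk_count <- function(x, nm, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
      stop(sprintf("'%s' must be a count >= %d", nm, min), call. = FALSE)
    }
  }
  chk_count(cfg$n_genes, "n_genes")
  chk_count(cfg$n_replicates_per_tissue, "n_replicates_per_tissue", 2L)
  chk_count(cfg$n_proteins, "n_proteins")
  chk_count(cfg$go_terms, "go_terms")
  chk_count(cfg$n_positions, "n_positions")
  for (nm in c("de_fraction", "storage_fraction", "prolamin_share",
               "storage_share", "tonoplast_fraction", "dropout_rate",
               "prediction_sensitivity", "prediction_background",
               "engulfment_fraction")) {
    chk_prop(cfg[[nm]], nm)
  }
  if (cfg$nb_dispersion < 0) stop("'nb_dispersion' must be >= 0", call. = FALSE)
  if (cfg$noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (cfg$membrane_enrichment_factor < 1) {
    stop("'membrane_enrichment_factor' must be >= 1", call. = FALSE)
  }
  if (cfg$ip_enrichment_factor <= 0) {
    stop("'ip_enrichment_factor' must be > 0", call. = FALSE)
  }
  if (length(cfg$library_size_range) != 2L ||
      any(cfg$library_size_range <= 0) ||
      diff(cfg$library_size_range) < 0) {
    stop("'library_size_range' must be a non-decreasing positive interval",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  cat("  RNA-seq : ", x$n_genes, " genes, timepoints ",
      paste(x$timepoints, collapse = "/"), " DAP, ",
      x$n_replicates_per_tissue, " paired replicates, phi = ",
      x$nb_dispersion, ", DE fraction ", x$de_fraction,
      " at |log2FC| = ", x$log2fc_effect, "\n", sep = "")
  cat("  Co-IP   : ", x$n_proteins, " proteins, tonoplast fraction ",
      x$tonoplast_fraction, ", IP enrichment x", x$ip_enrichment_factor,
      ", dropout ", x$dropout_rate, "\n", sep = "")
  cat("  GO      : ", x$go_terms, " terms, ", x$go_enriched_terms,
      " planted enriched\n", sep = "")
  cat("  Imaging : per-membrane factor ", x$membrane_enrichment_factor,
      ", noise sd ", x$noise_sd, "\n", sep = "")
  invisible(x)
}
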