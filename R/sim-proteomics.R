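#' Simulate co-IP proteomics abundances with a pre-immune control
#'
#' Generates per-protein label-free abundances across three biological
#' replicates of an immunoprecipitation (IP) against a tonoplast marker and
#' the matched pre-immune serum control. A planted subset of true tonoplast
#' proteins carries IP abundance approximately `ip_enrichment_factor` times
#' the pre-immune baseline; non-targets have IP ~ pre-immune. Every single
#' abundance is independently zeroed with probability `dropout_rate`,
#' emulating stochastic per-replicate detection failure. A tonoplast
#' prediction list over a larger protein-coding universe is emitted
#' alongside (true targets carried with `prediction_sensitivity`, plus a
#' `prediction_background` fraction of spurious universe members), so the
#' Fisher enrichment stage has a realistic input.
#'
#' @param config A [sim_config()].
#' @return A list with `abundances` (long data frame: `protein`,
#'   `replicate`, `assay` in ip/preimmune, `abundance`), `predicted`
#'   (character vector of predicted tonoplast ids over the universe),
#'   `universe_size`, and `truth` (with `tonoplast_proteins`).
#' @examples
#' sim <- simulate_proteomics_ip(sim_config(seed = 1, n_proteins = 50))
#' head(sim$abundances)
#' @export
simulate_proteomics_ip <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  np <- config$n_proteins
  universe <- sprintf("prot%05d", seq_len(config$protein_universe_size))
  ## detected proteins are the first np universe members after shuffling
  detected <- sample(universe, np)
  n_t <- round(config$tonoplast_fraction * np)
  tono <- detected[seq_len(n_t)]

  baseline <- stats::rlnorm(np, meanlog = log(20), sdlog = 1)
  is_tono <- detected %in% tono
  rows <- vector("list", 6L)
  i <- 0L
  for (r in 1:3) {
    for (assay in c("ip", "preimmune")) {
      mu <- baseline * ifelse(is_tono & assay == "ip",
                              config$ip_enrichment_factor, 1)
      ab <- mu * stats::rlnorm(np, 0, config$abundance_cv)
      if (config$dropout_rate > 0) {
        ab[stats::runif(np) < config$dropout_rate] <- 0
      }
      i <- i + 1L
      rows[[i]] <- data.frame(protein = detected, replicate = r,
                              assay = assay, abundance = ab,
                              stringsAsFactors = FALSE)
    }
  }
  abundances <- do.call(rbind, rows)
  rownames(abundances) <- NULL

  ## prediction list over the universe
  pred_true <- tono[stats::runif(n_t) < config$prediction_sensitivity]
  non_tono <- setdiff(universe, tono)
  pred_bg <- non_tono[stats::runif(length(non_tono)) <
                        config$prediction_background]
  predicted <- sort(unique(c(pred_true, pred_bg)))

  truth <- structure(list(tonoplast_proteins = tono,
                          detected_proteins = detected,
                          ip_enrichment_factor = config$ip_enrichment_factor),
                     class = "sim_truth")
  list(abundances = abundances, predicted = predicted,
       universe_size = config$protein_universe_size, truth = truth)
}
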