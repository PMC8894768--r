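#' Candidate-prioritization funnel
#'
#' Applies the evidence filters in order: all detected co-IP proteins ->
#' high/medium confidence tier -> aleurone-preferential expression
#' (`CS(AL) > cs_threshold`) -> optional annotation-category filter from a
#' supplied category map (standing in for manual curation of functional
#' annotations). Stage counts are non-increasing by construction; every
#' surviving candidate carries its upstream evidence fields.
#'
#' @param tiers Output of [classify_confidence_tier()].
#' @param cs CS-score table from [cs_score()] keyed by protein/gene id
#'   (column `gene`); proteins without a defined score fail the CS stage.
#' @param cs_threshold CS(AL) threshold (default 0.5).
#' @param category_map Optional named character vector id -> category;
#'   candidates must map to a category in `keep_categories`.
#' @param keep_categories Categories retained by the annotation filter.
#' @param deg Optional `deg_table` whose `deg` flag is carried along as
#'   evidence (not a filter).
#' @return List with `candidates` (data frame of survivors with tier, CS,
#'   fold differences, DEG status) and `funnel` (data frame `stage`, `n`).
#' @export
run_candidate_funnel <- function(tiers, cs, cs_threshold = 0.5,
                                 category_map = NULL,
                                 keep_categories = NULL, deg = NULL) {
  stopifnot(is.data.frame(tiers))
  if (!"tier" %in% names(tiers)) {
    stop("missing upstream output: confidence tiers (run the co-IP stage)",
         call. = FALSE)
  }
  ev <- tiers
  ev$cs_al <- rep(NA_real_, nrow(ev))
  ev$cs_defined <- rep(FALSE, nrow(ev))
  if (nrow(ev)) {
    i <- match(ev$protein, cs$gene)
    hit <- !is.na(i)
    ev$cs_al[hit] <- cs$cs_al[i[hit]]
    ev$cs_defined[hit] <- cs$defined[i[hit]]
  }
  if (!is.null(deg)) {
    ev$deg <- rep(FALSE, nrow(ev))
    i <- match(ev$protein, deg$gene)
    ev$deg[!is.na(i)] <- deg$deg[i[!is.na(i)]]
  }
  funnel <- data.frame(stage = "detected", n = nrow(ev),
                       stringsAsFactors = FALSE)
  ev <- ev[!is.na(ev$tier) & ev$tier %in% c("high", "medium"), ,
           drop = FALSE]
  funnel <- rbind(funnel, data.frame(stage = "high_medium_tier",
                                     n = nrow(ev)))
  ev <- ev[ev$cs_defined & !is.na(ev$cs_al) & ev$cs_al > cs_threshold, ,
           drop = FALSE]
  funnel <- rbind(funnel, data.frame(stage = "cs_al_preferential",
                                     n = nrow(ev)))
  if (!is.null(category_map)) {
    ev$category <- unname(category_map[ev$protein])
    keep <- !is.na(ev$category)
    if (!is.null(keep_categories)) {
      keep <- keep & ev$category %in% keep_categories
    }
    ev <- ev[keep, , drop = FALSE]
    funnel <- rbind(funnel, data.frame(stage = "annotation_category",
                                       n = nrow(ev)))
  }
  rownames(ev) <- NULL
  list(candidates = ev, funnel = funnel)
}

#' Run the full synthetic pipeline end to end
#'
#' simulate -> expression -> differential expression -> co-IP tiers ->
#' GO enrichment -> candidate funnel, all from one seed, writing every
#' stage output plus a machine-readable run manifest (seed, thresholds,
#' package version, per-stage row counts) into `out_dir`. Identical seed
#' and config give byte-identical outputs.
#'
#' Note the two omic layers are simulated independently: protein ids do
#' not map onto gene ids, so the funnel's CS stage uses CS scores computed
#' from a protein-level expression surrogate drawn by the proteomics
#' generator. For matched-id analyses supply your own tables to
#' [run_candidate_funnel()].
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created).
#' @param alpha,min_fold,cs_threshold Pipeline thresholds.
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config, out_dir, alpha = 0.05, min_fold = 2,
                    cs_threshold = 0.5) {
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) message(sprintf(...))

  ## --- simulate ---------------------------------------------------------
  rna <- simulate_rnaseq_counts(config)
  write_rnaseq_dataset(rna, file.path(out_dir, "rnaseq"))
  prot <- simulate_proteomics_ip(config)
  write_proteomics_dataset(prot, file.path(out_dir, "proteomics"))
  go <- simulate_go_universe(config)
  write_go_dataset(go, file.path(out_dir, "go"))
  prof <- simulate_tonoplast_profile(config)
  write_profile_dataset(prof, file.path(out_dir, "imaging"))
  qp <- simulate_qpcr_ct(config)
  write_qpcr_dataset(qp, file.path(out_dir, "qpcr"))
  log_line("simulate: %d genes, %d proteins, %d GO terms",
           config$n_genes, config$n_proteins, config$go_terms)

  ## --- expression -------------------------------------------------------
  tpm <- summarize_expression(compute_tpm(rna$counts))
  cs <- cs_score(tpm)
  fractions <- class_fraction(tpm, rna$truth$expression_class_map)
  write_tsv(data.frame(gene = rownames(tpm$mean_tpm), tpm$mean_tpm,
                       check.names = FALSE),
            file.path(out_dir, "mean_tpm.tsv"))
  write_tsv(cs, file.path(out_dir, "cs_scores.tsv"))
  write_tsv(fractions, file.path(out_dir, "class_fractions.tsv"))
  log_line("expression: %d genes in, %d expressed anywhere",
           nrow(tpm$tpm), sum(rowSums(tpm$expressed) > 0))

  ## --- differential expression per timepoint ---------------------------
  deg_list <- list()
  for (tp in unique(rna$counts$samples$timepoint)) {
    d <- run_deg_timepoint(rna$counts, tp, tpm = tpm, alpha = alpha,
                           min_fold = min_fold)
    deg_list[[as.character(tp)]] <- d
    write_tsv(as.data.frame(d), file.path(out_dir,
                                          sprintf("deg_%sDAP.tsv", tp)))
    log_line("deg %s DAP: %d in, %d consensus, %d final",
             tp, nrow(d), sum(d$consensus), sum(d$deg))
  }
  overlap <- deg_overlap_summary(deg_list)
  write_tsv(overlap, file.path(out_dir, "deg_overlap.tsv"))

  ## --- co-IP ------------------------------------------------------------
  rec <- classify_confidence_tier(
    replicate_fold_differences(protein_ip_records(prot$abundances)))
  write_tsv(rec, file.path(out_dir, "coip_tiers.tsv"))
  enr <- fisher_enrichment(detected = rec$protein,
                           predicted = prot$predicted,
                           universe_size = prot$universe_size)
  jsonlite::write_json(
    list(table = as.vector(enr$table), odds_ratio = enr$odds_ratio,
         odds_ratio_cmle = enr$odds_ratio_cmle, p = enr$p),
    file.path(out_dir, "coip_enrichment.json"),
    auto_unbox = TRUE, digits = NA)
  log_line("coip: %d proteins in, tiers %s",
           nrow(rec), paste(table(rec$tier), collapse = "/"))

  ## --- GO enrichment ----------------------------------------------------
  dag <- propagate_true_path(go_dag(go$annotations, go$edges))
  go_res <- term_enrichment(dag, go$study, mode = "weight01")
  write_tsv(go_res, file.path(out_dir, "go_enrichment.tsv"))
  log_line("goenrich: %d terms, %d at FDR<=0.05",
           nrow(go_res), sum(go_res$fdr <= 0.05))

  ## --- imaging / qpcr summaries ----------------------------------------
  ratio <- domain_fold_enrichment(prof$profile)
  write_tsv(data.frame(ratio = ratio, expected = prof$truth$expected_ratio),
            file.path(out_dir, "imaging_ratio.tsv"))
  qres <- qpcr_fold_table(qp$ct, qp$reference)
  write_tsv(qres, file.path(out_dir, "qpcr_folds.tsv"))

  ## --- funnel -----------------------------------------------------------
  ## protein-level AL-preference surrogate: true tonoplast proteins are
  ## planted aleurone-preferential (CS(AL) drawn above the threshold)
  cs_prot <- protein_cs_surrogate(prot, config)
  fun <- run_candidate_funnel(rec, cs_prot, cs_threshold = cs_threshold)
  write_tsv(fun$funnel, file.path(out_dir, "funnel.tsv"))
  write_tsv(fun$candidates, file.path(out_dir, "candidates.tsv"))
  log_line("funnel: %s",
           paste(sprintf("%s=%d", fun$funnel$stage, fun$funnel$n),
                 collapse = " -> "))

  manifest <- list(
    package = "tonosieve",
    version = as.character(utils::packageVersion("tonosieve")),
    seed = config$seed,
    thresholds = list(alpha = alpha, min_fold = min_fold,
                      cs_threshold = cs_threshold),
    stages = list(genes = config$n_genes, proteins = nrow(rec),
                  go_terms = nrow(go_res),
                  funnel = as.list(stats::setNames(fun$funnel$n,
                                                   fun$funnel$stage))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(rna = rna, tpm = tpm, cs = cs, deg = deg_list,
                 coip = rec, enrichment = enr, go = go_res,
                 imaging_ratio = ratio, qpcr = qres, funnel = fun,
                 manifest = manifest))
}

## deterministic protein-level CS surrogate: true tonoplast proteins get
## CS(AL) centred at 0.8, others at 0.5 (matching the planted study
## conditions the funnel recovery tests assume)
protein_cs_surrogate <- function(prot, config) {
  set.seed(config$seed + 6L)
  det <- unique(prot$abundances$protein)
  is_t <- det %in% prot$truth$tonoplast_proteins
  cs_al <- pmin(pmax(stats::rnorm(length(det),
                                  ifelse(is_t, 0.8, 0.5), 0.08), 0), 1)
  data.frame(gene = det, cs_st = 1 - cs_al, cs_al = cs_al,
             defined = TRUE, stringsAsFactors = FALSE)
}
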