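test_that("generators are deterministic given seed and config", {
  cfg <- sim_config(seed = 9, n_genes = 120, n_proteins = 40,
                    go_terms = 12, timepoints = c(18, 22))
  expect_identical(simulate_rnaseq_counts(cfg),
                   simulate_rnaseq_counts(cfg))
  expect_identical(simulate_proteomics_ip(cfg),
                   simulate_proteomics_ip(cfg))
  expect_identical(simulate_go_universe(cfg), simulate_go_universe(cfg))
  expect_identical(simulate_tonoplast_profile(cfg),
                   simulate_tonoplast_profile(cfg))
  expect_identical(simulate_qpcr_ct(cfg), simulate_qpcr_ct(cfg))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(de_fraction = 1.2), "proportion")
  expect_error(sim_config(n_replicates_per_tissue = 1), "count")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(sim_config(membrane_enrichment_factor = 0.5),
               "membrane_enrichment_factor")
  expect_error(sim_config(library_size_range = c(2e6, 1e6)),
               "library_size_range")
})

test_that("zero dispersion gives Poisson counts (variance equals mean)", {
  cfg <- sim_config(seed = 2, n_genes = 1000, de_fraction = 0,
                    storage_share = 0, nb_dispersion = 0, block_sd = 0,
                    n_replicates_per_tissue = 20, timepoints = 18,
                    library_size_range = c(1e6, 1e6))
  sim <- simulate_rnaseq_counts(cfg)
  al <- sim$counts$counts[, sim$counts$samples$tissue == "AL"]
  m <- rowMeans(al)
  v <- apply(al, 1, stats::var)
  keep <- m > 1
  pooled <- sum(v[keep]) / sum(m[keep])
  expect_lt(abs(pooled - 1), 0.1)
})

test_that("generated dispersion matches nb_dispersion by method of moments", {
  cfg <- sim_config(seed = 4, n_genes = 5000, de_fraction = 0,
                    storage_share = 0, nb_dispersion = 0.1, block_sd = 0,
                    n_replicates_per_tissue = 6, timepoints = 18,
                    library_size_range = c(1e6, 1e6))
  sim <- simulate_rnaseq_counts(cfg)
  al <- sim$counts$counts[, sim$counts$samples$tissue == "AL"]
  m <- rowMeans(al)
  v <- apply(al, 1, stats::var)
  keep <- m > 5
  phi <- sum(v[keep] - m[keep]) / sum(m[keep]^2)
  expect_lt(abs(phi - 0.1) / 0.1, 0.2)
})

test_that("planted DE genes show the configured AL/ST mean-count ratio", {
  cfg <- sim_config(seed = 3, n_genes = 2000, de_fraction = 0.1,
                    log2fc_effect = 2, storage_share = 0, block_sd = 0,
                    nb_dispersion = 0.1, n_replicates_per_tissue = 12,
                    timepoints = 18, library_size_range = c(1e6, 1e6))
  sim <- simulate_rnaseq_counts(cfg)
  tr <- sim$truth
  al <- sim$counts$samples$tissue == "AL"
  rs_al <- rowSums(sim$counts$counts[tr$de_genes, al])
  rs_st <- rowSums(sim$counts$counts[tr$de_genes, !al])
  up <- tr$log2fc > 0
  expect_lt(abs(stats::median((rs_al / rs_st)[up]) - 4), 0.5)
  expect_lt(abs(stats::median((rs_st / rs_al)[!up]) - 4), 0.5)
})

test_that("truth identifiers live in the generated universes", {
  cfg <- sim_config(seed = 13, n_genes = 150, n_proteins = 60,
                    go_terms = 15, timepoints = 18)
  rna <- simulate_rnaseq_counts(cfg)
  expect_true(all(rna$truth$de_genes %in% rownames(rna$counts$counts)))
  prot <- simulate_proteomics_ip(cfg)
  expect_true(all(prot$truth$tonoplast_proteins %in%
                    prot$abundances$protein))
  go <- simulate_go_universe(cfg)
  all_terms <- unique(c(go$annotations$term, go$edges$child,
                        go$edges$parent))
  expect_true(all(go$truth$enriched_terms %in% all_terms))
  expect_true(all(go$study %in% go$annotations$gene))
})

test_that("proteomics targets clear the tier threshold without dropout", {
  ## (10b + 1) / (b + 1) >= 2 iff b >= 1/8, far below the baseline scale
  cfg <- sim_config(seed = 5, n_proteins = 200, dropout_rate = 0,
                    ip_enrichment_factor = 10)
  sim <- simulate_proteomics_ip(cfg)
  rec <- replicate_fold_differences(protein_ip_records(sim$abundances))
  fd <- as.matrix(rec[match(sim$truth$tonoplast_proteins, rec$protein),
                      c("fd_1", "fd_2", "fd_3")])
  expect_true(all(fd >= 2))
})

test_that("a null IP (enrichment factor 1) yields few high-tier proteins", {
  cfg <- sim_config(seed = 6, n_proteins = 300, ip_enrichment_factor = 1,
                    dropout_rate = 0.1)
  sim <- simulate_proteomics_ip(cfg)
  rec <- classify_confidence_tier(
    replicate_fold_differences(protein_ip_records(sim$abundances)))
  expect_lt(mean(rec$tier == "high"), 0.1)
})

test_that("generated ontologies are acyclic across many seeds", {
  for (s in 1:100) {
    cfg <- sim_config(seed = s, n_genes = 40, go_terms = 20)
    go <- simulate_go_universe(cfg)
    expect_true(is_acyclic_edges(go$edges))
  }
})

test_that("noise-free profiles encode the double-membrane geometry", {
  p1 <- simulate_tonoplast_profile(
    sim_config(seed = 1, membrane_enrichment_factor = 1, noise_sd = 0))
  expect_equal(domain_fold_enrichment(p1$profile), 2)
  p3 <- simulate_tonoplast_profile(
    sim_config(seed = 1, membrane_enrichment_factor = 3, noise_sd = 0))
  expect_equal(domain_fold_enrichment(p3$profile), 6)
  ## degenerate geometry: no engulfment domain -> undefined ratio
  flat <- simulate_tonoplast_profile(
    sim_config(seed = 1, engulfment_fraction = 0, noise_sd = 0))
  expect_error(domain_fold_enrichment(flat$profile), "engulfment")
})

test_that("noise-free Ct tables invert to the planted fold changes", {
  sim <- simulate_qpcr_ct(sim_config(seed = 8, ct_noise_sd = 0,
                                     qpcr_log2_ratios = c(2, 0)))
  res <- qpcr_fold_table(sim$ct, sim$reference)
  expect_equal(res$mean_fold[res$gene == "target01"], 4)
  expect_equal(res$mean_fold[res$gene == "target02"], 1)
})

test_that("dataset writers round-trip through plain-text files", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 10, n_genes = 50, timepoints = c(18, 22))
  sim <- simulate_rnaseq_counts(cfg)
  write_rnaseq_dataset(sim, dir)
  back <- read_rnaseq_dataset(dir)
  expect_equal(unname(back$counts), unname(sim$counts$counts))
  expect_equal(back$samples$tissue, sim$counts$samples$tissue)
  prof <- simulate_tonoplast_profile(cfg)
  write_profile_dataset(prof, dir)
  prof2 <- read_profile(file.path(dir, "profile.csv"))
  expect_equal(prof2$intensity, prof$profile$intensity, tolerance = 1e-6)
  expect_identical(prof2$domain, prof$profile$domain)
})
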