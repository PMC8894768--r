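test_that("TMM factors are trivial without composition bias", {
  cm <- matrix(rep(c(10L, 200L, 35L, 1000L), 2), 4, 2,
               dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  f <- tmm_factors(cm)
  expect_equal(f$factor, c(1, 1))
  ## pure depth difference: all M-values zero
  cm2 <- cbind(s1 = c(10L, 200L, 35L, 1000L),
               s2 = 2L * c(10L, 200L, 35L, 1000L))
  rownames(cm2) <- paste0("g", 1:4)
  expect_equal(tmm_factors(cm2)$factor, c(1, 1))
  expect_error(tmm_factors(cbind(s1 = c(1L, 1L), s2 = c(0L, 0L))),
               "all-zero")
})

test_that("TMM factors match the brute-force trimmed weighted mean", {
  fx <- matrix(c(1000L, 10L, 20L, 30L, 100L, 12L, 22L, 28L), 4, 2,
               dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  expect_equal(tmm_factors(fx)$factor, brute_force_tmm(fx),
               tolerance = 1e-10)
  set.seed(31)
  for (i in 1:5) {
    n <- sample(c(40, 120), 1)
    cm <- matrix(stats::rnbinom(n * 3, mu = stats::rexp(n, 1 / 300),
                                size = 2), n, 3)
    cm <- cm[rowSums(cm) > 0, , drop = FALSE]
    dimnames(cm) <- list(paste0("g", seq_len(nrow(cm))),
                         paste0("s", 1:3))
    expect_equal(tmm_factors(cm)$factor, brute_force_tmm(cm),
                 tolerance = 1e-10)
  }
})

test_that("dispersion estimation hits the Poisson limit and boundaries", {
  sim <- make_paired_counts(41, n_genes = 2000, blocks = 4,
                            nb_dispersion = 0, de_fraction = 0,
                            storage_share = 0)
  sub <- subset_timepoint(sim$counts, 18)
  des <- design_spec(sub$samples)
  disp <- estimate_dispersion(sub, des)
  expect_lt(disp$common, 0.01)
  ## constant gene: tagwise finite and non-negative
  cm <- sub$counts
  cm[1, ] <- 100L
  disp2 <- estimate_dispersion(cm, des$design)
  expect_true(is.finite(disp2$tagwise[1]) && disp2$tagwise[1] >= 0)
  ## zero residual df
  one_block <- sub$samples[sub$samples$replicate_block ==
                             sub$samples$replicate_block[1], ]
  des1 <- design_spec(one_block)
  expect_error(
    estimate_dispersion(sub$counts[, one_block$sample], des1$design),
    "residual")
})

test_that("NB GLM log2FC equals the closed-form two-group ratio", {
  ## equal offsets (unit factors, equal library sizes): the NB MLE of a
  ## group mean is the arithmetic mean, so the coefficient is the log2
  ## ratio of group means (counts large enough that the reporting
  ## prior count is negligible)
  g1 <- 100L * c(10L, 20L, 30L, 40L, 50L, 60L)
  cm <- rbind(g1 = g1, g2 = 100000L - g1)
  colnames(cm) <- paste0("s", 1:6)
  grp <- factor(rep(c("A", "B"), each = 3))
  dm <- stats::model.matrix(~grp)
  fac <- data.frame(sample = colnames(cm), factor = 1,
                    lib_size = colSums(cm),
                    effective_lib_size = colSums(cm))
  res <- nb_glm_lrt(cm, dm, dispersion = 0.1, factors = fac)
  expect_equal(res$log2fc[1], log2(mean(g1[4:6]) / mean(g1[1:3])),
               tolerance = 1e-3)
  ## a gene with identical values in every sample carries no signal
  cm2 <- rbind(flat = rep(5000L, 6), g2 = 100000L - rep(5000L, 6))
  colnames(cm2) <- paste0("s", 1:6)
  res2 <- nb_glm_lrt(cm2, dm, dispersion = 0.1, factors = fac)
  expect_lt(res2$lr_stat[1], 1e-6)
  expect_gt(res2$p_nb[1], 0.999)
})

test_that("swapping tissue labels negates fold changes, keeps p-values", {
  sim <- make_paired_counts(5, n_genes = 300, blocks = 2)
  sub <- subset_timepoint(sim$counts, 18)
  des <- design_spec(sub$samples)
  sw <- sub$samples
  sw$tissue <- ifelse(sw$tissue == "AL", "ST", "AL")
  cm_sw <- count_matrix(sub$counts, sub$gene_length, sw)
  fac <- tmm_factors(sub)
  nb1 <- nb_glm_lrt(sub, des, estimate_dispersion(sub, des, fac), fac)
  des_sw <- design_spec(sw)
  nb2 <- nb_glm_lrt(cm_sw, des_sw,
                    estimate_dispersion(cm_sw, des_sw, fac), fac)
  expect_equal(nb1$log2fc, -nb2$log2fc, tolerance = 1e-6)
  expect_equal(nb1$p_nb, nb2$p_nb, tolerance = 1e-4)
})

test_that("log-CPM transform matches its formula and scale invariance", {
  set.seed(7)
  cm <- matrix(stats::rnbinom(200 * 6, mu = 400, size = 5), 200, 6,
               dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6)))
  dm <- stats::model.matrix(~ rep(c("A", "B"), each = 3))
  fac <- tmm_factors(cm)
  v <- voom_transform(cm, dm, fac)
  manual <- log2(sweep(cm + 0.5, 2, fac$effective_lib_size + 1, "/") * 1e6)
  expect_equal(unname(v$logcpm), unname(manual), tolerance = 1e-10)
  ## zero count at effective library size 1e6 - 1 -> exactly -1
  cm0 <- cm
  cm0[1, ] <- 0L
  extra <- (1e6 - 1) - colSums(cm0)
  cm0[2, ] <- cm0[2, ] + as.integer(extra)
  fac0 <- data.frame(sample = colnames(cm0), factor = 1,
                     lib_size = colSums(cm0),
                     effective_lib_size = colSums(cm0))
  v0 <- voom_transform(cm0, dm, fac0)
  expect_equal(unname(v0$logcpm[1, ]), rep(-1, 6))
  ## doubling counts and library sizes barely moves log-CPM (pseudocount)
  fac2 <- fac
  fac2$lib_size <- 2 * fac$lib_size
  fac2$effective_lib_size <- 2 * fac$effective_lib_size
  v2 <- voom_transform(2L * cm, dm, fac2)
  big <- cm >= 100
  expect_lt(max(abs(v2$logcpm[big] - v$logcpm[big])), 1e-2)
  ## homoscedastic data -> approximately constant weights
  expect_lt(stats::sd(v$weights) / mean(v$weights), 0.2)
})

test_that("moderated variance obeys the shrinkage formula", {
  ## heteroscedastic genes so the prior df is finite and shrinkage real
  set.seed(55)
  n <- 120
  sds <- stats::rlnorm(n, 0, 0.8)
  y <- matrix(stats::rnorm(n * 6, sd = rep(sds, 6)), n, 6,
              dimnames = list(sprintf("g%03d", 1:n), paste0("s", 1:6)))
  dm <- stats::model.matrix(~ rep(c("A", "B"), each = 3))
  lm <- moderated_t_test(list(logcpm = y,
                              weights = matrix(1, n, 6)), dm)
  d0 <- attr(lm, "df_prior")
  s02 <- attr(lm, "s2_prior")
  s2 <- attr(lm, "sigma")^2
  d <- attr(lm, "df_residual")
  expect_true(is.finite(d0) && d0 > 0)
  expect_equal(lm$s2_post, (d0 * s02 + d * s2) / (d0 + d),
               tolerance = 1e-10)
  ## posterior variance sits between the gene variance and the prior
  expect_true(all(lm$s2_post >= pmin(s2, s02) - 1e-12 &
                    lm$s2_post <= pmax(s2, s02) + 1e-12))
  ## full-shrinkage limit: identical variances drive the prior df to
  ## infinity and every posterior variance to the prior
  y2 <- matrix(stats::rnorm(n * 6), n, 6,
               dimnames = dimnames(y))
  lm2 <- moderated_t_test(list(logcpm = y2,
                               weights = matrix(1, n, 6)), dm)
  if (is.infinite(attr(lm2, "df_prior"))) {
    expect_equal(lm2$s2_post,
                 rep(attr(lm2, "s2_prior"), n))
  }
})

test_that("BH adjustment matches the hand step-up and handles edge cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.05)), c(0.03, 0.03, 0.05))
  expect_equal(bh_adjust(1), 1)
  ## ties get equal FDRs
  expect_equal(bh_adjust(c(0.02, 0.02, 0.5))[1],
               bh_adjust(c(0.02, 0.02, 0.5))[2])
  ## NA passthrough and validation
  expect_equal(is.na(bh_adjust(c(0.1, NA))), c(FALSE, TRUE))
  expect_error(bh_adjust(c(-0.1, 0.5)), "0, 1")
  expect_error(bh_adjust(0.5, pi0 = 0), "pi0")
  ## optional Storey scaling reduces to BH at pi0 = 1
  p <- c(0.001, 0.2, 0.8)
  expect_equal(bh_adjust(p, pi0 = 0.5), pmin(bh_adjust(p) * 0.5, 1))
  ## brute-force equivalence on random vectors
  set.seed(99)
  for (i in 1:50) {
    p <- stats::runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), brute_force_bh(p))
  }
})

test_that("consensus calls intersect the paths and apply elimination", {
  nb <- data.frame(gene = c("g1", "g2", "g3"),
                   log2fc = c(3, 3, 3), lr_stat = 1,
                   p_nb = c(1e-6, 1e-6, 0.9), dispersion = 0.1)
  lm <- data.frame(gene = c("g1", "g2", "g3"),
                   log2fc = c(3, 3, 3), t = 1,
                   p_lm = c(1e-6, 0.9, 1e-6), s2_post = 1)
  res <- call_consensus_degs(nb, lm)
  expect_equal(res$consensus, c(TRUE, FALSE, FALSE))
  ## sign disagreement breaks consensus
  lm2 <- lm
  lm2$log2fc <- c(-3, 3, 3)
  expect_false(call_consensus_degs(nb, lm2)$consensus[1])
  ## sub-threshold fold change breaks consensus
  nb2 <- nb
  nb2$log2fc <- c(0.5, 3, 3)
  expect_false(call_consensus_degs(nb2, lm)$consensus[1])
  ## gene set mismatch errors
  expect_error(call_consensus_degs(nb, lm[-1, ]), "gene sets|different")
})

test_that("zero-TPM elimination removes consensus calls, flag preserved", {
  counts <- matrix(c(9L, 5L, 0L, 6L), 2, 2,
                   dimnames = list(c("g1", "g2"), c("a1", "s1")))
  sheet <- data.frame(sample = c("a1", "s1"), tissue = c("AL", "ST"),
                      timepoint = 18, replicate_block = "b1")
  tpm <- summarize_expression(compute_tpm(
    count_matrix(counts, c(g1 = 1000, g2 = 1000), sheet)))
  nb <- data.frame(gene = c("g1", "g2"), log2fc = 3, lr_stat = 1,
                   p_nb = 1e-6, dispersion = 0.1)
  lm <- data.frame(gene = c("g1", "g2"), log2fc = 3, t = 1,
                   p_lm = 1e-6, s2_post = 1)
  res <- call_consensus_degs(nb, lm, tpm = tpm, timepoint = 18)
  ## g1 has zero mean TPM in ST: eliminated despite consensus
  expect_true(res$consensus[res$gene == "g1"])
  expect_true(res$eliminated_zero_tpm[res$gene == "g1"])
  expect_false(res$deg[res$gene == "g1"])
  expect_true(res$deg[res$gene == "g2"])
})

test_that("final consensus set is contained in each path's calls", {
  sim <- make_paired_counts(23, n_genes = 600, blocks = 3,
                            de_fraction = 0.15, storage_share = 0)
  tpm <- summarize_expression(compute_tpm(sim$counts))
  d <- run_deg_timepoint(sim$counts, 18, tpm = tpm)
  expect_true(all(d$fdr_nb[d$deg] <= 0.05))
  expect_true(all(d$fdr_lm[d$deg] <= 0.05))
  expect_true(all(abs(d$log2fc_nb[d$deg]) > 1))
  expect_true(all(abs(d$log2fc_lm[d$deg]) > 1))
  ## overlap summary counts are consistent
  ov <- deg_overlap_summary(list(`18` = d, also = d))
  expect_equal(ov$n_deg[3], sum(d$deg))
})
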