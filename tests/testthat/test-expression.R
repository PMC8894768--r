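## builds a summarized tpm_table directly from per-(tissue, timepoint)
## group-mean matrices, for tests that exercise downstream formulas
make_summary_tpm <- function(al, st, timepoints = c(8, 15, 18, 22)) {
  stopifnot(ncol(al) == length(timepoints))
  genes <- rownames(al)
  groups <- data.frame(
    key = c(paste0("AL_", timepoints), paste0("ST_", timepoints)),
    tissue = rep(c("AL", "ST"), each = length(timepoints)),
    timepoint = rep(timepoints, 2), stringsAsFactors = FALSE)
  mean_tpm <- cbind(al, st)
  colnames(mean_tpm) <- groups$key
  structure(list(tpm = mean_tpm, samples = NULL, mean_tpm = mean_tpm,
                 expressed = mean_tpm > 0, groups = groups),
            class = "tpm_table")
}

test_that("TPM follows the length-normalized per-million formula", {
  counts <- matrix(c(10L, 20L), 2, 1,
                   dimnames = list(c("gA", "gB"), "s1"))
  cm <- count_matrix(counts, c(gA = 1000, gB = 2000),
                     data.frame(sample = "s1", tissue = "AL",
                                timepoint = 18, replicate_block = "b1"))
  tpm <- compute_tpm(cm)
  expect_equal(unname(tpm$tpm[, 1]), c(5e5, 5e5))

  ## a single expressed gene takes the whole million
  counts2 <- matrix(c(7L, 0L), 2, 1,
                    dimnames = list(c("gA", "gB"), "s1"))
  cm2 <- count_matrix(counts2, c(gA = 1000, gB = 2000), cm$samples)
  expect_equal(unname(compute_tpm(cm2)$tpm[, 1]), c(1e6, 0))
})

test_that("TPM columns always sum to one million", {
  sim <- simulate_rnaseq_counts(sim_config(seed = 21, n_genes = 300,
                                           timepoints = c(18, 22)))
  tpm <- compute_tpm(sim$counts)
  expect_equal(unname(colSums(tpm$tpm)), rep(1e6, ncol(tpm$tpm)),
               tolerance = 1e-9)
})

test_that("container validation catches bad counts and lengths", {
  counts <- matrix(1L, 2, 1, dimnames = list(c("gA", "gB"), "s1"))
  sheet <- data.frame(sample = "s1", tissue = "AL", timepoint = 18,
                      replicate_block = "b1")
  expect_error(count_matrix(counts, c(gA = 1000), sheet), "gB")
  expect_error(count_matrix(matrix(-1L, 2, 1,
                                   dimnames = dimnames(counts)),
                            c(gA = 1000, gB = 1000), sheet),
               "non-negative")
  ## an all-zero sample yields an all-zero TPM column with a warning
  cm <- count_matrix(matrix(0L, 2, 1, dimnames = dimnames(counts)),
                     c(gA = 1000, gB = 1000), sheet)
  expect_warning(tpm <- compute_tpm(cm), "all-zero")
  expect_equal(unname(tpm$tpm[, 1]), c(0, 0))
})

test_that("expressed rule requires every replicate to be positive", {
  ## 3 replicates, one tissue/timepoint; gene TPM zero iff count zero
  counts <- matrix(c(1L, 1L,   0L, 1L,   2L, 1L), 2, 3,
                   dimnames = list(c("gA", "gB"),
                                   c("s1", "s2", "s3")))
  sheet <- data.frame(sample = c("s1", "s2", "s3"), tissue = "AL",
                      timepoint = 18,
                      replicate_block = c("b1", "b2", "b3"))
  cm <- count_matrix(counts, c(gA = 1000, gB = 1000), sheet)
  tpm <- summarize_expression(compute_tpm(cm))
  ## gA has a zero replicate: not expressed, mean forced to 0
  expect_false(tpm$expressed["gA", "AL_18"])
  expect_equal(tpm$mean_tpm["gA", "AL_18"], 0)
  ## gB positive everywhere: plain mean of its replicate TPMs
  expect_true(tpm$expressed["gB", "AL_18"])
  expect_equal(tpm$mean_tpm["gB", "AL_18"],
               mean(tpm$tpm["gB", ]))
  ## degenerate single replicate: the mean is the value itself
  cm1 <- count_matrix(counts[, 1, drop = FALSE],
                      c(gA = 1000, gB = 1000), sheet[1, ])
  tpm1 <- summarize_expression(compute_tpm(cm1))
  expect_equal(tpm1$mean_tpm["gA", "AL_18"], tpm1$tpm["gA", "s1"])
})

test_that("CS score is the ST share of summed mean TPM", {
  al <- matrix(1, 3, 4, dimnames = list(c("g1", "g2", "g3"), NULL))
  st <- matrix(3, 3, 4, dimnames = list(c("g1", "g2", "g3"), NULL))
  st["g2", ] <- 1            # symmetric gene
  st["g3", ] <- 0; al["g3", ] <- 2   # AL-only gene
  tpm <- make_summary_tpm(al, st)
  cs <- cs_score(tpm)
  expect_equal(cs$cs_st[cs$gene == "g1"], 0.75)   # 12 / 16
  expect_equal(cs$cs_st[cs$gene == "g2"], 0.5)
  expect_equal(cs$cs_st[cs$gene == "g3"], 0)
  expect_equal(cs$cs_al[cs$gene == "g3"], 1)
  expect_equal(cs$cs_st + cs$cs_al, rep(1, 3))
  expect_error(cs_score(tpm, gene = "nope"), "unknown gene")
})

test_that("CS score flags all-zero genes and is monotone in ST abundance", {
  al <- matrix(0, 2, 4, dimnames = list(c("g1", "g2"), NULL))
  st <- matrix(0, 2, 4, dimnames = list(c("g1", "g2"), NULL))
  al["g2", ] <- 1
  tpm <- make_summary_tpm(al, st)
  cs <- cs_score(tpm)
  expect_false(cs$defined[cs$gene == "g1"])
  expect_true(is.na(cs$cs_st[cs$gene == "g1"]))
  ## raising ST abundance with AL fixed raises cs_st
  vals <- sapply(c(1, 2, 5), function(v) {
    st2 <- st; st2["g2", ] <- v
    cs_score(make_summary_tpm(al, st2))$cs_st[2]
  })
  expect_true(all(diff(vals) > 0))
})

test_that("class fractions partition to 100% and match arithmetic", {
  al <- matrix(c(250, 750), 2, 4, dimnames = list(c("g1", "g2"), NULL))
  st <- al
  tpm <- make_summary_tpm(al, st)
  fr <- class_fraction(tpm, c(g1 = "prolamin"))
  one <- fr[fr$tissue == "AL" & fr$timepoint == 8, ]
  expect_equal(one$percent[one$class == "prolamin"], 25)
  expect_equal(sum(one$percent), 100)
  ## every gene in the class
  fr_all <- class_fraction(tpm, c(g1 = "prolamin", g2 = "prolamin"))
  expect_equal(fr_all$percent[fr_all$class == "prolamin"], rep(100, 8))
})

test_that("correlation suite matches hand-computed values and invariances", {
  ## identical replicate columns -> rho 1; reversed ranks -> rho -1
  counts <- matrix(c(1L, 5L, 9L,  1L, 5L, 9L,  9L, 5L, 1L), 3, 3,
                   dimnames = list(c("g1", "g2", "g3"),
                                   c("s1", "s2", "s3")))
  sheet <- data.frame(sample = c("s1", "s2", "s3"), tissue = "AL",
                      timepoint = 18,
                      replicate_block = c("b1", "b2", "b3"))
  cm <- count_matrix(counts, c(g1 = 1, g2 = 1, g3 = 1) * 1000, sheet)
  tpm <- summarize_expression(compute_tpm(cm))
  rs <- correlation_suite(tpm, mode = "replicate_spearman")
  expect_equal(rs$rho[rs$sample_a == "s1" & rs$sample_b == "s2"], 1)
  expect_equal(rs$rho[rs$sample_a == "s1" & rs$sample_b == "s3"], -1)

  ## cross-tissue Pearson against the definition, 5-gene fixture
  genes <- paste0("g", 1:5)
  al <- matrix(c(10, 55, 300, 40, 7), 5, 4, dimnames = list(genes, NULL))
  st <- matrix(c(12, 80, 150, 60, 3), 5, 4, dimnames = list(genes, NULL))
  tp <- make_summary_tpm(al, st)
  pc <- correlation_suite(tp, mode = "cross_tissue_pcc")
  expect_equal(pc$pcc[pc$timepoint == 8],
               hand_pearson(log10(al[, 1]), log10(st[, 1])))
  ## Pearson invariant to affine transforms (scale TPM in one tissue)
  pc2 <- correlation_suite(make_summary_tpm(al, st * 100),
                           mode = "cross_tissue_pcc")
  expect_equal(pc2$pcc, pc$pcc)
})
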