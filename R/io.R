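## Plain-text readers and writers for every format the pipeline consumes.
## TSV for matrices and tables, CSV for sample sheets and instrument-style
## outputs (profiles, Ct tables); deterministic formatting so identical
## inputs produce byte-identical files.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

write_csv <- function(x, path) {
  utils::write.table(x, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

read_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an RNA-seq dataset to plain-text files
#'
#' Writes `counts.tsv` (gene column + one column per sample),
#' `gene_lengths.tsv`, `samples.csv`, and a `truth_rnaseq.tsv` sidecar
#' with the planted DE genes and gene classes.
#'
#' @param sim Result of [simulate_rnaseq_counts()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_rnaseq_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- sim$counts
  counts_df <- data.frame(gene = rownames(cm$counts), cm$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  p1 <- file.path(dir, "counts.tsv")
  write_tsv(counts_df, p1)
  p2 <- file.path(dir, "gene_lengths.tsv")
  write_tsv(data.frame(gene = names(cm$gene_length),
                       length = unname(cm$gene_length)), p2)
  p3 <- file.path(dir, "samples.csv")
  write_csv(cm$samples, p3)
  p4 <- file.path(dir, "truth_rnaseq.tsv")
  tr <- sim$truth
  truth_df <- data.frame(gene = names(tr$expression_class_map),
                         class = unname(tr$expression_class_map),
                         true_log2fc = 0, stringsAsFactors = FALSE)
  truth_df$true_log2fc[match(tr$de_genes, truth_df$gene)] <- tr$log2fc
  write_tsv(truth_df, p4)
  invisible(c(p1, p2, p3, p4))
}

#' Read an RNA-seq dataset written by [write_rnaseq_dataset()]
#'
#' @param dir Directory holding `counts.tsv`, `gene_lengths.tsv`,
#'   `samples.csv`.
#' @return A [count_matrix()].
#' @export
read_rnaseq_dataset <- function(dir) {
  for (f in c("counts.tsv", "gene_lengths.tsv", "samples.csv")) {
    if (!file.exists(file.path(dir, f))) {
      stop("missing input file: ", file.path(dir, f), call. = FALSE)
    }
  }
  counts_df <- read_tsv(file.path(dir, "counts.tsv"))
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df$gene
  lens <- read_tsv(file.path(dir, "gene_lengths.tsv"))
  samples <- read_csv(file.path(dir, "samples.csv"))
  count_matrix(counts, stats::setNames(lens$length, lens$gene), samples)
}

#' Write a co-IP proteomics dataset
#'
#' Writes `abundances.tsv` (long format), `predicted_tonoplast.tsv`, and a
#' `truth_proteomics.tsv` sidecar listing the planted tonoplast proteins.
#'
#' @param sim Result of [simulate_proteomics_ip()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_proteomics_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "abundances.tsv")
  write_tsv(sim$abundances, p1)
  p2 <- file.path(dir, "predicted_tonoplast.tsv")
  write_tsv(data.frame(protein = sim$predicted), p2)
  p3 <- file.path(dir, "truth_proteomics.tsv")
  write_tsv(data.frame(protein = sim$truth$tonoplast_proteins), p3)
  invisible(c(p1, p2, p3))
}

#' Write a GO universe dataset
#'
#' Writes `annotations.tsv` (gene, term), `edges.tsv` (child, parent),
#' `study.tsv`, and a `truth_go.tsv` sidecar of planted enriched terms.
#'
#' @param sim Result of [simulate_go_universe()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_go_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(file.path(dir, "annotations.tsv"), file.path(dir, "edges.tsv"),
         file.path(dir, "study.tsv"), file.path(dir, "truth_go.tsv"))
  write_tsv(sim$annotations, p[1])
  write_tsv(sim$edges, p[2])
  write_tsv(data.frame(gene = sim$study), p[3])
  write_tsv(data.frame(term = sim$truth$enriched_terms), p[4])
  invisible(p)
}

#' Write a tonoplast profile dataset
#'
#' Writes `profile.csv` (position, intensity, domain, saturated) and a
#' `truth_profile.tsv` sidecar with the planted enrichment factor.
#'
#' @param sim Result of [simulate_tonoplast_profile()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_profile_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "profile.csv")
  write_csv(as.data.frame(sim$profile), p1)
  p2 <- file.path(dir, "truth_profile.tsv")
  write_tsv(data.frame(
    membrane_enrichment_factor = sim$truth$membrane_enrichment_factor,
    expected_ratio = sim$truth$expected_ratio), p2)
  invisible(c(p1, p2))
}

#' Read a profile CSV into a [tonoplast_profile()]
#'
#' @param path Path to a `profile.csv`.
#' @return A [tonoplast_profile()].
#' @export
read_profile <- function(path) {
  df <- read_csv(path)
  tonoplast_profile(df$position, df$intensity, df$domain,
                    as.logical(df$saturated))
}

#' Write a qPCR Ct dataset
#'
#' Writes `ct.csv` (gene, tissue, bio_rep, tech_rep, ct) and a
#' `truth_qpcr.tsv` sidecar with the true fold changes.
#'
#' @param sim Result of [simulate_qpcr_ct()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_qpcr_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "ct.csv")
  write_csv(sim$ct, p1)
  p2 <- file.path(dir, "truth_qpcr.tsv")
  write_tsv(data.frame(gene = names(sim$truth$fold_changes),
                       true_fold = unname(sim$truth$fold_changes),
                       reference = sim$reference), p2)
  invisible(c(p1, p2))
}
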