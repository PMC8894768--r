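#' Build per-protein co-IP records from a long abundance table
#'
#' Reshapes a long table (`protein`, `replicate`, `assay` in
#' ip/preimmune, `abundance`) into one row per protein with per-replicate
#' IP and pre-immune abundances and detection flags (abundance > 0).
#'
#' @param abundances Long-format abundance data frame.
#' @return Data frame with columns `protein`, `a_ip_1..3`, `a_pi_1..3`,
#'   `detected_ip_1..3`, `detected_pi_1..3`.
#' @export
protein_ip_records <- function(abundances) {
  req <- c("protein", "replicate", "assay", "abundance")
  if (!all(req %in% names(abundances))) {
    stop("need columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(abundances$abundance < 0)) {
    stop("negative abundance", call. = FALSE)
  }
  reps <- sort(unique(abundances$replicate))
  if (!length(reps)) reps <- 1:3   # empty table keeps the 3-replicate shape
  prots <- unique(abundances$protein)
  out <- data.frame(protein = prots, stringsAsFactors = FALSE)
  for (assay in c("ip", "pi")) {
    long_assay <- if (assay == "ip") "ip" else "preimmune"
    for (r in reps) {
      sub <- abundances[abundances$assay == long_assay &
                          abundances$replicate == r, ]
      v <- stats::setNames(sub$abundance, sub$protein)[prots]
      v[is.na(v)] <- 0   # absent row = not detected
      out[[sprintf("a_%s_%d", assay, r)]] <- unname(v)
      out[[sprintf("detected_%s_%d", assay, r)]] <- unname(v) > 0
    }
  }
  out
}

#' Add-one pseudocount fold differences per replicate
#'
#' `fd[r] = (a_ip[r] + 1) / (a_pi[r] + 1)`: one is added to both
#' abundances before dividing so that proteins undetected in the
#' pre-immune control never produce a zero denominator. The higher the
#' fold difference, the more likely the protein was captured by specific
#' interaction with the antibody rather than by the beads.
#'
#' @param records Output of [protein_ip_records()].
#' @return The records with `fd_1`, `fd_2`, `fd_3` columns added.
#' @examples
#' rec <- data.frame(protein = "p", a_ip_1 = 3, a_pi_1 = 1,
#'                   a_ip_2 = 0, a_pi_2 = 0, a_ip_3 = 0, a_pi_3 = 9)
#' replicate_fold_differences(rec)[, c("fd_1", "fd_2", "fd_3")]
#' @export
replicate_fold_differences <- function(records) {
  reps <- grep("^a_ip_", names(records))
  if (!length(reps)) stop("no IP abundance columns", call. = FALSE)
  for (col in names(records)[reps]) {
    r <- sub("^a_ip_", "", col)
    pi_col <- paste0("a_pi_", r)
    if (any(records[[col]] < 0) || any(records[[pi_col]] < 0)) {
      stop("negative abundance", call. = FALSE)
    }
    records[[paste0("fd_", r)]] <-
      (records[[col]] + 1) / (records[[pi_col]] + 1)
  }
  records
}

#' Confidence tiers for co-IP proteins
#'
#' High confidence: at least two of the three biological replicates have
#' fold differences >= `threshold`. Medium confidence: exactly one
#' replicate reaches the threshold and the protein is never detected in
#' the pre-immune serum (all pre-immune abundances zero). Low confidence:
#' every remaining protein. The rule is defined for exactly three
#' replicates.
#'
#' @param records Output of [replicate_fold_differences()].
#' @param threshold Fold-difference threshold (default 2).
#' @return The records with a `tier` factor (high/medium/low).
#' @export
classify_confidence_tier <- function(records, threshold = 2) {
  fd_cols <- grep("^fd_", names(records), value = TRUE)
  if (length(fd_cols) != 3) {
    stop("tier rule is defined for exactly 3 replicates", call. = FALSE)
  }
  fd <- as.matrix(records[, fd_cols])
  pi_cols <- paste0("a_pi_", sub("^fd_", "", fd_cols))
  pi <- as.matrix(records[, pi_cols])
  n_over <- rowSums(fd >= threshold)
  never_pi <- rowSums(pi > 0) == 0
  tier <- ifelse(n_over >= 2, "high",
                 ifelse(n_over == 1 & never_pi, "medium", "low"))
  records$tier <- factor(tier, levels = c("high", "medium", "low"))
  records
}

#' Replicate detection-overlap summary
#'
#' Counts proteins detected in exactly 1, 2 or 3 IP replicates (the
#' Venn-style reproducibility summary) and the fraction detected in two or
#' more; the same breakdown for the pre-immune control.
#'
#' @param records Output of [protein_ip_records()].
#' @return Data frame with rows for IP and pre-immune: `n_detected`,
#'   `in_1`, `in_2`, `in_3`, `frac_ge2` (percent).
#' @export
detection_overlap_summary <- function(records) {
  summarize_assay <- function(prefix) {
    cols <- grep(paste0("^detected_", prefix, "_"), names(records),
                 value = TRUE)
    det <- if (nrow(records)) rowSums(as.matrix(records[, cols])) else
      integer(0)
    det <- det[det > 0]
    data.frame(assay = prefix,
               n_detected = length(det),
               in_1 = sum(det == 1), in_2 = sum(det == 2),
               in_3 = sum(det == 3),
               frac_ge2 = if (length(det)) 100 * mean(det >= 2) else 0,
               stringsAsFactors = FALSE)
  }
  out <- rbind(summarize_assay("ip"), summarize_assay("pi"))
  rownames(out) <- NULL
  out
}

#' One-sided Fisher's exact enrichment of a prediction among detections
#'
#' Builds the 2x2 table (detected x predicted over a universe of known
#' size) and computes the one-sided (greater) Fisher's exact p-value via
#' the hypergeometric upper tail. The headline fold-enrichment statistic
#' is the sample odds ratio `a*d / (b*c)`; the conditional MLE odds ratio
#' is reported as a secondary field.
#'
#' @param detected Character vector (or count) of detected ids.
#' @param predicted Character vector (or count) of predicted ids.
#' @param universe_size Total universe size.
#' @param overlap Overlap count; required when `detected`/`predicted` are
#'   given as counts, otherwise computed from the id sets.
#' @return List of class `"enrichment_2x2"`: `table` (2x2 matrix),
#'   `odds_ratio`, `odds_ratio_cmle`, `p`, `or_infinite` flag.
#' @examples
#' fisher_enrichment(detected = 881, predicted = round(0.02 * 39465),
#'                   universe_size = 39465, overlap = 166)
#' @export
fisher_enrichment <- function(detected, predicted, universe_size,
                              overlap = NULL) {
  if (is.character(detected) || is.character(predicted)) {
    overlap <- length(intersect(detected, predicted))
    detected <- length(unique(detected))
    predicted <- length(unique(predicted))
  }
  if (is.null(overlap)) stop("'overlap' required with count inputs",
                             call. = FALSE)
  a <- overlap
  b <- detected - overlap
  c_ <- predicted - overlap
  d <- universe_size - detected - predicted + overlap
  if (min(a, b, c_, d) < 0) {
    stop("inconsistent counts for the given universe", call. = FALSE)
  }
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(detected = c("yes", "no"),
                                predicted = c("yes", "no")))
  ## hypergeometric upper tail: P(X >= a)
  p <- stats::phyper(a - 1, predicted, universe_size - predicted,
                     detected, lower.tail = FALSE)
  or_inf <- (b * c_) == 0
  or <- if (or_inf) Inf else (a * d) / (b * c_)
  cmle <- stats::fisher.test(tab, alternative = "greater")$estimate
  structure(list(table = tab, odds_ratio = or,
                 odds_ratio_cmle = unname(cmle), p = p,
                 or_infinite = or_inf),
            class = "enrichment_2x2")
}

#' @export
print.enrichment_2x2 <- function(x, ...) {
  print(x$table)
  cat(sprintf("odds ratio %.2f (conditional MLE %.2f), one-sided p = %.3g\n",
              x$odds_ratio, x$odds_ratio_cmle, x$p))
  invisible(x)
}
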