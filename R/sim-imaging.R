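#' Simulate a tonoplast fluorescence intensity profile
#'
#' Generates an ordered 1-D intensity profile along a traced vacuolar
#' membrane. Positions inside the engulfment domain carry the signal of two
#' apposed tonoplast membranes, each accumulating the tagged protein by
#' `membrane_enrichment_factor` relative to the rest of the tonoplast, so
#' the noise-free engulfment/other intensity ratio is
#' `2 * membrane_enrichment_factor` (the analytic null for an evenly
#' distributed protein is exactly 2). Gaussian noise of SD `noise_sd` is
#' added and values at or above `saturation_level` are clipped and flagged
#' saturated.
#'
#' @param config A [sim_config()].
#' @return A list with `profile` (a [tonoplast_profile()]) and `truth`
#'   (with `membrane_enrichment_factor` and the expected ratio).
#' @examples
#' sim <- simulate_tonoplast_profile(sim_config(seed = 1, noise_sd = 0))
#' domain_fold_enrichment(sim$profile)
#' @export
simulate_tonoplast_profile <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  n <- config$n_positions
  pos <- seq_len(n)
  n_eng <- round(config$engulfment_fraction * n)
  domain <- rep("other", n)
  if (n_eng > 0) {
    start <- if (n - n_eng > 0) sample.int(n - n_eng + 1L, 1) else 1L
    domain[start:(start + n_eng - 1L)] <- "engulfment"
  }
  E <- config$membrane_enrichment_factor
  mu <- ifelse(domain == "engulfment",
               2 * E * config$baseline_intensity,
               config$baseline_intensity)
  intensity <- mu + stats::rnorm(n, 0, config$noise_sd)
  intensity <- pmax(intensity, 0)
  saturated <- intensity >= config$saturation_level
  intensity[saturated] <- config$saturation_level

  prof <- tonoplast_profile(position = pos, intensity = intensity,
                            domain = domain, saturated = saturated)
  truth <- structure(list(membrane_enrichment_factor = E,
                          expected_ratio = if (n_eng > 0) 2 * E else NA_real_),
                     class = "sim_truth")
  list(profile = prof, truth = truth)
}

#' Render a synthetic 2-D ring image of a vacuole
#'
#' Optional 2-D counterpart of [simulate_tonoplast_profile()]: draws a
#' circular tonoplast ring on a square image, with an angular sector of
#' doubled, enriched signal standing for the double-membrane engulfment
#' domain, and returns the image together with a polyline trace along the
#' ring so the image path reduces to the 1-D profile path via
#' [profile_from_image()].
#'
#' @param config A [sim_config()].
#' @param size Image side length in pixels.
#' @return A list with `image` (numeric matrix), `trace` (data frame `x`,
#'   `y`, `domain`), and `truth`.
#' @export
simulate_tonoplast_image <- function(config, size = 128L) {
  validate_sim_config(config)
  set.seed(config$seed + 4L)
  size <- as.integer(size)
  img <- matrix(stats::rnorm(size * size, 10, config$noise_sd / 2),
                size, size)
  cx <- cy <- (size + 1) / 2
  radius <- size * 0.35
  E <- config$membrane_enrichment_factor
  theta <- seq(0, 2 * pi, length.out = config$n_positions + 1L)[-1L]
  eng_arc <- 2 * pi * config$engulfment_fraction
  domain <- ifelse(theta <= eng_arc, "engulfment", "other")
  xs <- round(cx + radius * cos(theta))
  ys <- round(cy + radius * sin(theta))
  mu <- ifelse(domain == "engulfment", 2 * E * config$baseline_intensity,
               config$baseline_intensity)
  for (i in seq_along(theta)) {
    img[ys[i], xs[i]] <- mu[i] + stats::rnorm(1, 0, config$noise_sd)
  }
  img[img < 0] <- 0
  img[img > config$saturation_level] <- config$saturation_level
  trace <- data.frame(x = xs, y = ys, domain = domain,
                      stringsAsFactors = FALSE)
  truth <- structure(list(membrane_enrichment_factor = E,
                          expected_ratio = 2 * E), class = "sim_truth")
  list(image = img, trace = trace, truth = truth)
}
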