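#' Tonoplast intensity profile
#'
#' Ordered fluorescence intensities along a traced membrane with a domain
#' label per position (`engulfment` for the tonoplast stretch wrapping a
#' storage-protein body, `other` elsewhere) and a saturation flag; only
#' unsaturated positions enter the fold-enrichment ratio.
#'
#' @param position Ordered positions (length units).
#' @param intensity Non-negative intensities (arbitrary units).
#' @param domain Character per position, `"engulfment"` or `"other"`.
#' @param saturated Logical per position.
#' @return Data frame of class `"tonoplast_profile"`.
#' @export
tonoplast_profile <- function(position, intensity, domain,
                              saturated = rep(FALSE, length(position))) {
  if (any(intensity < 0) || any(!is.finite(intensity))) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  if (!all(domain %in% c("engulfment", "other"))) {
    stop("domain must be 'engulfment' or 'other'", call. = FALSE)
  }
  out <- data.frame(position = position, intensity = intensity,
                    domain = domain, saturated = as.logical(saturated),
                    stringsAsFactors = FALSE)
  class(out) <- c("tonoplast_profile", "data.frame")
  out
}

#' Engulfment-domain fold enrichment
#'
#' Mean intensity over unsaturated engulfment positions divided by the
#' mean over unsaturated other positions. The analytic null for a protein
#' evenly distributed along the tonoplast is 2, because the engulfment
#' domain consists of two closely apposed tonoplast membranes; ratios
#' clearly above 2 indicate specific accumulation at the engulfment site.
#' An optional constant background is subtracted first (the ratio is not
#' background-invariant).
#'
#' @param profile A [tonoplast_profile()].
#' @param background Constant background intensity to subtract (default 0).
#' @return The ratio (scalar).
#' @examples
#' p <- tonoplast_profile(1:4, c(4, 4, 2, 2),
#'                        c("engulfment", "engulfment", "other", "other"))
#' domain_fold_enrichment(p)   # 2: the double-membrane null
#' @export
domain_fold_enrichment <- function(profile, background = 0) {
  stopifnot(inherits(profile, "tonoplast_profile"))
  usable <- !profile$saturated
  for (dom in c("engulfment", "other")) {
    if (!any(usable & profile$domain == dom)) {
      stop("no unsaturated positions in the '", dom,
           "' domain; ratio undefined", call. = FALSE)
    }
  }
  eng <- profile$intensity[usable & profile$domain == "engulfment"] -
    background
  oth <- profile$intensity[usable & profile$domain == "other"] - background
  mean(eng) / mean(oth)
}

#' Bulb frequency per construct and fold change over the control
#'
#' Percentage of protoplasts showing rounded tonoplast invaginations
#' ("bulbs") per construct, and each construct's fold change relative to
#' the control construct. The fold is undefined (NA, flagged) when the
#' control shows no bulbs.
#'
#' @param observations Data frame with columns `construct`, `has_bulbs`
#'   (logical), one row per protoplast.
#' @param control_label Construct name of the control.
#' @return Data frame `construct`, `n`, `n_bulbed`, `percent`, `fold`,
#'   `fold_defined`.
#' @export
bulb_frequency <- function(observations, control_label) {
  stopifnot(all(c("construct", "has_bulbs") %in% names(observations)))
  if (!control_label %in% observations$construct) {
    stop("unknown control label: ", control_label, call. = FALSE)
  }
  sp <- split(observations$has_bulbs, observations$construct)
  out <- data.frame(
    construct = names(sp),
    n = vapply(sp, length, 1L),
    n_bulbed = vapply(sp, sum, 1L),
    stringsAsFactors = FALSE, row.names = NULL)
  out$percent <- 100 * out$n_bulbed / out$n
  ctrl <- out$percent[out$construct == control_label]
  out$fold_defined <- ctrl > 0
  out$fold <- if (ctrl > 0) out$percent / ctrl else NA_real_
  out
}

#' Pearson co-localization within a region of interest
#'
#' Pearson correlation of two channel images over the pixels of a logical
#' ROI mask (e.g. a traced vacuole). Errors when either channel is
#' constant within the mask (correlation undefined).
#'
#' @param channel_a,channel_b Numeric matrices of identical shape.
#' @param roi_mask Logical matrix of the same shape; TRUE pixels enter.
#' @return Correlation in [-1, 1].
#' @export
roi_pearson <- function(channel_a, channel_b, roi_mask) {
  if (!all(dim(channel_a) == dim(channel_b)) ||
      !all(dim(channel_a) == dim(roi_mask))) {
    stop("images and mask must share dimensions", call. = FALSE)
  }
  if (!any(roi_mask)) stop("empty ROI mask", call. = FALSE)
  a <- channel_a[roi_mask]
  b <- channel_b[roi_mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant channel within the ROI; correlation undefined",
         call. = FALSE)
  }
  stats::cor(a, b)
}

#' Sample a 1-D profile from a 2-D image along a trace
#'
#' Reduces the image path to the 1-D profile path: intensities are read at
#' the (rounded) trace coordinates with their supplied domain labels, and
#' pixels at or above `saturation_level` are flagged saturated.
#'
#' @param image Numeric matrix (rows = y, columns = x).
#' @param trace Data frame with columns `x`, `y`, `domain`.
#' @param saturation_level Saturation threshold (default 4095).
#' @return A [tonoplast_profile()].
#' @export
profile_from_image <- function(image, trace, saturation_level = 4095) {
  stopifnot(all(c("x", "y", "domain") %in% names(trace)))
  xs <- round(trace$x); ys <- round(trace$y)
  if (any(xs < 1 | xs > ncol(image) | ys < 1 | ys > nrow(image))) {
    stop("trace leaves the image", call. = FALSE)
  }
  inten <- image[cbind(ys, xs)]
  tonoplast_profile(position = seq_along(xs), intensity = inten,
                    domain = trace$domain,
                    saturated = inten >= saturation_level)
}
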