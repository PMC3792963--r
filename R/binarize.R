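# Channel binarization.
#
# The vessel stain is typically delivered already masked (vessels white on a
# zero background), for which the decision rule is simply "any pixel that is
# not 0 is vessel". Raw intensity channels (drug auto-fluorescence) are
# thresholded by Otsu's method over a 256-bin histogram, or by a fixed
# calibrated threshold.

#' Binarize a channel of a field
#'
#' @param image a [field_image()].
#' @param channel channel name.
#' @param method decision rule: `"nonzero"` (intensity > 0; the rule for
#'   pre-masked vessel images), `"otsu"` (intensity > Otsu threshold over the
#'   channel histogram) or `"fixed"` (intensity > `fixed_threshold`).
#' @param fixed_threshold required iff `method = "fixed"`.
#' @param semantics what the mask means (`"vessel"`, `"drug"`, `"exclusion"`);
#'   recorded as an attribute.
#' @return a logical matrix of class `binary_mask` with attributes
#'   `semantics`, `method` and `threshold` (the numeric cut actually used).
#' @export
#' @examples
#' fi <- field_image(list(v = matrix(c(0, 7, 255, 0), 2, 2)), "x200")
#' m <- binarize_channel(fi, "v", method = "nonzero")
#' sum(m) # 2
binarize_channel <- function(image, channel,
                             method = c("nonzero", "otsu", "fixed"),
                             fixed_threshold = NULL,
                             semantics = c("drug", "vessel", "exclusion")) {
  method <- match.arg(method)
  semantics <- match.arg(semantics)
  x <- get_channel(image, channel)
  if (method == "fixed" && is.null(fixed_threshold)) {
    abort("`fixed_threshold` must be supplied when method = 'fixed'.")
  }
  if (method != "fixed" && !is.null(fixed_threshold)) {
    abort("`fixed_threshold` is only meaningful when method = 'fixed'.")
  }
  thr <- switch(method,
    nonzero = 0,
    fixed = fixed_threshold,
    otsu = otsu_threshold(x)
  )
  binary_mask(x > thr, semantics = semantics, method = method, threshold = thr)
}

#' Otsu threshold of an intensity raster
#'
#' Classic Otsu: build a histogram of `levels` bins spanning the observed
#' range and choose the cut maximizing the between-class variance
#' `w1 * w2 * (mu1 - mu2)^2`, with the boundary bin belonging to the lower
#' class (the convention of the method's standard implementations). The
#' returned cut is on the original intensity scale; pixels strictly above it
#' are foreground. Ties resolve to the lowest maximizing cut.
#'
#' @param x numeric matrix or vector of intensities.
#' @param levels number of histogram bins.
#' @return threshold on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) stop_degenerate_histogram()
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  bin <- pmin(pmax(findInterval(x, breaks, all.inside = TRUE), 1L), levels)
  counts <- tabulate(bin, nbins = levels)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  w1 <- cumsum(counts)
  m1 <- cumsum(counts * mids)
  total <- w1[levels]
  msum <- m1[levels]
  # candidate cuts after bins 1..levels-1
  w1 <- w1[-levels]; m1 <- m1[-levels]
  w2 <- total - w1
  valid <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, levels - 1L)
  bcv[valid] <- w1[valid] * w2[valid] *
    (m1[valid] / w1[valid] - (msum - m1[valid]) / w2[valid])^2
  breaks[which.max(bcv) + 1L]
}

#' Construct a binary mask raster
#'
#' @param m logical matrix.
#' @param semantics `"vessel"`, `"drug"` or `"exclusion"`.
#' @param method,threshold provenance of the decision rule, if any.
#' @return logical matrix of class `binary_mask`.
#' @export
binary_mask <- function(m, semantics = c("drug", "vessel", "exclusion"),
                        method = NA_character_, threshold = NA_real_) {
  stopifnot(is.matrix(m), is.logical(m))
  semantics <- match.arg(semantics)
  structure(m,
    semantics = semantics, method = method, threshold = threshold,
    class = c("binary_mask", class(m))
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask:%s> %d x %d px, %d TRUE (method %s, threshold %s)\n",
    attr(x, "semantics"), nrow(x), ncol(x), sum(x),
    attr(x, "method"), format(attr(x, "threshold"))
  ))
  invisible(x)
}
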