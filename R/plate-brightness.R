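#' Convert an RGB raster to grayscale
#'
#' Applies luma weights per pixel (ITU-R 601 by default:
#' `0.299 R + 0.587 G + 0.114 B`). A matrix input (already gray) is
#' returned unchanged.
#'
#' @param image Numeric matrix (H x W, gray) or array (H x W x 3, RGB), on
#'   any intensity scale (0-255 or 0-1).
#' @param weights Channel weights, length 3, summing to 1.
#' @return Numeric H x W matrix.
#' @examples
#' to_grayscale(array(c(255, 0, 0), dim = c(1, 1, 3)))[1, 1] # 76.245
#' @export
to_grayscale <- function(image, weights = c(0.299, 0.587, 0.114)) {
  if (is.matrix(image)) return(image)
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] >= 3L)) {
    abort("image must be an H x W matrix or an H x W x 3 array")
  }
  g <- weights[1] * image[, , 1] + weights[2] * image[, , 2] + weights[3] * image[, , 3]
  if (!is.matrix(g)) g <- matrix(g, nrow = dim(image)[1], ncol = dim(image)[2])
  g
}

#' Mean brightness inside a circular region of interest
#'
#' The ROI is a disc whose diameter is `diameter_fraction` of the plate
#' diameter; the plate diameter defaults to `min(width, height)` of the
#' image and the plate center to the image center. A pixel is included iff
#' its center lies within the ROI radius.
#'
#' @param gray Numeric H x W matrix (see [to_grayscale()]).
#' @param center Optional `c(row, col)` plate center in pixels (defaults to
#'   the image center).
#' @param diameter_fraction Fraction of the plate diameter used as ROI
#'   diameter (default 0.7). Must be > 0.
#' @return Mean of included pixel values (scalar).
#' @export
roi_mean <- function(gray, center = NULL, diameter_fraction = 0.7) {
  if (!is.matrix(gray)) gray <- to_grayscale(gray)
  if (diameter_fraction <= 0) abort("diameter_fraction must be > 0")
  h <- nrow(gray); w <- ncol(gray)
  if (is.null(center)) center <- c((h + 1) / 2, (w + 1) / 2)
  radius <- diameter_fraction / 2 * min(h, w)
  d2 <- outer((seq_len(h) - center[1])^2, (seq_len(w) - center[2])^2, `+`)
  inside <- d2 <= radius^2
  if (!any(inside)) abort("ROI contains no pixels")
  mean(gray[inside])
}

#' Brightness time series of a plate image stack
#'
#' Computes the ROI mean brightness of every frame and min-max normalizes
#' the series to `[0, 1]`. A constant raw series cannot be normalized; it is
#' set to all zeros and flagged.
#'
#' @param images List of frames (matrices/arrays) or character vector of
#'   PNG file paths (read at 0-255 scale).
#' @param times Numeric vector of frame times (hours since inoculation),
#'   strictly increasing, same length as `images`.
#' @inheritParams roi_mean
#' @return A `plate_series` tibble with columns `time_h`, `raw`, `norm`;
#'   attributes `roi` (center, radius spec) and `constant` (flag).
#' @export
brightness_series <- function(images, times, center = NULL,
                              diameter_fraction = 0.7) {
  if (is.character(images)) images <- lapply(images, read_plate_image)
  if (length(images) < 2L) abort("need at least 2 frames")
  if (length(times) != length(images)) abort("times and images differ in length")
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  raw <- vapply(images, function(im) {
    roi_mean(to_grayscale(im), center = center,
             diameter_fraction = diameter_fraction)
  }, numeric(1))
  rng <- range(raw)
  constant <- rng[1] == rng[2]
  if (constant) {
    warn("constant brightness series; normalized values set to 0")
    norm <- rep(0, length(raw))
  } else {
    norm <- (raw - rng[1]) / (rng[2] - rng[1])
  }
  out <- tibble(time_h = times, raw = raw, norm = norm)
  class(out) <- c("plate_series", class(out))
  attr(out, "roi") <- list(center = center, diameter_fraction = diameter_fraction)
  attr(out, "constant") <- constant
  out
}

#' Read a plate image from PNG
#'
#' @param path PNG file path.
#' @return Gray matrix or RGB array on the 0-255 scale.
#' @export
read_plate_image <- function(path) {
  img <- png::readPNG(path)
  img * 255
}

#' Detect developmental transitions in a brightness series
#'
#' Smooths the normalized series with a centered moving average, then
#' reports local maxima (`brightness_peak`) and minima (`brightness_trough`)
#' whose topographic prominence is at least `min_prominence`. On a plate
#' series a brightness peak marks aerial hyphae formation and the following
#' trough gray-spore maturation, but the labels are left to the user.
#'
#' @param series A `plate_series` (see [brightness_series()]) or a tibble
#'   with `time_h` and `norm`.
#' @param smooth_window Moving-average width in frames (odd; default 3).
#' @param min_prominence Minimum prominence in normalized units (default
#'   0.1).
#' @return Tibble `kind`, `time_h`, `prominence`, sorted by time.
#' @export
transition_times <- function(series, smooth_window = 3L, min_prominence = 0.1) {
  v <- series$norm
  t <- series$time_h
  if (length(v) < 3L) return(tibble(kind = character(), time_h = numeric(),
                                    prominence = numeric()))
  s <- .moving_average(v, smooth_window)
  peaks <- .prominent_extrema(s, min_prominence, prefer = v)
  troughs <- .prominent_extrema(-s, min_prominence, prefer = -v)
  out <- bind_rows(
    if (nrow(peaks)) mutate(peaks, kind = "brightness_peak") else NULL,
    if (nrow(troughs)) mutate(troughs, kind = "brightness_trough") else NULL
  )
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(kind = character(), time_h = numeric(), prominence = numeric()))
  }
  out %>%
    mutate(time_h = t[.data$index]) %>%
    select("kind", "time_h", "prominence") %>%
    arrange(.data$time_h)
}

# Centered moving average; the window shrinks symmetrically at the edges.
.moving_average <- function(v, window) {
  window <- max(1L, as.integer(window))
  half <- window %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(v[lo:hi])
  }, numeric(1))
}

# Local maxima of v with topographic prominence >= min_prom.
# A plateau (run of equal smoothed values) is collapsed to the sample with
# the largest value of `prefer` (the unsmoothed series), falling back to
# the plateau center.
.prominent_extrema <- function(v, min_prom, prefer = NULL) {
  n <- length(v)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  res <- list()
  for (j in seq_len(k)) {
    left_ok <- j == 1L || r$values[j - 1L] < r$values[j]
    right_ok <- j == k || r$values[j + 1L] < r$values[j]
    # edge runs are not peaks unless interior on the other side
    if (j == 1L || j == k) next
    if (!(left_ok && right_ok)) next
    h <- r$values[j]
    run <- starts[j]:ends[j]
    i <- if (!is.null(prefer)) run[which.max(prefer[run])] else (starts[j] + ends[j]) %/% 2L
    # walk left to the nearest strictly higher point; base = min en route
    lo <- v[seq_len(starts[j] - 1L)]
    higher_l <- which(lo > h)
    left_base <- if (length(higher_l)) min(lo[(max(higher_l) + 1L):(starts[j] - 1L)]) else min(lo)
    hi <- v[(ends[j] + 1L):n]
    higher_r <- which(hi > h)
    right_base <- if (length(higher_r)) min(hi[seq_len(min(higher_r) - 1L)]) else min(hi)
    prom <- h - max(left_base, right_base)
    if (prom >= min_prom) {
      res[[length(res) + 1L]] <- tibble(index = i, prominence = prom)
    }
  }
  if (length(res) == 0L) return(tibble(index = integer(), prominence = numeric()))
  bind_rows(res)
}

#' Plot a plate brightness series
#'
#' @param object A `plate_series`.
#' @param events Optional output of [transition_times()] to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plate_series <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h, y = .data$norm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after inoculation (h)", y = "normalized brightness") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0L) {
    p <- p + ggplot2::geom_vline(data = events,
                                 ggplot2::aes(xintercept = .data$time_h),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Tidy a plate series
#'
#' @param x A `plate_series`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.plate_series <- function(x, ...) {
  tibble(time_h = x$time_h, raw = x$raw, norm = x$norm)
}
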