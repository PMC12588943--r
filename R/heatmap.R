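# Per-pixel observer-agreement counts, colour banding, and transparent
# overlay rendering on the B-mode base image.

#' Per-pixel observer agreement counts
#'
#' Sums the binary masks elementwise: each pixel gets an aggregate score
#' from 0 (no observer marked it as tumour) to n (all observers did).
#'
#' @param masks list of >= 1 [mask_image]s for one image on a common grid.
#' @return An object of class `pixel_agreement_map` with fields `image_id`,
#'   `counts` (integer matrix in \[0, n\]) and `n_observers`.
#' @export
aggregate_map <- function(masks) {
  n <- length(masks)
  if (n < 1) stop("need at least 1 mask")
  ref <- dim(masks[[1]]$pixels)
  counts <- matrix(0L, ref[1], ref[2])
  for (m in masks) {
    stopifnot(inherits(m, "mask_image"))
    if (!identical(dim(m$pixels), ref))
      stop(sprintf("grid mismatch: %dx%d vs %dx%d",
                   nrow(m$pixels), ncol(m$pixels), ref[1], ref[2]))
    counts <- counts + m$pixels
  }
  image_id <- unique(vapply(masks, function(m) m$image_id, character(1)))
  if (length(image_id) != 1)
    stop("masks belong to different images: ", paste(image_id, collapse = ", "))
  structure(list(image_id = image_id, counts = counts, n_observers = n),
            class = "pixel_agreement_map")
}

#' @export
print.pixel_agreement_map <- function(x, ...) {
  cat(sprintf("<pixel_agreement_map> image %s: %d observers, counts %d..%d\n",
              x$image_id, x$n_observers, min(x$counts), max(x$counts)))
  invisible(x)
}

#' Colour-band specification for agreement counts
#'
#' Partitions the achievable counts `0..n` into three bands: white (low
#' agreement, rendered fully transparent), red (intermediate) and green
#' (high agreement). The default thresholds follow the >80% green /
#' 20%-79% red percentage rule: white `[0, ceiling(0.2 n) - 1]`, red up to
#' `floor(0.8 n)`, green above. For 18 observers that is white 0-3,
#' red 4-14, green 15-18.
#'
#' @param n_observers number of observers n.
#' @param white,red,green optional explicit inclusive `(lo, hi)` count
#'   ranges; must partition `0..n` exactly (gaps or overlaps are an error).
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(n_observers,
                      white = c(0, ceiling(0.2 * n_observers) - 1),
                      red = c(white[2] + 1, floor(0.8 * n_observers)),
                      green = c(red[2] + 1, n_observers)) {
  n <- as.integer(n_observers)
  stopifnot(n >= 1)
  bands <- list(white = as.integer(white), red = as.integer(red),
                green = as.integer(green))
  cover <- integer(0)
  for (b in names(bands)) {
    rng <- bands[[b]]
    # lo == hi + 1 encodes an empty band (possible at very small n)
    if (length(rng) != 2 || rng[1] > rng[2] + 1)
      stop("band '", b, "' is not a valid (lo, hi) range")
    if (rng[1] <= rng[2]) cover <- c(cover, seq(rng[1], rng[2]))
  }
  if (anyDuplicated(cover))
    stop("band ranges overlap at count(s): ",
         paste(unique(cover[duplicated(cover)]), collapse = ", "))
  missing <- setdiff(0:n, cover)
  if (length(missing))
    stop("band ranges leave a gap at count(s): ", paste(missing, collapse = ", "))
  structure(c(bands, list(n_observers = n)), class = "band_spec")
}

#' Classify agreement counts into colour bands
#'
#' @param map a [aggregate_map()] result.
#' @param spec a [band_spec()]; defaults to the percentage-rule bands for
#'   the map's observer count.
#' @return An object of class `banded_map`: `classes` (character matrix
#'   over white/red/green) and the `band_spec` used.
#' @export
classify_pixels <- function(map, spec = band_spec(map$n_observers)) {
  stopifnot(inherits(map, "pixel_agreement_map"), inherits(spec, "band_spec"))
  if (spec$n_observers != map$n_observers)
    stop("band_spec is for n=", spec$n_observers,
         " but map has n=", map$n_observers)
  lut <- character(spec$n_observers + 1)
  for (b in c("white", "red", "green")) {
    rng <- spec[[b]]
    if (rng[1] <= rng[2]) lut[seq(rng[1], rng[2]) + 1] <- b
  }
  classes <- matrix(lut[map$counts + 1L],
                    nrow(map$counts), ncol(map$counts))
  structure(list(image_id = map$image_id, classes = classes,
                 band_spec = spec),
            class = "banded_map")
}

#' Render a banded agreement map as a transparent overlay
#'
#' Blends the band colours onto the grayscale base image: white-band
#' pixels show the base image unchanged (the overlay is fully transparent
#' there); green and red pixels are alpha-blended
#' `(1 - alpha) * base + alpha * colour` per channel.
#'
#' @param banded a [classify_pixels()] result.
#' @param base grayscale matrix in \[0, 255\] with the same shape.
#' @param alpha overlay opacity in \[0, 1\]; 0 reproduces the base image.
#' @param colours named list with `green` and `red` RGB triplets in 0..255.
#' @return An H x W x 4 RGBA array in \[0, 1\], writable with
#'   [write_overlay_png()].
#' @export
render_overlay <- function(banded, base, alpha = 0.5,
                           colours = list(green = c(0, 255, 0),
                                          red = c(255, 0, 0))) {
  stopifnot(inherits(banded, "banded_map"))
  if (!identical(dim(banded$classes), dim(base)))
    stop(sprintf("shape mismatch: bands %dx%d vs base %dx%d",
                 nrow(banded$classes), ncol(banded$classes),
                 nrow(base), ncol(base)))
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  g <- pmin(pmax(base, 0), 255) / 255
  out <- array(0, dim = c(nrow(base), ncol(base), 4))
  out[, , 1] <- out[, , 2] <- out[, , 3] <- g
  out[, , 4] <- 1
  for (b in c("green", "red")) {
    sel <- banded$classes == b
    if (!any(sel)) next
    col <- colours[[b]] / 255
    for (ch in 1:3)
      out[, , ch][sel] <- (1 - alpha) * g[sel] + alpha * col[ch]
  }
  out
}

#' Write an RGBA overlay to PNG
#' @param overlay array from [render_overlay()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(overlay, path) {
  png::writePNG(overlay, target = path)
  invisible(path)
}

#' Export agreement counts as CSV
#' @param map a [aggregate_map()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(map, path) {
  stopifnot(inherits(map, "pixel_agreement_map"))
  utils::write.table(map$counts, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
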