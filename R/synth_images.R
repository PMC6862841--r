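# Synthetic plot imagery with pixel-exact ground truth.

# Canopy mask with exactly round(cover * npix) foreground pixels: a smooth
# blob intensity field (Gaussian bumps centered on simulated plants along
# the row axis, plus tie-breaking noise) is thresholded at the k-th largest
# value, so the mask fraction matches the requested cover to within half a
# pixel.
render_canopy_mask <- function(h, w, cover, gsd_cm = 1.5) {
  npix <- h * w
  k <- round(cover * npix)
  mask <- matrix(FALSE, h, w)
  if (k <= 0L) return(mask)
  if (k >= npix) return(matrix(TRUE, h, w))
  plant_cm <- 10                      # nominal plant spacing along the row
  n_plants <- max(3L, round(w * gsd_cm / plant_cm))
  cx <- (seq_len(n_plants) - 0.5) * w / n_plants +
    stats::rnorm(n_plants, 0, 0.1 * w / n_plants)
  cy <- h / 2 + stats::rnorm(n_plants, 0, 0.05 * h)
  sx <- w / n_plants * stats::runif(n_plants, 0.7, 1.1)
  sy <- h * stats::runif(n_plants, 0.25, 0.4)
  field <- matrix(0, h, w)
  xs <- seq_len(w); ys <- seq_len(h)
  for (p in seq_len(n_plants)) {
    field <- field + exp(-(ys - cy[p])^2 / (2 * sy[p]^2)) %o%
      exp(-(xs - cx[p])^2 / (2 * sx[p]^2))
  }
  field <- field + stats::runif(npix) * 1e-6   # break ties deterministically
  mask[order(field, decreasing = TRUE)[seq_len(k)]] <- TRUE
  attr(mask, "plant_x") <- cx
  mask
}

# Color a mask into an 8-bit RGB raster. Soil is brownish with mostly
# luminance noise (R >= G); canopy is green-dominant with a G-over-R margin
# drawn per plant blob, so Excess Green separates the classes realistically
# but not trivially. Illumination varies per image.
colorize_plot_image <- function(mask, illumination = 1) {
  h <- nrow(mask); w <- ncol(mask); npix <- h * w
  lum <- stats::rnorm(npix, 0, 12)
  r <- 125 + lum + stats::rnorm(npix, 0, 2)
  g <- r - (18 + abs(stats::rnorm(npix, 0, 5)))
  b <- 0.62 * r + stats::rnorm(npix, 0, 3)
  fg <- as.vector(mask)
  if (any(fg)) {
    nfg <- sum(fg)
    plant_x <- attr(mask, "plant_x")
    if (is.null(plant_x)) plant_x <- w / 2
    # nearest plant center along the row axis defines the blob
    col_of <- rep(seq_len(w), each = h)[fg]
    nearest <- vapply(seq_len(w),
                      function(x) which.min(abs(plant_x - x)), integer(1))
    blob <- nearest[col_of]
    margin <- stats::runif(length(plant_x), 42, 58)[blob]
    gl <- stats::rnorm(nfg, 135, 6)
    r[fg] <- gl - margin
    g[fg] <- gl + stats::rnorm(nfg, 0, 3)
    b[fg] <- gl - margin * stats::runif(nfg, 0.75, 0.85)
  }
  px <- array(0L, c(h, w, 3L))
  px[, , 1] <- matrix(as.integer(pmin(pmax(round(r * illumination), 0), 255)),
                      h, w)
  px[, , 2] <- matrix(as.integer(pmin(pmax(round(g * illumination), 0), 255)),
                      h, w)
  px[, , 3] <- matrix(as.integer(pmin(pmax(round(b * illumination), 0), 255)),
                      h, w)
  px
}

#' Simulate one RGB plot image with known canopy ground truth
#'
#' Renders a single-row soybean plot seen from above: a textured brownish
#' soil background with green canopy blobs along the row axis whose pixel
#' fraction matches `cover` to within half a pixel. The exact foreground
#' mask is returned alongside the image.
#'
#' @param cover Target canopy cover fraction in `[0, 1]`.
#' @param image_px Image size `c(height, width)` in pixels. The default is
#'   the footprint of a 1.83 m x 0.76 m plot at the default ground-sampling
#'   distance.
#' @param gsd_cm Ground-sampling distance in cm per pixel (default 1.5, a
#'   50 m RGB flight).
#' @param seed Optional integer seed (draws from the current RNG stream when
#'   `NULL`, for use inside batch generators).
#' @return A list of class `"plot_image"` with elements `pixels` (integer
#'   `H x W x 3` array, 8-bit channels), `mask` (logical `H x W` ground
#'   truth), and `cover` (the realized mask fraction).
#' @examples
#' img <- simulate_plot_image(0.4, image_px = c(64, 64), seed = 1)
#' mean(img$mask)
#' @export
simulate_plot_image <- function(cover, image_px = c(51L, 122L), gsd_cm = 1.5,
                                seed = NULL) {
  if (!is.numeric(cover) || length(cover) != 1L || is.na(cover) ||
      cover < 0 || cover > 1) {
    stop("cover must be a single value in [0, 1]", call. = FALSE)
  }
  gen <- function() {
    mask <- render_canopy_mask(image_px[1], image_px[2], cover, gsd_cm)
    illum <- stats::runif(1, 0.85, 1.15)
    px <- colorize_plot_image(mask, illumination = illum)
    structure(list(pixels = px, mask = matrix(as.logical(mask), nrow(mask)),
                   cover = mean(mask)),
              class = "plot_image")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate replicated plot images for a trial's sampling dates
#'
#' Generates `n_replicate_images` RGB images (plus ground-truth masks) for
#' every plot and sampling date, given the matrix of true covers. Replicate
#' images of the same plot-date re-draw blob placement and illumination but
#' share the target cover, emulating repeated extractions of the same plot
#' from overlapping aerial frames.
#'
#' @param true_cover Numeric matrix of true cover fractions, plots x dates,
#'   with rownames = plot ids (e.g. from [true_cover_schedule()]).
#' @param dates Integer DAP vector, one per column of `true_cover`.
#' @param n_replicate_images Images per plot-date.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, images and masks are written
#'   as PNGs named `{plot}_{dap}_{rep}.png` (masks with suffix `_mask`) and
#'   indexed by a `manifest.csv`.
#' @inheritParams simulate_plot_image
#' @return When `dir` is `NULL`, a list of `"plot_image"` records, each
#'   carrying `plot_id`, `dap` and `replicate`; otherwise the manifest data
#'   frame (invisibly written to disk).
#' @export
simulate_plot_images <- function(true_cover, dates, image_px = c(51L, 122L),
                                 gsd_cm = 1.5, n_replicate_images = 3L,
                                 seed = 1L, dir = NULL) {
  true_cover <- as.matrix(true_cover)
  if (any(true_cover < 0 | true_cover > 1)) {
    stop("true_cover must lie in [0, 1]", call. = FALSE)
  }
  if (length(dates) != ncol(true_cover)) {
    stop("length(dates) must match ncol(true_cover)", call. = FALSE)
  }
  plot_ids <- rownames(true_cover)
  if (is.null(plot_ids)) plot_ids <- sprintf("P%05d", seq_len(nrow(true_cover)))
  n_replicate_images <- check_count(n_replicate_images, "n_replicate_images",
                                    min = 1L)
  with_seed(seed, {
    out <- vector("list", nrow(true_cover) * length(dates) *
                    n_replicate_images)
    manifest <- NULL
    rows <- list()
    idx <- 0L
    for (i in seq_len(nrow(true_cover))) {
      for (j in seq_along(dates)) {
        for (r in seq_len(n_replicate_images)) {
          img <- simulate_plot_image(true_cover[i, j], image_px = image_px,
                                     gsd_cm = gsd_cm, seed = NULL)
          img$plot_id <- plot_ids[i]
          img$dap <- dates[j]
          img$replicate <- r
          idx <- idx + 1L
          if (is.null(dir)) {
            out[[idx]] <- img
          } else {
            stem <- sprintf("%s_%d_%d", plot_ids[i], dates[j], r)
            png::writePNG(img$pixels / 255, file.path(dir,
                                                      paste0(stem, ".png")))
            png::writePNG(img$mask * 1, file.path(dir,
                                                  paste0(stem, "_mask.png")))
            rows[[idx]] <- data.frame(path = paste0(stem, ".png"),
                                      mask_path = paste0(stem, "_mask.png"),
                                      plot_id = plot_ids[i], dap = dates[j],
                                      replicate = r,
                                      true_cover = true_cover[i, j],
                                      stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (is.null(dir)) return(out)
    manifest <- do.call(rbind, rows)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    invisible(manifest)
  })
}

#' Read a plot image from a PNG file
#'
#' @param path PNG path.
#' @param plot_id,dap,replicate Optional identifiers to attach.
#' @return A `"plot_image"` with 8-bit integer channels.
#' @export
read_plot_image <- function(path, plot_id = NA_character_, dap = NA_integer_,
                            replicate = NA_integer_) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  px <- px[, , 1:3, drop = FALSE]
  structure(list(pixels = array(as.integer(round(px * 255)), dim(px)),
                 plot_id = plot_id, dap = dap, replicate = replicate),
            class = "plot_image")
}

#' @export
print.plot_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("plot image %dx%d px", d[1], d[2]))
  if (!is.null(x$plot_id) && !is.na(x$plot_id)) {
    cat(sprintf(" (plot %s, %s DAP, replicate %s)", x$plot_id, x$dap,
                x$replicate))
  }
  if (!is.null(x$mask)) cat(sprintf(", true cover %.3f", mean(x$mask)))
  cat("\n")
  invisible(x)
}
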