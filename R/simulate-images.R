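# Synthetic fluorescence images with disk-shaped foci and labelled cell
# masks. Foci are ideal filled disks (no optics/PSF model): the analysis
# under test is percentile thresholding plus size gating, not deconvolution.

#' Parameters for the synthetic image generator
#'
#' Images are 16-bit single-channel arrays containing `n_cells` rectangular
#' cell regions (the labelled mask) laid out on a grid with background gaps
#' between cells. Each cell receives a Poisson(`foci_per_cell`) number of
#' non-overlapping foci: filled disks with diameter drawn uniformly from
#' `focus_diameter_range_um` (default 0.1–0.5 um, the size range of mitotic
#' SERBP1 bodies) rendered at `focus_intensity` grey levels, after which
#' `background_level` plus Gaussian noise is added and an optional gamma
#' distortion applied.
#'
#' @param image_shape integer (rows, cols) in pixels.
#' @param pixel_size_um physical pixel size, um per pixel (> 0).
#' @param n_cells cells per image.
#' @param foci_per_cell Poisson mean focus count per cell.
#' @param focus_diameter_range_um (min, max) focus diameter in um; must lie
#'   within \[0.05, 1.0\].
#' @param focus_intensity,background_level,noise_sd grey-level parameters;
#'   `focus_intensity > background_level`.
#' @param gamma distortion exponent applied to the finished image (1 = none).
#' @param seed RNG seed for [simulate_images()].
#' @return an `image_sim_params` list.
#' @export
image_sim_params <- function(image_shape = c(256, 256), pixel_size_um = 0.05,
                             n_cells = 4, foci_per_cell = 6,
                             focus_diameter_range_um = c(0.1, 0.5),
                             focus_intensity = 20000,
                             background_level = 2000, noise_sd = 500,
                             gamma = 1, seed = 1L) {
  if (length(image_shape) != 2L || any(image_shape < 16)) {
    abort_param("`image_shape` must be two dimensions >= 16 pixels")
  }
  check_number(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  check_number(n_cells, "n_cells", lower = 1, integerish = TRUE)
  check_number(foci_per_cell, "foci_per_cell", lower = 0)
  if (length(focus_diameter_range_um) != 2L ||
      focus_diameter_range_um[1] > focus_diameter_range_um[2] ||
      focus_diameter_range_um[1] < 0.05 || focus_diameter_range_um[2] > 1.0) {
    abort_param("`focus_diameter_range_um` must be an increasing pair ",
                "within [0.05, 1.0]")
  }
  check_number(focus_intensity, "focus_intensity", lower = 0)
  check_number(background_level, "background_level", lower = 0)
  if (focus_intensity <= background_level) {
    abort_param("`focus_intensity` must exceed `background_level`")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(gamma, "gamma", lower = 0, strict_lower = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
                 foci_per_cell = foci_per_cell,
                 focus_diameter_range_um = focus_diameter_range_um,
                 focus_intensity = focus_intensity,
                 background_level = background_level, noise_sd = noise_sd,
                 gamma = gamma, seed = as.integer(seed)),
            class = "image_sim_params")
}

#' Simulate fluorescence images with ground-truth foci
#'
#' @param params an [image_sim_params()] object.
#' @param n_images number of images to generate.
#' @return list with
#'   \describe{
#'     \item{images}{list of integer matrices (16-bit range).}
#'     \item{masks}{list of labelled integer matrices (0 background,
#'       k = cell k), shared geometry across images.}
#'     \item{truth}{tibble: `image`, `cell`, `row`, `col` (centre, pixel
#'       units), `diameter_um`. Truth foci never overlap.}
#'   }
#' @export
#' @examples
#' sim <- simulate_images(image_sim_params(image_shape = c(64, 64),
#'                                         n_cells = 1, foci_per_cell = 2))
#' sim$truth
simulate_images <- function(params, n_images = 1) {
  if (!inherits(params, "image_sim_params")) {
    abort_param("`params` must come from image_sim_params()")
  }
  check_number(n_images, "n_images", lower = 1, integerish = TRUE)
  p <- params
  rng <- local_rng(p$seed)
  on.exit(rng())

  mask <- cell_grid_mask(p$image_shape, p$n_cells)
  images <- vector("list", n_images)
  truth <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    out <- render_image(p, mask)
    images[[i]] <- out$image
    if (nrow(out$truth) > 0) out$truth$image <- i
    truth[[i]] <- out$truth
  }
  truth <- dplyr::bind_rows(truth)
  if (nrow(truth) > 0) {
    truth <- truth[, c("image", "cell", "row", "col", "diameter_um")]
  } else {
    truth <- tibble::tibble(image = integer(), cell = integer(),
                            row = numeric(), col = numeric(),
                            diameter_um = numeric())
  }
  list(images = images, masks = rep(list(mask), n_images), truth = truth)
}

# labelled mask: cells are rectangles on a near-square grid, separated and
# bordered by 3 background pixels.
cell_grid_mask <- function(shape, n_cells) {
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  gap <- 3L
  cell_h <- (shape[1] - gap * (nrow_grid + 1)) %/% nrow_grid
  cell_w <- (shape[2] - gap * (ncol_grid + 1)) %/% ncol_grid
  if (cell_h < 8 || cell_w < 8) {
    abort_param("image too small for ", n_cells, " cells")
  }
  mask <- matrix(0L, shape[1], shape[2])
  k <- 0L
  for (r in seq_len(nrow_grid)) {
    for (cc in seq_len(ncol_grid)) {
      if (k >= n_cells) break
      k <- k + 1L
      r0 <- gap * r + cell_h * (r - 1L) + 1L
      c0 <- gap * cc + cell_w * (cc - 1L) + 1L
      mask[r0:(r0 + cell_h - 1L), c0:(c0 + cell_w - 1L)] <- k
    }
  }
  mask
}

render_image <- function(p, mask) {
  shape <- p$image_shape
  img <- matrix(0, shape[1], shape[2])
  truth <- list()
  placed <- NULL  # rows: row, col, radius_px
  max_tries <- 200L
  for (cell in seq_len(p$n_cells)) {
    n_foci <- rpois(1, p$foci_per_cell)
    if (n_foci == 0) next
    idx <- which(mask == cell, arr.ind = TRUE)
    rr <- range(idx[, 1]); cr <- range(idx[, 2])
    for (f in seq_len(n_foci)) {
      d_um <- runif(1, p$focus_diameter_range_um[1],
                    p$focus_diameter_range_um[2])
      rad_px <- d_um / 2 / p$pixel_size_um
      if (rr[1] + rad_px >= rr[2] - rad_px ||
          cr[1] + rad_px >= cr[2] - rad_px) {
        abort_param("infeasible focus packing: cell ", cell,
                    " is smaller than a focus")
      }
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cy <- runif(1, rr[1] + rad_px, rr[2] - rad_px)
        cx <- runif(1, cr[1] + rad_px, cr[2] - rad_px)
        if (is.null(placed) ||
            all((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2 >
                (placed[, 3] + rad_px + 1)^2)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort_param("infeasible focus packing: could not place focus ", f,
                    " in cell ", cell, " after ", max_tries, " tries")
      }
      placed <- rbind(placed, c(cy, cx, rad_px))
      img <- draw_disk(img, cy, cx, rad_px, p$focus_intensity)
      truth[[length(truth) + 1L]] <-
        tibble::tibble(cell = cell, row = cy, col = cx, diameter_um = d_um)
    }
  }
  img <- img + p$background_level +
    matrix(rnorm(length(img), 0, p$noise_sd), shape[1], shape[2])
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 65535)),
                shape[1], shape[2])
  img <- gamma_correct(img, p$gamma)
  list(image = img,
       truth = if (length(truth)) dplyr::bind_rows(truth) else
         tibble::tibble(cell = integer(), row = numeric(), col = numeric(),
                        diameter_um = numeric()))
}

# set pixels whose centre falls within the disk to `value`
draw_disk <- function(img, cy, cx, rad_px, value) {
  r <- ceiling(rad_px) + 1L
  rows <- max(1L, floor(cy) - r):min(nrow(img), ceiling(cy) + r)
  cols <- max(1L, floor(cx) - r):min(ncol(img), ceiling(cx) + r)
  sub <- outer((rows - cy)^2, (cols - cx)^2, `+`) <= rad_px^2
  img[rows, cols][sub] <- value
  img
}

#' Write / read images as TIFF
#'
#' 16-bit single-channel TIFF I/O for images and labelled masks (masks fit
#' comfortably in 16 bits). Values are integers in \[0, 65535\].
#'
#' @param image integer matrix.
#' @param path file path.
#' @return `read_image_tiff()` returns an integer matrix.
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}
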