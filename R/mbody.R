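# Foci ("M-body") quantification: gamma correction, control-calibrated
# percentile threshold, 8-connected component detection with a physical
# size gate, per-cell counting and group comparison.

#' Gamma-correct an integer image
#'
#' `output = max_value * (input / max_value)^gamma`, computed in floating
#' point and rounded back to the input's integer range. `gamma = 1` returns
#' the input unchanged. `max_value` defaults to the full 16-bit range.
#'
#' @param image integer matrix.
#' @param gamma exponent (> 0).
#' @param max_value top of the dynamic range (default 65535).
#' @return integer matrix of the same shape.
#' @export
#' @examples
#' gamma_correct(matrix(64L, 1, 1), gamma = 0.5, max_value = 255)  # -> 128
gamma_correct <- function(image, gamma, max_value = 65535) {
  check_number(gamma, "gamma", lower = 0, strict_lower = TRUE)
  if (gamma == 1) return(image)
  out <- round(max_value * (image / max_value)^gamma)
  storage.mode(out) <- "integer"
  out
}

#' Calibrate a detection threshold from control images
#'
#' For each control image the given percentile of all in-mask (cell) pixel
#' intensities is computed with linear interpolation between order
#' statistics ([stats::quantile()] type 7); the threshold is the arithmetic
#' mean of the per-image percentile values. Calibration is per experiment:
#' pass only one experiment's control images at a time.
#'
#' @param control_images list of integer matrices.
#' @param control_masks list of labelled masks aligned to the images; pixels
#'   with mask 0 are excluded. Pass `NULL` to use all pixels.
#' @param percentile calibration percentile in (0, 100); default 99.5.
#' @param experiment experiment identifier carried into the model.
#' @return a `threshold_model` list: `percentile`, `per_control_values`,
#'   `threshold`, `experiment`.
#' @export
calibrate_threshold <- function(control_images, control_masks = NULL,
                                percentile = 99.5, experiment = NA_character_) {
  if (!is.list(control_images)) control_images <- list(control_images)
  if (!is.null(control_masks) && !is.list(control_masks)) {
    control_masks <- list(control_masks)
  }
  if (length(control_images) == 0) {
    abort_param("calibration error: no control images",
                if (!is.na(experiment)) paste0(" for experiment ", experiment))
  }
  check_number(percentile, "percentile", lower = 0, upper = 100,
               strict_lower = TRUE)
  if (percentile >= 100) abort_param("`percentile` must be < 100")
  vals <- vapply(seq_along(control_images), function(i) {
    img <- control_images[[i]]
    px <- if (is.null(control_masks)) as.numeric(img) else {
      if (!all(dim(img) == dim(control_masks[[i]]))) {
        abort_param("image/mask shape mismatch in control image ", i)
      }
      as.numeric(img[control_masks[[i]] > 0])
    }
    unname(quantile(px, percentile / 100, type = 7))
  }, 0)
  structure(list(percentile = percentile, per_control_values = vals,
                 threshold = mean(vals), experiment = experiment),
            class = "threshold_model")
}

#' Label 8-connected foreground components
#'
#' Connected-component labelling of a logical matrix under 8-connectivity
#' (edge or corner adjacency). Components are numbered 1..k in raster order
#' of their first pixel.
#'
#' @param binary logical matrix.
#' @return integer matrix; 0 is background.
#' @export
label_components <- function(binary) {
  stopifnot(is.matrix(binary))
  nr <- nrow(binary)
  nc <- ncol(binary)
  fg <- which(binary)
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0) return(lab)
  pos <- match(seq_len(nr * nc), fg)  # linear index -> vertex id (NA if bg)
  row_i <- ((fg - 1L) %% nr) + 1L
  edges <- list()
  # neighbour offsets covering all 8-adjacencies once: down, right,
  # down-right, up-right (column-major linear indexing)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    keep <- row_i + dr >= 1L & row_i + dr <= nr
    nb <- fg[keep] + dr + dc * nr
    keep2 <- nb >= 1L & nb <= nr * nc
    from <- pos[fg[keep][keep2]]
    to <- pos[nb[keep2]]
    has <- !is.na(to)
    if (any(has)) edges[[length(edges) + 1L]] <- cbind(from[has], to[has])
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, c(edges, list(cbind(
    seq_along(fg), seq_along(fg))))), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber in raster (column-major) order of first appearance
  first <- !duplicated(comp)
  renum <- integer(max(comp))
  renum[comp[first]] <- seq_len(sum(first))
  lab[fg] <- renum[comp]
  lab
}

#' Detect size-gated foci in one image
#'
#' Pixels strictly above `threshold` form the binary map; 8-connected
#' components are measured, assigned to the cell containing their centroid
#' (nearest pixel; centroids on background are discarded), and kept when
#' their equivalent diameter `2 * sqrt(area_px * pixel_size_um^2 / pi)` lies
#' inside the inclusive gate.
#'
#' @param image integer matrix (already gamma-corrected if desired).
#' @param mask labelled cell mask aligned to `image`.
#' @param threshold intensity threshold (strict `>`).
#' @param size_gate_um inclusive (min, max) equivalent diameter in um;
#'   default 0.1–0.5, the reported M-body size range.
#' @param pixel_size_um physical pixel size.
#' @return tibble, one row per focus: `cell`, `area_px`, `diameter_um`,
#'   `centroid_row`, `centroid_col`, `mean_intensity`.
#' @export
detect_foci <- function(image, mask, threshold,
                        size_gate_um = c(0.1, 0.5), pixel_size_um = 0.05) {
  if (!all(dim(image) == dim(mask))) {
    abort_param("image and mask shapes differ")
  }
  check_number(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  if (length(size_gate_um) != 2L || size_gate_um[1] > size_gate_um[2]) {
    abort_param("`size_gate_um` must be an increasing pair")
  }
  empty <- tibble::tibble(cell = integer(), area_px = integer(),
                          diameter_um = numeric(), centroid_row = numeric(),
                          centroid_col = numeric(), mean_intensity = numeric())
  lab <- label_components(image > threshold)
  k <- max(lab)
  if (k == 0) return(empty)
  fg <- which(lab > 0)
  l <- lab[fg]
  rows <- ((fg - 1L) %% nrow(image)) + 1L
  cols <- ((fg - 1L) %/% nrow(image)) + 1L
  area <- tabulate(l, k)
  cr <- rowsum(rows, l)[, 1] / area
  cc <- rowsum(cols, l)[, 1] / area
  mi <- rowsum(as.numeric(image[fg]), l)[, 1] / area
  diam <- 2 * sqrt(area * pixel_size_um^2 / pi)
  cell <- mask[cbind(pmin(pmax(floor(cr + 0.5), 1), nrow(mask)),
                     pmin(pmax(floor(cc + 0.5), 1), ncol(mask)))]
  keep <- cell > 0 & diam >= size_gate_um[1] & diam <= size_gate_um[2]
  tibble::tibble(cell = as.integer(cell), area_px = as.integer(area),
                 diameter_um = diam, centroid_row = cr, centroid_col = cc,
                 mean_intensity = mi)[keep, ]
}

#' Per-cell focus counts
#'
#' Counts detected foci per cell, including zero rows for cells present in
#' the mask but without foci.
#'
#' @param foci tibble from [detect_foci()].
#' @param mask labelled mask (defines the full cell set).
#' @return tibble: `cell`, `n_foci`.
#' @export
count_foci_per_cell <- function(foci, mask) {
  cells <- sort(unique(mask[mask > 0]))
  n <- vapply(cells, function(k) sum(foci$cell == k), 0L)
  tibble::tibble(cell = as.integer(cells), n_foci = n)
}

#' Run the foci-quantification pipeline on an image set
#'
#' For each experiment: gamma-correct all images, calibrate the threshold on
#' that experiment's control images ([calibrate_threshold()]), detect and
#' size-gate foci in every image (controls included), count per cell, and
#' compare per-cell counts between conditions with [compare_groups()].
#'
#' @param images,masks lists of integer matrices, parallel to `design`.
#' @param design tibble: `image` (index into the lists), `experiment`,
#'   `condition`, `is_control` (logical).
#' @param percentile calibration percentile (default 99.5).
#' @param gamma gamma-correction exponent (default 1, none).
#' @param size_gate_um inclusive diameter gate in um.
#' @param pixel_size_um physical pixel size.
#' @return list: `foci` (focus level), `cells` (per-cell counts with design
#'   columns), `thresholds` (per-experiment model summaries), `groups`
#'   (output of [compare_groups()] on per-cell counts by condition).
#' @export
run_mbody <- function(images, masks, design, percentile = 99.5, gamma = 1,
                      size_gate_um = c(0.1, 0.5), pixel_size_um = 0.05) {
  stopifnot(length(images) == nrow(design), length(masks) == nrow(design))
  images <- lapply(images, gamma_correct, gamma = gamma)
  foci_all <- list()
  cells_all <- list()
  thr_all <- list()
  for (exp_id in unique(design$experiment)) {
    rows <- which(design$experiment == exp_id)
    ctrl <- rows[design$is_control[rows]]
    if (length(ctrl) == 0) {
      abort_param("calibration error: no control images for experiment ",
                  exp_id)
    }
    model <- calibrate_threshold(images[ctrl], masks[ctrl],
                                 percentile = percentile,
                                 experiment = as.character(exp_id))
    thr_all[[length(thr_all) + 1L]] <- tibble::tibble(
      experiment = as.character(exp_id), percentile = percentile,
      threshold = model$threshold,
      n_controls = length(model$per_control_values))
    for (i in rows) {
      f <- detect_foci(images[[i]], masks[[i]], model$threshold,
                       size_gate_um, pixel_size_um)
      f$image <- design$image[i]
      f$condition <- design$condition[i]
      foci_all[[length(foci_all) + 1L]] <- f
      ct <- count_foci_per_cell(f, masks[[i]])
      ct$image <- design$image[i]
      ct$condition <- design$condition[i]
      cells_all[[length(cells_all) + 1L]] <- ct
    }
  }
  cells <- dplyr::bind_rows(cells_all)
  groups <- if (length(unique(cells$condition)) >= 2) {
    compare_groups(cells$n_foci, cells$condition)
  } else NULL
  list(foci = dplyr::bind_rows(foci_all), cells = cells,
       thresholds = dplyr::bind_rows(thr_all), groups = groups)
}
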