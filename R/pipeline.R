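# End-to-end synthetic demonstration run: simulate all three input kinds,
# run all three analysis stages, and write a self-describing run directory
# (config echo, every table as TSV, manifest with checksums).

#' Run the full pipeline on synthetic data
#'
#' Simulates a screen table, an image set and a crosslink table with the
#' given per-stage parameter objects, runs [screen_stats()], [run_mbody()]
#' and [run_clip()], and writes every documented output plus a `config.yaml`
#' echo and a `manifest.tsv` (file, md5 checksum) into `out_dir`. All
#' randomness flows from `seed`, expanded into per-stage generator seeds, so
#' the same call twice produces byte-identical outputs.
#'
#' @param out_dir output directory (created; must be empty or absent).
#' @param seed top-level seed.
#' @param screen_params,image_params,clip_params per-stage generator
#'   parameter objects; their `seed` fields are overridden from `seed`.
#' @param alpha,d_min screen classification thresholds.
#' @param percentile,size_gate_um foci-stage parameters.
#' @return invisibly, the manifest tibble.
#' @export
#' @examples
#' \donttest{
#' dir <- file.path(tempdir(), "xlink-demo")
#' run_demo(dir, seed = 1,
#'          screen_params = screen_sim_params(n_background = 100))
#' }
run_demo <- function(out_dir, seed = 1,
                     screen_params = screen_sim_params(),
                     image_params = image_sim_params(),
                     clip_params = clip_sim_params(),
                     alpha = 0.05, d_min = 1,
                     percentile = 99.5, size_gate_um = c(0.1, 0.5)) {
  if (missing(out_dir) || is.null(out_dir) || !nzchar(out_dir)) {
    abort_param("config error: `out_dir` is required")
  }
  check_number(seed, "seed", integerish = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  screen_params$seed <- as.integer(seed * 3L + 1L)
  image_params$seed <- as.integer(seed * 3L + 2L)
  clip_params$seed <- as.integer(seed * 3L + 3L)

  config <- list(seed = seed, alpha = alpha, d_min = d_min,
                 percentile = percentile, size_gate_um = size_gate_um,
                 screen_params = unclass(screen_params),
                 image_params = unclass(image_params),
                 clip_params = list(
                   ref_length = clip_params$ref_length,
                   reference = clip_params$reference,
                   background_rate = clip_params$background_rate,
                   library_size_jitter = clip_params$library_size_jitter,
                   n_reps = clip_params$n_reps,
                   conditions = clip_params$conditions,
                   conserve_total = clip_params$conserve_total,
                   seed = clip_params$seed))
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))

  # stage 1: screen
  scr <- simulate_screen(screen_params)
  write_tsv_file(scr$intensities, file.path(out_dir, "screen_intensities.tsv"))
  write_tsv_file(scr$design, file.path(out_dir, "screen_design.tsv"))
  write_tsv_file(scr$truth, file.path(out_dir, "screen_truth.tsv"))
  res <- screen_stats(scr$intensities, alpha = alpha, d_min = d_min)
  write_screen_result(res, out_dir)

  # stage 2: foci
  img <- simulate_images(image_params, n_images = 3)
  for (i in seq_along(img$images)) {
    write_image_tiff(img$images[[i]],
                     file.path(out_dir, sprintf("image_%02d.tif", i)))
    write_image_tiff(img$masks[[i]],
                     file.path(out_dir, sprintf("mask_%02d.tif", i)))
  }
  write_tsv_file(img$truth, file.path(out_dir, "foci_truth.tsv"))
  design <- tibble::tibble(image = seq_along(img$images), experiment = "E1",
                           condition = "control", is_control = TRUE)
  mb <- run_mbody(img$images, img$masks, design, percentile = percentile,
                  size_gate_um = size_gate_um,
                  pixel_size_um = image_params$pixel_size_um)
  write_tsv_file(mb$foci, file.path(out_dir, "foci.tsv"))
  write_tsv_file(mb$cells, file.path(out_dir, "foci_per_cell.tsv"))
  write_tsv_file(mb$thresholds, file.path(out_dir, "foci_thresholds.tsv"))

  # stage 3: iCLIP
  clip <- simulate_crosslinks(clip_params)
  write_tsv_file(clip$crosslinks, file.path(out_dir, "crosslinks.tsv"))
  write_tsv_file(clip$design, file.path(out_dir, "crosslink_design.tsv"))
  write_tsv_file(clip$truth, file.path(out_dir, "crosslink_truth.tsv"))
  cl <- run_clip(clip$crosslinks, clip$design, clip_params$reference,
                 clip_params$ref_length,
                 conditions = clip_params$conditions[1:2])
  write_tsv_file(cl$condition_profiles,
                 file.path(out_dir, "metaprofile_condition.tsv"))
  write_tsv_file(cl$windows, file.path(out_dir, "window_comparison.tsv"))
  prof_long <- tibble::as_tibble(as.data.frame.table(
    cl$normalized, responseName = "normalized"))
  names(prof_long)[1:2] <- c("sample", "position")
  prof_long$position <- as.integer(prof_long$position)
  prof_long$smoothed <- as.vector(cl$smoothed)
  write_tsv_file(prof_long, file.path(out_dir, "metaprofile_samples.tsv"))

  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- setdiff(files, "manifest.tsv")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  write_tsv_file(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}
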