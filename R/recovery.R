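# Parameter-recovery simulations: run a generator with known truth, push
# the data through the corresponding analysis stage, and measure what comes
# back. These drive the package's calibration checks and the acceptance
# script.

#' Recovery of the mitotic ES3SB fold change
#'
#' Repeatedly simulates crosslink tables ([simulate_crosslinks()]), runs
#' [normalize_profile()] and [quantify_windows()], and records the recovered
#' fold change and Welch p for one window per simulated dataset. With the
#' default generator the injected ES3SB truth is the published 3.5-fold
#' mitotic gain, so the mean recovered fold over many simulations estimates
#' how faithfully the pipeline returns that number.
#'
#' @param n_sims number of simulated datasets.
#' @param seed base seed; dataset i uses `seed + i`.
#' @param params a [clip_sim_params()] template; its `seed` is overridden
#'   per dataset.
#' @param window window name to extract (default `"ES3SB"`).
#' @return tibble: `sim`, `fold_change`, `p`.
#' @export
#' @examples
#' rec <- es3sb_recovery(n_sims = 5, seed = 1)
#' mean(rec$fold_change)
es3sb_recovery <- function(n_sims = 100, seed = 1,
                           params = clip_sim_params(), window = "ES3SB") {
  check_number(n_sims, "n_sims", lower = 1, integerish = TRUE)
  wins <- default_windows()
  out <- lapply(seq_len(n_sims), function(i) {
    params$seed <- as.integer(seed + i)
    sim <- simulate_crosslinks(params)
    norm <- normalize_profile(sim$crosslinks, params$reference,
                              params$ref_length)
    q <- quantify_windows(norm, sim$design, wins,
                          conditions = params$conditions[1:2])
    row <- q[q$window == window, ]
    tibble::tibble(sim = i, fold_change = row$fold_change, p = row$p)
  })
  dplyr::bind_rows(out)
}

#' Recovery of spiked substrates in the screen
#'
#' Repeatedly simulates a screen table with known spiked substrates
#' ([simulate_screen()]), runs [screen_stats()], and records how many spiked
#' proteins were classed blue and how many background proteins were (the
#' false-positive side).
#'
#' @param n_seeds number of simulated screens.
#' @param seed base seed; screen i uses `seed + i`.
#' @param params a [screen_sim_params()] template; `seed` overridden per
#'   screen.
#' @param alpha,d_min classification thresholds (see [screen_stats()]).
#' @return tibble: `sim`, `n_spiked`, `spiked_blue`, `background_blue`,
#'   `n_background_tested`.
#' @export
screen_recovery <- function(n_seeds = 100, seed = 1,
                            params = screen_sim_params(),
                            alpha = 0.05, d_min = 1) {
  check_number(n_seeds, "n_seeds", lower = 1, integerish = TRUE)
  out <- lapply(seq_len(n_seeds), function(i) {
    params$seed <- as.integer(seed + i)
    sim <- simulate_screen(params)
    res <- screen_stats(sim$intensities, alpha = alpha, d_min = d_min)
    res <- dplyr::left_join(res, sim$truth, by = "protein")
    tibble::tibble(
      sim = i,
      n_spiked = sum(res$spiked),
      spiked_blue = sum(res$spiked & res$class == "blue"),
      background_blue = sum(!res$spiked & res$class == "blue"),
      n_background_tested = sum(!res$spiked & res$class != "untested"))
  })
  dplyr::bind_rows(out)
}

#' In-silico treated-vs-untreated foci experiment
#'
#' Simulates one experiment per run: foci-free calibration control images
#' (emulating a condition without foci, which is what a percentile
#' calibration needs), untreated images with `untreated_foci` expected foci
#' per cell, and treated images whose expectation is reduced
#' `fold_reduction`-fold. All images go through [run_mbody()] — the
#' threshold calibrated on the controls, every image thresholded, counted
#' and size-gated — and the untreated-vs-treated p-value on per-cell counts
#' is recorded (Tukey-adjusted, since the control condition makes three
#' groups). Defaults give 15 cells per counted condition, the per-condition
#' cell count used in the study's foci comparisons.
#'
#' @param n_runs number of simulated experiments.
#' @param seed base seed; run i derives its image seeds from `seed + i`.
#' @param untreated_foci expected foci per cell in the untreated condition.
#' @param fold_reduction treated expectation = `untreated_foci /
#'   fold_reduction`.
#' @param n_images images per counted condition (2 extra calibration images
#'   are always generated); with the default 5-cell images, 3 images per
#'   condition give 15 cells.
#' @param params an [image_sim_params()] template (its `foci_per_cell` and
#'   `seed` are overridden).
#' @return tibble: `run`, `mean_untreated`, `mean_treated`, `p`.
#' @export
mbody_treatment_experiment <- function(n_runs = 100, seed = 1,
                                       untreated_foci = 6, fold_reduction = 3,
                                       n_images = 3,
                                       params = image_sim_params(n_cells = 5)) {
  check_number(n_runs, "n_runs", lower = 1, integerish = TRUE)
  check_number(fold_reduction, "fold_reduction", lower = 0,
               strict_lower = TRUE)
  out <- lapply(seq_len(n_runs), function(i) {
    params$foci_per_cell <- 0
    params$seed <- as.integer(seed + 3L * i)
    ctrl <- simulate_images(params, n_images = 2)
    params$foci_per_cell <- untreated_foci
    params$seed <- as.integer(seed + 3L * i + 1L)
    unt <- simulate_images(params, n_images = n_images)
    params$foci_per_cell <- untreated_foci / fold_reduction
    params$seed <- as.integer(seed + 3L * i + 2L)
    trt <- simulate_images(params, n_images = n_images)
    design <- tibble::tibble(
      image = seq_len(2L + 2L * n_images),
      experiment = "E1",
      condition = c(rep("control", 2L), rep("untreated", n_images),
                    rep("treated", n_images)),
      is_control = c(rep(TRUE, 2L), rep(FALSE, 2L * n_images)))
    res <- run_mbody(c(ctrl$images, unt$images, trt$images),
                     c(ctrl$masks, unt$masks, trt$masks),
                     design, pixel_size_um = params$pixel_size_um)
    s <- res$groups$summary
    cmp <- res$groups$comparisons
    pick <- grepl("untreated", cmp$comparison) & grepl("treated", cmp$comparison)
    tibble::tibble(run = i,
                   mean_untreated = s$mean[s$condition == "untreated"],
                   mean_treated = s$mean[s$condition == "treated"],
                   p = cmp$p[pick & !grepl("control", cmp$comparison)][1])
  })
  dplyr::bind_rows(out)
}
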