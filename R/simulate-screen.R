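# Synthetic dual-crosslinker screen tables with known spiked substrates.

#' Parameters for the synthetic screen generator
#'
#' Describes a replicated label-free intensity table for the dual
#' photocrosslinker pulldown design: two crosslinker conditions (AbK,
#' DiZASeC) x two fractions (released by cleavage, retained on resin) x
#' `n_reps` replicates. True substrates ("spiked" proteins) are enriched by
#' `release_effect` log2 units in the (DiZASeC, released) groups and,
#' mirrored, in the (AbK, resin) groups: a cleavable crosslinker releases its
#' trapped partners while a non-cleavable one keeps them on the resin.
#'
#' The background proteome size and intensity scale of the original screen
#' are not published; `n_background`, `base_log_mean` and `base_log_sd`
#' defaults are placeholders chosen to look like a typical label-free
#' experiment (about a thousand quantified proteins, log2 intensities in the
#' mid-20s) and should be set by the user when emulating a specific dataset.
#'
#' @param n_background number of non-substrate proteins.
#' @param n_spiked number of true substrates; must be <= `n_background / 10`.
#' @param n_reps replicates per condition x fraction.
#' @param base_log_mean,base_log_sd mean and SD of the per-protein baseline
#'   log2 intensity (shared across all groups of that protein).
#' @param release_effect log2 enrichment of spiked proteins (>= 0).
#' @param noise_sd replicate noise SD (log2 units).
#' @param missing_rate fraction of values dropped completely at random,
#'   in \[0, 1).
#' @param seed RNG seed for [simulate_screen()].
#' @return a `screen_sim_params` list.
#' @export
screen_sim_params <- function(n_background = 1000, n_spiked = 5, n_reps = 3,
                              base_log_mean = 25, base_log_sd = 2,
                              release_effect = 2, noise_sd = 0.5,
                              missing_rate = 0, seed = 1L) {
  check_number(n_background, "n_background", lower = 1, integerish = TRUE)
  check_number(n_spiked, "n_spiked", lower = 0, integerish = TRUE)
  if (n_spiked > n_background / 10) {
    abort_param("`n_spiked` must be <= n_background/10")
  }
  check_number(n_reps, "n_reps", lower = 2, integerish = TRUE)
  check_number(base_log_mean, "base_log_mean")
  check_number(base_log_sd, "base_log_sd", lower = 0)
  check_number(release_effect, "release_effect", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(missing_rate, "missing_rate", lower = 0, upper = 1)
  if (missing_rate >= 1) abort_param("`missing_rate` must be < 1")
  check_number(seed, "seed", integerish = TRUE)
  structure(list(n_background = n_background, n_spiked = n_spiked,
                 n_reps = n_reps, base_log_mean = base_log_mean,
                 base_log_sd = base_log_sd, release_effect = release_effect,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "screen_sim_params")
}

#' Simulate a dual-crosslinker screen intensity table
#'
#' Draws a per-protein baseline log2 intensity from
#' `N(base_log_mean, base_log_sd)`, adds `release_effect` for spiked proteins
#' in the (DiZASeC, released) and (AbK, resin) groups, adds replicate noise
#' `N(0, noise_sd)`, and finally blanks values completely at random at
#' `missing_rate`. The generator uses one local RNG stream seeded from
#' `params$seed`; the caller's RNG state is untouched.
#'
#' @param params a [screen_sim_params()] object.
#' @return list with
#'   \describe{
#'     \item{intensities}{long tibble: `protein`, `sample`, `condition`
#'       (AbK/DiZASeC), `fraction` (released/resin), `replicate`,
#'       `log2_intensity` (NA where missing).}
#'     \item{design}{tibble: `sample`, `condition`, `fraction`, `replicate`.}
#'     \item{truth}{tibble: `protein`, `spiked` (logical).}
#'   }
#' @export
#' @examples
#' sim <- simulate_screen(screen_sim_params(n_background = 50, n_spiked = 3))
#' head(sim$intensities)
simulate_screen <- function(params) {
  if (!inherits(params, "screen_sim_params")) {
    abort_param("`params` must come from screen_sim_params()")
  }
  p <- params
  rng <- local_rng(p$seed)
  on.exit(rng())

  n_prot <- p$n_background + p$n_spiked
  proteins <- sprintf("P%04d", seq_len(n_prot))
  # spiked ids scattered through the table, not a prefix
  spiked <- rep(FALSE, n_prot)
  spiked[sample.int(n_prot, p$n_spiked)] <- TRUE

  design <- tidyr::expand_grid(condition = c("AbK", "DiZASeC"),
                               fraction = c("released", "resin"),
                               replicate = seq_len(p$n_reps))
  design$sample <- with(design, paste(condition, fraction, replicate, sep = "_"))
  design <- design[, c("sample", "condition", "fraction", "replicate")]

  base <- rnorm(n_prot, p$base_log_mean, p$base_log_sd)
  long <- tidyr::expand_grid(protein = proteins, sample = design$sample)
  long <- dplyr::left_join(long, design, by = "sample")
  long$log2_intensity <- base[match(long$protein, proteins)] +
    rnorm(nrow(long), 0, p$noise_sd)
  enriched <- spiked[match(long$protein, proteins)] &
    ((long$condition == "DiZASeC" & long$fraction == "released") |
     (long$condition == "AbK" & long$fraction == "resin"))
  long$log2_intensity <- long$log2_intensity + enriched * p$release_effect
  if (p$missing_rate > 0) {
    drop <- runif(nrow(long)) < p$missing_rate
    long$log2_intensity[drop] <- NA_real_
  }
  list(intensities = tibble::as_tibble(long),
       design = tibble::as_tibble(design),
       truth = tibble::tibble(protein = proteins, spiked = spiked))
}

# Run `expr`-less scoped RNG: seeds a private stream, returns a restorer.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
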