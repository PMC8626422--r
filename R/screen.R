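# Dual-crosslinker screen statistics: per-protein Welch tests in the
# released and resin-retained fractions, two stacked volcano plots, and
# quadrant hit classing.
#
# The screen contrasts a cleavable (DiZASeC) and a non-cleavable (AbK)
# photocrosslinker: a genuine substrate trapped by the bait is *released*
# from the resin when the DiZASeC crosslink is cleaved, and conversely stays
# on the resin in the AbK arm. A hit therefore shows up twice, with opposite
# signs: DiZASeC-enriched among released proteins (negative Welch
# difference, upper-left of the released volcano) and AbK-enriched among
# resin-retained proteins (positive difference, lower-right of the inverted
# resin volcano). That dual signature is the "blue" class; "green" marks
# DiZASeC enrichment on the resin only; everything else is "grey".

#' Filter an intensity table to reliably quantified proteins
#'
#' A protein is testable only if every (condition, fraction) group retains at
#' least `min_reps` observed (non-missing, finite) values. Others are marked
#' untested and excluded from testing; an exclusion report is returned.
#'
#' @param intensities long tibble as produced by [simulate_screen()]:
#'   columns `protein`, `condition`, `fraction`, `replicate`,
#'   `log2_intensity`.
#' @param min_reps minimum observed replicates per group (>= 2).
#' @return list with `intensities` (rows of testable proteins only),
#'   `untested` (tibble: `protein`, `min_observed` = the smallest per-group
#'   count that disqualified it).
#' @export
filter_quantified <- function(intensities, min_reps = 2) {
  check_number(min_reps, "min_reps", lower = 2, integerish = TRUE)
  if (nrow(intensities) == 0) abort_param("empty intensity table")
  counts <- dplyr::summarise(
    dplyr::group_by(intensities, .data$protein, .data$condition, .data$fraction),
    n_obs = sum(is.finite(.data$log2_intensity)), .groups = "drop")
  worst <- dplyr::summarise(dplyr::group_by(counts, .data$protein),
                            min_observed = min(.data$n_obs), .groups = "drop")
  bad <- worst[worst$min_observed < min_reps, ]
  list(intensities = intensities[!intensities$protein %in% bad$protein, ],
       untested = bad)
}

#' Per-protein screen statistics and quadrant classification
#'
#' Runs, for every testable protein, a Welch test of AbK vs DiZASeC log2
#' intensities separately in the released and the resin-retained fraction
#' (difference = mean(AbK) - mean(DiZASeC), so DiZASeC enrichment is
#' negative), attaches volcano coordinates (`released_y = -log10 p`;
#' `resin_y = +log10 p`, the inverted lower plot), Benjamini-Hochberg
#' q-values (reported, never used for classing), the quadrant class and the
#' ranking score `welch_score = -released difference`.
#'
#' @param intensities long intensity tibble (see [filter_quantified()]).
#' @param alpha significance threshold on the raw Welch p (default 0.05).
#' @param d_min minimum absolute log2 difference for a call (default 1).
#' @param min_reps passed to [filter_quantified()].
#' @return tibble, one row per protein (untested proteins carry NA statistics
#'   and class `"untested"`): `protein`, `released_difference`, `released_t`,
#'   `released_df`, `released_p`, `released_q`, `released_y`, the same six
#'   for `resin`, `class`, `welch_score`. `alpha` and `d_min` are attached
#'   as attributes and echoed by [write_screen_result()].
#' @export
#' @examples
#' sim <- simulate_screen(screen_sim_params(n_background = 60, n_spiked = 4))
#' res <- screen_stats(sim$intensities)
#' table(res$class)
screen_stats <- function(intensities, alpha = 0.05, d_min = 1,
                         min_reps = 2) {
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(d_min, "d_min", lower = 0)
  flt <- filter_quantified(intensities, min_reps)
  tested <- flt$intensities
  proteins <- sort(unique(intensities$protein))

  stats_for <- function(frac) {
    sub <- tested[tested$fraction == frac, ]
    a <- values_matrix(sub[sub$condition == "AbK", ], proteins)
    b <- values_matrix(sub[sub$condition == "DiZASeC", ], proteins)
    row_welch(a, b)
  }
  rel <- stats_for("released")
  res <- stats_for("resin")

  out <- tibble::tibble(
    protein = proteins,
    released_difference = rel$difference,
    released_t = rel$t, released_df = rel$df, released_p = rel$p,
    released_q = p.adjust(rel$p, method = "BH"),
    released_y = -log10(rel$p),
    resin_difference = res$difference,
    resin_t = res$t, resin_df = res$df, resin_p = res$p,
    resin_q = p.adjust(res$p, method = "BH"),
    resin_y = log10(res$p)
  )
  out$class <- classify_quadrants(
    released_difference = out$released_difference, released_p = out$released_p,
    resin_difference = out$resin_difference, resin_p = out$resin_p,
    alpha = alpha, d_min = d_min)
  out$welch_score <- -out$released_difference
  attr(out, "alpha") <- alpha
  attr(out, "d_min") <- d_min
  out
}

# proteins x replicates value matrix for one condition/fraction cell;
# proteins absent from `sub` become all-NA rows (-> untested).
values_matrix <- function(sub, proteins) {
  reps <- sort(unique(sub$replicate))
  m <- matrix(NA_real_, length(proteins), max(length(reps), 2L),
              dimnames = list(proteins, NULL))
  m[cbind(match(sub$protein, proteins), match(sub$replicate, reps))] <-
    sub$log2_intensity
  m
}

#' Quadrant classification of screen hits
#'
#' Vectorized rule behind the volcano colour classes:
#' \describe{
#'   \item{blue}{released p < alpha and released difference < -d_min
#'     (DiZASeC-enriched when released) AND resin p < alpha and resin
#'     difference > +d_min (AbK-enriched on the resin).}
#'   \item{green}{not blue, resin p < alpha and resin difference < -d_min
#'     (DiZASeC-enriched on the resin).}
#'   \item{grey}{tested, neither of the above.}
#'   \item{untested}{any NA statistic.}
#' }
#'
#' @param released_difference,released_p,resin_difference,resin_p numeric
#'   vectors of per-protein Welch statistics.
#' @param alpha,d_min classification thresholds.
#' @return character vector of classes.
#' @export
classify_quadrants <- function(released_difference, released_p,
                               resin_difference, resin_p,
                               alpha = 0.05, d_min = 1) {
  blue <- released_p < alpha & released_difference < -d_min &
    resin_p < alpha & resin_difference > d_min
  green <- !blue & resin_p < alpha & resin_difference < -d_min
  cls <- ifelse(blue, "blue", ifelse(green, "green", "grey"))
  cls[is.na(blue) | is.na(green)] <- "untested"
  cls
}

#' Ranked hit list
#'
#' Blue and green hits ordered by decreasing `welch_score` (the magnitude of
#' DiZASeC enrichment in the released fraction); ties broken
#' lexicographically by protein identifier so ranking is deterministic.
#'
#' @param result tibble from [screen_stats()].
#' @return tibble of hits with a `rank` column.
#' @export
rank_hits <- function(result) {
  hits <- result[result$class %in% c("blue", "green"), ]
  hits <- hits[order(-hits$welch_score, hits$protein), ]
  hits$rank <- seq_len(nrow(hits))
  hits[, c("rank", "protein", "class", "welch_score",
           "released_difference", "released_p",
           "resin_difference", "resin_p")]
}

#' Write screen outputs
#'
#' Writes the full per-protein result, per-plot volcano coordinate tables and
#' the ranked hit list as TSV into `dir`. The thresholds used for classing
#' are echoed in `screen_params.tsv` so every report is self-describing.
#'
#' @param result tibble from [screen_stats()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_screen_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    result = file.path(dir, "screen_result.tsv"),
    volcano_released = file.path(dir, "volcano_released.tsv"),
    volcano_resin = file.path(dir, "volcano_resin.tsv"),
    hits = file.path(dir, "screen_hits.tsv"),
    params = file.path(dir, "screen_params.tsv")
  )
  write_tsv_file(result, paths["result"])
  write_tsv_file(
    result[, c("protein", "released_difference", "released_y", "class")],
    paths["volcano_released"])
  write_tsv_file(
    result[, c("protein", "resin_difference", "resin_y", "class")],
    paths["volcano_resin"])
  write_tsv_file(rank_hits(result), paths["hits"])
  write_tsv_file(tibble::tibble(parameter = c("alpha", "d_min"),
                                value = c(attr(result, "alpha"),
                                          attr(result, "d_min"))),
                 paths["params"])
  invisible(paths)
}
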