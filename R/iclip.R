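# iCLIP crosslink-profile analysis on rRNA: UMI collapse, RNA-type
# proportions, per-sample depth normalization, Gaussian metaprofile
# smoothing, expansion-segment window quantification and condition
# comparison.

#' Collapse PCR duplicates by UMI
#'
#' Reads sharing (sample, reference, position, UMI) are one crosslink event;
#' distinct UMIs at a position sum. Collapse is exact-match only (no
#' edit-distance clustering).
#'
#' @param reads tibble: `sample`, `reference`, `position`, `umi`. UMIs must
#'   use only the characters A, C, G, T, N.
#' @return crosslink tibble: `sample`, `reference`, `position`, `count`.
#' @export
#' @examples
#' reads <- tibble::tibble(sample = "s1", reference = "18S", position = 527,
#'                         umi = c("AAAA", "AAAA", "CCCC"))
#' umi_collapse(reads)  # count 2
umi_collapse <- function(reads) {
  bad <- grepl("[^ACGTN]", reads$umi)
  if (any(bad)) {
    abort_param("malformed UMIs (characters outside A/C/G/T/N) in rows: ",
                paste(utils::head(which(bad), 10), collapse = ", "),
                if (sum(bad) > 10) " ..." else "")
  }
  events <- dplyr::distinct(reads, .data$sample, .data$reference,
                            .data$position, .data$umi)
  out <- dplyr::summarise(
    dplyr::group_by(events, .data$sample, .data$reference, .data$position),
    count = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, .data$sample, .data$reference, .data$position)
}

#' Per-sample RNA-subtype proportions with condition comparison
#'
#' Computes, per sample, the proportion of reads assigned to each RNA
#' subtype (assignment happens upstream), the per-condition mean and SD of
#' those proportions, and a Welch test per subtype between two chosen
#' conditions. Samples with zero reads are excluded with a warning.
#'
#' @param assignments tibble: `sample`, `subtype`, and optionally `n`
#'   (aggregated read counts; defaults to one read per row).
#' @param design tibble mapping `sample` to a condition column.
#' @param condition_col name of the condition column in `design`.
#' @param compare length-2 character naming the conditions to test per
#'   subtype; `NULL` (default) skips the tests and returns proportions and
#'   condition summaries only.
#' @return list: `proportions` (sample x subtype long tibble, proportions
#'   summing to 1 per sample), `condition_summary` (mean, sd per condition x
#'   subtype), `tests` (per-subtype Welch results, NULL if skipped).
#' @export
rna_type_summary <- function(assignments, design, condition_col = "cycle",
                             compare = NULL) {
  if (!"n" %in% names(assignments)) assignments$n <- 1L
  counts <- dplyr::summarise(
    dplyr::group_by(assignments, .data$sample, .data$subtype),
    n = sum(.data$n), .groups = "drop")
  totals <- dplyr::summarise(dplyr::group_by(counts, .data$sample),
                             total = sum(.data$n), .groups = "drop")
  zero <- totals$sample[totals$total == 0]
  if (length(zero) > 0) {
    warning("samples with zero reads excluded: ",
            paste(zero, collapse = ", "), call. = FALSE)
    counts <- counts[!counts$sample %in% zero, ]
    totals <- totals[!totals$sample %in% zero, ]
  }
  # complete the sample x subtype grid so absent subtypes are proportion 0
  grid <- tidyr::expand_grid(sample = unique(counts$sample),
                             subtype = unique(counts$subtype))
  props <- dplyr::left_join(grid, counts, by = c("sample", "subtype"))
  props$n[is.na(props$n)] <- 0L
  props <- dplyr::left_join(props, totals, by = "sample")
  props$proportion <- props$n / props$total
  props <- dplyr::left_join(props,
                            design[, c("sample", condition_col)],
                            by = "sample")
  names(props)[names(props) == condition_col] <- "condition"

  cond_summary <- dplyr::summarise(
    dplyr::group_by(props, .data$condition, .data$subtype),
    mean = mean(.data$proportion), sd = sd(.data$proportion),
    n_samples = dplyr::n(), .groups = "drop")

  tests <- NULL
  if (!is.null(compare)) {
    tests <- dplyr::bind_rows(lapply(unique(props$subtype), function(st) {
      a <- props$proportion[props$subtype == st & props$condition == compare[1]]
      b <- props$proportion[props$subtype == st & props$condition == compare[2]]
      cbind(tibble::tibble(subtype = st), welch_test(a, b))
    }))
  }
  list(proportions = tibble::as_tibble(
         props[, c("sample", "condition", "subtype", "n", "proportion")]),
       condition_summary = cond_summary, tests = tests)
}

#' Depth-normalize crosslink profiles along one reference
#'
#' Every sample's per-position counts on `reference` are divided by that
#' sample's total rRNA crosslink count (the sum over `rrna_references`,
#' which defaults to all references in the table). Positions without a
#' record are 0. Samples with a zero rRNA total are dropped with a warning.
#'
#' @param crosslinks tibble: `sample`, `reference`, `position`, `count`.
#' @param reference reference to profile.
#' @param ref_length reference length (positions 1..ref_length).
#' @param rrna_references references counted in the normalizer; default all.
#' @return numeric matrix, samples in rows (rownames = sample ids),
#'   `ref_length` columns of normalized counts.
#' @export
#' @examples
#' x <- tibble::tibble(sample = "s1", reference = "18S",
#'                     position = c(527, 100), count = c(10, 90))
#' normalize_profile(x, "18S", 600)[, 527]  # 0.1
normalize_profile <- function(crosslinks, reference, ref_length,
                              rrna_references = NULL) {
  check_number(ref_length, "ref_length", lower = 1, integerish = TRUE)
  if (is.null(rrna_references)) {
    rrna_references <- unique(crosslinks$reference)
  }
  if (any(crosslinks$position < 1 |
          (crosslinks$reference == reference &
           crosslinks$position > ref_length))) {
    abort_param("crosslink positions outside [1, ref_length]")
  }
  rr <- crosslinks[crosslinks$reference %in% rrna_references, ]
  totals <- tapply(rr$count, rr$sample, sum)
  samples <- sort(unique(crosslinks$sample))
  tot <- setNames(rep(0, length(samples)), samples)
  tot[names(totals)] <- totals
  zero <- samples[tot == 0]
  if (length(zero) > 0) {
    warning("samples with zero rRNA crosslinks dropped: ",
            paste(zero, collapse = ", "), call. = FALSE)
    samples <- setdiff(samples, zero)
  }
  mat <- matrix(0, length(samples), ref_length,
                dimnames = list(samples, NULL))
  sub <- crosslinks[crosslinks$reference == reference &
                    crosslinks$sample %in% samples, ]
  mat[cbind(match(sub$sample, samples), sub$position)] <- sub$count
  mat / tot[samples]
}

#' Gaussian-smooth a profile (mass-preserving)
#'
#' Smooths with a discrete Gaussian kernel of odd `width` taps (offsets
#' -(width-1)/2 .. +(width-1)/2) and standard deviation `sd` in position
#' units, normalized to sum 1. Edge handling is mass-preserving kernel
#' truncation: each input position distributes its full value over the taps
#' that fall inside the vector (the kernel is renormalized over in-range
#' taps), so the vector sum is conserved exactly and interior positions
#' (further than the kernel radius from either end) equal ordinary
#' convolution.
#'
#' @param x numeric vector, or a matrix whose rows are smoothed
#'   independently.
#' @param width odd kernel width (default 9).
#' @param sd kernel standard deviation in positions (default 2).
#' @return object of the same shape as `x`.
#' @export
smooth_profile <- function(x, width = 9, sd = 2) {
  check_number(width, "width", lower = 1, integerish = TRUE)
  if (width %% 2 == 0) abort_param("`width` must be odd")
  check_number(sd, "sd", lower = 0, strict_lower = TRUE)
  if (is.matrix(x)) {
    return(t(apply(x, 1, smooth_profile, width = width, sd = sd)))
  }
  n <- length(x)
  half <- (width - 1L) / 2L
  kern <- dnorm(-half:half, 0, sd)
  kern <- kern / sum(kern)
  out <- numeric(n)
  mass <- in_range_mass(n, half, kern)  # in-range kernel mass per source
  src <- x / mass
  # distribute each input j over outputs j+o for in-range offsets o
  for (o in -half:half) {
    j <- seq_len(n)
    i <- j + o
    ok <- i >= 1L & i <= n
    out[i[ok]] <- out[i[ok]] + src[j[ok]] * kern[o + half + 1L]
  }
  out
}

# per-position sum of kernel taps that stay in range (vector over sources)
in_range_mass <- function(n, half, kern) {
  m <- rep(1, n)
  if (n <= 2 * half) {
    # every position is edge-affected; compute directly
    for (j in seq_len(n)) {
      o <- -half:half
      m[j] <- sum(kern[o + half + 1L][j + o >= 1 & j + o <= n])
    }
    return(m)
  }
  for (j in seq_len(half)) {
    o <- -half:half
    m[j] <- sum(kern[o + half + 1L][j + o >= 1])
    jr <- n - j + 1L
    m[jr] <- sum(kern[o + half + 1L][jr + o <= n])
  }
  m
}

#' Condition mean and standard-error metaprofiles
#'
#' @param profile_mat samples x positions matrix (e.g. from
#'   [normalize_profile()] or [smooth_profile()]).
#' @param design tibble mapping `sample` to a condition column.
#' @param condition_col condition column name (default `"cycle"`).
#' @return long tibble: `condition`, `position`, `mean`, `se`.
#' @export
profile_condition_summary <- function(profile_mat, design,
                                      condition_col = "cycle") {
  cond <- design[[condition_col]][match(rownames(profile_mat),
                                        design$sample)]
  dplyr::bind_rows(lapply(unique(cond), function(g) {
    sub <- profile_mat[cond == g, , drop = FALSE]
    tibble::tibble(condition = g, position = seq_len(ncol(sub)),
                   mean = colMeans(sub),
                   se = apply(sub, 2, sd) / sqrt(nrow(sub)))
  }))
}

#' Default 18S analysis windows
#'
#' ES3SB 200–250, Site A 510–550, ES10S 1500–1600 (1-based inclusive).
#'
#' @return tibble: `window`, `start`, `end`.
#' @export
default_windows <- function() {
  tibble::tibble(window = c("ES3SB", "SiteA", "ES10S"),
                 start = c(200L, 510L, 1500L),
                 end = c(250L, 550L, 1600L))
}

#' Quantify analysis windows and compare conditions
#'
#' For every window, sums each sample's raw normalized counts over the
#' inclusive window (smoothing is display-only and never feeds
#' quantification), summarises per condition (mean, SD), reports the fold
#' change `mean(condition2) / mean(condition1)` and a Welch test
#' (condition2 vs condition1, so `difference = mean2 - mean1`). Groups of
#' size 2 are allowed and flagged `low_n`.
#'
#' @param profile_mat samples x positions matrix of raw normalized counts.
#' @param design tibble mapping `sample` to a condition column.
#' @param windows tibble: `window`, `start`, `end` (1-based inclusive);
#'   default [default_windows()].
#' @param condition_col condition column in `design` (default `"cycle"`).
#' @param conditions length-2 character (reference, alternative); defaults
#'   to the design's first two levels in order of appearance.
#' @return tibble, one row per window: `window`, `start`, `end`,
#'   `mean_<ref>`, `sd_<ref>`, `mean_<alt>`, `sd_<alt>`, `fold_change`,
#'   `difference`, `t`, `df`, `p`, `low_n`, plus a `window_sums` attribute
#'   (per-sample sums, long tibble).
#' @export
quantify_windows <- function(profile_mat, design, windows = default_windows(),
                             condition_col = "cycle", conditions = NULL) {
  if (any(windows$start < 1 | windows$end > ncol(profile_mat) |
          windows$start > windows$end)) {
    abort_param("window out of range for this profile")
  }
  cond <- design[[condition_col]][match(rownames(profile_mat),
                                        design$sample)]
  if (is.null(conditions)) conditions <- unique(cond)[1:2]
  if (length(conditions) != 2 || !all(conditions %in% cond)) {
    abort_param("`conditions` must name two conditions present in the design")
  }
  sums_long <- list()
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    s <- rowSums(profile_mat[, windows$start[i]:windows$end[i],
                             drop = FALSE])
    sums_long[[i]] <<- tibble::tibble(window = windows$window[i],
                                      sample = rownames(profile_mat),
                                      condition = cond, window_sum = s)
    a <- s[cond == conditions[1]]  # reference (e.g. asynchronous)
    b <- s[cond == conditions[2]]  # alternative (e.g. mitotic)
    wt <- welch_test(b, a)
    out <- tibble::tibble(window = windows$window[i],
                          start = windows$start[i], end = windows$end[i])
    out[[paste0("mean_", conditions[1])]] <- mean(a)
    out[[paste0("sd_", conditions[1])]] <- sd(a)
    out[[paste0("mean_", conditions[2])]] <- mean(b)
    out[[paste0("sd_", conditions[2])]] <- sd(b)
    out$fold_change <- mean(b) / mean(a)
    out$difference <- wt$difference
    out$t <- wt$t
    out$df <- wt$df
    out$p <- wt$p
    out$low_n <- min(length(a), length(b)) == 2
    out
  })
  res <- dplyr::bind_rows(rows)
  attr(res, "window_sums") <- dplyr::bind_rows(sums_long)
  res
}

#' Run the iCLIP rRNA pipeline on one reference
#'
#' Normalizes ([normalize_profile()]), smooths for display
#' ([smooth_profile()]), summarises condition metaprofiles and quantifies
#' windows ([quantify_windows()]).
#'
#' @inheritParams normalize_profile
#' @inheritParams quantify_windows
#' @param kernel_width,kernel_sd smoothing parameters (defaults 9 and 2).
#' @return list: `normalized` (matrix), `smoothed` (matrix),
#'   `condition_profiles` (tibble from [profile_condition_summary()], on the
#'   smoothed profiles), `windows` (tibble from [quantify_windows()], on the
#'   raw normalized profiles).
#' @export
run_clip <- function(crosslinks, design, reference, ref_length,
                     windows = default_windows(), condition_col = "cycle",
                     conditions = NULL, kernel_width = 9, kernel_sd = 2,
                     rrna_references = NULL) {
  norm <- normalize_profile(crosslinks, reference, ref_length,
                            rrna_references)
  sm <- smooth_profile(norm, kernel_width, kernel_sd)
  rownames(sm) <- rownames(norm)
  list(normalized = norm,
       smoothed = sm,
       condition_profiles = profile_condition_summary(sm, design,
                                                      condition_col),
       windows = quantify_windows(norm, design, windows, condition_col,
                                  conditions))
}
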