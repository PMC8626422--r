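test_that("umi_collapse counts distinct UMIs per site", {
  reads <- tibble::tibble(sample = "s1", reference = "18S",
                          position = 527L,
                          umi = c("AAAA", "AAAA", "CCCC"))
  expect_equal(umi_collapse(reads)$count, 2L)
  # all-distinct UMIs leave raw read counts untouched
  reads2 <- tibble::tibble(sample = "s1", reference = "18S",
                           position = rep(c(5L, 9L), c(3, 2)),
                           umi = c("AAAA", "AATT", "GGGG", "CCCC", "TTTT"))
  expect_equal(umi_collapse(reads2)$count, c(3L, 2L))
})

test_that("umi_collapse rejects malformed UMIs and names offending rows", {
  reads <- tibble::tibble(sample = "s1", reference = "18S",
                          position = c(1L, 2L, 3L),
                          umi = c("ACGT", "ACXT", "NNNN"))
  expect_error(umi_collapse(reads), "malformed UMIs.*2")
})

test_that("umi_collapse equals a brute-force group-by tally", {
  set.seed(61)
  n <- 10000
  reads <- tibble::tibble(
    sample = sample(c("a", "b"), n, replace = TRUE),
    reference = sample(c("18S", "28S"), n, replace = TRUE),
    position = sample.int(200, n, replace = TRUE),
    umi = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    }, ""))
  got <- umi_collapse(reads)
  key <- paste(reads$sample, reads$reference, reads$position, sep = "|")
  want <- vapply(split(reads$umi, key), function(u) length(unique(u)), 0L)
  got_key <- paste(got$sample, got$reference, got$position, sep = "|")
  expect_equal(got$count, unname(want[got_key]))
  expect_setequal(got_key, names(want))
})

test_that("RNA-type proportions sum to one and recover known probabilities", {
  design <- tibble::tibble(sample = c("s1", "s2"), cycle = c("AS", "M"))
  asg <- tibble::tibble(sample = "s1",
                        subtype = c("rRNA", "rRNA", "mRNA"))
  res <- rna_type_summary(asg, design, compare = NULL)
  expect_equal(sum(res$proportions$proportion), 1)
  expect_equal(
    res$proportions$proportion[res$proportions$subtype == "rRNA"], 2 / 3)

  # multinomial recovery: mean proportions within 3 SE of the truth
  set.seed(62)
  probs <- c(rRNA = 0.6, mRNA = 0.25, tRNA = 0.15)
  n_samp <- 500
  counts <- stats::rmultinom(n_samp, size = 300, prob = probs)
  asg2 <- tibble::tibble(
    sample = rep(paste0("x", seq_len(n_samp)), each = 3),
    subtype = rep(names(probs), n_samp),
    n = as.vector(counts))
  des2 <- tibble::tibble(sample = paste0("x", seq_len(n_samp)), cycle = "AS")
  res2 <- rna_type_summary(asg2, des2, compare = NULL)
  per_sample_sums <- tapply(res2$proportions$proportion,
                            res2$proportions$sample, sum)
  expect_true(all(abs(per_sample_sums - 1) < 1e-9))
  for (st in names(probs)) {
    m <- res2$condition_summary$mean[res2$condition_summary$subtype == st]
    se <- sqrt(probs[[st]] * (1 - probs[[st]]) / 300) / sqrt(n_samp)
    expect_lt(abs(m - probs[[st]]), 3 * se)
  }
})

test_that("normalization divides by the sample's total rRNA crosslinks", {
  x <- tibble::tibble(sample = "s1", reference = "18S",
                      position = c(527L, 100L), count = c(10L, 90L))
  mat <- normalize_profile(x, "18S", 600)
  expect_equal(unname(mat["s1", 527]), 0.1)
  expect_equal(sum(mat), 1)
  # doubling all counts changes nothing
  x2 <- x
  x2$count <- x2$count * 2L
  expect_equal(normalize_profile(x2, "18S", 600), mat)
  # crosslinks on other rRNA references enter the denominator
  x3 <- dplyr::bind_rows(x, tibble::tibble(
    sample = "s1", reference = "28S", position = 5L, count = 100L))
  expect_equal(unname(normalize_profile(x3, "18S", 600)["s1", 527]), 0.05)
})

test_that("zero-total samples are dropped with a warning", {
  x <- tibble::tibble(sample = c("ok", "empty"), reference = "18S",
                      position = c(10L, 20L), count = c(5L, 0L))
  x <- x[x$count > 0, ]
  # sample 'empty' appears only via design; absent samples simply absent
  expect_equal(rownames(normalize_profile(x, "18S", 100)), "ok")
  expect_error(normalize_profile(
    tibble::tibble(sample = "s", reference = "18S",
                   position = 200L, count = 1L), "18S", 100),
    "positions outside")
})

test_that("smoothing has a unit interior DC response and reproduces the kernel", {
  # the mass-preserving edge rule redistributes within the kernel radius of
  # each end; interior positions of a constant vector are untouched
  v <- rep(3.7, 50)
  sm <- smooth_profile(v)
  expect_equal(sm[9:42], v[9:42], tolerance = 1e-12)
  expect_equal(sum(sm), sum(v), tolerance = 1e-12)
  imp <- numeric(41)
  imp[21] <- 1
  sm <- smooth_profile(imp)
  kern <- dnorm(-4:4, 0, 2)
  kern <- kern / sum(kern)
  expect_equal(sm[17:25], kern, tolerance = 1e-12)
  expect_equal(which.max(sm), 21)
  expect_error(smooth_profile(1:10, width = 8), "odd")
})

test_that("interior smoothing matches the double-loop oracle", {
  set.seed(63)
  x <- rpois(120, 5) + runif(120)
  sm <- smooth_profile(x)
  orc <- smooth_oracle_interior(x)
  interior <- 9:112  # untouched by either edge rule
  expect_equal(sm[interior], orc[interior], tolerance = 1e-12)
})

test_that("smoothing conserves the vector sum", {
  set.seed(64)
  for (n in c(5, 9, 40, 200)) {
    x <- rpois(n, 3) + runif(n)
    expect_equal(sum(smooth_profile(x)), sum(x), tolerance = 1e-12)
  }
  m <- matrix(rpois(60, 4), 3, 20)
  expect_equal(rowSums(smooth_profile(m)), rowSums(m), tolerance = 1e-12)
})

test_that("identical profiles across conditions give fold 1 and p 1", {
  mat <- matrix(rep(c(0.1, 0.2, 0.3, 0.4), each = 4), 4, 4, byrow = FALSE)
  rownames(mat) <- c("a1", "a2", "m1", "m2")
  design <- tibble::tibble(sample = rownames(mat),
                           cycle = c("AS", "AS", "M", "M"))
  win <- tibble::tibble(window = "w", start = 1L, end = 4L)
  q <- quantify_windows(mat, design, win, conditions = c("AS", "M"))
  expect_equal(q$fold_change, 1)
  expect_equal(q$p, 1)
  expect_true(q$low_n)
})

test_that("window fold change is the ratio of condition means", {
  mat <- matrix(0, 6, 10)
  rownames(mat) <- c(paste0("a", 1:3), paste0("m", 1:3))
  mat[, 2] <- c(1, 2, 3, 2, 4, 6)  # window sums 1,2,3 vs 2,4,6
  design <- tibble::tibble(sample = rownames(mat),
                           cycle = rep(c("AS", "M"), each = 3))
  win <- tibble::tibble(window = "w", start = 1L, end = 5L)
  q <- quantify_windows(mat, design, win, conditions = c("AS", "M"))
  expect_equal(q$fold_change, 2)
  expect_false(q$low_n)
  # reciprocity
  q_rev <- quantify_windows(mat, design, win, conditions = c("M", "AS"))
  expect_equal(q$fold_change * q_rev$fold_change, 1)
  expect_equal(q$p, q_rev$p)
  expect_error(
    quantify_windows(mat, design,
                     tibble::tibble(window = "bad", start = 5L, end = 11L)),
    "window out of range")
})

test_that("an injected window multiplier is recovered from the pipeline", {
  peaks <- default_clip_peaks()
  peaks$mitotic[peaks$name == "ES3SB"] <- 4  # 2 -> 4: true fold 2
  folds <- vapply(1:50, function(s) {
    sim <- simulate_crosslinks(clip_sim_params(peaks = peaks,
                                               seed = 5000 + s))
    mat <- normalize_profile(sim$crosslinks, "18S", 1869)
    q <- quantify_windows(mat, sim$design,
                          conditions = c("asynchronous", "mitotic"))
    q$fold_change[q$window == "ES3SB"]
  }, 0)
  expect_lt(abs(mean(folds) - 2) / 2, 0.1)
})

test_that("null window comparisons are calibrated", {
  peaks <- default_clip_peaks()
  peaks$mitotic <- peaks$asynchronous  # no condition effect anywhere
  n_sims <- 300
  ps <- vapply(seq_len(n_sims), function(s) {
    sim <- simulate_crosslinks(clip_sim_params(peaks = peaks,
                                               seed = 7000 + s))
    mat <- normalize_profile(sim$crosslinks, "18S", 1869)
    q <- quantify_windows(mat, sim$design,
                          conditions = c("asynchronous", "mitotic"))
    q$p[q$window == "ES3SB"]
  }, 0)
  frac <- mean(ps < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sims))
})

test_that("pipeline outputs are invariant to sample order", {
  sim <- simulate_crosslinks(clip_sim_params(n_reps = 3, seed = 66))
  res1 <- run_clip(sim$crosslinks, sim$design, "18S", 1869,
                   conditions = c("asynchronous", "mitotic"))
  shuffle <- sample.int(nrow(sim$crosslinks))
  res2 <- run_clip(sim$crosslinks[shuffle, ],
                   sim$design[sample.int(nrow(sim$design)), ],
                   "18S", 1869, conditions = c("asynchronous", "mitotic"))
  expect_equal(res1$normalized, res2$normalized)
  expect_equal(res1$windows, res2$windows)
})

test_that("run_clip returns coherent normalized, smoothed and window views", {
  sim <- simulate_crosslinks(clip_sim_params(seed = 67))
  res <- run_clip(sim$crosslinks, sim$design, "18S", 1869,
                  conditions = c("asynchronous", "mitotic"))
  expect_equal(dim(res$normalized), c(6, 1869))
  expect_equal(rowSums(res$smoothed), rowSums(res$normalized),
               tolerance = 1e-9)
  expect_equal(nrow(res$windows), 3)
  expect_setequal(unique(res$condition_profiles$condition),
                  c("asynchronous", "mitotic"))
})
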