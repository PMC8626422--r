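#' @importFrom rlang .data
#' @importFrom stats aov dnorm median p.adjust pt quantile rbinom rlnorm rnorm
#'   rpois runif sd t.test var TukeyHSD setNames
#' @importFrom utils read.table write.table
NULL

# internal parameter checks -----------------------------------------------

abort_param <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_param("`", name, "` must be a single finite number")
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort_param("`", name, "` must be a whole number")
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    abort_param("`", name, "` must be in ",
                if (strict_lower) "(" else "[", lower, ", ", upper, "]")
  }
  invisible(x)
}

#' Significance tier string for a p-value
#'
#' Maps p-values to the tier convention used in the figure legends of the
#' field: `ns` for p > 0.05, then `*` (p <= 0.05), `**` (p <= 0.01),
#' `***` (p <= 0.001) and `****` (p <= 0.0001).
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return character vector of tier strings.
#' @export
#' @examples
#' significance_tier(c(0.2, 0.03, 0.0005))
significance_tier <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] > 0.05, "ns",
             ifelse(p[ok] > 0.01, "*",
             ifelse(p[ok] > 0.001, "**",
             ifelse(p[ok] > 0.0001, "***", "****"))))
  out
}

# TSV helpers: all on-disk tables are plain tab-separated text ------------

#' Read / write a tab-separated table
#'
#' Thin wrappers enforcing the package's on-disk convention: tab-separated,
#' header line, no quoting, no row names.
#'
#' @param path file path.
#' @param x data frame to write.
#' @return `read_tsv_file()` returns a tibble.
#' @export
read_tsv_file <- function(path) {
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, check.names = FALSE))
}

#' @rdname read_tsv_file
#' @export
write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
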