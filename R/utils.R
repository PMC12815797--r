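#' @keywords internal
"_PACKAGE"

# Deterministic seed for pipeline stage `index` derived from a global seed.
stage_seed <- function(seed, index) {
  s <- (as.integer(seed) + as.integer(index))
  s %% .Machine$integer.max
}

# Trapezoidal area under y(t); t must be sorted increasing.
trapz_auc <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 2L, !is.unsorted(t))
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two label vectors of equal length.
#' Used throughout the test bed to compare recovered cluster labels with
#' planted ground truth; 1 means identical partitions up to relabelling,
#' values near 0 are expected under independence.
#'
#' @param a,b label vectors (any atomic type) of equal length.
#' @return a scalar in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Parse scalar-or-interval values such as 0.06 or "0.05-0.07"/"0.05–0.07";
# intervals are ingested as midpoints.
parse_criterion_value <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(as.character(x), function(v) {
    v <- gsub("–", "-", trimws(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    # split on a dash BETWEEN numbers so leading minus signs survive
    parts <- strsplit(v, "(?<=[0-9])\\s*-\\s*(?=[0-9.+-])", perl = TRUE)[[1]]
    if (length(parts) == 2) return(mean(as.numeric(parts)))
    stop("cannot parse criterion value: ", v)
  }, numeric(1), USE.NAMES = FALSE)
}
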