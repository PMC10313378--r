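#' @importFrom rlang abort warn .data := %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map2
NULL

# classed condition helpers so callers can distinguish failure modes
stop_param <- function(msg, ...) abort(msg, class = "tilfrc_parameter_error", ...)
stop_format <- function(msg, ...) abort(msg, class = "tilfrc_format_error", ...)
stop_schema <- function(msg, ...) abort(msg, class = "tilfrc_schema_error", ...)
stop_validation <- function(msg, ...) abort(msg, class = "tilfrc_validation_error", ...)
stop_degenerate <- function(msg, ...) abort(msg, class = "tilfrc_degenerate_input_error", ...)
stop_panel <- function(msg, ...) abort(msg, class = "tilfrc_panel_error", ...)
stop_placement <- function(msg, ...) abort(msg, class = "tilfrc_placement_error", ...)

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(sprintf("`%s` must be a single finite number", name))
  if (strict && x <= min) stop_param(sprintf("`%s` must be > %g", name, min))
  if (!strict && x < min) stop_param(sprintf("`%s` must be >= %g", name, min))
  invisible(x)
}

check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_schema(sprintf("%s is missing required column(s): %s",
                        what, paste(missing, collapse = ", ")))
  invisible(df)
}

# Otsu threshold on an arbitrary non-negative numeric vector (EBImage::otsu
# expects values in [0,1]; rescale, threshold, map back).
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1])
  m <- matrix((x - rng[1]) / diff(rng), nrow = 1L)
  thr <- EBImage::otsu(m, range = c(0, 1), levels = levels)
  rng[1] + thr * diff(rng)
}

#' Adjusted Rand index between two labelings
#'
#' Measures agreement between two partitions of the same objects, corrected
#' for chance; 1 means identical partitions, ~0 means independent.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_param("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
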