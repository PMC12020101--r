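#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Z-prime result
#' @param x A `zprime_result`.
#' @param ... Unused.
#' @return One-row tibble with the Z-prime value and group statistics.
#' @method tidy zprime_result
#' @export
tidy.zprime_result <- function(x, ...) {
  tibble(zprime = x$value, mean_pos = x$mean_pos, sd_pos = x$sd_pos,
         n_pos = x$n_pos, mean_neg = x$mean_neg, sd_neg = x$sd_neg,
         n_neg = x$n_neg, flag = x$flag)
}

#' @rdname tidy.zprime_result
#' @method glance zprime_result
#' @export
glance.zprime_result <- function(x, ...) tidy.zprime_result(x, ...)

#' Tidy a two-group comparison
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return `tidy()`: per-group summary rows; `glance()`: one-row test result.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$groups

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(test_used = x$test_used, statistic = x$statistic,
         p_value = x$p_value, alpha_norm = x$alpha_norm, flag = x$flag)
}

#' Tidy plate scores
#' @param x A `plate_scores` tibble.
#' @param ... Unused.
#' @return `tidy()`: the long score table; `glance()`: per-parameter
#'   reference statistics (median, SD, n, source).
#' @method tidy plate_scores
#' @export
tidy.plate_scores <- function(x, ...) as_tibble(x)

#' @rdname tidy.plate_scores
#' @method glance plate_scores
#' @export
glance.plate_scores <- function(x, ...) attr(x, "reference")

#' Tidy a hit table
#' @param x A `hit_table`.
#' @param ... Unused.
#' @return `tidy()`: the per-compound table; `glance()`: one row with
#'   compound/hit counts and the thresholds used.
#' @method tidy hit_table
#' @export
tidy.hit_table <- function(x, ...) as_tibble(x)

#' @rdname tidy.hit_table
#' @method glance hit_table
#' @export
glance.hit_table <- function(x, ...) {
  thr <- attr(x, "thresholds")
  tibble(n_compounds = nrow(x), n_hits = sum(x$hit),
         n_flagged = sum(!is.na(x$flag)),
         thresholds = paste(names(thr), thr, sep = "=", collapse = ", "))
}
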