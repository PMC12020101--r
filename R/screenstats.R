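# Plate QC (Z'), robust SD-distance scoring against the sample median,
# four-parameter intersection hit calling, and the normality-gated two-group
# comparison used for organelle statistics.

#' Z-prime factor of a control pair
#'
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`, the standard
#' assay-window statistic; `Z' > 0.5` conventionally indicates an excellent
#' screen. `Z' <= 1` always, with equality exactly when both SDs are zero
#' and the means differ. Symmetric in the two groups.
#'
#' @param pos,neg Numeric well values of the two control groups (>= 2 each).
#' @return Object of class `zprime_result`: `value`, per-group mean/SD/n,
#'   `flag` (`"equal_means"` when the window is undefined).
#' @export
zprime <- function(pos, neg) {
  pos <- pos[is.finite(pos)]; neg <- neg[is.finite(neg)]
  if (length(pos) < 2 || length(neg) < 2) {
    abort("need >= 2 finite wells per control group.", class = "ldscreen_bad_spec")
  }
  mp <- mean(pos); mn <- mean(neg)
  sp <- sd(pos); sn <- sd(neg)
  flag <- NA_character_
  if (mp == mn) {
    value <- NA_real_
    flag <- "equal_means"
  } else {
    value <- 1 - 3 * (sp + sn) / abs(mp - mn)
  }
  structure(list(value = value, mean_pos = mp, sd_pos = sp, n_pos = length(pos),
                 mean_neg = mn, sd_neg = sn, n_neg = length(neg), flag = flag),
            class = "zprime_result")
}

#' @export
print.zprime_result <- function(x, ...) {
  cat(sprintf("<zprime_result> Z' = %s (pos: %.4g +/- %.4g, n=%d; neg: %.4g +/- %.4g, n=%d)%s\n",
              ifelse(is.na(x$value), "undefined", sprintf("%.4f", x$value)),
              x$mean_pos, x$sd_pos, x$n_pos, x$mean_neg, x$sd_neg, x$n_neg,
              ifelse(is.na(x$flag), "", paste0(" [", x$flag, "]"))))
  invisible(x)
}

#' Score every compound's SD-distance from the sample median
#'
#' For each of the four LD parameters, each compound's score is its distance
#' from the reference median in units of the reference standard deviation:
#' `z = (x - median_ref) / sd_ref`. The reference set defaults to all
#' test-compound wells on the plate ("median of the samples"): with a mostly
#' inert library the sample median sits at the null centre and is robust.
#' Negative-control referencing and an MAD-based robust SD are options.
#'
#' @param wells Per-well tibble with columns `well`, `role`, `compound_id`
#'   and the four [ld_params()] (from [build_plate()] feature mode or
#'   [aggregate_well()] joined to a plate map). Wells with a non-`NA`
#'   `qc_flag` are excluded.
#' @param reference_source `"all_samples"` (default: every compound well) or
#'   `"negative_controls"`.
#' @param robust_sd Use `1.4826 * MAD` instead of the sample SD.
#' @param parameters Parameter columns to score.
#' @return Tibble of class `plate_scores` (long): `compound_id`, `well`,
#'   `parameter`, `value`, `z`; the per-parameter reference statistics are in
#'   `attr(, "reference")` and via [glance()].
#' @export
score_plate <- function(wells, reference_source = c("all_samples",
                                                    "negative_controls"),
                        robust_sd = FALSE, parameters = ld_params()) {
  reference_source <- match.arg(reference_source)
  stopifnot(all(c("well", "role", "compound_id", parameters) %in% names(wells)))
  if ("qc_flag" %in% names(wells)) {
    wells <- dplyr::filter(wells, is.na(.data$qc_flag))
  }
  ref_wells <- if (reference_source == "all_samples") {
    dplyr::filter(wells, .data$role == "compound")
  } else {
    dplyr::filter(wells, .data$role == "negative_control")
  }
  cmp <- dplyr::filter(wells, .data$role == "compound")
  if (nrow(cmp) == 0) abort("no compound wells to score.", class = "ldscreen_bad_spec")

  reference <- purrr::map_dfr(parameters, function(p) {
    v <- ref_wells[[p]]
    v <- v[is.finite(v)]
    if (length(v) < 3) {
      abort(sprintf("reference set has fewer than 3 defined wells for %s.", p),
            class = "ldscreen_bad_spec")
    }
    s <- if (robust_sd) mad(v) else sd(v)
    tibble(parameter = p, median = median(v), sd = s, n_ref = length(v),
           source = reference_source, robust_sd = robust_sd,
           degenerate = s == 0)
  })
  if (any(reference$degenerate)) {
    warn(paste0("zero reference SD for: ",
                paste(reference$parameter[reference$degenerate], collapse = ", "),
                "; scores undefined for these parameters."))
  }
  scores <- cmp %>%
    select(all_of(c("compound_id", "well", parameters))) %>%
    tidyr::pivot_longer(all_of(parameters), names_to = "parameter",
                        values_to = "value") %>%
    left_join(reference[, c("parameter", "median", "sd")], by = "parameter") %>%
    mutate(z = if_else(.data$sd > 0, (.data$value - .data$median) / .data$sd,
                       NA_real_)) %>%
    select(all_of(c("compound_id", "well", "parameter", "value", "z")))
  scores$parameter <- factor(scores$parameter, levels = parameters)
  structure(scores, reference = reference,
            class = c("plate_scores", class(scores)))
}

default_thresholds <- function() {
  c(ld_area = 2, ld_total_area = 2, ld_compactness = 2, ld_form_factor = 4)
}

default_directions <- function() {
  c(ld_area = "two_sided", ld_total_area = "decrease",
    ld_compactness = "two_sided", ld_form_factor = "two_sided")
}

#' Call hits by four-parameter threshold intersection
#'
#' A compound passes a parameter when its score exceeds that parameter's SD
#' threshold (defaults: 2 SD for area, compactness and total area; 4 SD for
#' form factor), in the configured direction: `two_sided` (`|z| >=
#' threshold`), `decrease` (`z <= -threshold`) or `increase`. Total LD area
#' must decrease by default (scores below -2 call a hit); the other three are
#' two-sided. A hit is a compound passing **all four** parameters
#' individually. Compounds with any undefined score are excluded and
#' flagged, never silently passed.
#'
#' @param scores A `plate_scores` tibble from [score_plate()].
#' @param thresholds Named per-parameter positive SD thresholds.
#' @param directions Named per-parameter directions.
#' @return Tibble of class `hit_table`: per compound, each `pass_*` flag,
#'   `hit`, `direction_total_area`, `flag`.
#' @export
call_hits <- function(scores, thresholds = default_thresholds(),
                      directions = default_directions()) {
  stopifnot(inherits(scores, "plate_scores"))
  params <- levels(scores$parameter)
  if (!all(params %in% names(thresholds)) || !all(params %in% names(directions))) {
    abort("thresholds and directions must cover every scored parameter.",
          class = "ldscreen_bad_spec")
  }
  if (any(thresholds[params] < 0)) {
    abort("thresholds must be non-negative.", class = "ldscreen_bad_spec")
  }
  wide <- scores %>%
    mutate(pass = purrr::pmap_lgl(
      list(.data$z, as.character(.data$parameter)),
      function(z, p) {
        if (!is.finite(z)) return(NA)
        switch(directions[[p]],
               two_sided = abs(z) >= thresholds[[p]],
               decrease = z <= -thresholds[[p]],
               increase = z >= thresholds[[p]],
               abort(sprintf("unknown direction '%s'.", directions[[p]]),
                     class = "ldscreen_bad_spec"))
      })) %>%
    select(all_of(c("compound_id", "parameter", "z", "pass"))) %>%
    tidyr::pivot_wider(names_from = "parameter",
                       values_from = c("z", "pass"), names_sep = "_")
  pass_cols <- paste0("pass_", params)
  passes <- as.matrix(wide[, pass_cols])
  any_na <- apply(passes, 1, anyNA)
  hit <- apply(passes, 1, all) & !any_na
  hit[any_na] <- FALSE
  out <- wide %>%
    mutate(
      hit = hit,
      direction_total_area = dplyr::case_when(
        !is.finite(.data$z_ld_total_area) ~ NA_character_,
        .data$z_ld_total_area < 0 ~ "decrease",
        .data$z_ld_total_area > 0 ~ "increase",
        TRUE ~ "none"),
      flag = if_else(any_na, "undefined_score", NA_character_)
    )
  structure(out, thresholds = thresholds[params], directions = directions[params],
            class = c("hit_table", class(out)))
}

#' Canonical strictly-standardised mean difference
#'
#' For layouts with per-compound replicate wells: the canonical SSMD
#' `(mean(x) - mean(ref)) / sqrt(var(x) + var(ref))`, distinct from the
#' sample-median SD-distance computed by [score_plate()] (which is what a
#' single-well-per-compound screen can estimate).
#'
#' @param x Replicate well values of one compound.
#' @param ref Reference (e.g. negative-control) well values.
#' @return Numeric SSMD estimate.
#' @export
ssmd_canonical <- function(x, ref) {
  if (length(x) < 2 || length(ref) < 2) {
    abort("canonical SSMD needs >= 2 values per group.", class = "ldscreen_bad_spec")
  }
  (mean(x) - mean(ref)) / sqrt(stats::var(x) + stats::var(ref))
}

#' Two-group comparison with a normality gate
#'
#' Shapiro-Wilk normality is tested per group at `alpha_norm`; when both
#' groups look normal a two-tailed Welch t-test is used, otherwise a
#' two-tailed Mann-Whitney U test (normal approximation without continuity
#' correction, so identical samples give p = 1 exactly). All-tied data, for
#' which the normality test is undefined, fall back to Mann-Whitney and are
#' flagged.
#'
#' @param a,b Numeric vectors (>= 3 observations each).
#' @param alpha_norm Normality-gate level (default 0.05).
#' @return Object of class `group_comparison`: per-group summaries,
#'   normality p-values, `test_used` (`"t"` or `"mann-whitney"`),
#'   `statistic`, `p_value`, `flag`.
#' @export
compare_groups <- function(a, b, alpha_norm = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) {
    abort("each group needs >= 3 finite observations.", class = "ldscreen_bad_spec")
  }
  shapiro_p <- function(v) {
    if (length(unique(v)) == 1) return(NA_real_)
    if (length(v) > 5000) v <- sample(v, 5000)
    tryCatch(shapiro.test(v)$p.value, error = function(e) NA_real_)
  }
  pa <- shapiro_p(a); pb <- shapiro_p(b)
  flag <- NA_character_
  normal <- !is.na(pa) && !is.na(pb) && pa >= alpha_norm && pb >= alpha_norm
  if (is.na(pa) || is.na(pb)) flag <- "normality_undefined"
  if (normal) {
    tt <- t.test(a, b, alternative = "two.sided")
    test_used <- "t"
    statistic <- unname(tt$statistic)
    p_value <- tt$p.value
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                       exact = FALSE, correct = FALSE))
    test_used <- "mann-whitney"
    statistic <- unname(wt$statistic)
    p_value <- wt$p.value
  }
  groups <- tibble(
    group = c("a", "b"), n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)), median = c(median(a), median(b)),
    sd = c(sd(a), sd(b)), normality_p = c(pa, pb)
  )
  structure(list(groups = groups, alpha_norm = alpha_norm,
                 test_used = test_used, statistic = statistic,
                 p_value = p_value, flag = flag),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s test: statistic = %.4g, p = %.4g%s\n",
              x$test_used, x$statistic, x$p_value,
              ifelse(is.na(x$flag), "", paste0(" [", x$flag, "]"))))
  print(x$groups)
  invisible(x)
}

#' Plate QC report: Z-prime per positive-control pairing
#'
#' Computes the Z-prime factor of the negative controls against each positive
#' control line separately, for a chosen parameter (total LD area by
#' default, the screen's primary readout).
#'
#' @param wells Per-well tibble (see [score_plate()]) including control rows
#'   with `cell_line`.
#' @param parameter Which of [ld_params()] to evaluate.
#' @return Tibble: `cell_line`, `parameter`, `zprime`, group means/SDs/ns.
#' @export
plate_qc <- function(wells, parameter = "ld_total_area") {
  stopifnot(parameter %in% names(wells))
  neg <- wells[[parameter]][wells$role == "negative_control"]
  pos_lines <- unique(wells$cell_line[wells$role == "positive_control"])
  purrr::map_dfr(pos_lines, function(line) {
    pos <- wells[[parameter]][wells$role == "positive_control" &
                                wells$cell_line == line]
    zp <- zprime(pos, neg)
    tibble(cell_line = line, parameter = parameter, zprime = zp$value,
           mean_pos = zp$mean_pos, sd_pos = zp$sd_pos, n_pos = zp$n_pos,
           mean_neg = zp$mean_neg, sd_neg = zp$sd_neg, n_neg = zp$n_neg,
           flag = zp$flag)
  })
}
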