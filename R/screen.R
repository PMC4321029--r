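# ---------------------------------------------------------------------------
# Screen statistic: % F1 males, fold change vs baseline, classification
# ---------------------------------------------------------------------------

#' Screen scoring configuration
#'
#' In the screen design, F1 males carry the sensitized (transgene-expressing)
#' genotype and F1 females are rescued controls, so the percent of males among
#' scored F1 adults measures relative male viability. Routine outcrossing of
#' the unmodified stock yields the baseline percentage (22%); per-line fold
#' change is the observed percent males divided by that baseline.
#'
#' @param baseline_pct Baseline percent F1 males (default 22).
#' @param enhancer_fold_max Display-rounded fold at or below which a line is
#'   called an enhancer (default 0.5).
#' @param suppressor_fold_min Display-rounded fold at or above which a line is
#'   called a suppressor (default 1.9).
#' @param alpha Significance level for replicate t-tests (default 0.05).
#' @param threshold_mode `"fold"` (fixed fold-change cutoffs, the default) or
#'   `"sd"` (cutoffs at mean +/- 1 SD of the screen's own percent values).
#' @param mean_pct,sd_pct Optional fixed mean/SD for `"sd"` mode; when `NULL`
#'   they are recomputed from the scored screen.
#' @return A `screen_config` object.
#' @export
screen_config <- function(baseline_pct = 22, enhancer_fold_max = 0.5,
                          suppressor_fold_min = 1.9, alpha = 0.05,
                          threshold_mode = c("fold", "sd"),
                          mean_pct = NULL, sd_pct = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(baseline_pct > 0, baseline_pct < 100,
            enhancer_fold_max < 1, suppressor_fold_min > 1,
            alpha > 0, alpha < 1)
  structure(
    list(baseline_pct = baseline_pct, enhancer_fold_max = enhancer_fold_max,
         suppressor_fold_min = suppressor_fold_min, alpha = alpha,
         threshold_mode = threshold_mode, mean_pct = mean_pct, sd_pct = sd_pct),
    class = "screen_config"
  )
}

#' Round half away from zero
#'
#' Printed screen tables round 0.5 up, unlike R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Percent F1 males of a cross
#'
#' @param males,females Non-negative F1 adult counts (vectorized).
#' @return Unrounded percent males, `100 * males / (males + females)`.
#' @examples
#' pct_males(314, 1123) # control pool, displays as 22%
#' @export
pct_males <- function(males, females) {
  stopifnot(all(males >= 0), all(females >= 0))
  if (any(males + females < 1)) stop("empty cross", call. = FALSE)
  100 * males / (males + females)
}

#' Fold change of a line versus the screen baseline
#'
#' @param pct Unrounded percent F1 males.
#' @param config A [screen_config()].
#' @return Unrounded fold change `pct / baseline_pct`.
#' @export
fold_change <- function(pct, config = screen_config()) {
  pct / config$baseline_pct
}

#' Display-rounded fold change and its printed form
#'
#' Fold changes are printed to one decimal place; only when the one-decimal
#' value is below 1.0 are two decimals shown (so a raw fold of 0.95 prints as
#' "1.0", while 0.45 prints as "0.45"). `display_fold()` returns the numeric
#' display value; `format_fold()` the printed string. Classification operates
#' on the display value.
#'
#' @param fold Unrounded fold change (vectorized).
#' @return Numeric display value, or character printed form.
#' @export
display_fold <- function(fold) {
  r1 <- round_half_up(fold, 1)
  ifelse(r1 >= 1, r1, round_half_up(fold, 2))
}

#' @rdname display_fold
#' @export
format_fold <- function(fold) {
  r1 <- round_half_up(fold, 1)
  ifelse(r1 >= 1, sprintf("%.1f", r1), sprintf("%.2f", round_half_up(fold, 2)))
}

#' Display-rounded percent males
#'
#' @param pct Unrounded percent (vectorized).
#' @return Integer percent, half rounded up.
#' @export
display_pct <- function(pct) {
  as.integer(round_half_up(pct, 0))
}

#' Classify a line as suppressor, enhancer or nonmodifier
#'
#' In `"fold"` mode a line is an enhancer when its display-rounded fold change
#' is at or below `enhancer_fold_max` and a suppressor at or above
#' `suppressor_fold_min`. In `"sd"` mode the cutoffs are one standard
#' deviation above/below the screen mean of percent males; the mean and SD are
#' taken from `config` when fixed there, otherwise from `screen_pcts`.
#'
#' @param pct Unrounded percent F1 males (vectorized).
#' @param config A [screen_config()].
#' @param screen_pcts Percent values of the whole screen, required for `"sd"`
#'   mode when `config` does not fix `mean_pct`/`sd_pct`.
#' @return Character vector in `c("enhancer", "suppressor", "nonmodifier")`.
#' @examples
#' classify(pct_males(47, 36))  # "suppressor"
#' classify(pct_males(3, 189))  # "enhancer"
#' @export
classify <- function(pct, config = screen_config(), screen_pcts = NULL) {
  if (config$threshold_mode == "sd") {
    if ((is.null(config$mean_pct) || is.null(config$sd_pct)) &&
        is.null(screen_pcts)) {
      stop("'sd' threshold mode needs screen_pcts or fixed mean/sd",
           call. = FALSE)
    }
    m <- config$mean_pct %||% mean(screen_pcts)
    s <- config$sd_pct %||% stats::sd(screen_pcts)
    out <- rep("nonmodifier", length(pct))
    out[pct > m + s] <- "suppressor"
    out[pct < m - s] <- "enhancer"
    return(out)
  }
  d <- display_fold(pct / config$baseline_pct)
  eps <- 1e-9
  out <- rep("nonmodifier", length(pct))
  out[d <= config$enhancer_fold_max + eps] <- "enhancer"
  out[d >= config$suppressor_fold_min - eps] <- "suppressor"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unpaired two-sample Student's t-test on replicate percentages
#'
#' Equal-variance, two-tailed. Each argument holds the per-cross percent F1
#' males of independent replicate crosses of one line.
#'
#' @param line_pcts,control_pcts Numeric vectors, each of length >= 2.
#' @return Two-sided p-value.
#' @export
replicate_t_test <- function(line_pcts, control_pcts) {
  if (length(line_pcts) < 2 || length(control_pcts) < 2) {
    stop("replicates required (>= 2 values per group)", call. = FALSE)
  }
  if (stats::var(line_pcts) == 0 && stats::var(control_pcts) == 0) {
    # degenerate pooled variance: zero t statistic when the means agree
    return(if (mean(line_pcts) == mean(control_pcts)) 1 else 0)
  }
  stats::t.test(line_pcts, control_pcts, var.equal = TRUE)$p.value
}

#' Score a screen: percent males, fold change, classification per line
#'
#' @param tallies A data frame with columns `line_id`, `males`, `females`;
#'   optional `breakpoints`, `p_value` (carried through, e.g. printed values),
#'   and `replicates` (list column of two-column males/females matrices, from
#'   which a replicate t-test against `control_replicates` is computed).
#' @param config A [screen_config()].
#' @param control_replicates Optional two-column males/females matrix of
#'   control replicate crosses for t-tests.
#' @return A tibble of screen records: unrounded `pct_males` and
#'   `fold_change`, display forms, `classification`, `p_value`, `significant`.
#'   Classification is not gated on significance.
#' @export
score_screen <- function(tallies, config = screen_config(),
                         control_replicates = NULL) {
  stopifnot(is.data.frame(tallies))
  if (nrow(tallies) == 0) stop("no records", call. = FALSE)
  req <- c("line_id", "males", "females")
  missing_cols <- setdiff(req, names(tallies))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  .check_replicate_sums(tallies)
  pct <- pct_males(tallies$males, tallies$females)
  fold <- fold_change(pct, config)
  cls <- classify(pct, config, screen_pcts = pct)
  p <- if ("p_value" %in% names(tallies)) tallies$p_value else NA_real_
  if ("replicates" %in% names(tallies) && !is.null(control_replicates)) {
    ctrl <- pct_males(control_replicates[, 1], control_replicates[, 2])
    p <- vapply(seq_len(nrow(tallies)), function(i) {
      reps <- tallies$replicates[[i]]
      if (is.null(reps) || nrow(reps) < 2) return(NA_real_)
      replicate_t_test(pct_males(reps[, 1], reps[, 2]), ctrl)
    }, numeric(1))
  }
  tibble::tibble(
    line_id = tallies$line_id,
    breakpoints = if ("breakpoints" %in% names(tallies)) tallies$breakpoints
                  else NA_character_,
    males = tallies$males,
    females = tallies$females,
    total = tallies$males + tallies$females,
    pct_males = pct,
    pct_display = display_pct(pct),
    fold_change = fold,
    fold_display = display_fold(fold),
    classification = cls,
    p_value = p,
    significant = !is.na(p) & p < config$alpha
  )
}

.check_replicate_sums <- function(tallies) {
  if (!"replicates" %in% names(tallies)) return(invisible(TRUE))
  for (i in seq_len(nrow(tallies))) {
    reps <- tallies$replicates[[i]]
    if (is.null(reps)) next
    if (sum(reps[, 1]) != tallies$males[i] ||
        sum(reps[, 2]) != tallies$females[i]) {
      stop("line '", tallies$line_id[i],
           "': replicate tallies do not sum to the pooled counts",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Screen-wide summary
#'
#' Mean and sample standard deviation (n-1 denominator) of percent F1 males
#' over deficiency lines, and classification counts under the active
#' configuration. Control rows (those with missing `breakpoints`, or named in
#' `control`) are excluded from the distribution.
#'
#' @param records Output of [score_screen()].
#' @param config A [screen_config()].
#' @param control Line ids to treat as controls (in addition to rows with no
#'   breakpoints).
#' @return A one-row tibble: `n_lines`, `mean_pct`, `sd_pct`, `n_suppressors`,
#'   `n_enhancers`, `baseline_pct`.
#' @export
summarize_screen <- function(records, config = screen_config(),
                             control = character()) {
  is_ctrl <- records$line_id %in% control
  if (any(!is.na(records$breakpoints))) {
    # breakpoint-less rows mark controls only when the column is informative
    # (synthetic screens carry no breakpoints at all)
    is_ctrl <- is_ctrl | is.na(records$breakpoints)
  }
  recs <- records[!is_ctrl, ]
  if (nrow(recs) < 2) stop("need at least two deficiency records", call. = FALSE)
  tibble::tibble(
    n_lines = nrow(recs),
    mean_pct = mean(recs$pct_males),
    sd_pct = stats::sd(recs$pct_males),
    n_suppressors = sum(recs$classification == "suppressor"),
    n_enhancers = sum(recs$classification == "enhancer"),
    baseline_pct = config$baseline_pct
  )
}
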