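# Tumor Control Index scoring of per-mouse growth curves and the associated
# group statistics (one-way ANOVA with Dunnett or Tukey follow-up, two-
# tailed t tests).

#' Read a tumor growth table
#'
#' Expects a CSV with columns `mouse_id`, `group`, `day` (integer days
#' post-challenge) and `diameter_mm` (average of two perpendicular
#' measurements).
#'
#' @param path CSV path.
#' @return data.frame of growth measurements.
#' @export
read_growth <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("mouse_id", "group", "day", "diameter_mm")
  missing <- setdiff(required, names(g))
  if (length(missing) > 0) {
    stop("growth table is missing column(s): ", paste(missing, collapse = ", "))
  }
  g
}

#' Trapezoidal area under a growth curve
#'
#' @param days Increasing numeric vector of measurement days.
#' @param diameters Non-negative tumor diameters (mm), same length.
#' @return Area in mm x day.
#' @export
growth_auc <- function(days, diameters) {
  stopifnot(length(days) == length(diameters))
  if (length(days) < 2) stop("need at least 2 time points for an AUC")
  if (is.unsorted(days, strictly = TRUE)) stop("days must be strictly increasing")
  pracma::trapz(days, diameters)
}

#' Mean growth curve of the control group
#'
#' @param growth data.frame from [read_growth()].
#' @param control Control group label.
#' @return data.frame with columns `day` and `diameter_mm` (per-day mean
#'   over control mice).
#' @export
control_mean_curve <- function(growth, control) {
  ctrl <- growth[growth$group == control, , drop = FALSE]
  if (nrow(ctrl) == 0) stop("control group '", control, "' is empty")
  agg <- stats::aggregate(diameter_mm ~ day, data = ctrl, FUN = mean)
  agg[order(agg$day), ]
}

#' Tumor Control Index of one growth curve
#'
#' The TCI decomposes control of tumor growth into three 0-10 components
#' whose sum (maximum 30) is the total score:
#' \describe{
#'   \item{rejection}{10 iff the tumor is undetectable (diameter below
#'     `detection_floor`) at the final observation and has remained
#'     undetectable ever since the first undetectable day following its
#'     first measurable day (a durable complete response; a tumor that
#'     never became measurable also scores 10); otherwise 0.}
#'   \item{inhibition}{`10 * clamp(1 - AUC(curve) / AUC(control), 0, 1)`:
#'     linear in the AUC reduction relative to the control mean curve.}
#'   \item{stability}{10 times the fraction of observation days on which
#'     the diameter is within `stability_band` (default +/-20%) of the
#'     diameter on the day the tumor first became measurable, or
#'     undetectable.}
#' }
#' The curve is linearly interpolated onto the control's day grid,
#' restricted to the curve's own observed range, so truncated (early-
#' euthanasia) curves contribute only over observed days.
#'
#' @param days,diameters The mouse's growth curve.
#' @param control_days,control_diameters The control-group mean curve.
#' @param detection_floor Diameter (mm) below which a tumor is
#'   undetectable; default 1.
#' @param stability_band Relative band for the stability component;
#'   default 0.2.
#' @return List of class `tci_score` with components `rejection`,
#'   `inhibition`, `stability`, `total`, and the `truncated` flag.
#' @export
tci_components <- function(days, diameters, control_days, control_diameters,
                           detection_floor = 1, stability_band = 0.2) {
  stopifnot(length(days) == length(diameters),
            length(control_days) == length(control_diameters))
  grid <- control_days[control_days >= min(days) & control_days <= max(days)]
  if (length(grid) < 2) {
    stop("curve and control day grids overlap at fewer than 2 days")
  }
  d <- stats::approx(days, diameters, xout = grid)$y
  ctrl <- control_diameters[control_days %in% grid]
  truncated <- max(days) < max(control_days)

  undet <- d < detection_floor
  rejection <- 0
  if (all(undet)) {
    rejection <- 10  # tumor never took
  } else if (undet[length(undet)]) {
    # durable complete response: undetectable from the first undetectable
    # day after the tumor first became measurable, through the end
    first_meas <- which(!undet)[1]
    after <- which(undet & seq_along(undet) > first_meas)
    if (length(after) > 0 && all(undet[after[1]:length(undet)])) {
      rejection <- 10
    }
  }

  auc_ctrl <- growth_auc(grid, ctrl)
  if (auc_ctrl <= 0) stop("control mean curve has zero AUC")
  inhibition <- 10 * clamp(1 - growth_auc(grid, d) / auc_ctrl, 0, 1)

  measurable <- which(!undet)
  if (length(measurable) == 0) {
    stability <- 10
  } else {
    baseline <- d[measurable[1]]
    ok <- undet | abs(d - baseline) <= stability_band * baseline
    stability <- 10 * mean(ok)
  }

  structure(
    list(rejection = rejection, inhibition = inhibition,
         stability = stability,
         total = rejection + inhibition + stability,
         truncated = truncated),
    class = "tci_score"
  )
}

#' @export
print.tci_score <- function(x, ...) {
  cat(sprintf(
    "<tci_score> total %.1f / 30  (rejection %.0f, inhibition %.1f, stability %.1f)%s\n",
    x$total, x$rejection, x$inhibition, x$stability,
    if (x$truncated) "  [truncated curve]" else ""))
  invisible(x)
}

#' Per-mouse and per-group Tumor Control Index
#'
#' Scores every mouse against the control group's mean curve and averages
#' totals by group.
#'
#' @param growth data.frame from [read_growth()].
#' @param control Control group label.
#' @param ... Passed to [tci_components()].
#' @return List with `per_mouse` (data.frame: mouse_id, group, rejection,
#'   inhibition, stability, total, truncated) and `per_group` (data.frame:
#'   group, n, mean_total).
#' @export
group_tci <- function(growth, control, ...) {
  ctrl <- control_mean_curve(growth, control)
  mice <- unique(growth[, c("mouse_id", "group")])
  rows <- lapply(seq_len(nrow(mice)), function(i) {
    m <- growth[growth$mouse_id == mice$mouse_id[i] &
                  growth$group == mice$group[i], , drop = FALSE]
    m <- m[order(m$day), ]
    s <- tci_components(m$day, m$diameter_mm, ctrl$day, ctrl$diameter_mm, ...)
    data.frame(mouse_id = mice$mouse_id[i], group = mice$group[i],
               rejection = s$rejection, inhibition = s$inhibition,
               stability = s$stability, total = s$total,
               truncated = s$truncated, stringsAsFactors = FALSE)
  })
  per_mouse <- do.call(rbind, rows)
  agg <- stats::aggregate(total ~ group, data = per_mouse, FUN = mean)
  counts <- stats::aggregate(total ~ group, data = per_mouse, FUN = length)
  per_group <- data.frame(group = agg$group, n = counts$total,
                          mean_total = agg$total, stringsAsFactors = FALSE)
  list(per_mouse = per_mouse, per_group = per_group)
}

#' Compare groups by ANOVA with multiplicity-corrected follow-up
#'
#' One-way ANOVA followed by Dunnett's many-to-one test against the control
#' (the convention for TCI comparisons) or Tukey's all-pairs test (the
#' convention for AUC comparisons). Adjusted p-values are reported.
#'
#' @param values Numeric response (one value per mouse).
#' @param groups Group labels, same length.
#' @param method `"dunnett"` or `"tukey"`.
#' @param control Control group label; required for Dunnett.
#' @return data.frame with columns `comparison`, `estimate`, `p_adj`.
#' @export
compare_groups <- function(values, groups, method = c("dunnett", "tukey"),
                           control = NULL) {
  method <- match.arg(method)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 values")
  d <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = d)
  s <- stats::sigma(fit)
  if (!is.finite(s) || s < sqrt(.Machine$double.eps) * max(abs(values), 1)) {
    stop("degenerate within-group variance; ANOVA follow-up undefined")
  }
  if (method == "dunnett") {
    if (is.null(control)) stop("Dunnett comparisons need a control group")
    if (!control %in% levels(groups)) {
      stop("control group '", control, "' not found")
    }
    d$g <- stats::relevel(d$g, ref = control)
    fit <- stats::aov(y ~ g, data = d)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    s <- summary(gl)
    data.frame(comparison = rownames(s$linfct),
               estimate = as.numeric(s$test$coefficients),
               p_adj = as.numeric(s$test$pvalues),
               stringsAsFactors = FALSE)
  } else {
    tk <- stats::TukeyHSD(fit)$g
    data.frame(comparison = rownames(tk),
               estimate = tk[, "diff"],
               p_adj = tk[, "p adj"],
               row.names = NULL, stringsAsFactors = FALSE)
  }
}

#' Two-tailed two-sample t test p-value
#'
#' Standard pooled-variance two-sample t test, two-tailed.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return The p-value.
#' @export
ttest_two_tailed <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  if (stats::var(a) + stats::var(b) == 0) {
    stop("degenerate variance: both groups are constant")
  }
  stats::t.test(a, b, var.equal = TRUE,
                alternative = "two.sided")$p.value
}
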