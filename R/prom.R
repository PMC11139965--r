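#' WOMAC subscale and total scores
#'
#' The 24 WOMAC items (each 0--4) are partitioned as 5 pain, 2 stiffness and
#' 17 physical-function items, giving subscale ranges 0--20, 0--8, 0--68 and
#' a total range 0--96.
#'
#' @param items integer vector of 24 item scores, each in 0..4, ordered
#'   pain (5), stiffness (2), physical function (17).
#' @return list `pain`, `stiffness`, `physical_function`, `total`.
#' @export
womac_scores <- function(items) {
  if (length(items) != 24) stop_field("items", "must have exactly 24 items")
  if (any(!is.finite(items)) || any(items < 0 | items > 4 | items != round(items)))
    stop_field("items", "each item must be an integer in 0..4")
  pain <- sum(items[1:5])
  stiffness <- sum(items[6:7])
  physical_function <- sum(items[8:24])
  list(pain = pain, stiffness = stiffness,
       physical_function = physical_function,
       total = pain + stiffness + physical_function)
}

#' Midpoint-rule severity cut-offs
#'
#' On the 0--4 item scale the mild/moderate midpoint is 1.5 and the
#' moderate/severe midpoint 2.5; multiplying by the number of items gives the
#' scale cut-offs. For the 24-item WOMAC total this yields (36, 60).
#'
#' @param n_items number of items on the scale (24 total, 5 pain,
#'   2 stiffness, 17 physical function).
#' @return numeric vector `c(low, high)` = `c(1.5, 2.5) * n_items`.
#' @export
midpoint_cutoffs <- function(n_items) {
  if (!is.finite(n_items) || n_items < 1) stop_field("n_items", "must be >= 1")
  c(low = 1.5 * n_items, high = 2.5 * n_items)
}

#' Three-class severity categorization
#'
#' Scores below `low` are mild, scores in the closed interval
#' `[low, high]` moderate, scores above `high` severe (literal reading of
#' "below 36, between 36 and 60, and above 60"; both boundaries belong to
#' the moderate class).
#'
#' @param score numeric vector of scores.
#' @param low,high cut-offs with `low < high`, e.g. from
#'   [midpoint_cutoffs()].
#' @return factor with ordered levels `mild < moderate < severe`.
#' @export
categorize_severity <- function(score, low, high) {
  if (!(low < high)) stop_field("low", "must be strictly below `high`")
  lab <- ifelse(score < low, "mild", ifelse(score <= high, "moderate", "severe"))
  factor(lab, levels = c("mild", "moderate", "severe"), ordered = TRUE)
}

#' Categorize VAS pain scores
#'
#' Applies the same midpoint fractions as the WOMAC rule (1.5/4 and 2.5/4)
#' rescaled to the 0--10 VAS, giving cut-offs (3.75, 6.25). The source
#' methodology never prints its VAS cut-offs; these are the package's
#' documented interpretation (configurable via [categorize_severity()]).
#'
#' @param vas numeric vector in [0, 10].
#' @return factor `mild < moderate < severe`.
#' @export
categorize_vas <- function(vas) {
  if (any(!is.finite(vas)) || any(vas < 0 | vas > 10))
    stop_field("vas", "must lie in [0, 10]")
  categorize_severity(vas, 10 * 1.5 / 4, 10 * 2.5 / 4)
}

#' Classical one-way ANOVA across severity groups
#'
#' Equal-variance one-way ANOVA F statistic and p-value for a feature across
#' severity groups (the group-difference screen applied at a 0.001
#' significance level).
#'
#' @param values numeric vector of feature values.
#' @param groups factor of group labels, parallel to `values`.
#' @return list `F`, `p`, `df` (numerator, denominator).
#' @export
group_anova <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  ns <- tabulate(groups)
  if (any(ns < 2)) stop("each group needs at least two observations", call. = FALSE)
  n <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  if (ssw <= 0) stop("zero within-group variance: F undefined", call. = FALSE)
  df1 <- k - 1
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE), df = c(df1, df2))
}

#' Welch t-test between two severity groups
#'
#' Two-sided t-test between adjacent severity groups; Welch correction by
#' default (set `welch = FALSE` for the pooled-variance Student form).
#'
#' @param x,y numeric vectors for the two groups.
#' @param welch use the Welch unequal-variance form (default `TRUE`).
#' @return list `t`, `p`, `df`.
#' @export
group_ttest <- function(x, y, welch = TRUE) {
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Group ensemble waveform with pointwise 95% confidence band
#'
#' Pointwise mean and mean +/- 1.96 standard errors per 1% gait-cycle bin for
#' each severity group. Groups with fewer than two envelopes are skipped with
#' a warning.
#'
#' @param envelopes list of `normalized_envelope` (or 101-vectors).
#' @param groups factor of group labels, parallel to `envelopes`.
#' @return named list per group: `mean`, `lower`, `upper`, `n` (101-point
#'   bands).
#' @export
ensemble_waveform <- function(envelopes, groups) {
  groups <- droplevels(as.factor(groups))
  vals <- vapply(envelopes, function(e)
    if (inherits(e, "normalized_envelope")) e$values else e, numeric(101))
  out <- list()
  for (g in levels(groups)) {
    sel <- which(groups == g)
    if (length(sel) < 2) {
      warning(sprintf("group '%s' skipped: fewer than 2 envelopes", g), call. = FALSE)
      next
    }
    m <- rowMeans(vals[, sel, drop = FALSE])
    se <- apply(vals[, sel, drop = FALSE], 1, sd) / sqrt(length(sel))
    out[[g]] <- list(mean = m, lower = m - 1.96 * se, upper = m + 1.96 * se,
                     n = length(sel))
  }
  out
}

#' Table-1-style severity group summary of a feature table
#'
#' Labels each limb row by the WOMAC-total midpoint rule, then reports per
#' group mean (sd) for the PROM scores and any requested features, with the
#' one-way ANOVA p-value across groups.
#'
#' @param tbl a feature table from [build_feature_table()].
#' @param columns columns to summarize (default the five PROM targets).
#' @return data.frame: one row per column with per-group `mean (sd)` strings
#'   and `p_anova`.
#' @export
severity_group_summary <- function(tbl, columns = c("womac_total", "pain",
                                                    "stiffness",
                                                    "physical_function", "vas")) {
  cuts <- midpoint_cutoffs(24)
  cls <- categorize_severity(tbl$womac_total, cuts["low"], cuts["high"])
  rows <- lapply(columns, function(cn) {
    v <- tbl[[cn]]
    cells <- vapply(levels(cls), function(g) {
      s <- v[cls == g]
      sprintf("%.2f (%.2f)", mean(s), sd(s))
    }, character(1))
    p <- tryCatch(group_anova(v, cls)$p, error = function(e) NA_real_)
    data.frame(feature = cn, mild = cells[1], moderate = cells[2],
               severe = cells[3], p_anova = p)
  })
  cnt <- table(cls)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "group_n") <- as.integer(cnt)
  out
}
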