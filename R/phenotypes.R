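#' Pool treatments into chronic-stress exposure groups
#'
#' Acute restraint has no effect on body or organ weight, so for biometric
#' analyses the four treatment histories collapse to two exposure groups:
#' CMSgroup (CMS, CMS-R) vs NHgroup (NH, NH-R).
#'
#' @param table phenotype data.frame with a `treatment` column.
#' @return The same table with a `pooled_group` column added.
#' @export
pool_groups <- function(table) {
  trt <- table$treatment
  known <- c("NH", "CMS", "NH-R", "CMS-R")
  bad <- setdiff(unique(trt), known)
  if (length(bad) > 0) {
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "))
  }
  table$pooled_group <- ifelse(trt %in% c("CMS", "CMS-R"), "CMSgroup", "NHgroup")
  table
}

#' Per-animal body-weight change
#'
#' Difference between weight at the end and at the beginning of the
#' chronic-stress period (grams); animals missing either weight are
#' excluded with a warning giving the count.
#'
#' @param table phenotype data.frame with `bw_start` and `bw_end` (g).
#' @return data.frame of the retained rows with a `bw_change` column.
#' @export
body_weight_change <- function(table) {
  stopifnot(all(c("bw_start", "bw_end") %in% names(table)))
  ok <- !is.na(table$bw_start) & !is.na(table$bw_end)
  if (any(!ok)) {
    warning(sum(!ok), " animal(s) excluded for missing body weight")
  }
  out <- table[ok, , drop = FALSE]
  out$bw_change <- out$bw_end - out$bw_start
  out
}

#' Single-pass 2-SD outlier removal within groups
#'
#' Presumed technical-artifact screening: within each group, values more
#' than `k` standard deviations from the group mean are dropped in a
#' single pass, with mean and SD computed on the full group including the
#' candidate point. Groups with fewer than 3 values are left untouched.
#'
#' @param values numeric vector.
#' @param groups grouping keys, same length as `values`.
#' @param k SD multiplier (default 2).
#' @return List with `kept` (logical keep mask in input order), `values`
#'   (the retained values) and `removed` (data.frame: index, value, group).
#' @export
remove_outliers <- function(values, groups, k = 2) {
  stopifnot(length(values) == length(groups))
  keep <- rep(TRUE, length(values))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 3) next
    m <- mean(values[idx])
    s <- stats::sd(values[idx])
    if (is.na(s) || s == 0) next
    keep[idx] <- abs(values[idx] - m) <= k * s
  }
  removed <- data.frame(
    index = which(!keep),
    value = values[!keep],
    group = groups[!keep],
    stringsAsFactors = FALSE
  )
  list(kept = keep, values = values[keep], removed = removed)
}

#' Two-way Type III ANOVA with eta-squared effect sizes
#'
#' Fits `response ~ A * B` under sum-to-zero contrasts and computes Type
#' III (partial) sums of squares via `car::Anova`, the convention matching
#' unbalanced designs where each term is tested adjusted for all others.
#' Effect size per term is eta-squared, SS of the term divided by the
#' corrected total SS.
#'
#' @param response numeric response vector.
#' @param a,b factors (coerced) with >= 2 levels; every cell of the a x b
#'   design must be non-empty.
#' @param names_ab optional length-2 labels for the two factors.
#' @return data.frame with rows for each factor, the interaction, and
#'   residuals: `term`, `ss`, `df`, `F`, `p`, `eta2`.
#' @export
anova2_type3 <- function(response, a, b, names_ab = c("A", "B")) {
  a <- factor(a); b <- factor(b)
  if (nlevels(a) < 2 || nlevels(b) < 2) stop("each factor needs >= 2 levels")
  cells <- table(a, b)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: ", levels(a)[empty[1]], " x ", levels(b)[empty[2]])
  }
  ss_total <- sum((response - mean(response))^2)
  d <- data.frame(y = response, A = a, B = b)
  term_names <- c(names_ab[1], names_ab[2],
                  paste0(names_ab[1], ":", names_ab[2]), "Residuals")
  if (ss_total == 0) {
    # constant response: nothing to partition
    n <- length(response)
    dfs <- c(nlevels(a) - 1, nlevels(b) - 1,
             (nlevels(a) - 1) * (nlevels(b) - 1),
             n - nlevels(a) * nlevels(b))
    return(data.frame(term = term_names, ss = 0, df = dfs,
                      F = c(0, 0, 0, NA), p = c(1, 1, 1, NA), eta2 = 0,
                      stringsAsFactors = FALSE))
  }
  fit <- stats::lm(y ~ A * B, data = d,
                   contrasts = list(A = "contr.sum", B = "contr.sum"))
  rss <- sum(stats::residuals(fit)^2)
  if (rss < 1e-10 * ss_total) {
    # saturated fit: car refuses a zero residual SS; compute the Type III
    # (partial) SS directly by dropping each term's sum-to-zero columns
    tab <- type3_ss_saturated(fit, d)
  } else {
    aov3 <- car::Anova(fit, type = 3)
    rows <- c("A", "B", "A:B", "Residuals")
    tab <- aov3[rows, , drop = FALSE]
  }
  data.frame(
    term = term_names,
    ss = tab[["Sum Sq"]],
    df = tab[["Df"]],
    F = c(tab[["F value"]][1:3], NA),
    p = c(tab[["Pr(>F)"]][1:3], NA),
    eta2 = tab[["Sum Sq"]] / ss_total,
    stringsAsFactors = FALSE
  )
}

## Type III SS when the full model fits exactly: for each term, the rise
## in residual SS after removing that term's columns from the
## sum-to-zero design. F is infinite (p = 0) for a nonzero SS and 0
## (p = 1) for a null one; the residual row carries SS 0.
type3_ss_saturated <- function(fit, d) {
  X <- stats::model.matrix(fit)
  y <- d$y
  asg <- attr(X, "assign")  # 0 intercept, 1 A, 2 B, 3 A:B
  rss_of <- function(cols) {
    sum(stats::lm.fit(X[, cols, drop = FALSE], y)$residuals^2)
  }
  full_rss <- rss_of(seq_len(ncol(X)))
  ss <- vapply(1:3, function(term) {
    rss_of(which(asg != term)) - full_rss
  }, numeric(1))
  ss <- pmax(ss, 0)
  dfs <- vapply(1:3, function(term) sum(asg == term), numeric(1))
  tol <- 1e-10 * max(sum((y - mean(y))^2), 1)
  data.frame(
    `Sum Sq` = c(ss, full_rss),
    Df = c(dfs, length(y) - ncol(X)),
    `F value` = c(ifelse(ss > tol, Inf, 0), NA),
    `Pr(>F)` = c(ifelse(ss > tol, 0, 1), NA),
    check.names = FALSE
  )
}

#' Welch unequal-variance t-test
#'
#' Standard Welch statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. When both groups have zero variance the test
#' degenerates: equal means give t = 0, p = 1; unequal means give p = 0
#' with a warning.
#'
#' @param a,b numeric vectors, >= 2 values each.
#' @return List: `t`, `df`, `p`, `mean_a`, `mean_b`, `var_a`, `var_b`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  va <- stats::var(a); vb <- stats::var(b)
  base <- list(mean_a = mean(a), mean_b = mean(b), var_a = va, var_b = vb)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(c(list(t = 0, df = length(a) + length(b) - 2, p = 1), base))
    }
    warning("both groups have zero variance with unequal means; p = 0 by convention")
    return(c(list(t = sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2, p = 0), base))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  c(list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value), base)
}

#' Fecal corticosterone strain-by-week ANOVA
#'
#' Concentrations are natural-log transformed to meet normality
#' assumptions, then analyzed by two-way Type III ANOVA with strain and
#' week (categorical) as crossed factors. The base of the log does not
#' affect F or p; natural log is used so transformed values are
#' reproducible.
#'
#' @param table data.frame with `strain`, `week`, `fcort` (positive).
#' @return ANOVA table as from [anova2_type3()] with terms strain, week,
#'   strain:week, residuals.
#' @export
fcort_analysis <- function(table) {
  stopifnot(all(c("strain", "week", "fcort") %in% names(table)))
  bad <- which(!is.finite(table$fcort) | table$fcort <= 0)
  if (length(bad) > 0) {
    stop("non-positive fCORT values at row(s): ", paste(bad, collapse = ", "))
  }
  anova2_type3(log(table$fcort), table$strain, factor(table$week),
               names_ab = c("strain", "week"))
}
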