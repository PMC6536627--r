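#' Template patterns for the stress response
#'
#' Transcripts are classified within strain by fitting their expression to
#' predicted response patterns over the three stress-history groups
#' (CMS, CMS-R, NH-R): the transient pattern 0:1:0 (elevated only when a
#' novel acute stressor follows chronic stress) and the sustained pattern
#' 1:1:0 (elevated whenever chronic stress occurred). Down-regulation is
#' the inverse of each pattern (1:0:1 and 0:0:1), which under the
#' single-indicator linear model is exactly a sign flip of the slope, so
#' both orientations are covered by one fit per shape.
#'
#' @name templates
#' @keywords internal
NULL

TEMPLATE_SHAPES <- c("TRANSIENT", "SUSTAINED")
TEMPLATE_GROUPS <- c("CMS", "CMS-R", "NH-R")

#' Encode a template pattern as a per-sample indicator
#'
#' Builds the 0/1 regressor for one strain and one template shape. Samples
#' are ordered by group (CMS, CMS-R, NH-R) and the normally housed (NH)
#' group is excluded: the templates are defined only over the three
#' stress-exposed histories.
#'
#' @param samples data.frame with columns `sample_id`, `strain`, `treatment`.
#' @param strain strain label to encode.
#' @param shape `"TRANSIENT"` (0:1:0) or `"SUSTAINED"` (1:1:0).
#' @return Named integer vector (names are sample ids) with one 0/1 entry
#'   per CMS/CMS-R/NH-R sample of the strain, in group order.
#' @export
encode_template <- function(samples, strain, shape = c("TRANSIENT", "SUSTAINED")) {
  shape <- match.arg(shape)
  stopifnot(all(c("sample_id", "strain", "treatment") %in% names(samples)))
  if (!strain %in% samples$strain) {
    stop("strain '", strain, "' not present in sample table")
  }
  sub <- samples[samples$strain == strain & samples$treatment %in% TEMPLATE_GROUPS, , drop = FALSE]
  counts <- table(factor(sub$treatment, levels = TEMPLATE_GROUPS))
  low <- names(counts)[counts < 2]
  if (length(low) > 0) {
    stop("strain '", strain, "' needs at least 2 samples in group(s): ",
         paste(low, collapse = ", "))
  }
  sub <- sub[order(match(sub$treatment, TEMPLATE_GROUPS)), , drop = FALSE]
  weights <- switch(shape,
    TRANSIENT = c("CMS" = 0L, "CMS-R" = 1L, "NH-R" = 0L),
    SUSTAINED = c("CMS" = 1L, "CMS-R" = 1L, "NH-R" = 0L)
  )
  x <- weights[sub$treatment]
  names(x) <- sub$sample_id
  x
}

#' Fit expression to a template indicator by least squares
#'
#' Regresses expression values on a single binary indicator. With a binary
#' regressor the slope t-test is algebraically identical to the
#' pooled-variance two-sample t-test grouping `y` by `x`; that equivalence
#' is the documented oracle for this fit. Degrees of freedom are n - 2.
#'
#' @param y numeric expression values (log2 scale).
#' @param x 0/1 indicator of the same length, containing both values.
#' @return List with `beta` (log2 slope), `se`, `t`, `df`, `p` (two-sided).
#'   Zero variance in `y` returns `beta = 0, p = 1` (non-responsive by
#'   convention) so all-flat fixtures pass through.
#' @export
fit_template <- function(y, x) {
  n <- length(y)
  if (length(x) != n || n < 4) {
    stop("y and x must have equal length >= 4")
  }
  if (!all(x %in% c(0, 1)) || length(unique(x)) < 2) {
    stop("x must be a binary indicator containing both 0 and 1")
  }
  if (anyNA(y) || any(!is.finite(y))) stop("y must be finite")
  syy <- sum((y - mean(y))^2)
  df <- n - 2L
  if (syy == 0) {
    return(list(beta = 0, se = NA_real_, t = 0, df = df, p = 1))
  }
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  beta <- sum(xc * y) / sxx
  rss <- max(syy - beta^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  if (se == 0) {
    tt <- sign(beta) * Inf
    p <- if (beta == 0) 1 else 0
  } else {
    tt <- beta / se
    p <- 2 * stats::pt(-abs(tt), df)
  }
  list(beta = beta, se = se, t = tt, df = df, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order, clipped at 1, monotone.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' NH-R vs CMS-R contrast with linear-scale relative change
#'
#' The prioritization filter: Welch unequal-variance two-sided t-test
#' between the two restrained groups, and the relative change on the
#' linear (unlogged) scale, `2^(mean log2 CMS-R - mean log2 NH-R) - 1`.
#'
#' @param y_nhr log2 values for NH-R samples (>= 2).
#' @param y_cmsr log2 values for CMS-R samples (>= 2).
#' @return List with `p` (Welch two-sided) and `rel_change` (fraction;
#'   +1.00 means a doubling).
#' @export
contrast_nhr_cmsr <- function(y_nhr, y_cmsr) {
  if (length(y_nhr) < 2 || length(y_cmsr) < 2) {
    stop("need at least 2 values per group for the NH-R vs CMS-R contrast")
  }
  w <- welch_t(y_nhr, y_cmsr)
  list(p = w$p, rel_change = 2^(mean(y_cmsr) - mean(y_nhr)) - 1)
}

## Vectorised per-row pooled regression of a matrix on a fixed binary
## indicator; returns beta, t, p with df = n - 2. Rows with zero variance
## get beta 0, p 1.
row_indicator_fit <- function(Y, x) {
  n <- length(x)
  df <- n - 2
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  rm <- rowMeans(Y)
  syy <- rowSums((Y - rm)^2)
  beta <- as.vector(Y %*% xc) / sxx
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  tt <- ifelse(se == 0, ifelse(beta == 0, 0, sign(beta) * Inf), beta / se)
  p <- ifelse(syy == 0, 1,
              ifelse(se == 0 & beta != 0, 0, 2 * stats::pt(-abs(tt), df)))
  beta[syy == 0] <- 0
  tt[syy == 0] <- 0
  list(beta = beta, t = tt, p = p)
}

## Vectorised per-row Welch test between two column subsets.
row_welch <- function(A, B) {
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1)
  v2 <- rowSums((B - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- ifelse(se2 == 0, ifelse(m1 == m2, 0, Inf), (m2 - m1) / sqrt(se2))
  df <- ifelse(se2 == 0, n1 + n2 - 2,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))))
  p <- ifelse(se2 == 0, ifelse(m1 == m2, 1, 0), 2 * stats::pt(-abs(tt), df))
  list(t = tt, df = df, p = p, mean_a = m1, mean_b = m2)
}

#' Per-transcript template fits for one strain
#'
#' Fits both template shapes to every transcript of one strain and returns
#' the per-shape slopes, t statistics and p-values. Used internally by
#' [call_stress_transcripts()] and useful for calibration checks.
#'
#' @param mat numeric matrix, transcripts x samples (log2), with rownames
#'   (transcript ids) and colnames (sample ids).
#' @param samples sample table (see [encode_template()]).
#' @param strain strain label.
#' @return data.frame with one row per transcript: `beta_transient`,
#'   `t_transient`, `p_transient`, `beta_sustained`, `t_sustained`,
#'   `p_sustained`.
#' @export
template_fits <- function(mat, samples, strain) {
  res <- lapply(TEMPLATE_SHAPES, function(shape) {
    x <- encode_template(samples, strain, shape)
    missing <- setdiff(names(x), colnames(mat))
    if (length(missing) > 0) {
      stop("samples absent from matrix: ", paste(missing, collapse = ", "))
    }
    row_indicator_fit(mat[, names(x), drop = FALSE], as.numeric(x))
  })
  names(res) <- TEMPLATE_SHAPES
  data.frame(
    transcript = rownames(mat),
    beta_transient = res$TRANSIENT$beta,
    t_transient = res$TRANSIENT$t,
    p_transient = res$TRANSIENT$p,
    beta_sustained = res$SUSTAINED$beta,
    t_sustained = res$SUSTAINED$t,
    p_sustained = res$SUSTAINED$p,
    stringsAsFactors = FALSE
  )
}

#' Call stress-responsive transcripts per strain
#'
#' The full within-strain classification: both template shapes are fit to
#' every transcript; a transcript is a candidate when its better template
#' p-value is at or below `alpha`; the best shape is the one with the
#' smaller p (ties broken by larger |t|, then TRANSIENT); direction is UP
#' when the best fit's slope points toward higher expression on the
#' chronic-stress side. Candidates are then prioritized by the NH-R vs
#' CMS-R contrast: a call passes when additionally the Welch contrast has
#' p < `alpha` and the linear-scale relative change exceeds `fc_threshold`
#' in the called direction. BH q-values over the best-template p-values are
#' reported per strain but do not gate the calls (few survive FDR at these
#' group sizes; the nominal threshold is the descriptive criterion).
#'
#' @param mat transcripts x samples log2 matrix with dimnames.
#' @param samples sample table with `sample_id`, `strain`, `treatment`.
#' @param alpha nominal significance threshold (template p <= alpha,
#'   contrast p < alpha). Default 0.05.
#' @param fc_threshold minimum linear-scale relative change, strict
#'   inequality. Default 0.10.
#' @return data.frame with one row per transcript x strain: `transcript`,
#'   `strain`, `shape`, `direction`, `template_p`, `q`, `contrast_p`,
#'   `rel_change`, `passes`.
#' @export
call_stress_transcripts <- function(mat, samples, alpha = 0.05, fc_threshold = 0.10) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (any(!is.finite(mat))) stop("expression matrix contains non-finite values")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids in sample table")
  strains <- unique(samples$strain)
  out <- lapply(strains, function(st) {
    fits <- template_fits(mat, samples, st)
    pick_sus <- (fits$p_sustained < fits$p_transient) |
      (fits$p_sustained == fits$p_transient &
         abs(fits$t_sustained) > abs(fits$t_transient))
    shape <- ifelse(pick_sus, "SUSTAINED", "TRANSIENT")
    beta <- ifelse(pick_sus, fits$beta_sustained, fits$beta_transient)
    template_p <- ifelse(pick_sus, fits$p_sustained, fits$p_transient)
    direction <- ifelse(beta > 0, "UP", ifelse(beta < 0, "DOWN", NA_character_))

    nhr <- samples$sample_id[samples$strain == st & samples$treatment == "NH-R"]
    cmsr <- samples$sample_id[samples$strain == st & samples$treatment == "CMS-R"]
    w <- row_welch(mat[, nhr, drop = FALSE], mat[, cmsr, drop = FALSE])
    rel <- 2^(w$mean_b - w$mean_a) - 1

    dir_sign <- ifelse(is.na(direction), 0, ifelse(direction == "UP", 1, -1))
    passes <- !is.na(direction) &
      template_p <= alpha &
      w$p < alpha &
      abs(rel) > fc_threshold &
      sign(rel) == dir_sign
    data.frame(
      transcript = fits$transcript,
      strain = st,
      shape = shape,
      direction = direction,
      template_p = template_p,
      q = bh_adjust(template_p),
      contrast_p = w$p,
      rel_change = rel,
      passes = passes,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Direction-bias chi-square test for one strain
#'
#' Tests whether passing calls split evenly between up- and down-regulation
#' using a 1-df goodness-of-fit chi-square against 50:50:
#' `(n_up - n_down)^2 / (n_up + n_down)`.
#'
#' @param calls output of [call_stress_transcripts()].
#' @param strain strain label to test.
#' @return One-row data.frame: `strain`, `n_up`, `n_down`, `chisq`, `p`.
#' @export
direction_bias_test <- function(calls, strain) {
  sub <- calls[calls$strain == strain & calls$passes, , drop = FALSE]
  n_up <- sum(sub$direction == "UP")
  n_down <- sum(sub$direction == "DOWN")
  if (n_up + n_down == 0) {
    stop("no passing calls for strain '", strain, "': direction bias test undefined")
  }
  stat <- (n_up - n_down)^2 / (n_up + n_down)
  data.frame(
    strain = strain, n_up = n_up, n_down = n_down,
    chisq = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
}
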