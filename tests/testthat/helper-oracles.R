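# Independent oracle implementations used to check package operations.
# These deliberately use textbook formulas / brute force, not the code
# paths they validate.

# pooled-variance two-sample t-test from the textbook formula, grouping
# y by the binary indicator x (x == 1 is the "treated" side)
oracle_pooled_t <- function(y, x) {
  a <- y[x == 0]; b <- y[x == 1]
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Welch statistic and Welch-Satterthwaite df from the hand formula
oracle_welch <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a); v2 <- var(b)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# brute-force BH step-up: sort, scale by m/rank, cummin from the largest,
# clip at 1, restore input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- sorted * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# classical balanced two-way ANOVA decomposition from cell means
oracle_anova2_balanced <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  n <- table(A, B)[1, 1]
  stopifnot(all(table(A, B) == n))
  g <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  cells <- tapply(y, list(A, B), mean)
  nB <- nlevels(B); nA <- nlevels(A)
  ss_a <- n * nB * sum((mA - g)^2)
  ss_b <- n * nA * sum((mB - g)^2)
  # interaction: n * sum (cell - rowmean - colmean + grand)^2
  dev <- sweep(sweep(cells, 1, mA), 2, mB) + g
  ss_ab <- n * sum(dev^2)
  ss_res <- sum((y - cells[cbind(A, B)])^2)
  df_a <- nA - 1; df_b <- nB - 1; df_ab <- df_a * df_b
  df_res <- length(y) - nA * nB
  f <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab) / (ss_res / df_res)
  list(ss = c(ss_a, ss_b, ss_ab, ss_res),
       df = c(df_a, df_b, df_ab, df_res),
       F = f,
       p = pf(f, c(df_a, df_b, df_ab), df_res, lower.tail = FALSE),
       ss_total = sum((y - g)^2))
}

# exhaustive hypergeometric upper tail: probability of >= k special ids
# when drawing n from a universe of N containing m specials, by
# enumerating all C(N, n) draws
oracle_hyper_tail_enum <- function(N, m, n, k) {
  draws <- combn(N, n)
  special <- seq_len(m)
  hits <- colSums(matrix(draws %in% special, nrow = n))
  mean(hits >= k)
}

# closed-form hypergeometric upper tail from binomial coefficients
oracle_hyper_tail_choose <- function(N, m, n, k) {
  ks <- k:min(m, n)
  sum(choose(m, ks) * choose(N - m, n - ks)) / choose(N, n)
}

# Monte Carlo estimate of the null rate of min(p_transient, p_sustained)
# <= alpha for one strain's design (reps per group), using t.test as the
# independent test engine
oracle_minp_null_rate <- function(n_sim, reps, alpha = 0.05, seed = 1) {
  set.seed(seed)
  x_tr <- rep(c(0, 1, 0), each = reps)  # CMS, CMS-R, NH-R
  x_su <- rep(c(1, 1, 0), each = reps)
  hits <- vapply(seq_len(n_sim), function(i) {
    y <- rnorm(3 * reps)
    p1 <- t.test(y[x_tr == 1], y[x_tr == 0], var.equal = TRUE)$p.value
    p2 <- t.test(y[x_su == 1], y[x_su == 0], var.equal = TRUE)$p.value
    min(p1, p2) <= alpha
  }, logical(1))
  mean(hits)
}
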