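# The study's statistical comparisons as reusable operations. The
# mixed-design (one between-subject factor, one complete within-subject
# factor) repeated-measures ANOVA is computed from its sums-of-squares
# partition; the many-to-one post hoc tests are Dunnett's (adjusted via a
# seeded Monte-Carlo evaluation of the equicorrelated multivariate t
# distribution) and Dunn's rank-based test with Bonferroni-style
# adjustment. Two-sample t tests go through stats::t.test.

#' Long-format table for a mixed-design ANOVA
#'
#' @param subject Subject (cell) identifier.
#' @param between Between-subject factor level (e.g. genotype).
#' @param within Within-subject factor level (e.g. current step).
#' @param value Response (e.g. number of action potentials).
#' @return A validated data frame of class `long_table`. Each subject must
#'   appear at exactly one between level and at every within level exactly
#'   once (complete design).
#' @export
long_table <- function(subject, between, within, value) {
  d <- data.frame(subject = as.character(subject),
                  between = as.character(between),
                  within = as.character(within),
                  value = as.numeric(value))
  lv <- unique(d$within)
  bad_b <- tapply(d$between, d$subject, function(x) length(unique(x)) > 1L)
  if (any(bad_b)) {
    stop("subject(s) at more than one between level: ",
         paste(names(bad_b)[bad_b], collapse = ", "))
  }
  tabs <- table(d$subject, d$within)
  if (any(tabs != 1L)) {
    off <- rownames(tabs)[rowSums(tabs != 1L) > 0][1L]
    stop("incomplete or duplicated within-factor design for subject ", off)
  }
  class(d) <- c("long_table", "data.frame")
  d
}

#' Two-way repeated-measures (mixed-design) ANOVA
#'
#' One between-subject factor (subjects nested in its levels) crossed with
#' one complete within-subject factor. The sums of squares follow the
#' classical univariate partition: the between-subject stratum splits into
#' the between-factor effect and subjects-within-groups (the error term for
#' the between effect); the within-subject stratum splits into the within
#' main effect, the interaction, and the within-error term. No sphericity
#' correction is applied by default; Greenhouse-Geisser adjustment of the
#' within-stratum degrees of freedom is available.
#'
#' @param t A [long_table()].
#' @param gg Apply Greenhouse-Geisser correction to the within-stratum
#'   tests (default `FALSE`).
#' @return A data frame of class `anova_result`: one row per effect
#'   (`between`, `within`, `interaction`) with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_two_way <- function(t, gg = FALSE) {
  if (!inherits(t, "long_table")) {
    t <- long_table(t$subject, t$between, t$within, t$value)
  }
  subj <- unique(t$subject)
  grp_of <- tapply(t$between, t$subject, function(x) x[1L])[subj]
  groups <- unique(t$between)
  p_lev <- length(groups)
  q_lev <- length(unique(t$within))
  if (p_lev < 2L || q_lev < 2L) stop("need >= 2 levels of each factor")
  if (any(table(grp_of) < 2L)) stop("singleton between-subject group")

  # response matrix: subjects x within levels
  Y <- matrix(NA_real_, length(subj), q_lev,
              dimnames = list(subj, unique(t$within)))
  Y[cbind(match(t$subject, rownames(Y)), match(t$within, colnames(Y)))] <- t$value
  g <- factor(grp_of, levels = groups)
  res <- rm_anova_matrix(Y, g, gg = gg)
  res
}

# Core computation on a subjects x within matrix with a group factor.
# Kept separate so Monte-Carlo calibration loops avoid data-frame overhead.
rm_anova_matrix <- function(Y, g, gg = FALSE) {
  n_s <- nrow(Y); q <- ncol(Y)
  ns_g <- tabulate(g)
  p <- nlevels(g)
  N <- n_s * q
  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  grp_means <- tapply(subj_means, g, mean)
  within_means <- colMeans(Y)
  # cell means: group x within
  cell <- rowsum(Y, g) / ns_g

  ss_total <- sum((Y - grand)^2)
  ss_bs <- q * sum((subj_means - grand)^2)
  ss_A <- q * sum(ns_g * (grp_means - grand)^2)
  ss_subj <- ss_bs - ss_A
  ss_B <- n_s * sum((within_means - grand)^2)
  ss_AB <- sum(ns_g * (cell - outer(as.numeric(grp_means), rep(1, q)) -
                         outer(rep(1, p), within_means) + grand)^2)
  ss_werr <- ss_total - ss_bs - ss_B - ss_AB

  df_A <- p - 1; df_subj <- n_s - p
  df_B <- q - 1; df_AB <- (p - 1) * (q - 1); df_werr <- (n_s - p) * (q - 1)
  eps <- 1
  if (gg) {
    # Greenhouse-Geisser epsilon from the pooled within-group covariance
    resid <- Y - cell[as.integer(g), , drop = FALSE]
    S <- crossprod(resid) / df_subj
    Sd <- S - outer(rowMeans(S), rep(1, q)) - outer(rep(1, q), colMeans(S)) + mean(S)
    eps <- sum(diag(Sd))^2 / ((q - 1) * sum(Sd^2))
    eps <- min(1, max(eps, 1 / (q - 1)))
  }
  F_A <- (ss_A / df_A) / (ss_subj / df_subj)
  F_B <- (ss_B / df_B) / (ss_werr / df_werr)
  F_AB <- (ss_AB / df_AB) / (ss_werr / df_werr)
  out <- data.frame(
    effect = c("between", "within", "interaction"),
    F = c(F_A, F_B, F_AB),
    df1 = c(df_A, df_B * eps, df_AB * eps),
    df2 = c(df_subj, df_werr * eps, df_werr * eps),
    p = c(stats::pf(F_A, df_A, df_subj, lower.tail = FALSE),
          stats::pf(F_B, df_B * eps, df_werr * eps, lower.tail = FALSE),
          stats::pf(F_AB, df_AB * eps, df_werr * eps, lower.tail = FALSE))
  )
  attr(out, "ss") <- c(total = ss_total, between_subjects = ss_bs,
                       between = ss_A, subjects_within = ss_subj,
                       within = ss_B, interaction = ss_AB, within_error = ss_werr)
  class(out) <- c("anova_result", "data.frame")
  out
}

#' One-way ANOVA with comparisons to a control group
#'
#' Omnibus one-way fixed-effects ANOVA followed by many-to-one post hoc
#' comparisons of every other group against the control. `method =
#' "dunnett"` adjusts each comparison by the distribution of the maximum
#' absolute Dunnett statistic, evaluated by seeded Monte Carlo on the
#' correlated multivariate t; `method = "dunn"` uses rank-based many-to-one
#' z tests with Bonferroni adjustment.
#'
#' @param groups List of numeric vectors, one per group.
#' @param control Index of the control group in `groups` (default 1).
#' @param method `"dunnett"` or `"dunn"`.
#' @param seed Seed for the Monte-Carlo adjustment.
#' @param B Number of Monte-Carlo draws.
#' @return List with `anova` (one row `anova_result`) and `posthoc` (data
#'   frame of class `posthoc_result`: `comparison`, `estimate`, `statistic`,
#'   `p_adjusted`, `method`).
#' @export
one_way_anova_control <- function(groups, control = 1L,
                                  method = c("dunnett", "dunn"),
                                  seed = 1, B = 20000L) {
  method <- match.arg(method)
  k <- length(groups)
  if (k < 2L) stop("need at least two groups")
  if (control < 1L || control > k) stop("control index out of range")
  if (any(vapply(groups, length, integer(1)) < 2L)) stop("each group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))

  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_len(k), vapply(groups, length, integer(1))))
  ns <- tabulate(f)
  N <- length(y)
  grand <- mean(y)
  means <- tapply(y, f, mean)
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((y - means[f])^2)
  df1 <- k - 1; df2 <- N - k
  Fstat <- (ss_b / df1) / (ss_w / df2)
  omnibus <- data.frame(effect = "group", F = Fstat, df1 = df1, df2 = df2,
                        p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
  class(omnibus) <- c("anova_result", "data.frame")

  others <- setdiff(seq_len(k), control)
  if (method == "dunnett") {
    s2 <- ss_w / df2
    tstat <- (means[others] - means[control]) /
      sqrt(s2 * (1 / ns[others] + 1 / ns[control]))
    padj <- dunnett_padj(abs(tstat), ns = ns, control = control, df = df2,
                         seed = seed, B = B)
    est <- means[others] - means[control]
    stat <- tstat
  } else {
    r <- rank(y)
    rbar <- tapply(r, f, mean)
    sigma2 <- N * (N + 1) / 12
    ties <- table(r[duplicated(r) | duplicated(r, fromLast = TRUE)])
    if (length(ties)) {
      tie_sizes <- as.integer(table(y)[table(y) > 1])
      sigma2 <- sigma2 - sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
    }
    z <- (rbar[others] - rbar[control]) /
      sqrt(sigma2 * (1 / ns[others] + 1 / ns[control]))
    padj <- pmin(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE) * length(others))
    est <- rbar[others] - rbar[control]
    stat <- z
  }
  ph <- data.frame(
    comparison = paste(names(groups)[others], "vs", names(groups)[control]),
    estimate = as.numeric(est), statistic = as.numeric(stat),
    p_adjusted = as.numeric(padj), method = method)
  class(ph) <- c("posthoc_result", "data.frame")
  list(anova = omnibus, posthoc = ph)
}

# Monte-Carlo adjusted p for Dunnett many-to-one comparisons: for each
# observed |t|, P(max_i |T_i| >= |t|) where (T_1..T_m) share the control
# group mean and a pooled variance estimate (equicorrelated multivariate t
# in the balanced case). Seeded and restored via on.exit.
dunnett_padj <- function(abs_t, ns, control, df, seed = 1, B = 20000L) {
  others <- setdiff(seq_along(ns), control)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  z0 <- stats::rnorm(B, 0, sqrt(1 / ns[control]))
  s <- sqrt(stats::rchisq(B, df) / df)
  maxT <- rep(0, B)
  for (i in others) {
    zi <- stats::rnorm(B, 0, sqrt(1 / ns[i]))
    Ti <- abs(zi - z0) / (s * sqrt(1 / ns[i] + 1 / ns[control]))
    maxT <- pmax(maxT, Ti)
  }
  vapply(abs_t, function(tt) (sum(maxT >= tt) + 1) / (B + 1), numeric(1))
}

#' Two-sample t test
#'
#' Thin wrapper over [stats::t.test()] reporting the statistic, degrees of
#' freedom and two-sided p value. When both samples have zero variance and
#' equal means the comparison is degenerate and `p = 1` is returned by
#' convention.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param welch Use the Welch (unequal-variance) statistic; default
#'   `FALSE` (Student, pooled variance).
#' @return List: `t`, `df`, `p`, `mean_diff`.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      message("zero variance in both samples with equal means; p = 1 by convention")
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_diff = 0))
    }
    stop("zero variance in both samples with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(diff(rev(ht$estimate))))
}
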