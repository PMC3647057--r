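#' Group summary triple
#'
#' The (mean, SD, n) unit of the published compartment tables.
#'
#' @param label group label.
#' @param mean group mean.
#' @param sd sample standard deviation (>= 0).
#' @param n number of replicates (kidneys).
#' @return Object of class `group_summary`.
#' @export
group_summary <- function(label, mean, sd, n) {
  if (sd < 0) stop("sd must be >= 0")
  structure(list(label = label, mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

new_test_result <- function(method, statistic, df, p, pairwise = NULL,
                            degenerate = FALSE) {
  structure(list(method = method, statistic = statistic, df = df,
                 p = p, pairwise = pairwise, degenerate = degenerate),
            class = "renograft_test")
}

#' @export
print.renograft_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g%s\n", x$method,
              x$statistic, paste(signif(x$df, 6), collapse = ", "), x$p,
              if (x$degenerate) " (degenerate)" else ""))
  if (!is.null(x$pairwise)) print(x$pairwise, ...)
  invisible(x)
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Equal-variance unpaired t-test computed from (mean, SD, n) alone, the
#' form needed to recompute the published between-condition comparisons from
#' table cells: pooled variance
#' s2 = ((n_a - 1) SD_a^2 + (n_b - 1) SD_b^2) / (n_a + n_b - 2),
#' t = (m_a - m_b) / sqrt(s2 (1/n_a + 1/n_b)), df = n_a + n_b - 2,
#' two-sided p.
#'
#' @param a,b `group_summary` objects with n >= 2.
#' @return A test result with `statistic` (t), `df`, `p`. Degenerate inputs
#'   (both SDs zero): p = 1 when the means are equal, p = 0 (flagged) when
#'   they differ.
#' @export
unpaired_t_from_summary <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$n < 2 || b$n < 2) stop("both groups need n >= 2")
  df <- a$n + b$n - 2
  s2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  se <- sqrt(s2 * (1 / a$n + 1 / b$n))
  if (se == 0) {
    if (a$mean == b$mean)
      return(new_test_result("unpaired t (pooled variance)", 0, df, 1,
                             degenerate = TRUE))
    return(new_test_result("unpaired t (pooled variance)",
                           sign(a$mean - b$mean) * Inf, df, 0,
                           degenerate = TRUE))
  }
  t <- (a$mean - b$mean) / se
  new_test_result("unpaired t (pooled variance)", t, df,
                  2 * stats::pt(-abs(t), df))
}

#' Paired t-test on per-subject differences
#'
#' One-sample two-sided t-test of the paired differences against zero (the
#' within-kidney before/after comparison). A zero-SD nonzero-difference
#' input is flagged degenerate with p = 0.
#'
#' @param differences numeric vector of per-subject differences, length >= 2.
#' @return A test result with `statistic` (t), `df`, `p`.
#' @export
paired_t <- function(differences) {
  n <- length(differences)
  if (n < 2) stop("paired test needs >= 2 pairs")
  m <- mean(differences); s <- stats::sd(differences)
  if (s == 0) {
    if (m == 0) return(new_test_result("paired t", 0, n - 1, 1, degenerate = TRUE))
    return(new_test_result("paired t", sign(m) * Inf, n - 1, 0, degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  new_test_result("paired t", t, n - 1, 2 * stats::pt(-abs(t), n - 1))
}

.as_summaries <- function(groups) {
  lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (inherits(g, "group_summary")) return(g)
    if (is.numeric(g)) {
      lab <- if (!is.null(names(groups))) names(groups)[i] else paste0("g", i)
      return(group_summary(lab, mean(g), stats::sd(g), length(g)))
    }
    stop("groups must be group_summary objects or numeric vectors")
  })
}

#' One-way ANOVA with Tukey's multiple-comparison test
#'
#' Accepts three or more groups, either as raw per-kidney values or as
#' (mean, SD, n) summaries (between- and within-group sums of squares are
#' identities of the summaries, so both routes agree exactly). Pairwise
#' comparisons use the studentized-range distribution with parameters
#' (k, N - k): q = |m_i - m_j| / sqrt(MSW/2 (1/n_i + 1/n_j)), adjusted
#' p = P(Q >= q).
#'
#' @param groups named list of `group_summary` objects or numeric vectors;
#'   >= 3 groups, each n >= 2.
#' @param allow_two permit a two-group analysis (useful to exercise the
#'   F = t^2 reduction); by default two groups are redirected to
#'   [unpaired_t_from_summary()].
#' @return A test result with `statistic` (F), `df` = c(k - 1, N - k), `p`
#'   (ANOVA), and `pairwise`: a data.frame of Tukey-adjusted comparisons.
#' @export
one_way_anova_tukey <- function(groups, allow_two = FALSE) {
  if (length(groups) < if (allow_two) 2 else 3)
    stop("need >= 3 groups; for two groups use unpaired_t_from_summary")
  gs <- .as_summaries(groups)
  if (any(vapply(gs, function(g) g$n < 2, logical(1))))
    stop("every group needs n >= 2")
  k <- length(gs)
  ns <- vapply(gs, function(g) g$n, integer(1))
  ms <- vapply(gs, function(g) g$mean, numeric(1))
  ss <- vapply(gs, function(g) g$sd, numeric(1))
  N <- sum(ns)
  gm <- sum(ns * ms) / N
  ssb <- sum(ns * (ms - gm)^2)
  ssw <- sum((ns - 1) * ss^2)
  df1 <- k - 1; df2 <- N - k
  msw <- ssw / df2
  if (msw == 0) {
    F <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    F <- (ssb / df1) / msw
    p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  }
  pairs <- utils::combn(k, 2)
  labels <- vapply(gs, function(g) g$label, character(1))
  pw <- data.frame(
    group_a = labels[pairs[1, ]], group_b = labels[pairs[2, ]],
    diff = ms[pairs[1, ]] - ms[pairs[2, ]]
  )
  if (msw == 0) {
    pw$q <- ifelse(pw$diff == 0, 0, Inf)
    pw$p_adj <- ifelse(pw$diff == 0, 1, 0)
  } else {
    se <- sqrt(msw / 2 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
    pw$q <- abs(pw$diff) / se
    pw$p_adj <- stats::ptukey(pw$q, nmeans = k, df = df2, lower.tail = FALSE)
  }
  new_test_result("one-way ANOVA + Tukey", F, c(df1, df2), p, pairwise = pw,
                  degenerate = msw == 0)
}
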