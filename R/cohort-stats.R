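#' Mann-Whitney U test with effect size r
#'
#' Rank-sum comparison of two independent small samples, reported the way
#' small clinical cohorts are analysed: the U statistic, a z-score from the
#' tie-corrected normal approximation with continuity correction, a
#' two-tailed p-value, and the effect size `r = |z| / sqrt(nA + nB)` with
#' its conventional label (>= 0.1 small, >= 0.3 moderate, >= 0.5 large).
#'
#' `method = "exact"` computes the two-tailed p by full enumeration of the
#' permutation distribution of U (feasible for small groups, required
#' untied for a clean reference); `"auto"` (default) uses enumeration for
#' untied samples with `nA + nB <= 20` and the normal approximation
#' otherwise. The z-score and r always come from the normal approximation.
#'
#' @param group_a,group_b Numeric vectors (each non-empty).
#' @param method `"auto"`, `"asymptotic"`, or `"exact"`.
#' @return One-row tibble `(n_a, n_b, u, z, p, r, effect, method)`.
#' @export
mann_whitney_with_effect <- function(group_a, group_b,
                                     method = c("auto", "asymptotic", "exact")) {
  method <- match.arg(method)
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)
  ra <- sum(rk[seq_len(na)])
  ua <- ra - na * (na + 1) / 2
  u <- min(ua, na * nb - ua)

  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  mu <- na * nb / 2
  sig2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sig2 <= 0) {                       # all values identical
    z <- 0; p_asy <- 1
  } else {
    cc <- min(abs(ua - mu), 0.5)         # continuity correction toward the mean
    z <- sign(ua - mu) * (abs(ua - mu) - cc) / sqrt(sig2)
    # Edgeworth refinement: U is symmetric, so the first correction to the
    # normal CDF is the kurtosis term. Exact fourth central moment (untied):
    # mu4 = mn(N+1)/240 * [5mn(m+n) + 3mn - 2(m+n) - 2(m^2+n^2)]
    sig2_free <- na * nb * (n + 1) / 12
    mu4 <- na * nb * (n + 1) / 240 *
      (5 * na * nb * n + 3 * na * nb - 2 * n - 2 * (na^2 + nb^2))
    g2 <- mu4 / sig2_free^2 - 3
    zc <- abs(z)
    tail <- pnorm(-zc) - stats::dnorm(zc) * (g2 / 24) * (3 * zc - zc^3)
    p_asy <- min(1, max(0, 2 * tail))
  }

  has_ties <- any(ties > 1)
  use_exact <- method == "exact" || (method == "auto" && !has_ties && n <= 20)
  p <- if (use_exact) mw_exact_p(group_a, group_b) else p_asy
  if (sig2 <= 0) p <- 1
  r <- abs(z) / sqrt(n)
  tibble(n_a = na, n_b = nb, u = u, z = z, p = p, r = r,
         effect = effect_size_label(r),
         method = if (use_exact) "exact" else "asymptotic")
}

# Exact two-tailed Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups: p = 2 * min(P(U <= u), P(U >= u)),
# capped at 1. Independent reference for the normal approximation.
mw_exact_p <- function(group_a, group_b) {
  na <- length(group_a); n <- na + length(group_b)
  rk <- rank(c(group_a, group_b))
  ua_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(n, na)
  ua_all <- colSums(matrix(rk[sets], nrow = na)) - na * (na + 1) / 2
  eps <- 1e-9
  p_le <- mean(ua_all <= ua_obs + eps)
  p_ge <- mean(ua_all >= ua_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

#' Effect-size label for Mann-Whitney r
#'
#' Half-open bands partitioning `[0, Inf)`: `[0, 0.1)` none, `[0.1, 0.3)`
#' small, `[0.3, 0.5)` moderate, `[0.5, Inf)` large.
#'
#' @param r Non-negative effect size(s).
#' @return Character vector of labels.
#' @export
effect_size_label <- function(r) {
  stopifnot(all(r >= 0))
  as.character(cut(r, breaks = c(0, 0.1, 0.3, 0.5, Inf), right = FALSE,
                   labels = c("none", "small", "moderate", "large")))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's statistic without continuity correction, after dropping
#' all-zero rows and columns; degrees of freedom come from the reduced
#' table. This is the categorical-comparison convention that reproduces
#' printed small-cohort p-values (Yates correction does not).
#'
#' @param table Integer matrix of counts (R x C).
#' @return One-row tibble `(chi2, df, p)`.
#' @export
pearson_chi_square <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) {
    abort("contingency table must hold non-negative integer counts",
          class = "cptstress_error_input")
  }
  m <- m[rowSums(m) > 0, , drop = FALSE]
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("degenerate contingency table after dropping all-zero rows/columns",
          class = "cptstress_error_degenerate_table")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble(chi2 = unname(res$statistic), df = unname(res$parameter),
         p = unname(res$p.value))
}

#' Pooled-variance two-sample t-test
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return One-row tibble `(t, df, p)` (two-tailed).
#' @export
two_sample_t <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  na <- length(group_a); nb <- length(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  df <- na + nb - 2
  if (sp2 == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(tibble(t = 0, df = df, p = 1))
    }
    return(tibble(t = sign(mean(group_a) - mean(group_b)) * Inf, df = df, p = 0))
  }
  tstat <- (mean(group_a) - mean(group_b)) / sqrt(sp2 * (1 / na + 1 / nb))
  tibble(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Median and interquartile range
#'
#' Quartiles use (n+1)-based weighted-average interpolation by default
#' (quantile type 6, the HAVERAGE convention of common clinical software);
#' the convention is configurable.
#'
#' @param values Numeric vector, length >= 1.
#' @param type Quantile type passed to [stats::quantile()].
#' @return One-row tibble `(median, p25, p75, n)`.
#' @export
median_iqr <- function(values, type = 6) {
  values <- values[is.finite(values)]
  stopifnot(length(values) >= 1)
  q <- quantile(values, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  tibble(median = q[2], p25 = q[1], p75 = q[3], n = length(values))
}

feasibility_statuses <- c("complete", "non_adherent", "technical",
                          "combination", "refusal", "dropout")

#' Tally measurement-completion reasons per study stage
#'
#' Counts participants per stage and completion status (the closed
#' taxonomy: complete, non-adherent participant, technical issue,
#' combination, participant refusal, drop-out) with percentages over the
#' participants enrolled at that stage.
#'
#' @param records Tibble `(id, stage, status)`, one row per participant and
#'   stage.
#' @return Tibble `(stage, status, n, enrolled, pct)`; statuses absent at a
#'   stage appear with `n = 0`.
#' @export
feasibility_tally <- function(records) {
  bad <- setdiff(unique(records$status), feasibility_statuses)
  if (length(bad)) {
    abort(paste0("unknown completion status: ", paste(bad, collapse = ", ")),
          class = "cptstress_error_input")
  }
  enrolled <- records |> dplyr::summarise(enrolled = dplyr::n(), .by = "stage")
  tidyr::expand_grid(stage = unique(records$stage),
                     status = feasibility_statuses) |>
    dplyr::left_join(
      records |> dplyr::summarise(n = dplyr::n(), .by = c("stage", "status")),
      by = c("stage", "status")
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::left_join(enrolled, by = "stage") |>
    dplyr::mutate(pct = 100 * .data$n / .data$enrolled)
}
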