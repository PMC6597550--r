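#' Pearson correlation test
#'
#' Sample Pearson coefficient with the exact t transform:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, two-sided p from the Student t
#' distribution with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, finite, each with
#'   positive variance.
#' @return List of class `correlation_result`: `n`, `r`, `r_squared`,
#'   `t_statistic`, `df`, `p_two_sided`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  xd <- x - mean(x); yd <- y - mean(y)
  sx <- sqrt(sum(xd^2)); sy <- sqrt(sum(yd^2))
  if (sx == 0 || sy == 0) stop("zero-variance input")
  r <- sum(xd * yd) / (sx * sy)
  r <- max(-1, min(1, r))
  df <- n - 2L
  t_stat <- if (abs(r) == 1) Inf * sign(r) else r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(t_stat), df)
  structure(list(n = n, r = r, r_squared = r^2, t_statistic = t_stat,
                 df = df, p_two_sided = p),
            class = "correlation_result")
}

#' Two-sided p-value from a printed r-squared and sample size
#'
#' Worked-example bridge for published correlations that report r^2 and p
#' but not the underlying data: applies the same t transform as
#' [pearson_test()], so it is consistent with it on any dataset having that
#' `r_squared` and `n`.
#'
#' @param r_squared coefficient of determination in `[0, 1)`.
#' @param n number of pairs, `>= 3`.
#' @param sign optional sign of r (the two-sided p does not depend on it).
#' @return Two-sided p-value.
#' @export
correlation_p_from_r2 <- function(r_squared, n, sign = 1) {
  if (r_squared < 0 || r_squared >= 1) stop("r_squared must lie in [0, 1)")
  if (n < 3) stop("need n >= 3")
  df <- n - 2
  t_stat <- sqrt(r_squared) * sqrt(df) / sqrt(1 - r_squared)
  2 * pt(-abs(t_stat), df)
}

#' One-way analysis of variance
#'
#' Classical between/within sum-of-squares decomposition with the F test.
#'
#' @param groups list of numeric vectors, at least two groups with at least
#'   two observations each.
#' @return List of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, `group_means`, `group_sizes`, `ss_between`, `ss_within`,
#'   `ss_total`, `ms_within`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least two groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) stop("every group needs at least two observations")
  all_vals <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(all_vals))) stop("values must be finite")
  k <- length(groups)
  N <- sum(sizes)
  grand <- mean(all_vals)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1L
  dfw <- N - k
  msw <- ssw / dfw
  F_stat <- if (msw == 0) {
    if (ssb == 0) 0 else Inf
  } else (ssb / dfb) / msw
  p <- pf(F_stat, dfb, dfw, lower.tail = FALSE)
  structure(list(F = F_stat, df_between = dfb, df_within = dfw, p = p,
                 group_means = means, group_sizes = sizes,
                 ss_between = ssb, ss_within = ssw, ss_total = ssb + ssw,
                 ms_within = msw),
            class = "anova_result")
}

#' Studentized range distribution function
#'
#' `P(Q <= q)` for the range of `k` independent standard normal means
#' studentized by an independent estimate of sigma on `df` degrees of
#' freedom, computed by direct numerical integration:
#' the inner integral `k * int phi(z) (Phi(z) - Phi(z - q u))^(k-1) dz`
#' is averaged over the scaled-chi density of `u = s / sigma`. Quadrature
#' tolerance 1e-8 (so the `k = 2` reduction to the t distribution holds to
#' about 1e-6 in p).
#'
#' @param q quantile, `>= 0`.
#' @param k number of groups, `>= 2`.
#' @param df error degrees of freedom, `>= 1`.
#' @return Cumulative probability.
#' @export
pstudrange <- function(q, k, df) {
  if (q <= 0) return(0)
  inner <- function(w) {
    # P(range of k std normals <= w), w may be a vector
    vapply(w, function(wi) {
      if (wi <= 0) return(0)
      f <- function(z) dnorm(z) * (pnorm(z) - pnorm(z - wi))^(k - 1)
      k * integrate(f, -Inf, Inf, rel.tol = 1e-9, abs.tol = 1e-12)$value
    }, numeric(1))
  }
  # density of u = s/sigma where df * u^2 ~ chi^2_df
  log_c <- (df / 2) * log(df / 2) - lgamma(df / 2) + log(2)
  dens <- function(u) exp(log_c + (df - 1) * log(u) - df * u^2 / 2)
  out <- integrate(function(u) dens(u) * inner(q * u), 0, Inf,
                   rel.tol = 1e-8, abs.tol = 1e-10)
  min(1, max(0, out$value))
}

# Compact letter display by insert-and-absorb over the significance graph:
# start from one set holding all groups; every significantly different pair
# splits each set containing both; subset sets are absorbed; letters follow
# group order.
.compact_letters <- function(group_names, sig_pairs) {
  sets <- list(seq_along(group_names))
  if (nrow(sig_pairs) > 0L) {
    for (p in seq_len(nrow(sig_pairs))) {
      i <- sig_pairs$i[p]; j <- sig_pairs$j[p]
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else new_sets <- c(new_sets, list(s))
      }
      # absorb subsets and duplicates
      new_sets <- new_sets[lengths(new_sets) > 0L]
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a != b && keep[a] &&
              all(new_sets[[a]] %in% new_sets[[b]]) &&
              (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b))
            keep[a] <- FALSE
        }
      }
      sets <- new_sets[keep]
    }
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  letters_out <- setNames(rep("", length(group_names)), group_names)
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) {
      letters_out[g] <- paste0(letters_out[g], letters[s])
    }
  }
  letters_out
}

#' Tukey HSD with compact letter display
#'
#' Tukey-Kramer pairwise comparisons after a one-way layout:
#' `q = |m_i - m_j| / sqrt(MSW * (1/n_i + 1/n_j) / 2)` with adjusted p from
#' the studentized range distribution ([pstudrange()], numerical
#' integration). Groups are summarised by letters: groups sharing a letter
#' are indistinguishable at the chosen alpha.
#'
#' @param groups named list of numeric vectors (names become group labels).
#' @param alpha significance level for the letter display.
#' @return List of class `tukey_result`: `pairs` (data frame with group
#'   pair, mean difference, `q`, `p_adj`), `letters` (named character),
#'   `alpha`, `df_within`, `ms_within`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  an <- oneway_anova(groups)
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  means <- an$group_means; sizes <- an$group_sizes
  msw <- an$ms_within; dfw <- an$df_within
  combs <- utils::combn(k, 2)
  pairs <- data.frame(group1 = nm[combs[1, ]], group2 = nm[combs[2, ]],
                      diff = means[combs[2, ]] - means[combs[1, ]],
                      q = NA_real_, p_adj = NA_real_)
  for (c_i in seq_len(ncol(combs))) {
    i <- combs[1, c_i]; j <- combs[2, c_i]
    se <- sqrt(msw * (1 / sizes[i] + 1 / sizes[j]) / 2)
    qv <- if (se == 0) { if (means[i] == means[j]) 0 else Inf }
          else abs(means[i] - means[j]) / se
    pairs$q[c_i] <- qv
    pairs$p_adj[c_i] <- if (is.infinite(qv)) 0 else 1 - pstudrange(qv, k, dfw)
  }
  sig <- pairs$p_adj < alpha
  sig_pairs <- data.frame(i = combs[1, sig], j = combs[2, sig])
  letts <- .compact_letters(nm, sig_pairs)
  structure(list(pairs = pairs, letters = letts, alpha = alpha,
                 df_within = dfw, ms_within = msw),
            class = "tukey_result")
}

#' Box-plot summary statistics
#'
#' Quartiles by linear interpolation between order statistics
#' (`quantile` type 7); whiskers are the sample minimum and maximum, the
#' convention used for the figures this pipeline reproduces.
#'
#' @param values numeric vector, `n >= 1`.
#' @return List: `min`, `q1`, `median`, `q3`, `max`, `whisker_low`,
#'   `whisker_high`, `n`.
#' @export
box_summary <- function(values) {
  if (length(values) < 1L) stop("empty input")
  if (!all(is.finite(values))) stop("values must be finite")
  qs <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(min = min(values), q1 = qs[1], median = qs[2], q3 = qs[3],
       max = max(values), whisker_low = min(values),
       whisker_high = max(values), n = length(values))
}
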