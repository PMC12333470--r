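#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Rank-based comparison of two or more groups of per-animal values. The H
#' statistic uses midranks with the standard tie correction; Dunn's pairwise
#' z statistics are built from pooled-rank means with tie-adjusted variance
#' and two-sided normal p values. With two groups this is rank-equivalent to
#' the Mann-Whitney test, which is why per-syllable two-group comparisons can
#' use the same machinery.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return List with `H`, `df`, `p`, and `dunn` (data.frame: group1, group2,
#'   z, p).
#' @export
kw_dunn <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("`groups` must be a list of >= 2 numeric vectors")
  if (any(vapply(groups, length, 1L) < 2L))
    stopf("every group needs >= 2 values")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  N <- length(x)
  r <- rank(x)                      # midranks
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  H_raw <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  denom <- 1 - tie_term / (N^3 - N)
  if (denom <= 0) {                  # all values identical
    H <- 0; p <- 1
  } else {
    H <- H_raw / denom
    p <- pchisq(H, df = length(groups) - 1L, lower.tail = FALSE)
  }
  pairs <- utils::combn(names(groups), 2L)
  dunn <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     z = NA_real_, p = NA_real_)
  var_base <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(var_base * (1 / n[[a]] + 1 / n[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    dunn$z[i] <- z
    dunn$p[i] <- 2 * pnorm(-abs(z))
  }
  list(H = H, df = length(groups) - 1L, p = p, dunn = dunn)
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Step-up false discovery rate control: adjusted p_(i) = min over k >= i of
#' m p_(k) / k, capped at 1; a hypothesis is rejected when its adjusted p is
#' at most `q`.
#'
#' @param p_values Raw p values in 0..1.
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` and logical `rejected`.
#' @export
bh_adjust <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p values must lie in [0, 1]")
  adjusted <- p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, rejected = !is.na(adjusted) & adjusted <= q)
}

#' Mann-Whitney U test
#'
#' Exact p by enumeration when `n_a * n_b <= 400` with no ties; normal
#' approximation with tie correction otherwise.
#'
#' @param a,b Numeric samples.
#' @return List with `U` and two-sided `p`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stopf("both samples must be non-empty")
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) * length(b) <= 400) && !has_ties
  w <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
  list(U = unname(w$statistic), p = w$p.value)
}

#' Ordinary least-squares regression of y on x
#'
#' @param x,y Numeric vectors (length >= 3, x non-constant).
#' @return List with `slope`, `intercept`, `r_squared`, `p` (slope t test,
#'   n - 2 dof).
#' @export
ols_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stopf("x and y must have equal length >= 3")
  if (var(x) == 0) stopf("x is constant; slope undefined")
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))   # silence the exact-fit warning
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared, p = unname(s$coefficients[2, 4]))
}

#' Per-syllable group comparison table
#'
#' For one metric (velocity or usage), runs Kruskal-Wallis across groups for
#' every syllable in the retained alphabet and applies Benjamini-Hochberg
#' across that family of syllables (the BH family is the retained set for
#' this metric and comparison, matching how per-syllable tables are
#' reported).
#'
#' @param values_by_group Named list of groups; each group is a named list of
#'   per-animal data.frames with columns `syllable` and the metric column.
#' @param metric Column name, e.g. "velocity" or "usage".
#' @param alphabet Integer syllable ids to test.
#' @param q FDR level.
#' @return data.frame: syllable, per-group mean and sem columns, p_raw,
#'   p_adjusted, significant.
#' @export
compare_syllables <- function(values_by_group, metric, alphabet, q = 0.05) {
  groups <- names(values_by_group)
  rows <- lapply(alphabet, function(s) {
    per_group <- lapply(values_by_group, function(animals) {
      vals <- vapply(animals, function(df) {
        hit <- df[df$syllable == s, metric]
        if (length(hit)) hit else if (metric == "usage") 0 else NA_real_
      }, numeric(1))
      vals[!is.na(vals)]
    })
    usable <- all(vapply(per_group, length, 1L) >= 2L)
    p_raw <- if (usable) kw_dunn(per_group)$p else NA_real_
    stats <- unlist(lapply(per_group, function(v)
      c(mean = mean(v), sem = sem(v))))
    names(stats) <- paste(rep(groups, each = 2), c("mean", "sem"), sep = "_")
    c(list(syllable = s), as.list(stats), list(p_raw = p_raw))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  adj <- bh_adjust(out$p_raw, q)
  out$p_adjusted <- adj$adjusted
  out$significant <- adj$rejected
  out
}
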