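# Permutation tests behind the cell-selection procedures.
#
# Monte-Carlo p-values use the add-one convention,
#   p = (1 + #{permuted statistic >= observed}) / (n_perm + 1),
# so p is never 0 and is exactly reproducible given (seed, n_perm).
# With exact = TRUE all distinct group assignments are enumerated instead
# and p = #{assignments >= observed} / n_total (the identity assignment
# counts itself, so this too is a valid p-value).

TIE_EPS <- 1e-12

perm_result <- function(statistic, p, n_perm, seed, method, exact = FALSE) {
  structure(list(statistic = statistic, p = p, n_perm = n_perm,
                 seed = seed, method = method, exact = exact),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s, n_perm = %d)\n",
              x$method, x$statistic, x$p,
              if (x$exact) "exhaustive" else "Monte-Carlo", x$n_perm))
  invisible(x)
}

# one-way ANOVA F via the between-group sum of squares; with the total SS
# fixed under permutation, F is monotone in SSB
anova_f_from_ssb <- function(ssb, sst, df1, df2) {
  ssw <- pmax(sst - ssb, 0)
  (ssb / df1) / (ssw / df2)
}

# enumerate all distinct assignments of n items into ordered groups of sizes
# `sizes`: each element is the concatenation of the chosen index sets, in
# group order (multinomial(n; sizes) assignments in total)
enumerate_assignments <- function(n, sizes) {
  rec <- function(avail, sizes) {
    if (length(sizes) == 1) return(list(avail))
    picks <- utils::combn(avail, sizes[1], simplify = FALSE)
    out <- list()
    for (g in picks) {
      rest <- rec(setdiff(avail, g), sizes[-1])
      out <- c(out, lapply(rest, function(r) c(g, r)))
    }
    out
  }
  rec(seq_len(n), sizes)
}

#' Permutation one-way ANOVA
#'
#' The observed statistic is the one-way ANOVA F over the given grouping;
#' significance is assessed by shuffling the group labels uniformly.
#'
#' @param values numeric responses (e.g. per-presentation firing rates).
#' @param groups group labels (e.g. image identity), at least 2 groups with
#'   at least 1 value each.
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed integer seed for the permutation stream (`NULL`: current RNG).
#' @param exact enumerate all distinct group assignments instead of
#'   sampling (feasible only for small samples).
#' @return a `perm_test` object with the F statistic and p-value.
#' @export
#' @examples
#' permutation_anova(c(1, 2, 9, 10), c("a", "a", "b", "b"), exact = TRUE)$p
permutation_anova <- function(values, groups, n_perm = 1000L, seed = NULL,
                              exact = FALSE) {
  g <- factor(groups)
  if (nlevels(g) < 2) stopf("permutation ANOVA needs at least 2 groups")
  if (length(values) != length(g)) stopf("values and groups differ in length")
  if (any(tabulate(g) == 0)) stopf("every group needs at least one value")
  x <- as.numeric(values)
  n <- length(x); k <- nlevels(g)
  df1 <- k - 1L; df2 <- n - k
  if (df2 < 1) stopf("no residual degrees of freedom")
  ct <- sum(x)^2 / n
  sst <- sum(x^2) - ct
  ng <- tabulate(g)
  ssb_of <- function(idx) {
    gs <- rowsum(x[idx], g)   # g fixed, responses permuted
    sum(gs^2 / ng) - ct
  }
  if (sst <= TIE_EPS * max(1, sum(x^2))) {
    # all responses identical: F degenerate, no assignment beats any other
    return(perm_result(0, 1, n_perm, seed, "permutation one-way ANOVA", exact))
  }
  f_obs <- anova_f_from_ssb(ssb_of(seq_len(n)), sst, df1, df2)
  if (exact) {
    # uniform label shuffling is uniform over the distinct assignments of
    # responses to groups; F depends only on the resulting group sums
    assigns <- enumerate_assignments(n, ng)
    f_all <- vapply(assigns, function(a) {
      ssb <- -ct; ptr <- 0L
      for (l in seq_along(ng)) {
        s <- sum(x[a[(ptr + 1L):(ptr + ng[l])]])
        ssb <- ssb + s^2 / ng[l]; ptr <- ptr + ng[l]
      }
      anova_f_from_ssb(ssb, sst, df1, df2)
    }, numeric(1))
    p <- mean(f_all >= f_obs - TIE_EPS)
    return(perm_result(f_obs, p, length(assigns), seed,
                       "permutation one-way ANOVA", TRUE))
  }
  f_perm <- with_seed(seed, {
    xm <- matrix(0, n, n_perm)
    for (j in seq_len(n_perm)) xm[, j] <- x[sample.int(n)]
    gs <- rowsum(xm, g)
    ssb <- colSums(gs^2 / ng) - ct
    anova_f_from_ssb(ssb, sst, df1, df2)
  })
  p <- (1 + sum(f_perm >= f_obs - TIE_EPS)) / (n_perm + 1)
  perm_result(f_obs, p, n_perm, seed, "permutation one-way ANOVA", FALSE)
}

#' Permutation t-type test of two means
#'
#' The statistic is the difference of sample means, `mean(a) - mean(b)`;
#' significance is assessed by permuting the pooled sample over the two
#' groups. One-sided (`"greater"`) counts permuted statistics at least as
#' large as observed; `"two.sided"` compares absolute values.
#'
#' @param a,b numeric samples (both non-empty).
#' @param alternative `"greater"` (a exceeds b) or `"two.sided"`.
#' @param n_perm,seed,exact as in [permutation_anova()].
#' @return a `perm_test` object.
#' @export
permutation_ttest <- function(a, b, alternative = c("greater", "two.sided"),
                              n_perm = 1000L, seed = NULL, exact = FALSE) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stopf("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b); tot <- sum(pooled)
  stat_of <- function(sum_a) sum_a / na - (tot - sum_a) / nb
  s_obs <- stat_of(sum(a))
  cmp <- function(s) if (alternative == "greater") s >= s_obs - TIE_EPS
                     else abs(s) >= abs(s_obs) - TIE_EPS
  if (exact) {
    sets <- utils::combn(n, na, simplify = FALSE)
    s_all <- vapply(sets, function(ix) stat_of(sum(pooled[ix])), numeric(1))
    return(perm_result(s_obs, mean(cmp(s_all)), length(sets), seed,
                       "permutation t-test", TRUE))
  }
  s_perm <- with_seed(seed, {
    im <- matrix(0L, na, n_perm)
    for (j in seq_len(n_perm)) im[, j] <- sample.int(n, na)
    stat_of(colSums(matrix(pooled[im], na, n_perm)))
  })
  p <- (1 + sum(cmp(s_perm))) / (n_perm + 1)
  perm_result(s_obs, p, n_perm, seed, "permutation t-test", FALSE)
}
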