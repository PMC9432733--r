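#' @title Nonparametric multi-group comparison
#' @description The comparison layer used for all between-arm contrasts:
#' a Kruskal-Wallis omnibus test (ties-corrected, chi-square reference),
#' Conover-Iman all-pairs post-hoc t statistics on ranks with pooled
#' variance (unadjusted p values by default, Holm optionally), the
#' epsilon-squared rank effect size, and a compact letter display in which
#' groups sharing a letter are not significantly different.
#' @name group_stats
NULL

#' Kruskal-Wallis omnibus test
#'
#' Thin wrapper around [stats::kruskal.test()] returning the H statistic
#' (ties-corrected) and chi-square p-value. Degenerate input (all values
#' identical) yields H = 0, p = 1.
#'
#' @param values Numeric vector.
#' @param groups Group labels (same length).
#' @return List with `H`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  if (length(unique(values)) == 1)
    return(list(H = 0, df = nlevels(groups) - 1L, p_value = 1,
                n = length(values)))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = length(values))
}

#' Conover-Iman all-pairs post-hoc test
#'
#' Pairwise t statistics on the ranks with the pooled rank variance,
#' `t_ij = (Rbar_i - Rbar_j) / sqrt(S2 (N - 1 - H)/(N - g) (1/n_i + 1/n_j))`
#' with `S2 = (sum R^2 - N (N+1)^2 / 4) / (N - 1)` (ties-corrected) and
#' `N - g` degrees of freedom. P values are unadjusted by default.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @param p_adjust Multiplicity adjustment passed to [stats::p.adjust()]
#'   (`"none"` default, `"holm"` available).
#' @return Symmetric matrix of pairwise p values with unit diagonal.
#' @export
conover_posthoc <- function(values, groups, p_adjust = "none") {
  groups <- factor(groups)
  g <- nlevels(groups)
  N <- length(values)
  stopifnot(N == length(groups), g >= 2)
  r <- rank(values)
  n_i <- tabulate(groups)
  rbar <- tapply(r, groups, mean)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  H <- kruskal_wallis(values, groups)$H
  dfree <- N - g
  scale2 <- S2 * (N - 1 - H) / dfree
  pmat <- matrix(1, g, g, dimnames = list(levels(groups), levels(groups)))
  pr <- c()
  idx <- which(upper.tri(pmat), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    se <- sqrt(pmax(scale2, 0) * (1 / n_i[i] + 1 / n_i[j]))
    tstat <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    pr[k] <- 2 * stats::pt(-abs(tstat), dfree)
  }
  pr <- stats::p.adjust(pmin(pr, 1), method = p_adjust)
  for (k in seq_len(nrow(idx))) {
    pmat[idx[k, 1], idx[k, 2]] <- pr[k]
    pmat[idx[k, 2], idx[k, 1]] <- pr[k]
  }
  pmat
}

#' Epsilon-squared rank effect size
#'
#' `eps2 = H / ((n^2 - 1) / (n + 1))`, in `[0, 1]`.
#'
#' @param H Kruskal-Wallis H statistic.
#' @param n Total number of observations (>= 2).
#' @return Effect size in `[0, 1]`.
#' @export
epsilon_squared <- function(H, n) {
  if (n < 2) return(NA_real_)
  min(max(H / ((n^2 - 1) / (n + 1)), 0), 1)
}

#' Compact letter display
#'
#' Insert-and-absorb assignment: groups sharing a letter are not
#' significantly different at `alpha`; every significantly different pair
#' shares no letter. Letter sets are kept minimal by absorbing columns
#' that are subsets of others.
#'
#' @param pmat Symmetric matrix of pairwise p values (dimnames = groups).
#' @param alpha Significance level.
#' @return Named character vector of letter codes per group.
#' @export
compact_letters <- function(pmat, alpha = 0.05) {
  stopifnot(is.matrix(pmat), nrow(pmat) == ncol(pmat))
  g <- nrow(pmat)
  nm <- rownames(pmat)
  if (is.null(nm)) nm <- as.character(seq_len(g))
  cols <- list(rep(TRUE, g))  # each column = a set of mutually ns groups
  sig <- which(upper.tri(pmat) & pmat < alpha, arr.ind = TRUE)
  if (nrow(sig)) for (k in seq_len(nrow(sig))) {
    i <- sig[k, 1]; j <- sig[k, 2]
    newcols <- list()
    for (col in cols) {
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        newcols <- c(newcols, list(a, b))
      } else newcols <- c(newcols, list(col))
    }
    # absorb: drop any column whose membership is a subset of another's
    keep <- rep(TRUE, length(newcols))
    for (a in seq_along(newcols)) for (b in seq_along(newcols)) {
      if (a != b && keep[a] && keep[b] &&
          all(newcols[[a]] <= newcols[[b]]) &&
          !identical(newcols[[a]], newcols[[b]])) keep[a] <- FALSE
    }
    # drop duplicates
    cols <- unique(newcols[keep])
  }
  # order columns by their first member for stable letters
  ord <- order(vapply(cols, function(c) which(c)[1], numeric(1)))
  cols <- cols[ord]
  letters_out <- vapply(seq_len(g), function(i)
    paste0(letters[which(vapply(cols, `[`, logical(1), i))], collapse = ""),
    character(1))
  stats::setNames(letters_out, nm)
}

#' Compare groups nonparametrically
#'
#' Omnibus Kruskal-Wallis test, Conover-Iman all-pairs post-hoc p values,
#' epsilon-squared effect size and compact letters, in one classed object.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @param alpha Significance level for lettering.
#' @param p_adjust Post-hoc p adjustment (`"none"` default).
#' @return Object of class `group_comparison` with fields `omnibus`,
#'   `pairwise`, `epsilon_squared`, `letters`, `medians`, `n`.
#' @examples
#' gc <- group_compare(c(1, 2, 3, 11, 12, 13, 21, 22, 23),
#'                     rep(c("SH", "RF", "MU"), each = 3))
#' print(gc)
#' @export
group_compare <- function(values, groups, alpha = 0.05, p_adjust = "none") {
  groups <- factor(groups, levels = unique(groups))
  omni <- kruskal_wallis(values, groups)
  pmat <- conover_posthoc(values, groups, p_adjust = p_adjust)
  structure(list(
    omnibus = omni,
    pairwise = pmat,
    epsilon_squared = epsilon_squared(omni$H, omni$n),
    letters = compact_letters(pmat, alpha),
    medians = tapply(values, groups, stats::median),
    n = tapply(values, groups, length),
    alpha = alpha), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.4g (eps^2 = %.3f)\n",
              x$omnibus$H, x$omnibus$df, x$omnibus$p_value,
              x$epsilon_squared))
  df <- data.frame(n = as.vector(x$n), median = round(as.vector(x$medians), 4),
                   letters = as.vector(x$letters),
                   row.names = names(x$letters))
  print(df)
  cat("Pairwise Conover p values:\n")
  print(round(x$pairwise, 4))
  invisible(x)
}

#' @export
summary.group_comparison <- function(object, ...) object
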