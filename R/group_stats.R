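#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA of a numeric response over a group
#' factor, computed through `stats::lm`/`stats::anova`. Groups must number at
#' least two, each with at least two observations.
#'
#' @param values numeric observations.
#' @param groups group labels, same length as `values`.
#' @return An object of class `anova_oneway`: `f_statistic`, `df_between`,
#'   `df_within`, `ms_error`, `p_value`, `group_means`, `group_n`, plus the
#'   underlying data.
#' @examples
#' one_way_anova(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'               rep(c("a", "b", "c"), each = 3)) # F = 3, p ~ 0.125
#' @export
one_way_anova <- function(values, groups) {
  values <- as.numeric(values)
  groups <- as.factor(groups)
  if (length(values) != length(groups)) abort_input("lengths differ")
  if (anyNA(values) || any(!is.finite(values))) abort_input("values must be finite")
  n_per <- table(groups)
  if (nlevels(groups) < 2L) abort_input("need at least 2 groups")
  if (any(n_per < 2L)) abort_input("every group needs at least 2 observations")
  # zero within-group variance everywhere makes the F ratio 0/0 (equal means:
  # degenerate) or infinite (separated means); lm's float noise is unreliable
  # there, so detect it on the data
  if (all(tapply(values, groups, function(v) max(v) == min(v)))) {
    means <- tapply(values, groups, mean)
    if (max(means) == min(means))
      abort_input("degenerate input: zero variance everywhere and equal means (F undefined)")
    return(structure(list(f_statistic = Inf,
                          df_between = nlevels(groups) - 1L,
                          df_within = length(values) - nlevels(groups),
                          ms_error = 0, p_value = 0,
                          group_means = means, group_n = as.integer(n_per),
                          groups = groups, values = values),
                     class = "anova_oneway"))
  }
  tab <- stats::anova(stats::lm(values ~ groups))
  mse <- tab[["Mean Sq"]][2]
  structure(list(f_statistic = tab[["F value"]][1],
                 df_between = tab[["Df"]][1],
                 df_within = tab[["Df"]][2],
                 ms_error = mse,
                 p_value = tab[["Pr(>F)"]][1],
                 group_means = tapply(values, groups, mean),
                 group_n = as.integer(n_per),
                 groups = groups, values = values),
            class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("<anova_oneway> F(%d, %d) = %0.4g, MSE = %0.4g, p = %0.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$ms_error, x$p_value))
  invisible(x)
}

#' Fisher's LSD pairwise comparisons, gatekept by the omnibus F test
#'
#' Pair (i, j) is declared significant when the omnibus ANOVA p-value is
#' below `alpha` AND |mean_i - mean_j| exceeds the least significant
#' difference t(1 - alpha/2, df_within) * sqrt(MSE * (1/n_i + 1/n_j)). When
#' the omnibus test is not significant, no pair is (the classical "protected
#' LSD" gate); no further multiplicity correction is applied.
#'
#' @param anova an [one_way_anova()] result.
#' @param alpha significance level in (0, 1), default 0.05.
#' @return An object of class `lsd_pairwise`: data frame `pairs` with columns
#'   `group_1`, `group_2`, `mean_diff`, `lsd`, `p_value` (unprotected pairwise
#'   t p-value), `significant`; plus `gate_passed`, `alpha`, `group_means`.
#' @export
lsd_pairwise <- function(anova, alpha = 0.05) {
  if (!inherits(anova, "anova_oneway")) abort_input("'anova' must be an anova_oneway")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    abort_config("'alpha' must be inside (0, 1)")
  means <- anova$group_means
  n <- anova$group_n
  k <- length(means)
  gate <- anova$p_value < alpha
  t_crit <- stats::qt(1 - alpha / 2, anova$df_within)
  idx <- utils::combn(k, 2)
  pairs <- data.frame(
    group_1 = names(means)[idx[1, ]],
    group_2 = names(means)[idx[2, ]],
    mean_diff = means[idx[1, ]] - means[idx[2, ]],
    stringsAsFactors = FALSE
  )
  se <- sqrt(anova$ms_error * (1 / n[idx[1, ]] + 1 / n[idx[2, ]]))
  pairs$lsd <- t_crit * se
  t_stat <- abs(pairs$mean_diff) / se
  pairs$p_value <- 2 * stats::pt(t_stat, anova$df_within, lower.tail = FALSE)
  pairs$significant <- gate & (abs(pairs$mean_diff) > pairs$lsd)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, gate_passed = gate, alpha = alpha,
                 group_means = means),
            class = "lsd_pairwise")
}

#' @export
print.lsd_pairwise <- function(x, ...) {
  cat(sprintf("<lsd_pairwise> alpha = %g, omnibus gate %s\n", x$alpha,
              if (x$gate_passed) "passed" else "NOT passed (no pair significant)"))
  print(x$pairs, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.lsd_pairwise <- function(object, ...) {
  letters <- compact_letters(object)
  cat(sprintf("Gatekept Fisher LSD at alpha = %g\n", object$alpha))
  print(data.frame(group = names(object$group_means),
                   mean = as.numeric(object$group_means),
                   letters = letters$letters[names(object$group_means)]),
        row.names = FALSE)
  invisible(letters)
}

#' Compact letter display from a pairwise significance table
#'
#' Insert-and-absorb lettering: groups are processed in descending order of
#' mean (largest mean gets 'a'); each group joins every existing letter class
#' it does not significantly differ from any member of, and a new letter is
#' opened when it joins none; redundant classes (subsets of another class)
#' are absorbed. Two groups share a letter exactly when they are not
#' significantly different, and no letter column is redundant. Ties in means
#' are broken by group input order.
#'
#' @param pairwise an [lsd_pairwise()] result, or a data frame with columns
#'   `group_1`, `group_2`, `significant` (complete and consistent over all
#'   pairs) together with `means` supplied separately.
#' @param means named numeric vector of group means (taken from `pairwise`
#'   when it is an `lsd_pairwise`).
#' @return An object of class `letter_display`: named character vector
#'   `letters` (in the input group order) and `ordering` (groups by
#'   descending mean).
#' @export
compact_letters <- function(pairwise, means = NULL) {
  if (inherits(pairwise, "lsd_pairwise")) {
    means <- pairwise$group_means
    tab <- pairwise$pairs
  } else {
    tab <- pairwise
    if (is.null(means)) abort_input("'means' required with a raw pairwise table")
  }
  req <- c("group_1", "group_2", "significant")
  if (!all(req %in% names(tab))) abort_input("pairwise table needs group_1, group_2, significant")
  gset <- names(means)
  # significance lookup, symmetric; error on inconsistent duplicates
  sig <- matrix(NA, length(gset), length(gset), dimnames = list(gset, gset))
  diag(sig) <- FALSE
  for (r in seq_len(nrow(tab))) {
    g1 <- tab$group_1[r]; g2 <- tab$group_2[r]
    if (!g1 %in% gset || !g2 %in% gset) abort_input("pairwise table names unknown group")
    s <- isTRUE(tab$significant[r])
    if (!is.na(sig[g1, g2]) && sig[g1, g2] != s)
      abort_input("inconsistent (non-symmetric) pairwise table")
    sig[g1, g2] <- s; sig[g2, g1] <- s
  }
  if (anyNA(sig)) abort_input("pairwise table incomplete: every pair must appear")

  ord <- gset[order(-as.numeric(means)[match(gset, names(means))])] # stable: ties keep input order
  # insert-and-absorb: start from one class holding every group; for each
  # significant pair split every class containing both; absorb subset classes
  classes <- list(ord)
  absorb <- function(cls) {
    keep <- rep(TRUE, length(cls))
    for (i in seq_along(cls)) for (j in seq_along(cls)) {
      if (i != j && keep[i] && keep[j] && all(cls[[i]] %in% cls[[j]]))
        keep[i] <- FALSE
    }
    cls[keep]
  }
  sig_pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (r in seq_len(nrow(sig_pairs))) {
    g1 <- gset[sig_pairs[r, 1]]; g2 <- gset[sig_pairs[r, 2]]
    nxt <- list()
    for (cl in classes) {
      if (g1 %in% cl && g2 %in% cl) {
        nxt[[length(nxt) + 1L]] <- setdiff(cl, g1)
        nxt[[length(nxt) + 1L]] <- setdiff(cl, g2)
      } else nxt[[length(nxt) + 1L]] <- cl
    }
    classes <- absorb(nxt)
  }
  # order classes by the rank of their highest-mean member so 'a' labels the
  # class containing the largest mean
  first_rank <- vapply(classes, function(cl) min(match(cl, ord)), numeric(1))
  classes <- classes[order(first_rank)]
  lab <- letters[seq_along(classes)]
  out <- vapply(gset, function(g) {
    paste0(lab[vapply(classes, function(cl) g %in% cl, logical(1))], collapse = "")
  }, character(1))
  structure(list(letters = out, ordering = ord), class = "letter_display")
}

#' @export
print.letter_display <- function(x, ...) {
  print(x$letters)
  invisible(x)
}

#' Letter a treatment table in one call
#'
#' Convenience wrapper running [one_way_anova()], [lsd_pairwise()] and
#' [compact_letters()] on long-format data.
#'
#' @inheritParams one_way_anova
#' @inheritParams lsd_pairwise
#' @return list with `anova`, `lsd`, `letters`.
#' @export
letter_groups <- function(values, groups, alpha = 0.05) {
  a <- one_way_anova(values, groups)
  l <- lsd_pairwise(a, alpha = alpha)
  list(anova = a, lsd = l, letters = compact_letters(l))
}
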