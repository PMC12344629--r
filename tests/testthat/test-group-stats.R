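# Independent oracle for the ANOVA decomposition: explicit sums of squares.
anova_oracle <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ni <- tabulate(groups)
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
       mse = ssw / (n - k))
}

test_that("one-way ANOVA matches a hand sums-of-squares oracle", {
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  a <- one_way_anova(v, g)
  expect_equal(a$f_statistic, 3)
  expect_equal(a$ms_error, 1)
  expect_equal(a$df_between, 2)
  expect_equal(a$df_within, 6)
  expect_equal(a$p_value, 0.125, tolerance = 1e-3)

  # agreement with the oracle on random unbalanced data
  set.seed(42)
  for (i in 1:10) {
    sizes <- sample(2:6, 4, replace = TRUE)
    vv <- stats::rnorm(sum(sizes))
    gg <- rep(paste0("g", 1:4), times = sizes)
    aa <- one_way_anova(vv, gg)
    oo <- anova_oracle(vv, gg)
    expect_equal(aa$f_statistic, oo$f)
    expect_equal(aa$p_value, oo$p)
    expect_equal(aa$ms_error, oo$mse)
  }
})

test_that("identical groups give F = 0 and affine transforms leave F unchanged", {
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  a <- one_way_anova(v, g)
  expect_equal(a$f_statistic, 0)
  expect_equal(a$p_value, 1)

  v2 <- c(1, 2, 3, 2, 3, 4, 3, 4, 7)
  a1 <- one_way_anova(v2, g)
  a2 <- one_way_anova(v2 + 100, g)
  a3 <- one_way_anova(3 * v2 - 7, g)
  expect_equal(a1$f_statistic, a2$f_statistic)
  expect_equal(a1$f_statistic, a3$f_statistic)

  expect_error(one_way_anova(rep(1, 6), rep(c("a", "b"), each = 3)), "degenerate")
  expect_error(one_way_anova(1:4, rep("a", 4)), "2 groups")
  expect_error(one_way_anova(1:3, c("a", "a", "b")), "2 observations")
})

test_that("LSD gatekeeping suppresses pairs when the omnibus test fails", {
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  a <- one_way_anova(v, g)
  l <- lsd_pairwise(a)
  # p ~ 0.125 > 0.05: gate closed although max mean diff 2 > LSD ~ 1.998
  expect_false(l$gate_passed)
  expect_equal(l$pairs$lsd, rep(stats::qt(0.975, 6) * sqrt(2 / 3), 3))
  expect_gt(2, max(l$pairs$lsd))
  expect_false(any(l$pairs$significant))
})

test_that("LSD detects extreme separation and reduces to the pooled t at k = 2", {
  v <- c(0, 0, 0.1, 10, 10, 10.1)
  g <- rep(c("lo", "hi"), each = 3)
  a <- one_way_anova(v, g)
  l <- lsd_pairwise(a)
  expect_true(l$gate_passed)
  expect_true(all(l$pairs$significant))
  # with k = 2 the pairwise LSD p equals the pooled two-sample t p
  tt <- stats::t.test(v[g == "hi"], v[g == "lo"], var.equal = TRUE)
  expect_equal(l$pairs$p_value, tt$p.value)
  expect_equal(a$p_value, tt$p.value)
})

test_that("two identical groups are never significant", {
  v <- c(1, 2, 3, 1, 2, 3, 5, 6, 7)
  g <- rep(c("a", "b", "c"), each = 3)
  l <- lsd_pairwise(one_way_anova(v, g))
  ab <- l$pairs[l$pairs$group_1 == "a" & l$pairs$group_2 == "b", ]
  expect_false(ab$significant)
  expect_error(lsd_pairwise(one_way_anova(v, g), alpha = 1.5),
               class = "n2okit_config_error")
})

# Brute-force validity check: a lettering is valid iff sharing a letter is
# equivalent to non-significance for every pair.
letters_valid <- function(letters, sig_lookup) {
  gs <- names(letters)
  for (i in seq_along(gs)) for (j in seq_len(i - 1L)) {
    share <- length(intersect(strsplit(letters[[gs[i]]], "")[[1]],
                              strsplit(letters[[gs[j]]], "")[[1]])) > 0
    if (share == sig_lookup(gs[i], gs[j])) return(FALSE)
  }
  TRUE
}

test_that("compact letters cover the canonical patterns", {
  means <- c(g1 = 3, g2 = 2, g3 = 1)
  pairs3 <- function(sig) data.frame(group_1 = c("g1", "g1", "g2"),
                                     group_2 = c("g2", "g3", "g3"),
                                     significant = sig)
  # no pair significant: all 'a'
  expect_equal(unname(compact_letters(pairs3(c(FALSE, FALSE, FALSE)), means)$letters),
               c("a", "a", "a"))
  # all pairs significant: a, b, c by descending mean
  expect_equal(compact_letters(pairs3(c(TRUE, TRUE, TRUE)), means)$letters,
               c(g1 = "a", g2 = "b", g3 = "c"))
  # only extremes differ: a, ab, b
  expect_equal(compact_letters(pairs3(c(FALSE, TRUE, FALSE)), means)$letters,
               c(g1 = "a", g2 = "ab", g3 = "b"))
  # inconsistent table rejected
  bad <- rbind(pairs3(c(TRUE, TRUE, TRUE)),
               data.frame(group_1 = "g2", group_2 = "g1", significant = FALSE))
  expect_error(compact_letters(bad, means), "inconsistent")
  # incomplete table rejected
  expect_error(compact_letters(pairs3(c(TRUE, TRUE, TRUE))[1:2, ], means),
               "incomplete")
})

test_that("letter displays are valid and minimal over random significance patterns", {
  set.seed(123)
  for (rep in 1:30) {
    k <- sample(3:5, 1)
    gs <- paste0("g", seq_len(k))
    means <- stats::setNames(sample(seq_len(k)), gs)
    idx <- utils::combn(k, 2)
    # random pattern, forced transitive-ish by construction of a threshold
    cut <- stats::runif(1, 0.5, k)
    sig <- abs(means[gs[idx[1, ]]] - means[gs[idx[2, ]]]) > cut
    tab <- data.frame(group_1 = gs[idx[1, ]], group_2 = gs[idx[2, ]],
                      significant = unname(sig))
    cl <- compact_letters(tab, means)
    lookup <- function(a, b) {
      r <- tab[(tab$group_1 == a & tab$group_2 == b) |
                 (tab$group_1 == b & tab$group_2 == a), ]
      r$significant[1]
    }
    expect_true(letters_valid(cl$letters, lookup))
    # minimality: no letter class is redundant, i.e. used letters are distinct
    used <- unique(unlist(strsplit(cl$letters, "")))
    expect_lte(length(used), k)
  }
})

test_that("the full lettering pipeline letters a clearly separated field table", {
  set.seed(9)
  v <- c(stats::rnorm(4, 5.5, 0.15), stats::rnorm(4, 4.5, 0.15),
         stats::rnorm(4, 5.0, 0.15), stats::rnorm(4, 4.0, 0.15))
  g <- rep(c("control", "FeSO4", "MnSO4", "ZnSO4"), each = 4)
  res <- letter_groups(v, g)
  expect_true(res$lsd$gate_passed)
  # control has the largest mean: letter 'a' appears in its label
  expect_match(res$letters$letters[["control"]], "a")
  # ZnSO4 (lowest) must not share a letter with control
  expect_length(intersect(strsplit(res$letters$letters[["control"]], "")[[1]],
                          strsplit(res$letters$letters[["ZnSO4"]], "")[[1]]), 0)
})
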