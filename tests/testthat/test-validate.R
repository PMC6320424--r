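test_that("Spearman correlations hit the monotone extremes and respect ties", {
  res <- spearman_holm(list(
    up = list(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8)),
    down = list(x = c(1, 2, 3, 4), y = c(8, 6, 4, 2))
  ))
  expect_equal(res$rho[res$pair == "up"], 1)
  expect_equal(res$rho[res$pair == "down"], -1)
})

test_that("Spearman correlation is invariant under strictly monotone transforms", {
  set.seed(31)
  x <- rnorm(60); y <- x + rnorm(60)
  base <- spearman_holm(list(p = list(x = x, y = y)))$rho
  expect_equal(spearman_holm(list(p = list(x = exp(x), y = y)))$rho, base)
  expect_equal(spearman_holm(list(p = list(x = x, y = y^3)))$rho, base)
  expect_equal(spearman_holm(list(p = list(x = rank(x), y = y)))$rho, base)
})

test_that("Holm-adjusted intervals are never narrower than unadjusted ones", {
  set.seed(13)
  pairs <- lapply(1:5, function(i) {
    x <- rnorm(40)
    list(x = x, y = 0.3 * i / 5 * x + rnorm(40))
  })
  names(pairs) <- paste0("pair", 1:5)
  res <- spearman_holm(pairs)
  ok <- !is.na(res$rho)
  expect_true(all(res$ci_high[ok] - res$ci_low[ok] >=
                    res$ci_high_unadj[ok] - res$ci_low_unadj[ok] - 1e-12))
  expect_true(all(res$ci_low[ok] <= res$rho[ok] & res$rho[ok] <= res$ci_high[ok]))
  expect_true(all(res$p_adjusted[ok] >= res$p_value[ok]))
})

test_that("a constant vector yields an undefined-correlation row, others still computed", {
  res <- spearman_holm(list(
    flat = list(x = rep(1, 10), y = rnorm(10)),
    fine = list(x = 1:10, y = (1:10)^2)
  ))
  expect_true(is.na(res$rho[res$pair == "flat"]))
  expect_match(res$note[res$pair == "flat"], "constant")
  expect_equal(res$rho[res$pair == "fine"], 1)
})

test_that("missing values are removed pairwise", {
  x <- c(1, 2, NA, 4, 5); y <- c(2, NA, 3, 8, 10)
  res <- spearman_holm(list(p = list(x = x, y = y)))
  expect_identical(res$n_pairs, 3L)
})

test_that("count regression reports multiplicative effects and explicit failures", {
  set.seed(17)
  dat <- simulate_count_exposure(2000, effect = 1.5)
  res <- count_regression(dat$y, dat$x, outcome_label = "visits", exposure_label = "load")
  est <- res[res$term == "load", ]
  expect_true(est$converged)
  expect_gt(est$effect, 1.2)
  expect_true(est$ci_low < 1.5 & 1.5 < est$ci_high)
  expect_identical(est$n_used, 2000L)

  zero <- count_regression(rep(0L, 100), rnorm(100))
  expect_false(zero$converged)
  expect_match(zero$note, "all-zero")

  expect_error(count_regression(c(-1, 2, 3, rep(1, 20)), rnorm(23)),
               class = "emrforge_config_error")
})

test_that("subsidy regressions recover reference-coded odds ratios and RSR betas", {
  set.seed(19)
  dat <- simulate_subsidy_exposure(8000)
  res <- subsidy_regressions(dat$status, dat$rsr, dat$housing_group)
  or_small <- res[res$model == "multinomial" &
                    res$outcome == "subsidized vs nonsubsidized" &
                    grepl("rental", res$term), ]
  expect_identical(nrow(or_small), 1L)
  expect_true(or_small$ci_low < 14 & 14 < or_small$ci_high)
  beta_small <- res[res$model == "linear" & grepl("rental", res$term), ]
  expect_lt(abs(beta_small$effect - 19), 3)
  expect_lt(beta_small$ci_high - beta_small$ci_low, 6)
  expect_true(all(res$effect[res$model == "multinomial"] > 0))
})

test_that("an empty status-by-housing cell warns and refuses category collapse", {
  set.seed(3)
  dat <- simulate_subsidy_exposure(500)
  dat$status[dat$housing_group == "3-room"] <- "subsidized"
  dat$status[which(dat$housing_group == "3-room")[1:2]] <- "mixed"
  expect_warning(subsidy_regressions(dat$status, dat$rsr, dat$housing_group),
                 "empty status-by-housing cell")
})

test_that("the chi-square test matches hand-computed statistics and df", {
  perfect <- chisq_independence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(perfect$statistic, 0)
  expect_identical(as.integer(perfect$df), 1L)

  diag40 <- chisq_independence(matrix(c(20, 0, 0, 20), 2))
  expect_equal(diag40$statistic, 40)

  tab53 <- matrix(rpois(15, 20) + 1, nrow = 5, ncol = 3)
  expect_identical(as.integer(chisq_independence(tab53)$df), 8L)

  # permutation invariance
  set.seed(7)
  tab <- matrix(rpois(12, 30) + 1, 4, 3)
  s1 <- chisq_independence(tab)$statistic
  s2 <- chisq_independence(tab[sample(4), sample(3)])$statistic
  expect_equal(s1, s2)

  expect_error(chisq_independence(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               class = "emrforge_config_error")
})

test_that("the Kruskal-Wallis test matches brute-force rank computation", {
  same <- kruskal_wallis(replicate(5, c(4, 4, 4), simplify = FALSE))
  expect_equal(same$statistic, 0)
  expect_identical(as.integer(same$df), 4L)

  g <- list(c(1, 2, 3), c(10, 11, 12))
  got <- kruskal_wallis(g)
  # no ties: H = 12 / (N (N+1)) * sum n_i (rbar_i - (N+1)/2)^2
  all_r <- rank(unlist(g))
  rbar <- tapply(all_r, rep(1:2, lengths(g)), mean)
  n_tot <- length(all_r)
  h <- 12 / (n_tot * (n_tot + 1)) * sum(lengths(g) * (rbar - (n_tot + 1) / 2)^2)
  expect_equal(got$statistic, h)
  expect_identical(as.integer(got$df), 1L)
  expect_error(kruskal_wallis(list(1:3)), class = "emrforge_config_error")
})
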