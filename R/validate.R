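#' Spearman correlations with Holm-adjusted confidence intervals
#'
#' Computes Spearman rank correlations (average ranks for ties) for a family
#' of variable pairs, removing missing values pairwise. Confidence intervals
#' use the Fisher z-transform. To account for multiplicity across the `m`
#' pairs, the Holm step-down allocation is applied to the CIs: the pair with
#' the k-th smallest p-value gets a CI at level `1 - alpha/(m - k + 1)`
#' (never narrower than the unadjusted interval); Holm-adjusted p-values are
#' reported alongside.
#'
#' A pair with a constant vector has no defined rank correlation; its row is
#' returned with `NA` estimates and a note, and the remaining pairs are
#' still computed (and still count towards `m`).
#'
#' @param pairs Named list; each element a list with numeric vectors `x` and
#'   `y` of equal length.
#' @param alpha Family-wise error level (default 0.05).
#' @return Tibble with one row per pair: `pair`, `rho`, `ci_low`, `ci_high`
#'   (Holm-adjusted), `ci_low_unadj`, `ci_high_unadj`, `p_value`,
#'   `p_adjusted`, `n_pairs`, `adjusted`, `note`.
#' @export
spearman_holm <- function(pairs, alpha = 0.05) {
  if (length(pairs) == 0) {
    emr_abort("no pairs supplied", "emrforge_config_error")
  }
  if (is.null(names(pairs)) || any(names(pairs) == "")) {
    names(pairs) <- paste0("pair_", seq_along(pairs))
  }
  m <- length(pairs)

  one <- function(p, label) {
    stopifnot(length(p$x) == length(p$y))
    ok <- stats::complete.cases(p$x, p$y)
    x <- p$x[ok]; y <- p$y[ok]
    n <- length(x)
    if (n < 3) {
      return(tibble::tibble(pair = label, rho = NA_real_, p_value = NA_real_,
                            n_pairs = n, note = "fewer than 3 complete pairs"))
    }
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
      return(tibble::tibble(pair = label, rho = NA_real_, p_value = NA_real_,
                            n_pairs = n, note = "constant vector: correlation undefined"))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
    tibble::tibble(pair = label, rho = unname(ct$estimate),
                   p_value = ct$p.value, n_pairs = n, note = NA_character_)
  }

  res <- dplyr::bind_rows(purrr::imap(pairs, function(p, label) one(p, label)))

  fisher_ci <- function(rho, n, level) {
    if (is.na(rho) || n <= 3 || abs(rho) >= 1) return(c(NA_real_, NA_real_))
    z <- atanh(rho); se <- 1 / sqrt(n - 3)
    q <- qnorm(1 - (1 - level) / 2)
    tanh(c(z - q * se, z + q * se))
  }

  # Holm step-down: rank pairs by p ascending; the k-th gets alpha/(m-k+1).
  ord <- rank(res$p_value, ties.method = "first", na.last = "keep")
  level_adj <- 1 - alpha / (m - ord + 1)
  ci_a <- t(mapply(fisher_ci, res$rho, res$n_pairs, level_adj))
  ci_u <- t(mapply(fisher_ci, res$rho, res$n_pairs, 1 - alpha))
  res$ci_low <- ci_a[, 1]; res$ci_high <- ci_a[, 2]
  res$ci_low_unadj <- ci_u[, 1]; res$ci_high_unadj <- ci_u[, 2]
  res$p_adjusted <- p.adjust(res$p_value, method = "holm")
  res$adjusted <- TRUE
  res[, c("pair", "rho", "ci_low", "ci_high", "ci_low_unadj", "ci_high_unadj",
          "p_value", "p_adjusted", "n_pairs", "adjusted", "note")]
}

fit_failure_row <- function(family, outcome_label, reason, n_used = 0L) {
  tibble::tibble(
    model = family, outcome = outcome_label, term = NA_character_,
    effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p_value = NA_real_, n_used = as.integer(n_used),
    converged = FALSE, note = reason
  )
}

#' Negative binomial regression of a utilization count on an exposure
#'
#' Fits a log-linked negative binomial generalized linear model of a health
#' care utilization count (inpatient / SOC / ED visits) on a complexity
#' exposure (CCI or PPS), adjusting for covariates. Effects are reported as
#' `exp(beta)` — multiplicative change in expected count per unit exposure —
#' with Wald 95% CIs. Rows with missing values are removed pairwise (per
#' analysis). The dispersion is estimated by maximum likelihood; when the
#' dispersion estimate diverges the model falls back to Poisson with a
#' warning. Non-convergence yields an explicit fit-failure row, never a
#' silent result.
#'
#' @param outcome Non-negative integer count vector.
#' @param exposure Numeric exposure vector.
#' @param covariates Optional tibble of adjustment covariates.
#' @param outcome_label,exposure_label Labels for the report.
#' @return Tibble of regression results, one row per model term: `model`,
#'   `outcome`, `term`, `effect`, `ci_low`, `ci_high`, `p_value`, `n_used`,
#'   `converged`, `note`.
#' @export
count_regression <- function(outcome, exposure, covariates = NULL,
                             outcome_label = "count", exposure_label = "exposure") {
  dat <- data.frame(.y = outcome, .x = exposure)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n_used <- nrow(dat)
  if (n_used < 10) {
    return(fit_failure_row("neg-binomial", outcome_label, "too few complete rows", n_used))
  }
  if (any(dat$.y < 0) || any(dat$.y != round(dat$.y))) {
    emr_abort("count outcome must be non-negative integers", "emrforge_config_error")
  }
  if (all(dat$.y == 0)) {
    return(fit_failure_row("neg-binomial", outcome_label, "all-zero outcome", n_used))
  }

  fml <- stats::as.formula(paste(".y ~", paste(setdiff(names(dat), ".y"), collapse = " + ")))
  family_used <- "neg-binomial"
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(fml, data = dat, control = stats::glm.control(maxit = 100))),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || !is.finite(fit$theta) || fit$theta > 1e5) {
    if (!is.null(fit) && !is.null(fit$theta) && is.finite(fit$theta) && fit$theta > 1e5) {
      rlang::warn("dispersion estimate diverged (no overdispersion detected); falling back to Poisson")
    } else {
      rlang::warn("negative binomial fit did not converge; falling back to Poisson")
    }
    family_used <- "poisson"
    fit <- tryCatch(stats::glm(fml, data = dat, family = stats::poisson()),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      return(fit_failure_row("neg-binomial", outcome_label, "fit failed", n_used))
    }
  }

  sm <- summary(fit)$coefficients
  terms <- rownames(sm)
  terms[terms == ".x"] <- exposure_label
  tibble::tibble(
    model = family_used, outcome = outcome_label, term = terms,
    effect = exp(sm[, "Estimate"]),
    ci_low = exp(sm[, "Estimate"] - qnorm(0.975) * sm[, "Std. Error"]),
    ci_high = exp(sm[, "Estimate"] + qnorm(0.975) * sm[, "Std. Error"]),
    p_value = sm[, 4],
    n_used = as.integer(n_used), converged = TRUE, note = NA_character_
  )
}

#' Subsidy-status and relative-subsidy regressions on housing group
#'
#' Criterion-validity models for the housing SES proxy. Subsidy status
#' (reference: nonsubsidized) is regressed on housing group (reference:
#' private) by multinomial logistic regression; effects are odds ratios
#' (`exp(beta)`) for the subsidized-vs-nonsubsidized and
#' mixed-vs-nonsubsidized contrasts. Relative subsidy received is regressed
#' on housing group by linear regression; effects are additive `beta` in
#' percentage points. Patients in the `missing` housing group are not used.
#' An empty status-by-housing cell is reported with a warning; categories
#' are never collapsed automatically.
#'
#' @param status Character/factor of patient subsidy status
#'   (`subsidized` / `mixed` / `nonsubsidized`).
#' @param rsr Numeric vector of relative subsidy received (percent), `NA`
#'   allowed.
#' @param housing_group Housing group labels as from [group_housing()].
#' @param covariates Optional tibble of adjustment covariates (e.g. a
#'   nationality indicator).
#' @return Tibble of regression results; multinomial rows carry the
#'   contrast in `outcome` (e.g. `"subsidized vs nonsubsidized"`), linear
#'   rows have `model = "linear"` and additive effects.
#' @export
subsidy_regressions <- function(status, rsr, housing_group, covariates = NULL) {
  keep <- housing_group != "missing" & !is.na(housing_group) & !is.na(status)
  hg <- factor(housing_group[keep],
               levels = setdiff(housing_group_levels(), "missing"))
  hg <- stats::relevel(hg, ref = "private")
  st <- factor(status[keep], levels = c("nonsubsidized", "subsidized", "mixed"))
  rs <- rsr[keep]
  cv <- if (!is.null(covariates)) as.data.frame(covariates)[keep, , drop = FALSE] else NULL

  cells <- table(st, hg)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    rlang::warn(sprintf(
      "empty status-by-housing cell(s): %s; categories are not collapsed",
      paste(sprintf("%s x %s", rownames(cells)[empty[, 1]],
                    colnames(cells)[empty[, 2]]), collapse = "; ")
    ))
  }

  dat <- data.frame(.st = st, .hg = hg)
  if (!is.null(cv)) dat <- cbind(dat, cv)
  ok <- stats::complete.cases(dat)
  dat_m <- dat[ok, , drop = FALSE]
  fml <- stats::as.formula(paste(".st ~", paste(setdiff(names(dat_m), ".st"), collapse = " + ")))
  fit <- nnet::multinom(fml, data = dat_m, trace = FALSE, maxit = 500)
  sm <- summary(fit)
  b <- sm$coefficients; se <- sm$standard.errors
  if (is.null(dim(b))) { # single contrast edge case
    b <- matrix(b, nrow = 1, dimnames = list(levels(st)[2], names(b)))
    se <- matrix(se, nrow = 1, dimnames = dimnames(b))
  }
  multi <- purrr::map_dfr(rownames(b), function(contrast) {
    z <- b[contrast, ] / se[contrast, ]
    tibble::tibble(
      model = "multinomial", outcome = paste(contrast, "vs nonsubsidized"),
      term = colnames(b),
      effect = exp(b[contrast, ]),
      ci_low = exp(b[contrast, ] - qnorm(0.975) * se[contrast, ]),
      ci_high = exp(b[contrast, ] + qnorm(0.975) * se[contrast, ]),
      p_value = 2 * pnorm(-abs(z)),
      n_used = as.integer(nrow(dat_m)), converged = fit$convergence == 0,
      note = NA_character_
    )
  })

  dat_l <- data.frame(.rsr = rs, .hg = hg)
  if (!is.null(cv)) dat_l <- cbind(dat_l, cv)
  dat_l <- dat_l[stats::complete.cases(dat_l), , drop = FALSE]
  fit_l <- stats::lm(stats::as.formula(
    paste(".rsr ~", paste(setdiff(names(dat_l), ".rsr"), collapse = " + "))
  ), data = dat_l)
  sl <- summary(fit_l)$coefficients
  ci <- stats::confint(fit_l)
  linear <- tibble::tibble(
    model = "linear", outcome = "relative subsidy received",
    term = rownames(sl),
    effect = sl[, "Estimate"],
    ci_low = ci[, 1], ci_high = ci[, 2],
    p_value = sl[, 4],
    n_used = as.integer(nrow(dat_l)), converged = TRUE, note = NA_character_
  )
  dplyr::bind_rows(multi, linear)
}

#' Pearson chi-square test of independence
#'
#' @param tab An r x c contingency matrix of counts.
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`.
#' @examples
#' chisq_independence(matrix(c(20, 0, 0, 20), 2)) # statistic 40, df 1
#' @export
chisq_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) == 0) {
    emr_abort("contingency table needs non-negative counts with a positive total",
              "emrforge_config_error")
  }
  zero_r <- which(rowSums(tab) == 0); zero_c <- which(colSums(tab) == 0)
  if (length(zero_r) > 0 || length(zero_c) > 0) {
    emr_abort(sprintf(
      "empty margin(s): %s%s",
      if (length(zero_r)) paste0("row ", paste(zero_r, collapse = ",")) else "",
      if (length(zero_c)) paste0(" column ", paste(zero_c, collapse = ",")) else ""
    ), "emrforge_config_error")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(test = "Pearson chi-square",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-sum comparison of a numeric outcome across k groups, with average
#' ranks and the standard tie correction; df = k - 1.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 || any(lengths(groups) == 0)) {
    emr_abort("need at least two non-empty groups", "emrforge_config_error")
  }
  if (length(unique(unlist(groups))) == 1) {
    # no spread at all: every observation shares one rank, no separation
    return(tibble::tibble(test = "Kruskal-Wallis", statistic = 0,
                          df = length(groups) - 1L, p_value = 1))
  }
  ht <- stats::kruskal.test(groups)
  tibble::tibble(test = "Kruskal-Wallis",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Run the full proxy-measure validation harness
#'
#' Bundles the validity analyses over a measured patient table: Spearman
#' correlations (Holm-adjusted) of CCI and PPS with each other and with
#' utilization counts; negative binomial regressions of each utilization
#' count on CCI and on PPS adjusting for sex, race, age and observed period;
#' multinomial and linear regressions of subsidy status and RSR on housing
#' group adjusting for nationality; and the housing-by-subsidy chi-square
#' and RSR-by-housing Kruskal-Wallis tests.
#'
#' @param patients Measured patient tibble (from [attach_measures()]).
#' @param alpha Family-wise level for the correlation CIs.
#' @return A list of class `validation_report` with elements `correlations`,
#'   `count_models`, `subsidy_models`, `independence`.
#' @export
validation_report <- function(patients, alpha = 0.05) {
  need <- c("cci", "pps", "n_inpatient", "n_soc", "n_ed",
            "subsidy_status", "rsr", "housing_group")
  assert_columns(patients, need, "measured patient table")

  pairs <- list(
    "CCI vs PPS" = list(x = patients$cci, y = patients$pps),
    "CCI vs inpatient visits" = list(x = patients$cci, y = patients$n_inpatient),
    "CCI vs SOC visits" = list(x = patients$cci, y = patients$n_soc),
    "CCI vs ED visits" = list(x = patients$cci, y = patients$n_ed),
    "PPS vs inpatient visits" = list(x = patients$pps, y = patients$n_inpatient),
    "PPS vs SOC visits" = list(x = patients$pps, y = patients$n_soc),
    "PPS vs ED visits" = list(x = patients$pps, y = patients$n_ed)
  )
  correlations <- spearman_holm(pairs, alpha = alpha)

  covars <- tibble::tibble(
    sex = factor(patients$sex),
    race = factor(patients$race),
    age = if ("age_at_end" %in% names(patients)) patients$age_at_end else NA_real_,
    observed_period = patients$observed_period
  )
  count_models <- dplyr::bind_rows(purrr::map2_dfr(
    rep(c("n_inpatient", "n_soc", "n_ed"), each = 2),
    rep(c("cci", "pps"), times = 3),
    function(ocol, xcol) {
      count_regression(patients[[ocol]], patients[[xcol]], covars,
                       outcome_label = ocol, exposure_label = xcol)
    }
  ))

  nat <- if ("singaporean" %in% names(patients)) {
    tibble::tibble(singaporean = as.logical(patients$singaporean))
  } else NULL
  subsidy_models <- subsidy_regressions(patients$subsidy_status, patients$rsr,
                                        patients$housing_group, nat)

  valid_housing <- patients$housing_group != "missing"
  tab <- table(patients$housing_group[valid_housing],
               patients$subsidy_status[valid_housing])
  rsr_groups <- split(patients$rsr[valid_housing],
                      patients$housing_group[valid_housing])
  rsr_groups <- lapply(rsr_groups, function(v) v[!is.na(v)])
  independence <- dplyr::bind_rows(
    chisq_independence(as.matrix(tab)),
    kruskal_wallis(rsr_groups)
  )

  structure(
    list(correlations = correlations, count_models = count_models,
         subsidy_models = subsidy_models, independence = independence),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  correlations: %d pairs (Holm-adjusted CIs)\n", nrow(x$correlations)))
  cat(sprintf("  count models: %d terms\n", nrow(x$count_models)))
  cat(sprintf("  subsidy models: %d terms\n", nrow(x$subsidy_models)))
  cat(sprintf("  independence tests: %d\n", nrow(x$independence)))
  invisible(x)
}
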