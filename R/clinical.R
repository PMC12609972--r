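#' Per-subject gene-signature score
#'
#' Scores each subject as the mean of the z-standardized expression of the
#' signature genes (each gene standardized across subjects). Signature
#' genes absent from the cohort are reported in the `"missing_genes"`
#' attribute; genes with zero variance are dropped with a warning.
#'
#' @param cohort A cohort tibble (`subject`, `time`, `event`, one column
#'   per gene).
#' @param gene_set Character vector of signature genes.
#' @return A tibble `subject`, `score`.
#' @export
signature_score <- function(cohort, gene_set) {
  present <- intersect(gene_set, names(cohort))
  missing <- setdiff(gene_set, names(cohort))
  if (length(present) == 0) {
    abort("no signature gene is present in the cohort expression matrix")
  }
  expr <- as.matrix(cohort[, present, drop = FALSE])
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping zero-variance gene(s): %s",
                 paste(present[sds == 0], collapse = ", ")))
    expr <- expr[, sds > 0, drop = FALSE]
    if (ncol(expr) == 0) abort("all signature genes have zero variance")
  }
  out <- tibble::tibble(
    subject = cohort$subject,
    score = rowMeans(scale(expr))
  )
  attr(out, "missing_genes") <- missing
  out
}

#' Median-split group assignment
#'
#' Dichotomizes scores at the median: strictly above the median is `high`,
#' at or below is `low` (ties go to the low group).
#'
#' @param scores Numeric vector (>= 4 values).
#' @param ties Which group median-tied scores join (default `"low"`).
#' @return A factor with levels `low`, `high`, same length and order.
#' @export
median_split <- function(scores, ties = c("low", "high")) {
  ties <- match.arg(ties)
  if (length(scores) < 4) abort("median_split() needs at least 4 subjects")
  if (length(unique(scores)) == 1) {
    abort("degenerate split: all scores are identical")
  }
  med <- stats::median(scores)
  high <- if (ties == "low") scores > med else scores >= med
  factor(dplyr::if_else(high, "high", "low"), levels = c("low", "high"))
}

#' Median-split Kaplan-Meier comparison with log-rank test and hazard ratio
#'
#' Estimates Kaplan-Meier survival curves per group, tests the difference
#' with the two-group log-rank test (1 df), and summarizes it as the
#' hazard ratio of the `high` group versus the `low` group estimated from
#' the log-rank observed/expected totals: `HR = (O_high/E_high) /
#' (O_low/E_low)`, with a log-scale confidence interval using
#' `SE(log HR) = sqrt(1/E_high + 1/E_low)`.
#'
#' @param cohort A cohort tibble with `time` and `event`.
#' @param groups Factor of group labels (`low`/`high`), one per subject.
#' @param conf_level Confidence level for the HR interval.
#' @return An object of class `"signature_survival"`; [glance()] gives the
#'   log-rank statistic, p-value, HR and CI; [tidy()] the KM curves.
#' @export
logrank_hr <- function(cohort, groups, conf_level = 0.95) {
  stopifnot(length(groups) == nrow(cohort))
  groups <- factor(groups, levels = c("low", "high"))
  if (any(table(groups) == 0)) abort("both groups must be non-empty")
  if (sum(cohort$event) == 0) abort("no events observed")
  surv <- survival::Surv(cohort$time, cohort$event)
  sd_fit <- survival::survdiff(surv ~ groups)
  km <- survival::survfit(surv ~ groups)
  chisq <- sd_fit$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  O <- sd_fit$obs
  E <- sd_fit$exp
  # index 2 = high group (factor level order)
  hr <- (O[2] / E[2]) / (O[1] / E[1])
  se_log <- sqrt(1 / E[1] + 1 / E[2])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      km = km,
      groups = groups,
      logrank_chisq = unname(chisq),
      p_value = unname(p),
      hr = unname(hr),
      hr_ci = c(lower = unname(exp(log(hr) - zq * se_log)),
                upper = unname(exp(log(hr) + zq * se_log))),
      observed = stats::setNames(as.numeric(O), c("low", "high")),
      expected = stats::setNames(as.numeric(E), c("low", "high"))
    ),
    class = "signature_survival"
  )
}

#' @export
glance.signature_survival <- function(x, ...) {
  tibble::tibble(
    logrank_chisq = x$logrank_chisq,
    p_value = x$p_value,
    hr = x$hr,
    hr_lower = x$hr_ci[["lower"]],
    hr_upper = x$hr_ci[["upper"]],
    n_low = sum(x$groups == "low"),
    n_high = sum(x$groups == "high")
  )
}

#' @export
tidy.signature_survival <- function(x, ...) {
  km <- x$km
  group <- rep(sub("^groups=", "", names(km$strata)), km$strata)
  tibble::tibble(
    group = group,
    time = km$time,
    n_risk = km$n.risk,
    n_event = km$n.event,
    survival = km$surv
  )
}

#' @export
print.signature_survival <- function(x, ...) {
  cat(sprintf("Median-split survival: log-rank chi-square = %.3f (p = %.3g), HR(high vs low) = %.3f [%.3f, %.3f]\n",
              x$logrank_chisq, x$p_value, x$hr, x$hr_ci[["lower"]], x$hr_ci[["upper"]]))
  invisible(x)
}

#' @export
autoplot.signature_survival <- function(object, ...) {
  df <- tidy(object)
  # prepend the (0, 1) start of each curve
  start <- dplyr::distinct(df, .data$group) %>%
    dplyr::mutate(time = 0, survival = 1, n_risk = NA_integer_, n_event = 0L)
  df <- dplyr::bind_rows(start, df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability", colour = "group") +
    ggplot2::theme_minimal()
}

#' Spearman rank correlation with exact small-sample permutation p-value
#'
#' Computes Spearman's rho on mid-ranks (ties averaged). The two-sided
#' p-value uses the large-sample t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` for `n > 9`, and the exact permutation
#' distribution (all `n!` rank permutations) for `n <= 9`.
#'
#' @param x,y Numeric vectors of equal length, `n >= 5`.
#' @return A tibble `rho`, `p`, `n`, `method`.
#' @export
spearman_corr <- function(x, y) {
  n <- length(x)
  if (n != length(y)) abort("`x` and `y` must have equal length")
  if (n < 5) abort("at least 5 observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("zero variance in `x` or `y`")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    # exact two-sided permutation p over all n! pairings of the mid-ranks
    perm_idx <- all_permutations(n)
    rx_c <- rx - mean(rx)
    ry_c <- ry - mean(ry)
    denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
    stat_obs <- abs(sum(rx_c * ry_c) / denom)
    permuted_rx <- matrix(rx_c[perm_idx], ncol = n)
    stats_perm <- abs((permuted_rx %*% ry_c)[, 1] / denom)
    p <- mean(stats_perm >= stat_obs - 1e-12)
    method <- "exact permutation"
  } else {
    if (abs(rho) == 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p = p, n = n, method = method)
}

all_permutations <- function(n) {
  # iterative Steinhaus-Johnson-like construction: insert n into all
  # positions of each permutation of n-1
  perms <- matrix(1L, nrow = 1, ncol = 1)
  for (k in 2:n) {
    prev <- perms
    out <- matrix(0L, nrow = nrow(prev) * k, ncol = k)
    row <- 1
    for (i in seq_len(nrow(prev))) {
      for (pos in seq_len(k)) {
        out[row, ] <- append(prev[i, ], k, after = pos - 1)
        row <- row + 1
      }
    }
    perms <- out
  }
  perms
}

#' End-to-end signature survival analysis
#'
#' Convenience wrapper: signature scoring, median split, and log-rank/HR
#' summary in one call.
#'
#' @param cohort A cohort tibble.
#' @param gene_set Signature gene symbols.
#' @param ties Median tie rule, see [median_split()].
#' @return A `"signature_survival"` object.
#' @export
signature_survival <- function(cohort, gene_set, ties = "low") {
  scores <- signature_score(cohort, gene_set)
  groups <- median_split(scores$score, ties = ties)
  logrank_hr(cohort, groups)
}
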