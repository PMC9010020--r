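new_test_result <- function(statistic, p_value, method, n, p_mode, ...) {
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         n = n, p_mode = p_mode, ...),
    class = "constrictr_test"
  )
}

#' @export
print.constrictr_test <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.6g, p = %.4g (%s)\n  n = %s\n",
              x$method, x$statistic, x$p_value, x$p_mode,
              paste(x$n, collapse = ", ")))
  invisible(x)
}

# asymptotic Kolmogorov survival function: P(sqrt(ne) * D >= lambda)
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs, computed by a
#' scan over the pooled sorted values (ties handled by ECDF
#' right-continuity). The p-value uses the asymptotic Kolmogorov
#' distribution with effective sample size `n_a * n_b / (n_a + n_b)`.
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @return A `constrictr_test` result with `statistic` (D in \[0, 1\]) and
#'   `p_value`.
#' @export
ks_2sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort_constrictr("both samples need at least 2 non-missing values",
                     "constrictr_parameter_error")
  }
  pooled <- sort(unique(c(a, b)))
  fa <- vapply(pooled, function(v) mean(a <= v), 0)
  fb <- vapply(pooled, function(v) mean(b <= v), 0)
  d <- max(abs(fa - fb))
  ne <- length(a) * length(b) / (length(a) + length(b))
  p <- kolmogorov_sf(sqrt(ne) * d)
  new_test_result(d, p, "Two-sample Kolmogorov-Smirnov test",
                  c(n_a = length(a), n_b = length(b)), "asymptotic")
}

#' Peacock two-dimensional two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the maximum, over origins and the four quadrant
#' orientations, of the absolute difference in empirical quadrant fractions
#' between the two point sets. `mode = "full_grid"` scans every origin on
#' the pooled-x by pooled-y coordinate grid (Peacock's original test);
#' `mode = "sample_origins"` restricts origins to the pooled data points
#' (the Fasano-Franceschini variant, whose D never exceeds the full-grid
#' D). The p-value comes from label permutation of the pooled sample:
#' `p = (count + 1) / (n_perm + 1)` where `count` is the number of permuted
#' statistics at least as large as the observed one.
#'
#' @param a,b Two-column numeric matrices (or data frames) of 2D points,
#'   each with at least 3 rows.
#' @param mode Origin set: `"full_grid"` (default) or `"sample_origins"`.
#' @param p_mode `"permutation"` (default) or `"none"` (statistic only,
#'   `p_value = NA`).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed applied via `set.seed()` for a
#'   reproducible permutation p-value.
#' @return A `constrictr_test` result; `statistic` is D in \[0, 1\].
#' @export
peacock_2d <- function(a, b, mode = c("full_grid", "sample_origins"),
                       p_mode = c("permutation", "none"),
                       n_perm = 999, seed = NULL) {
  mode <- match.arg(mode)
  p_mode <- match.arg(p_mode)
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != 2 || ncol(b) != 2) {
    abort_constrictr("samples must be n x 2 matrices of points",
                     "constrictr_parameter_error")
  }
  a <- a[stats::complete.cases(a), , drop = FALSE]
  b <- b[stats::complete.cases(b), , drop = FALSE]
  if (nrow(a) < 3 || nrow(b) < 3) {
    abort_constrictr("both samples need at least 3 complete points",
                     "constrictr_parameter_error")
  }
  full <- mode == "full_grid"
  pooled <- rbind(a, b)
  # degenerate fast path: every point identical -> distributions equal
  if (nrow(unique(pooled)) == 1) {
    return(new_test_result(0, 1, "Peacock 2D Kolmogorov-Smirnov test",
                           c(n_a = nrow(a), n_b = nrow(b)), "degenerate",
                           mode = mode))
  }
  if (p_mode == "none") {
    d <- peacock_stat_cpp(a[, 1], a[, 2], b[, 1], b[, 2], full)
    return(new_test_result(d, NA_real_, "Peacock 2D Kolmogorov-Smirnov test",
                           c(n_a = nrow(a), n_b = nrow(b)), "none",
                           mode = mode))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- peacock_perm_cpp(pooled[, 1], pooled[, 2], nrow(a), n_perm, full)
  p <- (res$count_ge + 1) / (n_perm + 1)
  new_test_result(res$statistic, p, "Peacock 2D Kolmogorov-Smirnov test",
                  c(n_a = nrow(a), n_b = nrow(b)),
                  sprintf("permutation(n_perm = %d%s)", n_perm,
                          if (is.null(seed)) "" else sprintf(", seed = %d", seed)),
                  mode = mode)
}

#' Pearson correlation with best-fit line
#'
#' Pearson's r with the usual t-transform p-value (n − 2 degrees of
#' freedom), plus the least-squares best-fit line through the scatter.
#'
#' @param x,y Paired numeric samples, n >= 3, each with nonzero variance.
#' @return A `constrictr_test` result with `statistic` (r), `p_value`,
#'   `slope` and `intercept`.
#' @export
pearson_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort_constrictr("need at least 3 complete pairs", "constrictr_parameter_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_constrictr("zero variance in a sample", "constrictr_parameter_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  slope <- unname(ct$estimate) * stats::sd(y) / stats::sd(x)
  new_test_result(unname(ct$estimate), ct$p.value, "Pearson correlation",
                  c(n = length(x)), "asymptotic",
                  slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Run a batch of statistical comparisons
#'
#' Consumes a comparisons specification and a data frame and emits a tidy
#' results table. Each row of `spec` names one comparison:
#' * `test = "ks"`: `variable` compared between `group_a` and `group_b`
#'   levels of `group_col`;
#' * `test = "peacock"`: the 2D distribution of (`variable2`, `variable`)
#'   compared between the two groups;
#' * `test = "pearson"`: correlation of `variable2` with `variable` within
#'   `group_a` (or all rows when `group_a` is `NA`).
#'
#' @param data A data frame (typically a per-track summary table).
#' @param spec Tibble with columns `name`, `test`, `variable`, and
#'   optionally `variable2`, `group_col`, `group_a`, `group_b`.
#' @param n_perm,seed Permutation settings passed to [peacock_2d()].
#' @return Tidy tibble with one row per comparison: `name`, `method`,
#'   `statistic`, `p_value`, `n_a`, `n_b`, `settings`.
#' @export
run_comparisons <- function(data, spec, n_perm = 999, seed = NULL) {
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    pick <- function(level) {
      if (is.null(s$group_col) || is.na(s$group_col) ||
          is.null(level) || is.na(level)) {
        data
      } else {
        data[!is.na(data[[s$group_col]]) & data[[s$group_col]] == level, ]
      }
    }
    res <- switch(
      s$test,
      ks = {
        ks_2sample(pick(s$group_a)[[s$variable]], pick(s$group_b)[[s$variable]])
      },
      peacock = {
        da <- pick(s$group_a); db <- pick(s$group_b)
        peacock_2d(cbind(da[[s$variable2]], da[[s$variable]]),
                   cbind(db[[s$variable2]], db[[s$variable]]),
                   n_perm = n_perm, seed = seed)
      },
      pearson = {
        da <- pick(s$group_a)
        pearson_cor(da[[s$variable2]], da[[s$variable]])
      },
      abort_constrictr(sprintf("unknown test name '%s' in comparison '%s'",
                               s$test, s$name),
                       "constrictr_config_error")
    )
    tibble::tibble(
      name = s$name, method = res$method, statistic = res$statistic,
      p_value = res$p_value, n_a = unname(res$n[1]),
      n_b = if (length(res$n) > 1) unname(res$n[2]) else NA_integer_,
      settings = res$p_mode
    )
  })
  dplyr::bind_rows(rows)
}
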