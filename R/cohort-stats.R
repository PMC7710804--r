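#' @title Two-cohort statistics with family-wise error control
#'
#' @description Nodewise and global comparison of two patient cohorts
#'   (impaired MSCI vs non-impaired MSNI) and correlation of network
#'   measures with the impairment index. Group tests are pooled-variance
#'   (Student) t-tests — the analysis assumes homoscedastic normal
#'   sampling — two-tailed at the node level and one-tailed with a
#'   per-measure expected direction at the global level. The family-wise
#'   error rate over the m nodewise tests (m = number of nodes, 333 for
#'   the Gordon parcellation) is controlled with the Holm-Sidak step-down
#'   procedure at alpha = 0.05. Stepwise regression is deliberately not
#'   offered anywhere in this package.
#' @name cohort-stats
NULL

#' Pooled-variance two-sample t-test
#'
#' Classic Student t with pooled variance and `df = n_a + n_b - 2`.
#' `tail = "two"` gives the two-tailed p; `"one_greater"` tests
#' `mean(a) > mean(b)`, `"one_less"` the reverse.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param tail `"two"`, `"one_greater"` or `"one_less"`.
#' @return list of class `t_test_result` with `statistic`, `df`,
#'   `p_value`, `tail`, `mean_diff` (`mean(a) - mean(b)`).
#' @export
pooled_t_test <- function(a, b, tail = c("two", "one_greater", "one_less")) {
  tail <- match.arg(tail)
  na <- length(a)
  nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("degenerate samples: zero pooled variance",
                     call. = FALSE)
  md <- mean(a) - mean(b)
  tval <- md / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2L
  p <- switch(tail,
              two = 2 * pt(-abs(tval), df),
              one_greater = pt(tval, df, lower.tail = FALSE),
              one_less = pt(tval, df))
  structure(list(statistic = tval, df = df, p_value = p, tail = tail,
                 mean_diff = md), class = "t_test_result")
}

# Vectorized pooled t over the columns of two subject-by-variable matrices.
# Returns NA p for columns with zero pooled variance and zero mean
# difference; p = 0 when the pooled variance is zero but the means differ.
pooled_t_columns <- function(A, B) {
  na <- nrow(A)
  nb <- nrow(B)
  stopifnot(na >= 2L, nb >= 2L, ncol(A) == ncol(B))
  ma <- colMeans(A)
  mb <- colMeans(B)
  va <- apply(A, 2, stats::var)
  vb <- apply(B, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  md <- ma - mb
  tval <- md / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2L
  p <- 2 * pt(-abs(tval), df)
  sep_idx <- which(sp2 <= 0 & md != 0)  # constant but different: certain
  p[sep_idx] <- 0
  tval[sep_idx] <- Inf * sign(md[sep_idx])
  flat_idx <- which(sp2 <= 0 & md == 0)  # no variation at all: untestable
  p[flat_idx] <- NA_real_
  tval[flat_idx] <- NA_real_
  list(statistic = tval, df = df, p_value = p, mean_diff = md,
       mean_a = ma, mean_b = mb, degenerate = is.na(p))
}

#' Holm-Sidak step-down multiple-comparison correction
#'
#' Sorts the m p-values ascending and compares the i-th smallest against
#' `1 - (1 - alpha)^(1 / (m - i + 1))`, stopping at the first failure.
#' Adjusted p-values use the standard step-down max construction
#' `p~_(i) = max_{j <= i} min(1, 1 - (1 - p_(j))^(m - j + 1))`, so that
#' `reject <=> adjusted p <= alpha`.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param alpha family-wise error level (default 0.05).
#' @return list with `reject` (logical) and `adjusted_p`, both in the
#'   original input order.
#' @export
holm_sidak <- function(p_values, alpha = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  m <- length(p_values)
  ord <- order(p_values)
  k <- m - seq_len(m) + 1
  adj_sorted <- cummax(pmin(1, 1 - (1 - p_values[ord])^k))
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  list(reject = adjusted <= alpha, adjusted_p = adjusted)
}

#' Nodewise two-cohort comparison
#'
#' One pooled-variance two-tailed t-test per node comparing the impaired
#' (MSCI) against the non-impaired (MSNI) cohort, with Holm-Sidak control
#' over the family of all tested nodes. Nodes with zero variance in both
#' cohorts and equal means (e.g. isolated in every subject) cannot be
#' tested; they are dropped from the family (m reduced accordingly, with
#' a message) and reported with `NA` p-values.
#'
#' @param msci,msni numeric matrices of one local measure, subjects in
#'   rows, nodes in columns (>= 2 subjects each, equal node count).
#' @param alpha family-wise error level (default 0.05).
#' @param measure_name label recorded in the output table.
#' @return data frame of class `node_stats_table`, one row per node:
#'   `node`, `measure_name`, `mean_msci`, `mean_msni`, `mean_diff`
#'   (MSCI - MSNI), `statistic`, `df`, `raw_p`, `adjusted_p`, `reject`,
#'   `direction` (sign of `mean_diff`). Attribute `m` holds the corrected
#'   family size.
#' @export
nodewise_comparison <- function(msci, msni, alpha = 0.05,
                                measure_name = "measure") {
  msci <- as.matrix(msci)
  msni <- as.matrix(msni)
  if (ncol(msci) != ncol(msni))
    stop("cohorts measured on different parcellations", call. = FALSE)
  if (nrow(msci) < 2L || nrow(msni) < 2L)
    stop("each cohort needs at least 2 subjects", call. = FALSE)
  tt <- pooled_t_columns(msci, msni)
  N <- ncol(msci)
  testable <- !tt$degenerate
  m <- sum(testable)
  if (m < N)
    message(sprintf("%d node(s) with zero variance dropped from testing; m = %d",
                    N - m, m))
  adjusted_p <- rep(NA_real_, N)
  reject <- rep(FALSE, N)
  if (m > 0L) {
    hs <- holm_sidak(tt$p_value[testable], alpha)
    adjusted_p[testable] <- hs$adjusted_p
    reject[testable] <- hs$reject
  }
  out <- data.frame(node = seq_len(N), measure_name = measure_name,
                    mean_msci = tt$mean_a, mean_msni = tt$mean_b,
                    mean_diff = tt$mean_diff, statistic = tt$statistic,
                    df = tt$df, raw_p = tt$p_value,
                    adjusted_p = adjusted_p, reject = reject,
                    direction = sign(tt$mean_diff))
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  class(out) <- c("node_stats_table", "data.frame")
  out
}

#' Expected directions for the global one-tailed tests
#'
#' The global comparison tests the hypothesis that network robustness is
#' higher in the non-impaired cohort, so for robustness-type measures the
#' expected direction is `"msni_greater"`. For characteristic path length
#' and diameter "more robust" does not fix a direction a priori, so those
#' two must be stated explicitly — there is no silent default.
#'
#' @param characteristic_path_length,diameter `"msni_greater"` or
#'   `"msci_greater"` (required, no default).
#' @param ... overrides for the remaining measures
#'   (`curvature`, `clustering_mean`, `density`, `global_efficiency`,
#'   `small_worldness`), each `"msni_greater"` or `"msci_greater"`.
#' @return named character vector of directions.
#' @export
global_test_directions <- function(characteristic_path_length, diameter,
                                   ...) {
  if (missing(characteristic_path_length) || missing(diameter))
    stop(paste("directions for characteristic_path_length and diameter",
               "must be stated explicitly"), call. = FALSE)
  dirs <- c(curvature = "msni_greater", clustering_mean = "msni_greater",
            density = "msni_greater", global_efficiency = "msni_greater",
            small_worldness = "msni_greater",
            characteristic_path_length = characteristic_path_length,
            diameter = diameter)
  dots <- list(...)
  for (nm in names(dots)) dirs[[nm]] <- dots[[nm]]
  if (!all(dirs %in% c("msni_greater", "msci_greater")))
    stop("directions must be 'msni_greater' or 'msci_greater'",
         call. = FALSE)
  dirs
}

#' Global two-cohort comparison
#'
#' One one-tailed pooled t-test per global measure, in the stated expected
#' direction, with Holm-Sidak control across the tested measures.
#'
#' @param msci,msni data frames of per-subject global measures (subjects
#'   in rows, one column per measure; columns present in both and named in
#'   `directions` are tested).
#' @param directions named vector from [global_test_directions()].
#' @param alpha family-wise error level (default 0.05).
#' @return data frame: `measure`, `direction`, `mean_msci`, `mean_msni`,
#'   `statistic`, `df`, `raw_p`, `adjusted_p`, `reject`.
#' @export
global_comparison <- function(msci, msni, directions, alpha = 0.05) {
  measures <- intersect(intersect(names(msci), names(msni)),
                        names(directions))
  if (length(measures) == 0L)
    stop("no measures shared by both cohorts and the direction map",
         call. = FALSE)
  rows <- lapply(measures, function(mm) {
    a <- msci[[mm]]
    b <- msni[[mm]]
    tail <- if (directions[[mm]] == "msci_greater") "one_greater"
            else "one_less"
    tt <- tryCatch(pooled_t_test(a, b, tail = tail),
                   error = function(e) list(statistic = NA_real_,
                                            df = NA_integer_,
                                            p_value = NA_real_))
    data.frame(measure = mm, direction = directions[[mm]],
               mean_msci = mean(a), mean_msni = mean(b),
               statistic = tt$statistic, df = tt$df, raw_p = tt$p_value)
  })
  out <- do.call(rbind, rows)
  testable <- !is.na(out$raw_p)  # e.g. zero between-subject variance
  if (!all(testable))
    message(sum(!testable), " degenerate global measure(s) not tested")
  out$adjusted_p <- NA_real_
  out$reject <- FALSE
  if (any(testable)) {
    hs <- holm_sidak(out$raw_p[testable], alpha)
    out$adjusted_p[testable] <- hs$adjusted_p
    out$reject[testable] <- hs$reject
  }
  out
}

#' Pearson correlation of a measure with the impairment index
#'
#' Two-tailed p-value from the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param values numeric measure values, one per subject.
#' @param ci_indices matching CI index values.
#' @return list with `pearson_r`, `p_value`, `n`.
#' @export
correlate_with_ci <- function(values, ci_indices) {
  ok <- !is.na(values) & !is.na(ci_indices)
  x <- values[ok]
  y <- ci_indices[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in one of the variables", call. = FALSE)
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tval), n - 2)
  }
  list(pearson_r = r, p_value = p, n = n)
}

#' Correlate nodewise measure values with the CI index
#'
#' One Pearson correlation per requested node, over all included
#' (borderline-excluded) subjects pooled across both cohorts, two-tailed
#' and uncorrected by default (mirroring per-node scatter plots); set
#' `correct = TRUE` to add Holm-Sidak control over the requested set.
#'
#' @param measure_table numeric matrix, subjects in rows, nodes in
#'   columns.
#' @param ci_indices CI index per subject (same row order).
#' @param nodes node indices to correlate (default: all).
#' @param measure_name label recorded in the output.
#' @param correct apply Holm-Sidak over the requested nodes.
#' @param alpha level for the optional correction.
#' @return data frame: `node`, `measure_name`, `pearson_r`, `p_value`,
#'   `n` (plus `adjusted_p`, `reject` when `correct = TRUE`).
#' @export
correlate_nodes_with_ci <- function(measure_table, ci_indices,
                                    nodes = NULL, measure_name = "measure",
                                    correct = FALSE, alpha = 0.05) {
  measure_table <- as.matrix(measure_table)
  if (is.null(nodes)) nodes <- seq_len(ncol(measure_table))
  rows <- lapply(nodes, function(v) {
    res <- tryCatch(correlate_with_ci(measure_table[, v], ci_indices),
                    error = function(e) list(pearson_r = NA_real_,
                                             p_value = NA_real_,
                                             n = sum(!is.na(measure_table[, v]))))
    data.frame(node = v, measure_name = measure_name,
               pearson_r = res$pearson_r, p_value = res$p_value,
               n = res$n)
  })
  out <- do.call(rbind, rows)
  if (correct) {
    ok <- !is.na(out$p_value)
    out$adjusted_p <- NA_real_
    out$reject <- FALSE
    if (any(ok)) {
      hs <- holm_sidak(out$p_value[ok], alpha)
      out$adjusted_p[ok] <- hs$adjusted_p
      out$reject[ok] <- hs$reject
    }
  }
  out
}
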