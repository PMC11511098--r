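# Two-group comparisons gated on Shapiro-Wilk normality (one-way ANOVA vs
# Kruskal-Wallis), per-task sign matrices, the mixed repeated-measures ANOVA
# on normalization values, and Tukey's-B homogeneous subsets.

#' Choose the two-group test from a Shapiro-Wilk normality gate
#'
#' Returns `"kruskal_wallis"` if the Shapiro-Wilk p-value falls below
#' `alpha_norm` in either group, `"anova"` otherwise. Constant (zero-variance)
#' data make Shapiro-Wilk undefined and are treated as non-normal, with a
#' warning.
#'
#' @param values Numeric outcome values.
#' @param groups Factor/character of the same length with exactly two levels.
#' @param alpha_norm Gate significance level.
#' @return `"anova"` or `"kruskal_wallis"`.
#' @export
normality_gate <- function(values, groups, alpha_norm = 0.05) {
  sp <- split(as.numeric(values), groups)
  if (any(vapply(sp, length, integer(1L)) < 3L)) {
    stop("normality gate needs n >= 3 per group")
  }
  for (v in sp) {
    if (length(unique(v)) == 1L) {
      warning("constant data in one group: Shapiro-Wilk undefined, ",
              "treated as non-normal")
      return("kruskal_wallis")
    }
    if (stats::shapiro.test(v)$p.value < alpha_norm) return("kruskal_wallis")
  }
  "anova"
}

#' Compare one parameter between the two groups
#'
#' Runs the normality-gated test (one-way ANOVA or Kruskal-Wallis) and
#' reports the statistic, p-value, and — when significant at `alpha` — the
#' direction of the patient group relative to healthy (group means for the
#' ANOVA branch, mean ranks for the rank test).
#'
#' @param values Numeric outcome values.
#' @param groups Character/factor with levels `"healthy"` and `"patient"`.
#' @param alpha Significance level for the direction call.
#' @param alpha_norm Normality-gate level.
#' @return One-row tibble: `test_used, statistic, p_value, direction`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05, alpha_norm = 0.05) {
  values <- as.numeric(values)
  groups <- as.character(groups)
  if (!all(groups %in% c("healthy", "patient"))) {
    stop("groups must be 'healthy' or 'patient'")
  }
  if (length(unique(groups)) < 2L) stop("both groups must be non-empty")
  test <- if (length(unique(values)) == 1L) {
    # identical data degenerate for both tests; report a null result
    return(tibble::tibble(test_used = "kruskal_wallis", statistic = 0,
                          p_value = 1, direction = "none"))
  } else {
    normality_gate(values, groups, alpha_norm)
  }
  g <- factor(groups, levels = c("healthy", "patient"))
  if (test == "anova") {
    fit <- stats::anova(stats::lm(values ~ g))
    statistic <- fit[["F value"]][1L]
    p <- fit[["Pr(>F)"]][1L]
    higher <- mean(values[g == "patient"]) > mean(values[g == "healthy"])
  } else {
    kt <- stats::kruskal.test(values, g)
    statistic <- unname(kt$statistic)
    p <- kt$p.value
    rk <- rank(values)
    higher <- mean(rk[g == "patient"]) > mean(rk[g == "healthy"])
  }
  direction <- if (!is.na(p) && p < alpha) {
    if (higher) "patient_higher" else "patient_lower"
  } else "none"
  tibble::tibble(test_used = test, statistic = statistic, p_value = p,
                 direction = direction)
}

#' Group comparisons for every variable of a participant summary
#'
#' @param summary Wide tibble from [participant_summary()] (or any tibble with
#'   `participant_id`, `group`, and numeric variable columns).
#' @param variables Variables to test; defaults to every numeric column.
#' @param alpha,alpha_norm Significance levels.
#' @param p_adjust Multiplicity correction applied across the tested grid
#'   (`"none"` matches the original reporting; `"BH"` available).
#' @return Tidy tibble, one row per variable, with the [compare_groups()]
#'   fields.
#' @export
compare_all_variables <- function(summary, variables = NULL, alpha = 0.05,
                                  alpha_norm = 0.05,
                                  p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (is.null(variables)) {
    variables <- setdiff(names(summary)[vapply(summary, is.numeric, logical(1L))],
                         c("sensor", "task_id"))
  }
  res <- dplyr::bind_rows(lapply(variables, function(v) {
    out <- compare_groups(summary[[v]], summary$group, alpha, alpha_norm)
    out$variable <- v
    out
  }))
  if (p_adjust == "BH") {
    res$p_value <- stats::p.adjust(res$p_value, "BH")
    res$direction[res$p_value >= alpha] <- "none"
  }
  res[, c("variable", "test_used", "statistic", "p_value", "direction")]
}

#' Per-task group comparisons
#'
#' Applies [compare_groups()] within every task x sensor x parameter cell of a
#' per-task feature table, re-running the normality gate per cell.
#'
#' @param feature_rows Long tibble with `participant_id, group, sensor,
#'   task_id` and one or more numeric parameter columns (plus an optional
#'   `method` column kept as a key).
#' @param params Names of the parameter columns to test.
#' @param alpha,alpha_norm Significance levels.
#' @return Tidy tibble with one row per cell: keys, `parameter`, and the
#'   comparison fields.
#' @export
per_task_comparisons <- function(feature_rows, params, alpha = 0.05,
                                 alpha_norm = 0.05) {
  keys <- intersect(c("sensor", "method", "task_id"), names(feature_rows))
  cells <- split(feature_rows,
                 feature_rows[keys], drop = TRUE, sep = "\r")
  out <- lapply(cells, function(cell) {
    dplyr::bind_rows(lapply(params, function(p) {
      r <- suppressWarnings(
        compare_groups(cell[[p]], cell$group, alpha, alpha_norm))
      r$parameter <- p
      for (k in keys) r[[k]] <- cell[[k]][1L]
      r
    }))
  })
  res <- dplyr::bind_rows(out)
  res[, c(keys, "parameter", "test_used", "statistic", "p_value", "direction")]
}

#' Build a sign matrix from per-task comparison results
#'
#' Rows are sensor x parameter (x method) combinations; columns are tasks;
#' entries are `"+"` when patients are significantly higher, `"-"` when
#' significantly lower, `""` otherwise.
#'
#' @param results Output of [per_task_comparisons()].
#' @return A character matrix with informative dimnames, class `sign_matrix`.
#' @export
build_sign_table <- function(results) {
  keys <- intersect(c("sensor", "method", "parameter"), names(results))
  row_id <- do.call(paste, c(results[keys], sep = " "))
  rows <- unique(row_id)
  tasks <- sort(unique(results$task_id))
  m <- matrix("", nrow = length(rows), ncol = length(tasks),
              dimnames = list(rows, paste0("task", tasks)))
  sign_chr <- ifelse(results$direction == "patient_higher", "+",
                     ifelse(results$direction == "patient_lower", "-", ""))
  m[cbind(match(row_id, rows), match(results$task_id, tasks))] <- sign_chr
  structure(m, class = c("sign_matrix", "matrix"))
}

#' @export
print.sign_matrix <- function(x, ...) {
  cat("<sign_matrix> + patients higher, - patients lower, blank n.s.\n")
  print(unclass(x), quote = FALSE)
  invisible(x)
}

#' Mixed repeated-measures ANOVA on normalization values
#'
#' Univariate mixed-design ANOVA with group (healthy/patient) as the
#' between-subject factor and sensor and normalization method as
#' within-subject factors, fitted via `stats::aov` with the
#' `Error(participant/(sensor*method))` strata. No sphericity correction is
#' applied by default; Greenhouse-Geisser is available.
#'
#' @param norms Output of [normalization_table()] (or a compatible tibble with
#'   `participant_id, group, sensor, max_mV, mvc_mV, grasp_mV`).
#' @param gg_correction Apply a Greenhouse-Geisser epsilon correction to the
#'   within-subject p-values.
#' @return Tidy tibble: `effect, df, df_error, ss, ms, f, p_value` (plus
#'   `epsilon` and `p_gg` when corrected), and attribute `strata` with the
#'   fitted `aov` object.
#' @export
mixed_rm_anova <- function(norms, gg_correction = FALSE) {
  long <- tidyr::pivot_longer(norms, c("max_mV", "mvc_mV", "grasp_mV"),
                              names_to = "method", values_to = "value")
  long$method <- factor(toupper(sub("_mV$", "", long$method)),
                        levels = c("MAX", "MVC", "GRASP"))
  long$sensor <- factor(long$sensor)
  long$group <- factor(long$group)
  long$participant_id <- factor(long$participant_id)
  counts <- table(long$participant_id)
  expected <- nlevels(long$sensor) * nlevels(long$method)
  if (any(counts != expected)) {
    stop("incomplete within-subject cells for participants: ",
         paste(names(counts)[counts != expected], collapse = ", "))
  }
  fit <- stats::aov(value ~ group * sensor * method +
                      Error(participant_id / (sensor * method)),
                    data = long)
  sm <- summary(fit)
  rows <- list()
  for (stratum in names(sm)) {
    tab <- sm[[stratum]][[1L]]
    eff <- trimws(rownames(tab))
    resid_row <- eff == "Residuals"
    df_err <- tab$Df[resid_row]
    ms_err <- tab$`Mean Sq`[resid_row]
    for (i in which(!resid_row)) {
      ss <- tab$`Sum Sq`[i]
      f <- tab$`F value`[i]
      p <- tab$`Pr(>F)`[i]
      if (!is.finite(f) || (!is.na(ss) && ss < 1e-12)) {
        # numerically zero effect (e.g. all-equal data): defined as F = 0
        f <- 0
        p <- 1
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        effect = gsub("sensor", "sensor", eff[i]), stratum = stratum,
        df = tab$Df[i], df_error = df_err, ss = ss, ms = tab$`Mean Sq`[i],
        ms_error = ms_err, f = f, p_value = p)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (gg_correction) {
    eps <- .gg_epsilon(long)
    out$epsilon <- eps[match(out$effect, names(eps))]
    out$p_gg <- ifelse(is.na(out$epsilon), out$p_value,
                       stats::pf(out$f, out$df * out$epsilon,
                                 out$df_error * out$epsilon,
                                 lower.tail = FALSE))
  }
  attr(out, "fit") <- fit
  out
}

# Greenhouse-Geisser epsilon per within-subject effect, from the covariance
# of subject x condition means
.gg_epsilon <- function(long) {
  eps_of <- function(wide) {
    S <- stats::cov(wide)
    k <- ncol(S)
    num <- (k * mean(diag(S)) - mean(S))^2
    den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mean(S)^2)
    min(1, num / den)
  }
  mk_wide <- function(fac) {
    agg <- stats::aggregate(value ~ participant_id + get(fac), data = long, mean)
    names(agg)[2L] <- "cond"
    w <- tidyr::pivot_wider(agg, names_from = "cond", values_from = "value")
    as.matrix(w[, -1L])
  }
  sens <- eps_of(mk_wide("sensor"))
  meth <- eps_of(mk_wide("method"))
  c(sensor = sens, method = meth, `group:sensor` = sens,
    `group:method` = meth, `sensor:method` = NA_real_,
    `group:sensor:method` = NA_real_)
}

#' Tukey's-B homogeneous subsets
#'
#' Range test whose critical value for a span of r means is the average of the
#' Tukey HSD studentized-range critical value (at the full number of levels)
#' and the Student-Newman-Keuls value (at span r). Levels are sorted by mean;
#' maximal contiguous runs whose range does not exceed the critical difference
#' form the homogeneous subsets, so every level belongs to at least one subset
#' and subsets are contiguous in the mean ordering.
#'
#' @param means Named numeric vector of level means.
#' @param ms_error Error mean square from the ANOVA.
#' @param df_error Error degrees of freedom (> 0).
#' @param n Observations per level (scalar, or vector for a harmonic-mean
#'   correction).
#' @param alpha Test level.
#' @return List of character vectors (level names), ordered by subset minimum;
#'   attribute `ordered_means` carries the sorted means.
#' @export
tukeys_b_subsets <- function(means, ms_error, df_error, n, alpha = 0.05) {
  if (df_error <= 0) stop("`df_error` must be > 0")
  k <- length(means)
  if (k < 2L) return(list(names(means)))
  if (is.null(names(means))) names(means) <- seq_len(k)
  n_h <- length(n) / sum(1 / n) # harmonic mean for (mildly) unequal n
  se <- sqrt(ms_error / n_h)
  ord <- order(means)
  m <- means[ord]
  crit <- function(r) {
    (stats::qtukey(1 - alpha, k, df_error) +
       stats::qtukey(1 - alpha, r, df_error)) / 2 * se
  }
  subsets <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && (m[j + 1L] - m[i]) <= crit(j - i + 2L)) j <- j + 1L
    run <- names(m)[i:j]
    keep <- !any(vapply(subsets, function(s) all(run %in% s), logical(1L)))
    if (keep) subsets[[length(subsets) + 1L]] <- run
  }
  structure(subsets, ordered_means = m)
}
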