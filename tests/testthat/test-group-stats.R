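test_that("the Shapiro-Wilk gate routes normal data to ANOVA and skewed data to Kruskal-Wallis", {
  groups <- rep(c("healthy", "patient"), each = 20)
  n_anova <- 0L
  for (s in 1:100) {
    set.seed(s)
    if (normality_gate(rnorm(40), groups) == "anova") n_anova <- n_anova + 1L
  }
  # both groups pass the gate with probability ~ (1 - 0.05)^2 = 0.9025
  expect_gt(n_anova, 80)
  n_kw <- 0L
  for (s in 1:100) {
    set.seed(s)
    if (normality_gate(rlnorm(40, 0, 1), groups) == "kruskal_wallis") {
      n_kw <- n_kw + 1L
    }
  }
  expect_gt(n_kw, 85)
  expect_warning(
    gate <- normality_gate(c(rep(1, 20), rnorm(20)), groups), "constant")
  expect_identical(gate, "kruskal_wallis")
  expect_error(normality_gate(1:4, rep(c("a", "b"), 2)), "n >= 3")
})

test_that("compare_groups matches closed-form ANOVA and Kruskal-Wallis oracles", {
  vals <- c(1, 2, 3, 4, 5, 6)
  grp <- rep(c("healthy", "patient"), each = 3)
  # sums-of-squares oracle: SSB = 13.5, SSW = 4, F = 13.5 / (4/4)
  ssb <- 3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2
  ssw <- sum((vals[1:3] - 2)^2) + sum((vals[4:6] - 5)^2)
  f_oracle <- (ssb / 1) / (ssw / 4)
  set.seed(1)
  res <- compare_groups(vals + rnorm(6, 0, 1e-9), grp) # jitter keeps SW defined
  res_exact <- compare_groups(vals, grp, alpha_norm = 1e-12)
  expect_identical(res_exact$test_used, "anova")
  expect_equal(res_exact$statistic, f_oracle, tolerance = 1e-9)
  expect_equal(res_exact$p_value, pf(f_oracle, 1, 4, lower.tail = FALSE),
               tolerance = 1e-9)
  # rank-formula oracle: H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2
  h_oracle <- 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2)
  res_kw <- compare_groups(vals, grp, alpha_norm = 1) # force the rank branch
  expect_identical(res_kw$test_used, "kruskal_wallis")
  expect_equal(res_kw$statistic, h_oracle, tolerance = 1e-9)
  expect_equal(res_kw$p_value, pchisq(h_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_identical(res_kw$direction,
                   if (res_kw$p_value < 0.05) "patient_higher" else "none")
})

test_that("identical groups give p ~ 1 and no direction", {
  res <- compare_groups(rep(c(1, 2, 3), 2), rep(c("healthy", "patient"), 3))
  expect_gte(res$p_value, 0.99)
  expect_identical(res$direction, "none")
  res2 <- compare_groups(rep(5, 10), rep(c("healthy", "patient"), 5))
  expect_identical(res2$p_value, 1)
  expect_error(compare_groups(1:4, rep("healthy", 4)), "non-empty")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(33)
  for (i in 1:10) {
    v <- rnorm(24)
    g <- rep(c("healthy", "patient"), each = 12)
    res <- compare_groups(v, g, alpha_norm = 1e-12)
    tt <- t.test(v[g == "healthy"], v[g == "patient"], var.equal = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
  }
})

test_that("mixed RM-ANOVA matches a brute-force sums-of-squares oracle", {
  # 2 groups x 3 participants x 2 sensors x 3 methods, balanced
  set.seed(55)
  d <- expand.grid(participant = 1:6, sensor = 1:2, method = 1:3)
  d$group <- ifelse(d$participant <= 3, "healthy", "patient")
  d$value <- round(rnorm(nrow(d), 10, 2), 2)
  norms <- tidyr::pivot_wider(
    tibble::tibble(participant_id = sprintf("S%d", d$participant),
                   group = d$group, sensor = d$sensor,
                   method = c("max_mV", "mvc_mV", "grasp_mV")[d$method],
                   value = d$value),
    names_from = "method", values_from = "value")
  out <- mixed_rm_anova(norms)

  # textbook balanced mixed-design decomposition from cell means
  mm <- function(...) tapply(d$value, list(...), mean)
  grand <- mean(d$value)
  n_g <- 3; b <- 2; cc <- 3
  m_subj <- mm(d$participant); m_grp <- mm(d$group)
  m_B <- mm(d$sensor); m_C <- mm(d$method)
  m_AB <- mm(d$group, d$sensor); m_AC <- mm(d$group, d$method)
  m_BC <- mm(d$sensor, d$method); m_ABC <- mm(d$group, d$sensor, d$method)
  m_SB <- mm(d$participant, d$sensor); m_SC <- mm(d$participant, d$method)
  grp_of <- c(rep("healthy", 3), rep("patient", 3))
  g_vec <- as.vector(m_grp[grp_of]) # drop the 1-D array dim for matrix maths
  ss_A <- b * cc * n_g * sum((m_grp - grand)^2)
  ss_S <- b * cc * sum((m_subj - m_grp[grp_of])^2)
  ss_B <- cc * 2 * n_g * sum((m_B - grand)^2)
  ss_AB <- cc * n_g * sum((m_AB - outer(m_grp, rep(1, b)) -
                             outer(rep(1, 2), m_B) + grand)^2)
  ss_BS <- cc * sum((m_SB - outer(as.vector(m_subj), rep(1, b)) -
                       m_AB[grp_of, ] + g_vec)^2)
  ss_C <- b * 2 * n_g * sum((m_C - grand)^2)
  ss_AC <- b * n_g * sum((m_AC - outer(m_grp, rep(1, cc)) -
                            outer(rep(1, 2), m_C) + grand)^2)
  ss_CS <- b * sum((m_SC - outer(as.vector(m_subj), rep(1, cc)) -
                      m_AC[grp_of, ] + g_vec)^2)
  ss_BC <- 2 * n_g * sum((m_BC - outer(m_B, rep(1, cc)) -
                            outer(rep(1, 2), m_C) + grand)^2)

  gv <- function(eff) out[out$effect == eff, ]
  expect_equal(gv("group")$ss, ss_A, tolerance = 1e-8)
  expect_equal(gv("group")$f, (ss_A / 1) / (ss_S / 4), tolerance = 1e-8)
  expect_equal(gv("sensor")$ss, ss_B, tolerance = 1e-8)
  expect_equal(gv("sensor")$f, (ss_B / 1) / (ss_BS / 4), tolerance = 1e-8)
  expect_equal(gv("group:sensor")$ss, ss_AB, tolerance = 1e-8)
  expect_equal(gv("method")$ss, ss_C, tolerance = 1e-8)
  expect_equal(gv("method")$f, (ss_C / 2) / (ss_CS / 8), tolerance = 1e-8)
  expect_equal(gv("group:method")$ss, ss_AC, tolerance = 1e-8)
  expect_equal(gv("sensor:method")$ss, ss_BC, tolerance = 1e-8)
})

test_that("an all-equal dataset gives zero F everywhere and incomplete cells error", {
  norms <- tidyr::expand_grid(participant_id = sprintf("S%d", 1:6),
                              sensor = 1:2)
  norms$group <- rep(c("healthy", "patient"), each = 6)
  norms$max_mV <- 1; norms$mvc_mV <- 1; norms$grasp_mV <- 1
  out <- suppressWarnings(mixed_rm_anova(norms))
  expect_true(all(out$f == 0))
  expect_true(all(out$p_value == 1))
  expect_error(mixed_rm_anova(norms[-1, ]), "incomplete")
})

test_that("injected maximal-effort deficit produces a group x method interaction", {
  hits <- 0L
  for (s in 1:8) {
    res <- run_reduced_comparisons(400 + s,
                                   effect = group_effect(
                                     mvc_amplitude_scale = 0.6,
                                     affected_sensors = 1:7))
    out <- mixed_rm_anova(res$norms)
    p <- out$p_value[out$effect == "group:method"]
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 6L)
})

test_that("Tukey's-B subsets are contiguous, cover all levels, and respond to separation", {
  means <- c(s1 = 5, s2 = 5, s3 = 5)
  eq <- tukeys_b_subsets(means, ms_error = 1, df_error = 30, n = 10)
  expect_length(eq, 1L)
  expect_identical(eq[[1]], c("s1", "s2", "s3"))
  far <- c(a = 0, b = 0.1, c = 10, d = 10.2)
  subs <- tukeys_b_subsets(far, ms_error = 0.1, df_error = 30, n = 10)
  expect_length(subs, 2L)
  expect_setequal(subs[[1]], c("a", "b"))
  expect_setequal(subs[[2]], c("c", "d"))
  # contiguity in the mean ordering + monotone subset count in MS_error
  set.seed(44)
  m <- sort(rnorm(6))
  names(m) <- letters[1:6]
  last_n <- Inf
  for (mse in c(0.01, 0.1, 1, 10)) {
    subs <- tukeys_b_subsets(m, mse, df_error = 20, n = 8)
    for (sub in subs) {
      idx <- match(sub, names(sort(m)))
      expect_identical(idx, seq(min(idx), max(idx)))
    }
    expect_setequal(unlist(subs), names(m))
    expect_lte(length(subs), last_n)
    last_n <- length(subs)
  }
  expect_error(tukeys_b_subsets(m, 1, df_error = 0, n = 5), "df_error")
})

test_that("sign matrices flag significant per-task cells with the patient direction", {
  rows <- tibble::tibble(
    sensor = rep(1:2, each = 4), task_id = rep(1:2, 4),
    parameter = rep(rep(c("median", "range"), each = 2), 2),
    test_used = "anova", statistic = 1,
    p_value = c(0.5, 0.5, 0.5, 0.5, 0.01, 0.5, 0.5, 0.03),
    direction = c("none", "none", "none", "none",
                  "patient_higher", "none", "none", "patient_lower"))
  m <- build_sign_table(rows)
  expect_identical(sum(m == "+"), 1L)
  expect_identical(sum(m == "-"), 1L)
  expect_identical(m["2 median", "task1"], "+")
  expect_identical(m["2 range", "task2"], "-")
  none <- rows
  none$direction <- "none"
  expect_true(all(build_sign_table(none) == ""))
})

test_that("per-task comparisons run the gate per cell and feed the sign matrix", {
  res <- run_reduced_comparisons(61, n_healthy = 5, n_patients = 5,
                                 n_sensors = 2, n_shft = 3)
  pt <- per_task_comparisons(res$wave, c("nzc_rescaled", "ewl_rescaled"))
  expect_identical(nrow(pt), 2L * 3L * 2L)
  expect_true(all(pt$test_used %in% c("anova", "kruskal_wallis")))
  m <- build_sign_table(pt)
  expect_identical(dim(m), c(4L, 3L))
})
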