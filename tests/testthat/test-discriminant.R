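test_that("Box's M is zero with identical covariances and matches the log-determinant formula", {
  set.seed(10)
  base <- matrix(rnorm(20), 10, 2)
  x <- rbind(base, base)
  g <- rep(c("healthy", "patient"), each = 10)
  res <- boxs_m_test(x, g)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$p_value, 1, tolerance = 1e-10)

  # hand dataset (<= 10 rows) against the direct formula
  xh <- matrix(c(1, 2, 3, 4, 5, 2, 1, 4, 3, 7,
                 1, 1, 2, 5, 3, 6, 4, 9, 2, 8), ncol = 2)
  gh <- rep(c("healthy", "patient"), each = 5)
  res <- boxs_m_test(xh, gh)
  S1 <- cov(xh[1:5, ]); S2 <- cov(xh[6:10, ])
  Sp <- (4 * S1 + 4 * S2) / 8
  M <- 8 * log(det(Sp)) - 4 * log(det(S1)) - 4 * log(det(S2))
  c1 <- (1 / 4 + 1 / 4 - 1 / 8) * (2 * 4 + 3 * 2 - 1) / (6 * 3 * 1)
  expect_equal(res$statistic, M, tolerance = 1e-10)
  expect_equal(res$chi_sq, M * (1 - c1), tolerance = 1e-10)
  expect_equal(res$df, 3)
  expect_equal(res$p_value, pchisq(M * (1 - c1), 3, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(boxs_m_test(xh[1:4, ], gh[c(1, 2, 6, 7)]), "n > number")
})

test_that("inflating one group's variance makes Box's M reject", {
  set.seed(20)
  x <- rbind(matrix(rnorm(200), 100, 2),
             matrix(rnorm(200, sd = sqrt(10)), 100, 2))
  g <- rep(c("healthy", "patient"), each = 100)
  expect_lt(boxs_m_test(x, g)$p_value, 0.05)
})

test_that("a perfectly separating candidate yields a single-variable model with 100% training accuracy", {
  d <- tibble::tibble(group = rep(c("healthy", "patient"), each = 6),
                      sep = c(rnorm(6, 10, 0.1), rnorm(6, 0, 0.1)),
                      other = rnorm(12))
  m <- stepwise_lda(d, c("sep", "other"))
  expect_identical(m$selected, "sep")
  pred <- predict(m, d)
  expect_identical(pred$class, as.character(d$group))
  # patient scores negative under the sign convention
  expect_true(all(pred$score[d$group == "patient"] < 0))
})

test_that("pure-noise candidates are excluded in the vast majority of runs", {
  excluded <- 0L
  for (s in 1:60) {
    set.seed(s)
    d <- tibble::tibble(group = rep(c("healthy", "patient"), each = 15),
                        signal = c(rnorm(15, 2), rnorm(15, 0)),
                        noise = rnorm(30))
    m <- stepwise_lda(d, c("signal", "noise"))
    if (!"noise" %in% m$selected) excluded <- excluded + 1L
  }
  expect_gte(excluded, 54L) # ~ 1 - p_enter of seeds
})

test_that("duplicated candidates trip the collinearity guard: exactly one enters", {
  set.seed(77)
  d <- tibble::tibble(group = rep(c("healthy", "patient"), each = 10),
                      v1 = c(rnorm(10, 3), rnorm(10, 0)))
  d$v2 <- d$v1
  m <- stepwise_lda(d, c("v1", "v2"))
  expect_identical(m$selected, "v1")
})

test_that("no candidate meeting the entry criterion returns a no-model result, not an error", {
  set.seed(88)
  d <- tibble::tibble(group = rep(c("healthy", "patient"), each = 10),
                      flat = rnorm(20))
  m <- stepwise_lda(d, "flat", p_enter = 1e-6)
  expect_true(m$no_model)
  expect_identical(m$selected, character(0))
  expect_error(predict(m, d), "empty model")
})

test_that("Wilks' lambda is non-increasing over stepwise entry steps", {
  set.seed(91)
  for (rep in 1:5) {
    n <- 40
    d <- tibble::tibble(group = rep(c("healthy", "patient"), each = n / 2))
    for (j in 1:6) {
      d[[paste0("v", j)]] <- rnorm(n) + (j <= 3) * 0.8 * (d$group == "patient")
    }
    m <- stepwise_lda(d, paste0("v", 1:6))
    if (length(m$lambda_trace) > 1L) {
      expect_true(all(diff(m$lambda_trace) <= 1e-12))
    }
    expect_false(isTRUE(m$no_model))
  }
})

test_that("fit_lda classifications agree with an independent LDA implementation", {
  set.seed(14)
  d <- tibble::tibble(group = rep(c("healthy", "patient"), each = 20),
                      a = rnorm(40) + 1.2 * rep(c(0, 1), each = 20),
                      b = rnorm(40) - 0.8 * rep(c(0, 1), each = 20))
  m <- fit_lda(d, c("a", "b"))
  ours <- predict(m, d)$class
  ref <- MASS::lda(group ~ a + b, data = d, prior = c(0.5, 0.5))
  theirs <- as.character(predict(ref, d)$class)
  expect_identical(ours, theirs)
})

test_that("LOOCV per-fold predictions match an exhaustive hand computation on 6 points", {
  # one variable: each fold classifies the held-out value by the midpoint of
  # the remaining group means (equal priors), patient side below
  d <- tibble::tibble(group = rep(c("healthy", "patient"), each = 3),
                      v = c(5, 6, 7, 1, 2, 12))
  hand <- character(6)
  for (i in 1:6) {
    tr <- d[-i, ]
    mu_h <- mean(tr$v[tr$group == "healthy"])
    mu_p <- mean(tr$v[tr$group == "patient"])
    cut <- (mu_h + mu_p) / 2
    hand[i] <- if (mu_h > mu_p) {
      if (d$v[i] < cut) "patient" else "healthy"
    } else {
      if (d$v[i] > cut) "patient" else "healthy"
    }
  }
  rep <- loocv(d, "v")
  expect_identical(rep$folds$predicted, hand)
  acc <- 100 * mean(hand == d$group)
  expect_equal(rep$accuracy, acc)
  expect_equal(rep$sensitivity, 100 * mean(hand[4:6] == "patient"))
  expect_equal(rep$specificity, 100 * mean(hand[1:3] == "healthy"))
})

test_that("LOOCV separates cleanly on wide margins and is chance-level under permuted labels", {
  d <- tibble::tibble(group = rep(c("healthy", "patient"), each = 10),
                      v = c(rnorm(10, 10, 0.2), rnorm(10, 0, 0.2)))
  expect_equal(loocv(d, "v")$accuracy, 100)
  # label-independent noise: chance-level accuracy over many seeds
  accs <- numeric(60)
  for (s in 1:60) {
    set.seed(s)
    dn <- tibble::tibble(group = d$group, v = rnorm(20))
    accs[s] <- loocv(dn, "v")$accuracy
  }
  expect_lt(abs(mean(accs) - 50), 8)
  # permuting labels of separable data cannot beat chance (leave-one-out
  # refitting biases it below 50%)
  perm <- numeric(30)
  for (s in 1:30) {
    set.seed(s)
    dp <- d
    dp$group <- sample(dp$group)
    perm[s] <- loocv(dp, "v")$accuracy
  }
  expect_lte(mean(perm), 55)
  # accuracy is the group-size-weighted mean of sensitivity and specificity
  r <- loocv(d, "v")
  expect_equal(r$accuracy, (10 * r$sensitivity + 10 * r$specificity) / 20)
})

test_that("LOOCV accuracy approaches the Bayes rate of a known generating model", {
  # 1-D two-Gaussian model, means +/-1, unit sd: Bayes rate = pnorm(1) ~ 84.1%
  set.seed(123)
  n <- 200
  d <- tibble::tibble(group = rep(c("healthy", "patient"), each = n / 2),
                      v = c(rnorm(n / 2, 1), rnorm(n / 2, -1)))
  acc <- loocv(d, "v")$accuracy
  expect_lt(abs(acc - 100 * pnorm(1)), 5)
})

test_that("published classifiers evaluate to their printed constants and coefficients", {
  zeros <- tibble::tibble(R_MAX2 = 0, M_MAX4 = 0, M_MVC4 = 0, R_MVC4 = 0,
                          R_MVC7 = 0, M_GRASP3 = 0, R_GRASP5 = 0,
                          R_GRASP6 = 0, R_GRASP7 = 0, EWL1 = 0, NZC4 = 0)
  wf <- evaluate_published_classifier("F_Waveform", zeros)
  expect_identical(wf$score, -1.481)
  expect_identical(wf$class, "patient")
  mx <- evaluate_published_classifier("F_MAX", zeros)
  expect_identical(mx$score, -0.586)
  expect_identical(mx$class, "patient")
  # exact affine map: unit-input differences recover each coefficient
  for (nm in published_classifiers()) {
    cl <- get_published_classifier(nm)
    base <- evaluate_published_classifier(nm, zeros)$score
    for (v in cl$variables) {
      unit <- zeros
      unit[[v]] <- 1
      expect_equal(evaluate_published_classifier(nm, unit)$score - base,
                   unname(cl$coefficients[v]), tolerance = 1e-12)
    }
  }
  expect_error(evaluate_published_classifier("F_MAX", zeros["M_MAX4"]),
               "R_MAX2")
  expect_error(get_published_classifier("F_BOGUS"), "unknown")
  expect_true(get_published_classifier("F_NoMVC")$incomplete)
})

test_that("a score of exactly zero classifies as healthy (strict < 0 rule)", {
  m <- structure(list(no_model = FALSE, selected = "v",
                      coefficients = c(v = 1), constant = 0,
                      sign_convention = "negative => patient"),
                 class = "discriminant_model")
  out <- predict(m, tibble::tibble(v = c(0, -1e-12, 1e-12)))
  expect_identical(out$score[1], 0)
  expect_identical(out$class, c("healthy", "patient", "healthy"))
})

test_that("negating scores and the convention yields identical classifications", {
  set.seed(17)
  d <- tibble::tibble(group = rep(c("healthy", "patient"), each = 12),
                      a = rnorm(24) + rep(c(1, 0), each = 12))
  m <- fit_lda(d, "a")
  sc <- predict(m, d)$score
  flipped <- ifelse(-sc > 0, "patient", "healthy") # flipped rule on -score
  expect_identical(predict(m, d)$class, flipped)
})
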