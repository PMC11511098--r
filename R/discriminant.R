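# Two-group linear discriminant analysis: Box's M homogeneity test, stepwise
# variable selection by Wilks' lambda, raw-score Fisher discriminant with the
# clinical sign convention (negative score => patient), leave-one-out
# cross-validation, and the frozen published classifiers.

#' Box's M test for equality of group covariance matrices
#'
#' Computes Box's M from the group and pooled covariance log-determinants with
#' the standard chi-square approximation. A precondition of linear
#' discriminant analysis; in the pipeline the analysis proceeds with a warning
#' when the test rejects.
#'
#' @param x Numeric matrix or data frame of predictor columns.
#' @param groups Two-level grouping vector.
#' @return List with `statistic` (M), `chi_sq`, `df`, and `p_value`.
#' @export
boxs_m_test <- function(x, groups) {
  x <- as.matrix(x)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups")
  p <- ncol(x)
  ns <- table(g)
  if (any(ns <= p)) {
    stop("each group needs n > number of variables (", p, ") for Box's M")
  }
  N <- nrow(x)
  k <- nlevels(g)
  covs <- lapply(levels(g), function(l) stats::cov(x[g == l, , drop = FALSE]))
  Sp <- Reduce(`+`, Map(function(S, n) (n - 1) * S, covs, as.list(ns))) / (N - k)
  logdet <- function(S) {
    d <- determinant(S, logarithm = TRUE)
    if (d$sign <= 0) {
      stop("singular group covariance matrix; reduce the variable set")
    }
    as.numeric(d$modulus)
  }
  M <- (N - k) * logdet(Sp) - sum((ns - 1) * vapply(covs, logdet, numeric(1L)))
  c1 <- (sum(1 / (ns - 1)) - 1 / (N - k)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1))
  chi <- M * (1 - c1)
  df <- p * (p + 1) * (k - 1) / 2
  list(statistic = M, chi_sq = chi, df = df,
       p_value = stats::pchisq(chi, df, lower.tail = FALSE))
}

# Wilks' lambda det(W)/det(T) for a variable subset (two or more groups)
.wilks_lambda <- function(x, g) {
  x <- as.matrix(x)
  n <- nrow(x)
  Tm <- crossprod(scale(x, scale = FALSE))
  W <- matrix(0, ncol(x), ncol(x))
  for (l in levels(g)) {
    xi <- x[g == l, , drop = FALSE]
    W <- W + crossprod(scale(xi, scale = FALSE))
  }
  dT <- det(Tm)
  if (dT <= 0) return(NA_real_)
  det(W) / dT
}

# partial F for the change lambda_small -> lambda_big-model (one added var)
.partial_f <- function(lambda_p, lambda_p1, n, g, p) {
  # p = number of variables already in the model before the addition
  df2 <- n - g - p
  f <- (lambda_p / lambda_p1 - 1) * df2 / (g - 1)
  pval <- stats::pf(f, g - 1, df2, lower.tail = FALSE)
  c(f = f, p = pval, df2 = df2)
}

#' Stepwise linear discriminant analysis selected by Wilks' lambda
#'
#' Forward selection with backward removal: at each step the candidate that
#' minimizes the model's Wilks' lambda enters if the partial F-test p-value is
#' below `p_enter`; after each entry, any included variable whose
#' F-to-remove p-value exceeds `p_remove` leaves. Ties are broken by smaller
#' p-value, then lower sensor index, then amplitude before waveform (the order
#' of `candidates`). A variable removed at one step cannot re-enter at the
#' next, and steps are capped at twice the candidate count, so the procedure
#' terminates. Near-collinear candidates (within-group tolerance below
#' `tol`) are skipped.
#'
#' @param data Tibble/data frame with a `group` column (`healthy`/`patient`)
#'   and numeric candidate columns.
#' @param candidates Character vector of candidate variable names, in
#'   tie-break order.
#' @param p_enter Entry threshold on the partial F p-value.
#' @param p_remove Removal threshold.
#' @param tol Within-group tolerance (1 - R^2 against included variables)
#'   below which a candidate is skipped.
#' @return A `discriminant_model` (see [fit_lda()]), or a `discriminant_model`
#'   with `no_model = TRUE` when no candidate meets the entry criterion. The
#'   model records `selected`, per-step `lambda_trace`, and the final Wilks'
#'   lambda.
#' @export
stepwise_lda <- function(data, candidates, p_enter = 0.05, p_remove = 0.10,
                         tol = 1e-4) {
  g <- factor(data$group, levels = c("healthy", "patient"))
  if (any(is.na(g))) stop("group must be 'healthy'/'patient'")
  n <- nrow(data)
  ng <- nlevels(g)
  candidates <- candidates[candidates %in% names(data)]
  selected <- character(0)
  lambda_cur <- 1
  lambda_trace <- numeric(0)
  just_removed <- character(0)
  steps <- 0L
  max_steps <- 2L * length(candidates)

  within_tol <- function(v, sel) {
    if (length(sel) == 0L) return(1)
    # tolerance from within-group (group-centered) regression
    xc <- as.matrix(data[, c(v, sel)])
    for (l in levels(g)) {
      idx <- g == l
      xc[idx, ] <- scale(xc[idx, , drop = FALSE], scale = FALSE)
    }
    fit <- stats::lm.fit(cbind(1, xc[, -1L, drop = FALSE]), xc[, 1L])
    ssr <- sum(fit$residuals^2)
    sst <- sum(xc[, 1L]^2)
    if (sst == 0) 0 else ssr / sst
  }

  repeat {
    steps <- steps + 1L
    if (steps > max_steps) break
    pool <- setdiff(candidates, c(selected, just_removed))
    best <- NULL
    for (v in pool) {
      if (within_tol(v, selected) < tol) next
      lam <- .wilks_lambda(data[, c(selected, v)], g)
      if (is.na(lam)) next
      pf <- .partial_f(lambda_cur, lam, n, ng, length(selected))
      cand <- list(v = v, lambda = lam, p = pf[["p"]], f = pf[["f"]])
      if (is.null(best) || cand$p < best$p ||
          (cand$p == best$p && match(v, candidates) < match(best$v, candidates))) {
        best <- cand
      }
    }
    entered <- FALSE
    if (!is.null(best) && !is.na(best$p) && best$p < p_enter) {
      selected <- c(selected, best$v)
      lambda_cur <- best$lambda
      lambda_trace <- c(lambda_trace, lambda_cur)
      entered <- TRUE
    }
    just_removed <- character(0)
    # removal pass
    if (length(selected) > 1L) {
      repeat {
        worst <- NULL
        for (v in selected) {
          lam_wo <- .wilks_lambda(data[, setdiff(selected, v), drop = FALSE], g)
          pf <- .partial_f(lam_wo, lambda_cur, n, ng, length(selected) - 1L)
          if (is.null(worst) || pf[["p"]] > worst$p) {
            worst <- list(v = v, p = pf[["p"]], lam_wo = lam_wo)
          }
        }
        if (!is.null(worst) && worst$p > p_remove) {
          selected <- setdiff(selected, worst$v)
          lambda_cur <- if (length(selected) > 0L) {
            .wilks_lambda(data[, selected, drop = FALSE], g)
          } else 1
          just_removed <- c(just_removed, worst$v)
        } else break
        if (length(selected) <= 1L) break
      }
    }
    if (!entered) break
  }

  if (length(selected) == 0L) {
    return(structure(list(no_model = TRUE, selected = character(0),
                          lambda = NA_real_, lambda_trace = numeric(0),
                          reason = "no candidate met the entry criterion"),
                     class = "discriminant_model"))
  }
  model <- fit_lda(data, selected)
  model$lambda <- lambda_cur
  model$lambda_trace <- lambda_trace
  model
}

#' Fit a two-group raw-score linear discriminant
#'
#' Fisher's linear discriminant on a fixed variable set: coefficients
#' `solve(S_pooled) %*% (mu_healthy - mu_patient)` with the constant set at
#' the midpoint of the group score means (equal priors), then oriented so the
#' patient-group mean score is negative. A score below zero classifies as
#' patient; zero or above classifies as healthy.
#'
#' @param data Tibble with `group` and the model variables.
#' @param variables Character vector of predictor names.
#' @return A `discriminant_model` list: `selected`, `coefficients`,
#'   `constant`, `sign_convention`, `no_model = FALSE`.
#' @export
fit_lda <- function(data, variables) {
  g <- factor(data$group, levels = c("healthy", "patient"))
  x <- as.matrix(data[, variables, drop = FALSE])
  n1 <- sum(g == "healthy")
  n2 <- sum(g == "patient")
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  mu1 <- colMeans(x[g == "healthy", , drop = FALSE])
  mu2 <- colMeans(x[g == "patient", , drop = FALSE])
  S1 <- stats::cov(x[g == "healthy", , drop = FALSE])
  S2 <- stats::cov(x[g == "patient", , drop = FALSE])
  Sp <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
  w <- tryCatch(solve(Sp, mu1 - mu2), error = function(e) {
    stop("singular pooled covariance for variables: ",
         paste(variables, collapse = ", "))
  })
  const <- -sum(w * (mu1 + mu2)) / 2
  # orient: patient mean score negative
  if (sum(w * mu2) + const > 0) {
    w <- -w
    const <- -const
  }
  structure(list(no_model = FALSE, selected = variables,
                 coefficients = stats::setNames(as.numeric(w), variables),
                 constant = const, sign_convention = "negative => patient",
                 lambda = NA_real_, lambda_trace = numeric(0)),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  if (isTRUE(x$no_model)) {
    cat("<discriminant_model> no model (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("<discriminant_model> score = ",
      paste(sprintf("%+.3f*%s", x$coefficients, x$selected), collapse = " "),
      sprintf(" %+.3f", x$constant), "\n  ", x$sign_convention,
      if (!is.na(x$lambda)) sprintf("; Wilks lambda = %.4f", x$lambda),
      "\n", sep = "")
  invisible(x)
}

#' Score and classify with a discriminant model
#'
#' @param object A `discriminant_model`.
#' @param newdata Tibble/data frame containing the model variables.
#' @param ... Unused.
#' @return Tibble with `score` and `class` (`"patient"` when score < 0,
#'   `"healthy"` otherwise — a score of exactly zero is healthy).
#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  if (isTRUE(object$no_model)) stop("cannot predict from an empty model")
  miss <- setdiff(object$selected, names(newdata))
  if (length(miss) > 0L) {
    stop("missing model variables: ", paste(miss, collapse = ", "))
  }
  x <- as.matrix(newdata[, object$selected, drop = FALSE])
  score <- as.numeric(x %*% object$coefficients) + object$constant
  tibble::tibble(score = score,
                 class = ifelse(score < 0, "patient", "healthy"))
}

#' Leave-one-out cross-validation of a discriminant variable set
#'
#' Holds out each participant in turn, refits the discriminant coefficients on
#' the remaining n - 1 (the variable set stays fixed — selection is not
#' repeated per fold), and classifies the held-out case. `strict = TRUE`
#' re-runs the stepwise selection inside every fold instead, as a sensitivity
#' analysis.
#'
#' @param data Tibble with `group` and the variables.
#' @param variables Selected variable names (ignored when `strict = TRUE`).
#' @param strict Re-run selection per fold.
#' @param candidates,p_enter,p_remove Passed to [stepwise_lda()] when
#'   `strict = TRUE`.
#' @return A `cv_report` list: `accuracy`, `sensitivity`, `specificity` (all
#'   percent), and `folds` (per-participant predictions).
#' @export
loocv <- function(data, variables, strict = FALSE, candidates = variables,
                  p_enter = 0.05, p_remove = 0.10) {
  g <- factor(data$group, levels = c("healthy", "patient"))
  n <- nrow(data)
  pred <- character(n)
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    if (length(unique(train$group)) < 2L) {
      stop("a leave-one-out fold has an empty group")
    }
    m <- if (strict) {
      stepwise_lda(train, candidates, p_enter, p_remove)
    } else {
      fit_lda(train, variables)
    }
    pred[i] <- if (isTRUE(m$no_model)) {
      NA_character_
    } else {
      predict(m, data[i, , drop = FALSE])$class
    }
  }
  truth <- as.character(g)
  ok <- pred == truth
  sens <- 100 * mean(ok[truth == "patient"], na.rm = FALSE)
  spec <- 100 * mean(ok[truth == "healthy"], na.rm = FALSE)
  acc <- 100 * mean(ok)
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 folds = tibble::tibble(participant = seq_len(n),
                                        truth = truth, predicted = pred)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(paste0("<cv_report> accuracy %.1f%% (sensitivity %.1f%%, ",
                     "specificity %.1f%%), %d folds\n"),
              x$accuracy, x$sensitivity, x$specificity, nrow(x$folds)))
  invisible(x)
}
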