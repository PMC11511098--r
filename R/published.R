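# Frozen published discriminant classifiers for hand-osteoarthritis
# screening. Coefficients and constants are fixed constants of the published
# formulas and are never refit. Variables follow the field naming convention:
# M_/R_ = task-averaged median/range of the normalized envelope under the
# MAX/MVC/GRASP method, EWL/NZC = task-averaged rescaled waveform parameters;
# the trailing digit is the sensor index (1..7). A negative score classifies
# the individual as a patient; zero or positive as healthy.

.published <- list(
  F_MAX = list(
    coefficients = c(R_MAX2 = 8.901, M_MAX4 = -20.053),
    constant = -0.586, incomplete = FALSE),
  F_MVC = list(
    coefficients = c(M_MVC4 = -11.308, R_MVC4 = 4.729, R_MVC7 = 2.971),
    constant = -2.931, incomplete = FALSE),
  F_GRASP = list(
    coefficients = c(M_GRASP3 = 7.755, R_GRASP5 = 3.302, R_GRASP6 = -3.184,
                     R_GRASP7 = 4.160),
    constant = -3.27, incomplete = FALSE),
  F_Waveform = list(
    coefficients = c(EWL1 = -8.738, NZC4 = 9.624),
    constant = -1.481, incomplete = FALSE),
  # printed with an ellipsis between the amplitude and waveform terms; only
  # the printed terms are frozen here, so scores other than at the printed
  # variables should be read with that caveat
  F_NoMVC = list(
    coefficients = c(R_MAX2 = -4.407, M_MAX4 = 14.673, EWL1 = 7.508,
                     NZC4 = -8.740),
    constant = 1.109, incomplete = TRUE))

#' Names of the built-in published classifiers
#' @return Character vector.
#' @export
published_classifiers <- function() names(.published)

#' Retrieve a frozen published classifier
#'
#' @param name One of [published_classifiers()]: `"F_MAX"`, `"F_MVC"`,
#'   `"F_GRASP"`, `"F_Waveform"`, `"F_NoMVC"`.
#' @return A `published_classifier` list with `name`, `coefficients`,
#'   `constant`, `variables`, `incomplete` (TRUE for `F_NoMVC`, whose printed
#'   form elides some terms), and the sign convention.
#' @export
get_published_classifier <- function(name) {
  if (!name %in% names(.published)) {
    stop("unknown classifier '", name, "'; available: ",
         paste(names(.published), collapse = ", "))
  }
  def <- .published[[name]]
  structure(list(name = name, coefficients = def$coefficients,
                 constant = def$constant,
                 variables = names(def$coefficients),
                 incomplete = def$incomplete,
                 sign_convention = "negative => patient"),
            class = "published_classifier")
}

#' @export
print.published_classifier <- function(x, ...) {
  cat("<published_classifier> ", x$name, ": score = ",
      paste(sprintf("%+g*%s", x$coefficients, x$variables), collapse = " "),
      sprintf(" %+g", x$constant), "\n  ", x$sign_convention,
      if (x$incomplete) "\n  note: published form elides some terms", "\n",
      sep = "")
  invisible(x)
}

#' Evaluate a published classifier on task-averaged parameters
#'
#' Computes the frozen linear score and the class call (`"patient"` when the
#' score is negative, `"healthy"` at zero or above). Inputs are the
#' task-averaged functional-task parameters under the classifier's
#' normalization, as produced by [participant_summary()].
#'
#' @param name Classifier name (see [published_classifiers()]).
#' @param inputs Named list/vector or single-row data frame holding every
#'   required variable.
#' @return Tibble with `score` and `class` (one row per input row).
#' @export
evaluate_published_classifier <- function(name, inputs) {
  cl <- get_published_classifier(name)
  if (is.data.frame(inputs)) {
    vals <- inputs
  } else {
    vals <- as.data.frame(as.list(unlist(inputs)))
  }
  miss <- setdiff(cl$variables, names(vals))
  if (length(miss) > 0L) {
    stop("classifier ", name, " requires missing input(s): ",
         paste(miss, collapse = ", "))
  }
  x <- as.matrix(vals[, cl$variables, drop = FALSE])
  score <- as.numeric(x %*% cl$coefficients) + cl$constant
  tibble::tibble(score = score,
                 class = ifelse(score < 0, "patient", "healthy"))
}
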