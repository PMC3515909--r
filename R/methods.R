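#' Specification of one classification method
#'
#' The seven methods compared by the pipeline are random forest (`RF`),
#' logistic regression (`LR`), support vector machines with radial
#' (`R-SVM`), linear (`L-SVM`), polynomial (`P-SVM`) and sigmoid
#' (`S-SVM`) kernels, and a single hidden-layer neural network (`NNET`).
#'
#' @param name One of `"RF"`, `"LR"`, `"R-SVM"`, `"L-SVM"`, `"P-SVM"`,
#'   `"S-SVM"`, `"NNET"`.
#' @param grid Hyperparameter grid: a tibble with one row per candidate
#'   setting (see [default_grid()] for the legal columns per method).
#' @return An object of class `method_spec`.
#' @export
method_spec <- function(name, grid = default_grid(name)) {
  if (!name %in% METHOD_NAMES) {
    abort_config(sprintf(
      "unknown method '%s'; must be one of %s",
      name, paste(METHOD_NAMES, collapse = ", ")
    ))
  }
  grid <- as_tibble(grid)
  if (nrow(grid) == 0) abort_config("hyperparameter grid must be nonempty")
  structure(list(name = name, grid = grid), class = "method_spec")
}

#' Default hyperparameter grid for a method
#'
#' Grid axes: `RF` searches the number of trees \{2000, 3000, 4000, 5000\}
#' and an `mtry` rule among \{1, 0.5*sqrt(p), sqrt(p), 2*sqrt(p), p\}
#' (resolved against the current feature count p, clipped to `[1, p]`);
#' the SVMs search cost C in \{0.01, 0.1, 1, 10\} and (for nonlinear
#' kernels) gamma in \{0.001, 0.01, 0.1, 1\}, with polynomial degree
#' \{2, 3, 4\} for `P-SVM`; `NNET` searches hidden units \{1, 3, 5\} and
#' weight decay \{0, 0.01, 0.1\}; `LR` has no tunable axis and is fitted
#' by maximum likelihood.
#'
#' @param name Method name, as in [method_spec()].
#' @param reduced If `TRUE`, return a small desk-scale grid per method:
#'   RF 500 trees with sqrt-p mtry, SVM cost \{1, 10\} by gamma
#'   \{0.1, 1\} (degree 2 for `P-SVM`), NNET 3 hidden units with
#'   decay 0.01.
#' @return A tibble of hyperparameter combinations.
#' @export
default_grid <- function(name, reduced = FALSE) {
  if (reduced) {
    return(switch(name,
      "RF" = tibble(ntree = 500, mtry_rule = "sqrt"),
      "LR" = tibble(.rows = 1),
      "L-SVM" = tibble(cost = c(1, 10)),
      "R-SVM" = ,
      "S-SVM" = tidyr::expand_grid(cost = c(1, 10), gamma = c(0.1, 1)),
      "P-SVM" = tidyr::expand_grid(
        cost = c(1, 10), gamma = c(0.1, 1), degree = 2
      ),
      "NNET" = tibble(size = 3, decay = 0.01)
    ))
  }
  switch(name,
    "RF" = tidyr::expand_grid(
      ntree = c(2000, 3000, 4000, 5000),
      mtry_rule = c("one", "half_sqrt", "sqrt", "twice_sqrt", "all")
    ),
    "LR" = tibble(.rows = 1),
    "L-SVM" = tibble(cost = c(0.01, 0.1, 1, 10)),
    "R-SVM" = ,
    "S-SVM" = tidyr::expand_grid(
      cost = c(0.01, 0.1, 1, 10),
      gamma = c(0.001, 0.01, 0.1, 1)
    ),
    "P-SVM" = tidyr::expand_grid(
      cost = c(0.01, 0.1, 1, 10),
      gamma = c(0.001, 0.01, 0.1, 1),
      degree = c(2, 3, 4)
    ),
    "NNET" = tidyr::expand_grid(size = c(1, 3, 5), decay = c(0, 0.01, 0.1))
  )
}

#' The full committee of seven method specifications
#'
#' @param reduced Passed to [default_grid()]; `TRUE` gives one grid point
#'   per method for fast experiments.
#' @return Named list of seven [method_spec()] objects.
#' @export
method_set <- function(reduced = FALSE) {
  specs <- lapply(METHOD_NAMES, function(nm) {
    method_spec(nm, default_grid(nm, reduced = reduced))
  })
  names(specs) <- METHOD_NAMES
  specs
}

# Resolve an RF mtry rule against the current number of features p.
resolve_mtry <- function(rule, p) {
  v <- switch(rule,
    one = 1,
    half_sqrt = 0.5 * sqrt(p),
    sqrt = sqrt(p),
    twice_sqrt = 2 * sqrt(p),
    all = p,
    abort_config(sprintf("unknown mtry rule '%s'", rule))
  )
  max(1L, min(p, as.integer(round(v))))
}

svm_kernel <- c(
  "R-SVM" = "radial", "L-SVM" = "linear",
  "P-SVM" = "polynomial", "S-SVM" = "sigmoid"
)

# Fit one classifier. x: samples x features matrix (standardized values),
# y: integer 0/1 labels, hp: one-row tibble of hyperparameters.
# Returns an internal classifier object usable by predict_classifier().
fit_classifier <- function(name, x, y, hp, seed) {
  yf <- factor(y, levels = c(0L, 1L))
  fit <- withr::with_seed(as.integer(seed), switch(name,
    "RF" = ranger::ranger(
      x = x, y = yf,
      num.trees = hp$ntree, mtry = resolve_mtry(hp$mtry_rule, ncol(x)),
      seed = as.integer(seed), num.threads = 1
    ),
    "LR" = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      # separation on wide expression data is handled by the iteration cap
      suppressWarnings(
        glm(.y ~ ., family = binomial(), data = df,
            control = list(maxit = 25))
      )
    },
    "L-SVM" = e1071::svm(
      x, yf, kernel = "linear", cost = hp$cost, scale = FALSE
    ),
    "R-SVM" = ,
    "S-SVM" = e1071::svm(
      x, yf, kernel = svm_kernel[[name]],
      cost = hp$cost, gamma = hp$gamma, scale = FALSE
    ),
    # inhomogeneous polynomial kernel (coef0 = 1): a homogeneous even-degree
    # kernel is sign-blind and cannot represent a linear class shift
    "P-SVM" = e1071::svm(
      x, yf, kernel = "polynomial", cost = hp$cost, gamma = hp$gamma,
      degree = hp$degree, coef0 = 1, scale = FALSE
    ),
    "NNET" = suppressWarnings(nnet::nnet(
      x, y,
      size = hp$size, decay = hp$decay,
      entropy = TRUE, maxit = 300, trace = FALSE
    ))
  ))
  structure(list(name = name, fit = fit), class = "crossvote_classifier")
}

# Predict integer 0/1 labels for new samples (samples x features matrix,
# same feature order as training). Probabilistic methods threshold at 0.5.
predict_classifier <- function(clf, xnew) {
  out <- switch(clf$name,
    "RF" = as.integer(as.character(
      predict(clf$fit, data = xnew, num.threads = 1)$predictions
    )),
    "LR" = {
      # explicit, sequential scoring; aliased coefficients count as zero
      beta <- stats::coef(clf$fit)
      beta[is.na(beta)] <- 0
      bx <- beta[match(colnames(xnew), names(beta))]
      bx[is.na(bx)] <- 0
      eta <- beta[["(Intercept)"]] + colSums(t(xnew) * bx)
      as.integer(eta > 0)
    },
    "NNET" = as.integer(predict(clf$fit, xnew) > 0.5),
    # the SVMs decide at the sign of the decision function
    as.integer(as.character(predict(clf$fit, xnew)))
  )
  names(out) <- rownames(xnew)
  out
}
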