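# Maximum-a-posteriori naive-Bayes classifier over mixed
# categorical/continuous predictors. Class priors are training-set relative
# frequencies; categorical conditionals are within-class category
# frequencies (multinomial); continuous conditionals are within-class
# Gaussians. Predictors are assumed conditionally independent given the
# class; posteriors are computed in the log domain.

#' Fit a MAP naive-Bayes classifier
#'
#' @param x data.frame of predictors: factor/character columns are treated
#'   as categorical (multinomial conditionals), numeric columns as
#'   continuous (Gaussian conditionals).
#' @param y class labels (factor; its level set defines the classes and the
#'   deterministic tie-break order).
#' @param prob_floor probability assigned to zero-frequency or unseen
#'   categories at prediction time (avoids -Inf log posteriors without
#'   materially changing MAP decisions).
#' @param var_floor lower bound on the Gaussian conditional sd, in predictor
#'   units.
#' @return object of class `nb_map` with elements `classes`, `priors`,
#'   `conditionals` (per predictor: either a levels-by-class probability
#'   table or per-class mean/sd), `prob_floor`, `n`.
#' @examples
#' x <- data.frame(touch = factor(c(1, 1, 0, 0, 1, 0)))
#' y <- factor(c("a", "a", "b", "b", "a", "b"))
#' fit <- nb_map(x, y)
#' predict(fit, x)
#' @export
nb_map <- function(x, y, prob_floor = 1e-9, var_floor = 1e-6) {
  stopifnot(is.data.frame(x), nrow(x) >= 1, ncol(x) >= 1)
  y <- if (is.factor(y)) y else factor(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (anyNA(y)) stop("missing class labels in y")
  counts <- table(y)
  if (any(counts == 0))
    stop("class(es) absent from training data: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  classes <- levels(y)
  priors <- as.numeric(counts) / length(y)
  names(priors) <- classes
  conditionals <- lapply(names(x), function(nm) {
    col <- x[[nm]]
    if (is.numeric(col)) {
      if (anyNA(col)) stop("missing values in predictor '", nm, "'")
      m <- tapply(col, y, mean)
      s <- tapply(col, y, stats::sd)
      s[is.na(s)] <- 0
      if (any(s < var_floor))
        message("variance floor applied to predictor '", nm, "'")
      s <- pmax(s, var_floor)
      list(kind = "gaussian", mean = m, sd = s)
    } else {
      col <- if (is.factor(col)) col else factor(col)
      if (anyNA(col)) stop("missing values in predictor '", nm, "'")
      tab <- table(col, y)
      tab <- sweep(tab, 2, colSums(tab), "/")
      list(kind = "categorical", table = unclass(tab),
           levels = levels(col))
    }
  })
  names(conditionals) <- names(x)
  structure(list(classes = classes, priors = priors,
                 conditionals = conditionals, prob_floor = prob_floor,
                 var_floor = var_floor, n = nrow(x),
                 call = match.call()),
            class = "nb_map")
}

#' Predict classes or posteriors from a fitted MAP classifier
#'
#' Per-trial log posterior = log prior + sum over predictors of the log
#' conditional; posteriors are normalized per trial, and the predicted class
#' is the posterior argmax with ties broken by the fixed class order of the
#' fit.
#'
#' @param object an [nb_map()] fit.
#' @param newdata data.frame with the fit's predictor columns.
#' @param type `"class"` for the predicted label, `"posterior"` for the
#'   trials-by-classes posterior matrix.
#' @param ... unused.
#' @return factor of predictions, or numeric posterior matrix.
#' @export
predict.nb_map <- function(object, newdata,
                           type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  stopifnot(is.data.frame(newdata))
  miss <- setdiff(names(object$conditionals), names(newdata))
  if (length(miss))
    stop("newdata is missing predictor(s): ", paste(miss, collapse = ", "))
  n <- nrow(newdata)
  K <- length(object$classes)
  lp <- matrix(rep(log(object$priors), each = n), n, K,
               dimnames = list(NULL, object$classes))
  for (nm in names(object$conditionals)) {
    cond <- object$conditionals[[nm]]
    col <- newdata[[nm]]
    if (anyNA(col))
      stop("missing value in predictor '", nm, "'")
    if (cond$kind == "gaussian") {
      if (!is.numeric(col)) stop("predictor '", nm, "' must be numeric")
      for (k in seq_len(K))
        lp[, k] <- lp[, k] +
          stats::dnorm(col, cond$mean[k], cond$sd[k], log = TRUE)
    } else {
      val <- as.character(col)
      ri <- match(val, cond$levels)      # NA = unseen category
      for (k in seq_len(K)) {
        p <- ifelse(is.na(ri), object$prob_floor, cond$table[ri, k])
        p <- pmax(p, object$prob_floor)
        lp[, k] <- lp[, k] + log(p)
      }
    }
  }
  if (type == "posterior") {
    mx <- apply(lp, 1, max)
    post <- exp(lp - mx)
    return(post / rowSums(post))
  }
  # ties (to within numerical tolerance of the log posterior) break to the
  # earlier class in the fixed class order
  rowmax <- apply(lp, 1, max)
  pick <- apply(lp >= rowmax - 1e-9, 1, which.max)
  factor(object$classes[pick], levels = object$classes)
}

#' @export
print.nb_map <- function(x, ...) {
  cat("MAP naive-Bayes classifier\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  priors: ", paste(sprintf("%s=%.3f", x$classes, x$priors),
                          collapse = ", "), "\n")
  kinds <- vapply(x$conditionals, `[[`, character(1), "kind")
  cat("  predictors:",
      paste(sprintf("%s (%s)", names(kinds), kinds), collapse = ", "), "\n")
  cat("  trained on", x$n, "trials\n")
  invisible(x)
}

#' @export
summary.nb_map <- function(object, ...) {
  print(object)
  for (nm in names(object$conditionals)) {
    cond <- object$conditionals[[nm]]
    cat("\nConditional distribution of", nm, "\n")
    if (cond$kind == "gaussian") {
      print(rbind(mean = cond$mean, sd = cond$sd))
    } else {
      print(round(cond$table, 4))
    }
  }
  invisible(object)
}

#' Extract fitted parameters
#'
#' @param object an [nb_map()] fit.
#' @param ... unused.
#' @return list with `priors` and `conditionals`.
#' @export
coef.nb_map <- function(object, ...) {
  list(priors = object$priors, conditionals = object$conditionals)
}
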