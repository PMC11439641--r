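#' Concordance index of predicted affinities
#'
#' Over all pairs (i, j) with `y_true[i] > y_true[j]`, counts 1 when the
#' prediction ranks them the same way, 0.5 when the predictions tie, and 0
#' otherwise; the CI is the mean over those pairs. Ties in `y_true` are not
#' compared. 0.5 corresponds to random ranking, 1 to a perfect ranking, and
#' the index is invariant under strictly increasing transforms of the
#' predictions.
#'
#' @param y_true Numeric vector of true affinities (length >= 2, not all
#'   equal).
#' @param y_pred Numeric vector of predicted affinities, same length.
#' @return The concordance index in `[0, 1]`.
#' @examples
#' concordance_index(c(1, 2, 3), c(1, 2, 3)) # 1
#' concordance_index(c(1, 2, 3), c(3, 2, 1)) # 0
#' concordance_index(c(1, 2), c(5, 5)) # 0.5
#' @export
concordance_index <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L,
            all(is.finite(y_true)), all(is.finite(y_pred)))
  dy <- outer(y_true, y_true, ">")
  if (!any(dy)) stop("all y_true values are tied; CI is undefined")
  dp <- outer(y_pred, y_pred, "-")
  num <- sum((dp > 0)[dy]) + 0.5 * sum((dp == 0)[dy])
  num / sum(dy)
}

#' Mean squared error
#'
#' @param y_true,y_pred Numeric vectors of equal, nonzero length.
#' @return Mean of squared residuals.
#' @examples
#' mean_squared_error(c(1, 2, 3), c(2, 2, 2)) # 2/3
#' @export
mean_squared_error <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) == 0L) stop("empty vectors")
  mean((y_true - y_pred)^2)
}

#' Evaluate predictions with CI and MSE
#'
#' @param y_true,y_pred Numeric vectors of equal length.
#' @return An `evaluation_result`: a one-row data frame with columns `ci`,
#'   `mse`, and `n_pairs_compared` (number of (i, j) pairs with differing
#'   true affinity).
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  ci <- concordance_index(y_true, y_pred)
  n_pairs <- sum(outer(y_true, y_true, ">"))
  out <- data.frame(ci = ci, mse = mean_squared_error(y_true, y_pred),
                    n_pairs_compared = n_pairs)
  class(out) <- c("evaluation_result", class(out))
  out
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("CI = %.4f  MSE = %.4f  (%d informative pairs)\n",
              x$ci, x$mse, x$n_pairs_compared))
  invisible(x)
}
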