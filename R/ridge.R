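# Ridge regression with an unpenalized intercept, solved in closed form.

#' The canonical ridge penalty grid
#'
#' The l2 penalties evaluated in the inner cross-validation loop.
#'
#' @return Numeric vector of alpha values.
#' @export
ridge_alpha_grid <- function() {
  c(0.001, 0.01, 1, 10, 50, 100, 500, 1000, 5000, 10000)
}

#' Fit ridge regression with an unpenalized intercept
#'
#' Minimizes `sum_i (y_i - beta' x_i - b)^2 + alpha * sum_k beta_k^2`. The
#' intercept is left out of the penalty: X and y are centered by their training
#' means, the centered system `(Xc'Xc + alpha I) beta = Xc' yc` is solved (via
#' the SVD of Xc), and `b = mean(y) - mean(x)' beta`.
#'
#' @param X Numeric matrix (n x K), n >= 2.
#' @param y Numeric response vector of length n.
#' @param alpha Nonnegative penalty. At `alpha = 0` with a rank-deficient
#'   design the system is singular; set `singular_ok = TRUE` to take the
#'   minimum-norm (pseudo-inverse) solution instead of erroring.
#' @param singular_ok See above.
#'
#' @return An object of class `ridge_model` with `coefficients`, `intercept`,
#'   and `alpha`.
#' @export
fit_ridge <- function(X, y, alpha, singular_ok = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) != length(y) || nrow(X) < 2) abort("need rows(X) = length(y) >= 2")
  if (alpha < 0) abort("alpha must be nonnegative")
  sv <- svd(scale(X, center = TRUE, scale = FALSE))
  beta <- ridge_beta_from_svd(sv, y - mean(y), alpha, singular_ok)
  structure(
    list(coefficients = as.numeric(beta),
         intercept = mean(y) - sum(colMeans(X) * beta),
         alpha = alpha),
    class = "ridge_model"
  )
}

# Coefficients for one alpha given the SVD of the centered design and the
# centered response. Shared by fit_ridge and the CV fast path (one SVD, many
# alphas).
ridge_beta_from_svd <- function(sv, yc, alpha, singular_ok = FALSE) {
  d <- sv$d
  uty <- crossprod(sv$u, yc)
  if (alpha == 0) {
    tol <- max(dim(sv$u)) * max(d, 0) * .Machine$double.eps
    if (any(d <= tol)) {
      if (!singular_ok) {
        abort("singular design at alpha = 0; set singular_ok = TRUE for the minimum-norm solution")
      }
      w <- ifelse(d > tol, 1 / d, 0)
    } else {
      w <- 1 / d
    }
  } else {
    w <- d / (d^2 + alpha)
  }
  drop(sv$v %*% (w * uty))
}

#' Predict from a fitted ridge model
#'
#' @param object A `ridge_model`.
#' @param newdata Numeric matrix with one column per coefficient.
#' @param ... Unused.
#'
#' @return Numeric vector of predictions.
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coefficients) + object$intercept
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("<ridge_model> %d coefficients, alpha = %g, intercept = %.4g\n",
              length(x$coefficients), x$alpha, x$intercept))
  invisible(x)
}

#' Tidy a ridge model
#'
#' @param x A `ridge_model`.
#' @param ... Unused.
#'
#' @return A tibble with one row per term (intercept first).
#' @method tidy ridge_model
#' @export
tidy.ridge_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", paste0("x", seq_along(x$coefficients))),
    estimate = c(x$intercept, x$coefficients)
  )
}

#' Glance at a ridge model
#'
#' @param x A `ridge_model`.
#' @param ... Unused.
#'
#' @return A one-row tibble with the penalty and coefficient count.
#' @method glance ridge_model
#' @export
glance.ridge_model <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, n_coef = length(x$coefficients),
                 l2_norm = sqrt(sum(x$coefficients^2)))
}
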