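#' Fit a nu-parameterized one-class support vector machine
#'
#' Learns a description of a single (target) class from positive examples
#' only, by separating the training data from the origin in kernel feature
#' space with maximum margin. The primal trades the margin against slack
#' penalties weighted by `1/(nu * l)`; this fitter solves the equivalent
#' dual
#' \deqn{\min_\alpha \tfrac12 \alpha' K \alpha \quad
#'   \text{s.t.} \quad 0 \le \alpha_i \le 1/(\nu l), \; \sum_i \alpha_i = 1}
#' with an in-package SMO solver, then recovers the offset \eqn{\rho} from
#' the Karush-Kuhn-Tucker conditions. `nu` upper-bounds the fraction of
#' training points scored as outliers and lower-bounds the fraction of
#' support vectors.
#'
#' @param X Numeric matrix of training feature vectors (rows = instances).
#' @param kernel A [kernel_spec()] or `"linear"`/`"rbf"`.
#' @param nu Rejection-fraction parameter in (0, 1).
#' @param gamma Optional RBF width, passed to [kernel_spec()]; defaults to
#'   1/d where d is the feature dimension.
#' @param tol Duality-gap convergence tolerance for the dual solver.
#' @return An object of class `ocsvm` with elements `alphas`, `rho`, `nu`,
#'   `kernel`, `support_vectors` (rows of `X` with non-negligible alpha),
#'   `sv_index`, `slacks` (the solved primal slack values
#'   \eqn{\xi_i = \max(0, \rho - f_{raw}(x_i))}), `objective`, and the
#'   training dimension `d`.
#' @seealso [predict.ocsvm()], [svdd()], [qp_oracle()]
#' @examples
#' m <- ocsvm(rbind(c(1, 0), c(0, 1)), kernel = "linear", nu = 0.5)
#' m$rho                      # 0.5
#' predict(m, c(1, 1), type = "score")  # 0.5 -> inlier
#' @export
ocsvm <- function(X, kernel = kernel_spec("linear"), nu = 0.05,
                  gamma = NULL, tol = 1e-8) {
  X <- as_feature_matrix(X)
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) ||
      nu <= 0 || nu >= 1) {
    stop("'nu' must be a single number strictly inside (0, 1), got: ",
         deparse(nu), call. = FALSE)
  }
  kernel <- resolve_kernel(as_kernel_spec(kernel, gamma), ncol(X))
  l <- nrow(X)
  upper <- 1 / (nu * l)
  K <- kernel_matrix(X, X, kernel)
  sol <- solve_sum1_qp(K, p = NULL, upper = upper, tol = tol)
  alpha <- sol$alpha

  f_raw <- drop(K %*% alpha)             # sum_j alpha_j k(x_j, x_i)
  rho <- recover_rho(alpha, f_raw, upper)

  sv_tol <- 1e-7 * max(alpha)
  sv_index <- which(alpha > sv_tol)
  structure(list(
    alphas = alpha,
    rho = rho,
    nu = nu,
    kernel = kernel,
    support_vectors = X[sv_index, , drop = FALSE],
    sv_index = sv_index,
    slacks = pmax(0, rho - f_raw),
    objective = sol$objective,
    training_scores = f_raw - rho,
    d = ncol(X)
  ), class = "ocsvm")
}

# rho from KKT: margin SVs (strictly inside the box) satisfy f_raw = rho
# exactly; average them. Degenerate fits without margin SVs admit any rho
# in [max over at-bound points, min over zero-alpha points] of f_raw --
# take the midpoint (deterministic), or the finite end when one side is
# unbounded.
recover_rho <- function(alpha, f_raw, upper) {
  btol <- 1e-7 * upper
  margin <- alpha > btol & alpha < upper - btol
  if (any(margin)) return(mean(f_raw[margin]))
  at_upper <- alpha >= upper - btol
  at_zero <- alpha <= btol
  lo <- if (any(at_upper)) max(f_raw[at_upper]) else -Inf
  hi <- if (any(at_zero)) min(f_raw[at_zero]) else Inf
  if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
  else if (is.finite(lo)) lo
  else hi
}

#' Decision scores and inlier/outlier labels for a one-class SVM
#'
#' The raw decision score of a query point x is
#' \eqn{f(x) = \sum_i \alpha_i k(x_i, x) - \rho}; non-negative scores are
#' inliers (members of the target class), negative scores outliers. Ties
#' at exactly zero are inliers.
#'
#' @param object A fitted [ocsvm()] model.
#' @param newdata Feature matrix (rows = query points) with the training
#'   feature dimension; a bare numeric vector is taken as one point.
#' @param type `"class"` for `"inlier"`/`"outlier"` labels, `"score"` for
#'   the raw decision values.
#' @param ... Unused.
#' @return Character vector of labels, or numeric score vector.
#' @export
predict.ocsvm <- function(object, newdata,
                          type = c("class", "score"), ...) {
  type <- match.arg(type)
  scores <- ocsvm_decision(object, newdata)
  if (type == "score") scores else score_to_label(scores)
}

ocsvm_decision <- function(model, X) {
  X <- as_feature_matrix(X)
  if (ncol(X) != model$d) {
    stop(sprintf(
      "query points have %d features but the model was trained on %d",
      ncol(X), model$d), call. = FALSE)
  }
  K <- kernel_matrix(model$support_vectors, X, model$kernel)
  drop(crossprod(K, model$alphas[model$sv_index])) - model$rho
}

score_to_label <- function(scores) {
  ifelse(scores >= 0, "inlier", "outlier")
}

#' @export
print.ocsvm <- function(x, ...) {
  cat("One-class SVM (nu formulation)\n")
  cat(sprintf("  nu: %g   rho: %.6g\n", x$nu, x$rho))
  print(x$kernel)
  cat(sprintf("  support vectors: %d of %d training points\n",
              length(x$sv_index), length(x$alphas)))
  invisible(x)
}
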