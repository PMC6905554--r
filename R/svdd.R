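#' Fit a support vector data description (minimum enclosing hypersphere)
#'
#' Encloses the target class in a hypersphere of minimal radius in kernel
#' feature space; points outside the sphere are outliers. The dual is
#' \deqn{\max_\alpha \sum_i \alpha_i k(x_i, x_i)
#'   - \sum_{i,j} \alpha_i \alpha_j k(x_i, x_j) \quad
#'   \text{s.t.} \quad 0 \le \alpha_i \le C, \; \sum_i \alpha_i = 1,}
#' solved with the same SMO engine as [ocsvm()] (as a minimization of the
#' negated objective). The center is \eqn{\sum_i \alpha_i \phi(x_i)}; the
#' squared radius is read off any margin support vector. For kernels with
#' constant self-similarity (the RBF kernel, or any kernel on normalized
#' data) SVDD with `C = 1/(nu * l)` and the nu-one-class SVM give the same
#' inlier/outlier rule.
#'
#' @param X Numeric matrix of training feature vectors.
#' @param kernel A [kernel_spec()] or `"linear"`/`"rbf"`.
#' @param C Box constraint on the dual coefficients; must be at least
#'   `1/nrow(X)` or the equality constraint is infeasible.
#' @param gamma Optional RBF width (default 1/d).
#' @param tol Duality-gap convergence tolerance.
#' @return An object of class `svdd` with `alphas`, `radius_sq`, `C`,
#'   `kernel`, `support_vectors`, `sv_index`, and the training dimension.
#' @examples
#' m <- svdd(rbind(c(0, 0), c(2, 0)), kernel = "linear", C = 1)
#' m$radius_sq                          # 1 (center at (1, 0))
#' predict(m, c(3, 0), type = "score")  # -3 -> outlier
#' @export
svdd <- function(X, kernel = kernel_spec("linear"), C = 1, gamma = NULL,
                 tol = 1e-8) {
  X <- as_feature_matrix(X)
  l <- nrow(X)
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0) {
    stop("'C' must be a single positive number", call. = FALSE)
  }
  if (C < 1 / l) {
    stop(sprintf(
      paste("C = %g is infeasible: with %d training points the dual",
            "coefficients cannot sum to 1 unless C >= 1/%d = %g"),
      C, l, l, 1 / l), call. = FALSE)
  }
  kernel <- resolve_kernel(as_kernel_spec(kernel, gamma), ncol(X))
  K <- kernel_matrix(X, X, kernel)
  # maximize diag(K)'a - a'Ka  ==  minimize 1/2 a'(2K)a - diag(K)'a
  sol <- solve_sum1_qp(2 * K, p = -diag(K), upper = C, tol = tol)
  alpha <- sol$alpha

  # squared distance of training point i to the center:
  # k(x_i,x_i) - 2 (K a)_i + a'Ka
  Ka <- drop(K %*% alpha)
  aKa <- sum(alpha * Ka)
  dist_sq <- diag(K) - 2 * Ka + aKa

  btol <- 1e-7 * C
  margin <- alpha > btol & alpha < C - btol
  radius_sq <- if (any(margin)) {
    mean(dist_sq[margin])
  } else if (l == 1L) {
    0
  } else {
    # degenerate: any radius between the farthest at-bound point and the
    # nearest zero-alpha point is KKT-valid; take the midpoint
    at_upper <- alpha >= C - btol
    at_zero <- alpha <= btol
    lo <- if (any(at_upper)) max(dist_sq[at_upper]) else -Inf
    hi <- if (any(at_zero)) min(dist_sq[at_zero]) else Inf
    if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
    else if (is.finite(lo)) lo else hi
  }

  sv_tol <- 1e-7 * max(alpha)
  sv_index <- which(alpha > sv_tol)
  structure(list(
    alphas = alpha,
    radius_sq = max(0, radius_sq),
    C = C,
    kernel = kernel,
    support_vectors = X[sv_index, , drop = FALSE],
    sv_index = sv_index,
    objective = -sol$objective,   # value of the maximized dual
    center_norm_sq = aKa,
    d = ncol(X)
  ), class = "svdd")
}

#' Decision scores and labels for a support vector data description
#'
#' Scores are \eqn{R^2 - \|\phi(x) - center\|^2} expanded in kernel form:
#' non-negative means the point lies inside (or on) the sphere and is an
#' inlier, negative means outlier.
#'
#' @param object A fitted [svdd()] model.
#' @param newdata Feature matrix of query points (or one numeric vector).
#' @param type `"class"` or `"score"`.
#' @param ... Unused.
#' @return Character labels or numeric scores.
#' @export
predict.svdd <- function(object, newdata,
                         type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  if (ncol(X) != object$d) {
    stop(sprintf(
      "query points have %d features but the model was trained on %d",
      ncol(X), object$d), call. = FALSE)
  }
  a <- object$alphas[object$sv_index]
  Kq <- kernel_matrix(object$support_vectors, X, object$kernel)
  self_sim <- if (object$kernel$kind == "rbf") {
    rep(1, nrow(X))
  } else {
    rowSums(X^2)
  }
  dist_sq <- self_sim - 2 * drop(crossprod(Kq, a)) + object$center_norm_sq
  scores <- object$radius_sq - dist_sq
  if (type == "score") scores else score_to_label(scores)
}

#' @export
print.svdd <- function(x, ...) {
  cat("Support vector data description\n")
  cat(sprintf("  C: %g   R^2: %.6g\n", x$C, x$radius_sq))
  print(x$kernel)
  cat(sprintf("  support vectors: %d of %d training points\n",
              length(x$sv_index), length(x$alphas)))
  invisible(x)
}
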