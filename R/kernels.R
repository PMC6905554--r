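#' Kernel specification
#'
#' Describes the kernel used by [ocsvm()] and [svdd()]. The feature map
#' \eqn{\phi} is never formed explicitly; all computations go through
#' \eqn{k(x, y) = \phi(x) \cdot \phi(y)}.
#'
#' @param kind Kernel family, `"linear"` (\eqn{x \cdot y}) or `"rbf"`
#'   (\eqn{\exp(-\gamma \|x - y\|^2)}).
#' @param gamma Positive RBF width parameter; ignored for the linear kernel.
#'   `NULL` means "use 1/d at fit time", with d the feature count.
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("rbf", gamma = 0.5)
#' @export
kernel_spec <- function(kind = c("linear", "rbf"), gamma = NULL) {
  kind <- match.arg(kind)
  if (kind == "rbf" && !is.null(gamma)) {
    if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
        gamma <= 0) {
      stop("'gamma' must be a single positive finite number, got: ",
           deparse(gamma), call. = FALSE)
    }
  }
  structure(list(kind = kind, gamma = if (kind == "rbf") gamma else NULL),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  if (x$kind == "linear") {
    cat("Kernel: linear\n")
  } else {
    cat(sprintf("Kernel: rbf (gamma = %s)\n",
                if (is.null(x$gamma)) "1/d at fit time" else
                  format(x$gamma)))
  }
  invisible(x)
}

as_kernel_spec <- function(kernel, gamma = NULL) {
  if (inherits(kernel, "kernel_spec")) return(kernel)
  kernel_spec(kernel, gamma = gamma)
}

# Fill in the data-dependent default gamma = 1/d.
resolve_kernel <- function(kernel, d) {
  if (kernel$kind == "rbf" && is.null(kernel$gamma)) {
    kernel$gamma <- 1 / d
  }
  kernel
}

#' Kernel (Gram) matrix between two sets of feature vectors
#'
#' @param X Numeric matrix, l rows of feature vectors.
#' @param Y Numeric matrix, m rows of feature vectors with the same number
#'   of columns as `X`.
#' @param kernel A [kernel_spec()] (or a kernel kind string).
#' @return l x m matrix with entry (i, j) = k(X\[i, \], Y\[j, \]).
#'   For `Y = X` the result is symmetric positive semidefinite.
#' @examples
#' kernel_matrix(diag(2), diag(2), kernel_spec("linear"))
#' @export
kernel_matrix <- function(X, Y, kernel = kernel_spec("linear")) {
  kernel <- as_kernel_spec(kernel)
  X <- as_feature_matrix(X)
  Y <- as_feature_matrix(Y)
  if (ncol(X) != ncol(Y)) {
    stop(sprintf(
      "feature dimensions differ: X is %d x %d but Y is %d x %d",
      nrow(X), ncol(X), nrow(Y), ncol(Y)), call. = FALSE)
  }
  kernel <- resolve_kernel(kernel, ncol(X))
  if (kernel$kind == "linear") {
    return(tcrossprod(X, Y))
  }
  # squared Euclidean distances via the expansion |x|^2 + |y|^2 - 2 x.y;
  # clamp tiny negatives from cancellation
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-kernel$gamma * d2)
}

as_feature_matrix <- function(X, what = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X) && is.numeric(X)) X <- matrix(X, nrow = 1L)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("'", what, "' must be a numeric matrix of feature vectors",
         call. = FALSE)
  }
  if (any(!is.finite(X))) {
    stop("'", what, "' contains non-finite values", call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}
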