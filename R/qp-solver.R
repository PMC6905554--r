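# Dual quadratic program shared by the one-class SVM and SVDD:
#
#   minimize   1/2 a' Q a + p' a
#   subject to 0 <= a_i <= upper_i,  sum(a) = 1
#
# solved by sequential minimal optimization: repeatedly pick the most
# violating pair (i, j), move along e_i - e_j (which preserves the sum
# constraint), and take the exact one-dimensional minimizer clipped to the
# box. Convergence is declared on the duality gap
#   f(a) - min_{a' feasible} [ f(a) + g(a)'(a' - a) ] <= tol,
# a certified bound on f(a) - f(a*) for a convex objective.

solve_sum1_qp <- function(Q, p = NULL, upper, tol = 1e-8,
                          max_iter = NULL) {
  l <- nrow(Q)
  if (is.null(p)) p <- numeric(l)
  upper <- rep_len(upper, l)
  if (sum(upper) < 1 - 1e-12) {
    stop("infeasible box: sum of upper bounds ", format(sum(upper)),
         " is below the required total of 1", call. = FALSE)
  }
  if (is.null(max_iter)) max_iter <- max(20000L, 200L * l)

  # feasible start: upper >= 1/l is guaranteed by the callers' parameter
  # checks (nu <= 1, C >= 1/l), so the uniform vector is always in the box
  alpha <- rep(1 / l, l)
  if (any(alpha > upper)) {
    alpha <- pmin(upper, 1 / l)
    deficit <- 1 - sum(alpha)
    room <- upper - alpha
    idx <- order(room, decreasing = TRUE)
    for (i in idx) {
      if (deficit <= 0) break
      add <- min(room[i], deficit)
      alpha[i] <- alpha[i] + add
      deficit <- deficit - add
    }
  }

  g <- drop(Q %*% alpha) + p
  eps <- 1e-12
  it <- 0L
  repeat {
    it <- it + 1L
    up_ok <- alpha < upper - eps
    dn_ok <- alpha > eps
    if (!any(up_ok) || !any(dn_ok)) break
    # first-order choice of i, second-order (maximum-gain) choice of j
    i <- which(up_ok)[which.min(g[up_ok])]
    cand <- which(dn_ok & g > g[i] + eps)
    if (length(cand) == 0L) {
      if (dual_gap(alpha, g, p, upper) <= tol) break
      cand <- which(dn_ok)
    }
    d_all <- pmax(Q[i, i] + diag(Q)[cand] - 2 * Q[cand, i], 1e-12)
    j <- cand[which.max((g[cand] - g[i])^2 / d_all)]
    viol <- g[j] - g[i]
    if (viol <= tol || it > max_iter) {
      if (dual_gap(alpha, g, p, upper) <= tol) break
      if (it > max_iter) {
        gp <- dual_gap(alpha, g, p, upper)
        if (gp > 100 * tol) {
          warning("QP solver reached the iteration cap (", max_iter,
                  ") with duality gap ", format(gp), call. = FALSE)
        }
        break
      }
    }
    denom <- Q[i, i] + Q[j, j] - 2 * Q[i, j]
    step <- if (denom > eps) viol / denom else Inf
    step <- min(step, upper[i] - alpha[i], alpha[j])
    if (step <= 0) {   # no ascent left along any feasible pair
      gp <- dual_gap(alpha, g, p, upper)
      if (gp > 100 * tol) {
        warning("QP solver stalled with duality gap ", format(gp),
                call. = FALSE)
      }
      break
    }
    alpha[i] <- alpha[i] + step
    alpha[j] <- alpha[j] - step
    g <- g + step * (Q[, i] - Q[, j])
  }

  obj <- 0.5 * sum(alpha * (g - p)) + sum(p * alpha)
  list(alpha = alpha, gradient = g, objective = obj, iterations = it)
}

# Lower-bounds f(a) - f(a*) by linearizing at a: the linear program
# min g'a' over the feasible set is solved greedily (pour mass of 1 into
# the coordinates with smallest gradient, up to their upper bounds).
dual_gap <- function(alpha, g, p, upper) {
  ord <- order(g)
  mass <- 1
  lin_min <- 0
  for (i in ord) {
    take <- min(upper[i], mass)
    lin_min <- lin_min + take * g[i]
    mass <- mass - take
    if (mass <= 0) break
  }
  sum(g * alpha) - lin_min
}

#' Brute-force reference solver for the box-and-simplex QP
#'
#' Solves `min 1/2 a' K a + linear_term' a` subject to
#' `lower <= a <= upper, sum(a) = 1` by exhaustive active-set enumeration:
#' every assignment of each coordinate to \{at lower bound, at upper bound,
#' free\} is tried, the free block is solved through its KKT linear system,
#' and the best feasible candidate wins. Exact for convex problems but
#' exponential in l, so it refuses problems with more than 12 variables.
#' Intended as an independent test oracle for [ocsvm()] and [svdd()], not
#' for production use.
#'
#' @param K Symmetric positive semidefinite l x l matrix (l <= 12).
#' @param lower,upper Bound vectors (recycled to length l).
#' @param linear_term Linear coefficient vector (default zero).
#' @return List with `alpha` (the minimizer) and `objective`.
#' @examples
#' qp_oracle(diag(2), lower = 0, upper = 1)
#' @export
qp_oracle <- function(K, lower = 0, upper = 1, linear_term = NULL) {
  l <- nrow(K)
  if (l > 12L) {
    stop("qp_oracle enumerates 3^l active sets and refuses l = ", l,
         " > 12; use the SMO solver for larger problems", call. = FALSE)
  }
  lower <- rep_len(lower, l)
  upper <- rep_len(upper, l)
  if (is.null(linear_term)) linear_term <- numeric(l)
  feas_eps <- 1e-9

  objective <- function(a) 0.5 * sum(a * (K %*% a)) + sum(linear_term * a)

  best <- NULL
  best_obj <- Inf
  # each coordinate: 0 = at lower, 1 = at upper, 2 = free
  states <- as.matrix(expand.grid(rep(list(0:2), l)))
  for (r in seq_len(nrow(states))) {
    s <- states[r, ]
    a <- numeric(l)
    a[s == 0] <- lower[s == 0]
    a[s == 1] <- upper[s == 1]
    fixed_sum <- sum(a)
    free <- which(s == 2)
    nf <- length(free)
    if (nf == 0L) {
      if (abs(fixed_sum - 1) > feas_eps) next
    } else {
      # KKT system for the free block with the equality multiplier:
      # [K_FF 1; 1' 0] [a_F; lambda] = [-(lin_F + K_FB a_B); 1 - fixed_sum]
      A <- rbind(cbind(K[free, free, drop = FALSE], 1),
                 c(rep(1, nf), 0))
      b <- c(-(linear_term[free] +
                 if (nf < l) drop(K[free, -free, drop = FALSE] %*% a[-free])
               else 0),
             1 - fixed_sum)
      sol <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(sol)) next
      af <- sol[seq_len(nf)]
      if (any(af < lower[free] - feas_eps) ||
          any(af > upper[free] + feas_eps)) next
      a[free] <- pmin(pmax(af, lower[free]), upper[free])
    }
    if (abs(sum(a) - 1) > 1e-7) next
    ob <- objective(a)
    if (ob < best_obj - 1e-15) {
      best_obj <- ob
      best <- a
    }
  }
  if (is.null(best)) {
    stop("no feasible point found: check that the bounds admit sum(a) = 1",
         call. = FALSE)
  }
  list(alpha = best, objective = best_obj)
}
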