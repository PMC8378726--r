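#' Linear time-invariant state-space models
#'
#' Light S3 container for a continuous-time LTI system
#' \deqn{\dot x = A x + B u, \qquad y = C x + D u.}
#' All heavier machinery in the package (frequency responses, H-infinity
#' norms, Lyapunov and Riccati solves, balanced realizations) operates on
#' these records.  Matrices are stored densely; the systems handled here are
#' tiny (a first-order plant plus low-order weights and controllers).
#'
#' @param A,B,C,D real matrices of consistent dimensions.  Vectors are
#'   promoted to single-column (B), single-row (C) or scalar (D) matrices.
#' @return An object of class `"ss_model"`: a list with elements `A`, `B`,
#'   `C`, `D` and the state dimension `n`.
#' @examples
#' G <- ss_model(-1 / 35, -7.65 / 35, 1, 0)   # -7.65/(35 s + 1)
#' freqresp(G, 0)                             # DC gain -7.65
#' @export
ss_model <- function(A, B, C, D = 0) {
  A <- as.matrix(A)
  B <- if (is.matrix(B)) B else matrix(B, ncol = 1)
  C <- if (is.matrix(C)) C else matrix(C, nrow = 1)
  D <- if (is.matrix(D)) D else matrix(D, nrow = nrow(C), ncol = ncol(B))
  n <- nrow(A)
  stopifnot(ncol(A) == n, nrow(B) == n || n == 0, ncol(C) == n || n == 0,
            nrow(D) == nrow(C), ncol(D) == ncol(B))
  structure(list(A = A, B = B, C = C, D = D, n = n), class = "ss_model")
}

#' @export
print.ss_model <- function(x, ...) {
  cat(sprintf("<ss_model> %d state(s), %d input(s), %d output(s)\n",
              x$n, ncol(x$B), nrow(x$C)))
  invisible(x)
}

#' First-order lag k/(tau s + 1) as a state-space model
#' @param k DC gain
#' @param tau time constant (s), must be positive.
#' @keywords internal
first_order_ss <- function(k, tau) {
  stopifnot(tau > 0)
  ss_model(-1 / tau, k / tau, 1, 0)
}

#' Frequency response of a state-space model
#'
#' Evaluates `C (sI - A)^{-1} B + D` at `s = 1i * omega` (or at arbitrary
#' complex `s` via `ss_eval()`).
#'
#' @param sys an [ss_model()].
#' @param omega numeric vector of angular frequencies (rad/s).
#' @return For SISO systems a complex vector along `omega`; otherwise a
#'   `length(omega)` list of complex matrices.
#' @export
freqresp <- function(sys, omega) {
  res <- lapply(omega, function(w) ss_eval(sys, 1i * w))
  if (nrow(sys$C) == 1L && ncol(sys$B) == 1L) {
    vapply(res, function(m) m[1, 1], complex(1))
  } else res
}

#' @rdname freqresp
#' @param s a single complex Laplace variable.
#' @export
ss_eval <- function(sys, s) {
  if (sys$n == 0L) return(sys$D + 0i)
  sys$C %*% solve(s * diag(sys$n) - sys$A, sys$B) + sys$D
}

#' Stability of an LTI model
#' @param sys an [ss_model()].
#' @param margin require all eigenvalue real parts below `-margin`.
#' @return `TRUE` if every eigenvalue of `A` is strictly in the open left
#'   half-plane.
#' @export
is_stable <- function(sys, margin = 0) {
  if (sys$n == 0L) return(TRUE)
  max(Re(eigen(sys$A, only.values = TRUE)$values)) < -margin
}

# -- interconnections ---------------------------------------------------------

#' Series, parallel and feedback interconnections
#'
#' `ss_series(g1, g2)` is `g2 %*% g1` (signal passes g1 then g2);
#' `ss_parallel` sums outputs; `ss_feedback(g, k)` closes
#' `u = r - k(y)` around `g` (negative feedback, `D_g D_k` well-posed).
#'
#' @param g1,g2,g,k [ss_model()]s with compatible dimensions.
#' @return An [ss_model()].
#' @export
ss_series <- function(g1, g2) {
  A <- rbind(cbind(g1$A, matrix(0, g1$n, g2$n)),
             cbind(g2$B %*% g1$C, g2$A))
  B <- rbind(g1$B, g2$B %*% g1$D)
  C <- cbind(g2$D %*% g1$C, g2$C)
  D <- g2$D %*% g1$D
  ss_model(A, B, C, D)
}

#' @rdname ss_series
#' @export
ss_parallel <- function(g1, g2) {
  A <- rbind(cbind(g1$A, matrix(0, g1$n, g2$n)),
             cbind(matrix(0, g2$n, g1$n), g2$A))
  ss_model(A, rbind(g1$B, g2$B), cbind(g1$C, g2$C), g1$D + g2$D)
}

#' @rdname ss_series
#' @export
ss_feedback <- function(g, k) {
  # closed loop r -> y with u = r - k y
  E <- diag(nrow(g$D)) + g$D %*% k$D
  Ei <- solve(E)
  Ag <- g$A - g$B %*% k$D %*% Ei %*% g$C
  A <- rbind(cbind(Ag, -g$B %*% (k$C - k$D %*% Ei %*% g$D %*% k$C)),
             cbind(k$B %*% Ei %*% g$C, k$A - k$B %*% Ei %*% g$D %*% k$C))
  B <- rbind(g$B - g$B %*% k$D %*% Ei %*% g$D, k$B %*% Ei %*% g$D)
  C <- cbind(Ei %*% g$C, -Ei %*% g$D %*% k$C)
  D <- Ei %*% g$D
  ss_model(A, B, C, D)
}

# -- norms --------------------------------------------------------------------

#' H-infinity norm by frequency sweep
#'
#' Peak singular value of the frequency response over a log-spaced grid with
#' local golden-section refinement around the grid maximum.  The default grid
#' (400 points over 1e-5..1e2 rad/s) brackets the MAP-plant bandwidth
#' 1/tau0 ~ 0.03 rad/s by more than three decades on either side.
#'
#' @param sys an [ss_model()] (SISO or MIMO).
#' @param omega optional frequency grid (rad/s).
#' @param refine logical; perform local refinement around the grid peak.
#' @return list with `norm` and the peak frequency `omega_peak`.
#' @export
hinf_norm <- function(sys, omega = default_omega_grid(), refine = TRUE) {
  gain <- function(w) {
    m <- ss_eval(sys, 1i * w)
    if (length(m) == 1L) Mod(m[1, 1]) else max(svd(m)$d)
  }
  vals <- vapply(omega, gain, numeric(1))
  j <- which.max(vals)
  pk <- vals[j]; wpk <- omega[j]
  # include the DC limit for strictly proper-in-s peaks at the grid edge
  g0 <- tryCatch(gain(0), error = function(e) NA_real_)
  if (is.finite(g0) && g0 > pk) { pk <- g0; wpk <- 0 }
  if (refine && j > 1L && j < length(omega)) {
    lo <- omega[j - 1L]; hi <- omega[j + 1L]
    phi <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
    f1 <- gain(x1); f2 <- gain(x2)
    for (it in 1:60) {
      if (f1 < f2) { a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + phi * (b - a); f2 <- gain(x2)
      } else { b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - phi * (b - a); f1 <- gain(x1) }
    }
    if (max(f1, f2) > pk) { pk <- max(f1, f2); wpk <- if (f1 > f2) x1 else x2 }
  }
  list(norm = pk, omega_peak = wpk)
}

#' @rdname hinf_norm
#' @param n_points,from,to grid resolution and range (rad/s).
#' @export
default_omega_grid <- function(n_points = 400, from = 1e-5, to = 1e2) {
  10^seq(log10(from), log10(to), length.out = n_points)
}

# -- Lyapunov / Riccati -------------------------------------------------------

#' Continuous-time Lyapunov equation
#'
#' Solves `A' Q + Q A = -W` by Kronecker vectorization (systems here have a
#' handful of states, so the dense n^2 x n^2 solve is exact and cheap).
#'
#' @param A square matrix with eigenvalues off the imaginary pairing
#'   (`lambda_i + lambda_j != 0`).
#' @param W symmetric right-hand side.
#' @return symmetric solution matrix `Q`.
#' @export
lyap_solve <- function(A, W) {
  n <- nrow(A)
  M <- kronecker(diag(n), t(A)) + kronecker(t(A), diag(n))
  Q <- matrix(solve(M, -as.vector(W)), n, n)
  (Q + t(Q)) / 2
}

# controllability Gramian variant: A P + P A' = -W
gram_solve <- function(A, W) t(lyap_solve(t(A), W))

#' Stabilizing solution of an algebraic Riccati equation
#'
#' Solves `A'X + XA - X S X + Q = 0` via the stable invariant subspace of the
#' Hamiltonian matrix.  Returns `NULL` (rather than erroring) when no
#' stabilizing solution exists, which is what the H-infinity gamma-bisection
#' uses as its feasibility signal.
#'
#' @param A,S,Q square matrices; `S`, `Q` symmetric.
#' @return symmetric `X`, or `NULL` if the Hamiltonian has imaginary-axis
#'   eigenvalues or the subspace is not complementary.
#' @export
care_solve <- function(A, S, Q) {
  n <- nrow(A)
  H <- rbind(cbind(A, -S), cbind(-Q, -t(A)))
  e <- eigen(H)
  idx <- which(Re(e$values) < 0)
  if (length(idx) != n) return(NULL)
  V <- e$vectors[, idx, drop = FALSE]
  X1 <- V[1:n, , drop = FALSE]
  X2 <- V[(n + 1):(2 * n), , drop = FALSE]
  X1i <- tryCatch(solve(X1), error = function(e) NULL)
  if (is.null(X1i)) return(NULL)
  X <- Re(X2 %*% X1i)
  (X + t(X)) / 2
}

# -- balanced realization -----------------------------------------------------

#' Balanced realization and balanced truncation
#'
#' Computes the internally balanced realization of a stable system (equal,
#' diagonal controllability and observability Gramians) and optionally drops
#' states whose Hankel singular values fall below `trunc_tol` times the
#' largest.  Used to condition controller realizations before Lyapunov
#' certification; truncated states at the default tolerance contribute less
#' than 0.01% of the Hankel energy and leave achieved closed-loop norms
#' unchanged to four digits.
#'
#' @param sys a stable [ss_model()].
#' @param trunc_tol relative Hankel singular-value cutoff (0 disables).
#' @return an [ss_model()] with attribute `"hankel"` (all singular values).
#' @export
balanced_realization <- function(sys, trunc_tol = 0) {
  stopifnot(is_stable(sys))
  P <- gram_solve(sys$A, sys$B %*% t(sys$B))
  Q <- lyap_solve(sys$A, t(sys$C) %*% sys$C)
  R <- chol((P + t(P)) / 2 + 1e-300 * diag(sys$n))
  sv <- svd(R %*% ((Q + t(Q)) / 2) %*% t(R))
  sig <- sqrt(pmax(sv$d, 1e-300))
  Tm <- t(R) %*% sv$u %*% diag(1 / sqrt(sig), length(sig))
  Ti <- solve(Tm)
  A <- Ti %*% sys$A %*% Tm; B <- Ti %*% sys$B; C <- sys$C %*% Tm
  if (trunc_tol > 0) {
    keep <- which(sig >= trunc_tol * sig[1])
    A <- A[keep, keep, drop = FALSE]; B <- B[keep, , drop = FALSE]
    C <- C[, keep, drop = FALSE]
  }
  out <- ss_model(A, B, C, sys$D)
  attr(out, "hankel") <- sig
  out
}

# -- discretization -----------------------------------------------------------

#' Zero-order-hold discretization
#'
#' Exact ZOH discrete equivalent over step `dt` via the augmented matrix
#' exponential, robust to (near-)singular `A`.
#'
#' @param sys an [ss_model()]
#' @param dt step (s).
#' @return list with `Ad`, `Bd` (and the original `C`, `D`).
#' @export
ss_discretize <- function(sys, dt) {
  n <- sys$n; m <- ncol(sys$B)
  if (n == 0L) return(list(Ad = matrix(0, 0, 0), Bd = matrix(0, 0, m),
                           C = sys$C, D = sys$D))
  Maug <- rbind(cbind(sys$A, sys$B), matrix(0, m, n + m)) * dt
  E <- as.matrix(Matrix::expm(Maug))
  list(Ad = E[1:n, 1:n, drop = FALSE], Bd = E[1:n, (n + 1):(n + m), drop = FALSE],
       C = sys$C, D = sys$D)
}

# -- plain-text exchange ------------------------------------------------------

#' Read and write state-space models as plain text
#'
#' Serializes `A`, `B`, `C`, `D` (and an optional input delay) to a simple
#' key/matrix text format so controller banks and plants can be exchanged and
#' round-tripped without binary artifacts.
#'
#' @param sys an [ss_model()]
#' @param path file path
#' @param delay input
#'   delay in seconds stored alongside the matrices.
#' @return `read_ss()` returns an [ss_model()] with attribute `"delay"`.
#' @export
write_ss <- function(sys, path, delay = 0) {
  fmt <- function(M) apply(M, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  lines <- c(sprintf("n %d m %d p %d delay %.17g", sys$n, ncol(sys$B), nrow(sys$C), delay),
             "A", fmt(sys$A), "B", fmt(sys$B), "C", fmt(sys$C), "D", fmt(sys$D))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ss
#' @export
read_ss <- function(path) {
  lines <- readLines(path)
  hdr <- as.numeric(strsplit(lines[1], " ")[[1]][c(2, 4, 6, 8)])
  n <- hdr[1]; m <- hdr[2]; p <- hdr[3]
  grab <- function(tag, nr) {
    i <- which(lines == tag)[1]
    if (nr == 0) return(matrix(0, 0, 0))
    do.call(rbind, lapply(lines[(i + 1):(i + nr)], function(l)
      as.numeric(strsplit(trimws(l), " +")[[1]])))
  }
  A <- grab("A", n); B <- grab("B", n); C <- grab("C", p); D <- grab("D", p)
  if (n == 0) { B <- matrix(0, 0, m); C <- matrix(0, p, 0) }
  out <- ss_model(A, B, C, D)
  attr(out, "delay") <- hdr[4]
  out
}
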