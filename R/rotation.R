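#' Rotate channel pairs by per-plane angles
#'
#' Treats consecutive channel pairs (1,2), (3,4), ... of each position's
#' vector as points in a complex plane and rotates plane `p` of position `t`
#' by `angles[p, t]` radians. Rotations are isometries: the Euclidean norm of
#' every position's vector is preserved.
#'
#' @param vectors N x d_h matrix (d_h even); rows are positions.
#' @param angles P x N matrix of radians, P = d_h / 2.
#' @return N x d_h matrix of rotated vectors.
#' @examples
#' rotate_pairs(matrix(c(1, 0), 1), matrix(pi / 2))  # (1,0) -> (0,1)
#' @export
rotate_pairs <- function(vectors, angles) {
  vectors <- as.matrix(vectors); angles <- as.matrix(angles)
  d_h <- ncol(vectors); n <- nrow(vectors)
  if (d_h %% 2L != 0L) stop("head width d_h must be even")
  P <- d_h %/% 2L
  if (nrow(angles) != P || ncol(angles) != n)
    stop("angles must be P x N with P = d_h/2")
  ev <- seq(1L, d_h, by = 2L); od <- ev + 1L
  ca <- t(cos(angles)); sa <- t(sin(angles))      # N x P
  xe <- vectors[, ev, drop = FALSE]; xo <- vectors[, od, drop = FALSE]
  out <- matrix(0, n, d_h)
  out[, ev] <- xe * ca - xo * sa
  out[, od] <- xe * sa + xo * ca
  out
}

#' Initialize rotation-learning parameters
#'
#' State of the position-wise kernel-3 convolution that maps a head input to
#' latent frequency and phase sequences. Weights start small so the initial
#' rotation is near the identity.
#'
#' @param d_h Head width (even).
#' @param seed Integer seed for the initialization.
#' @param scale Weight scale.
#' @return An object of class `rotation_state`: list with `W` (3 x d_h x 2P
#'   array) and `b` (length 2P).
#' @export
rotation_state <- function(d_h, seed = 1, scale = 0.1) {
  if (d_h %% 2L != 0L) stop("d_h must be even")
  P <- d_h %/% 2L
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  structure(list(W = array(stats::rnorm(3 * d_h * 2 * P, 0, scale),
                           dim = c(3, d_h, 2 * P)),
                 b = stats::rnorm(2 * P, 0, scale), d_h = d_h, P = P),
            class = "rotation_state")
}

#' Learn per-plane frequencies and phases from a head input
#'
#' A 1-D convolution (kernel 3, replicate padding) over positions followed by
#' squashing maps: frequencies through `0.5 * sigmoid` so they respect the
#' Nyquist bound for unit-step sampling, phases through `pi * tanh` so they
#' lie in (-pi, pi). Query-side and key-side attention keep separate states.
#' A constant-in-time input therefore yields constant-in-time frequencies and
#' phases (every convolution window is identical under replicate padding).
#'
#' @param head_input N x d_h matrix.
#' @param state A [rotation_state()].
#' @return An object of class `rotation_params`: list with `omega` (cycles
#'   per step, in `[0, 0.5]`) and `theta` (radians, in `(-pi, pi)`), both
#'   P x N matrices.
#' @export
learn_rotation_params <- function(head_input, state) {
  stopifnot(inherits(state, "rotation_state"))
  x <- as.matrix(head_input)
  n <- nrow(x)
  if (ncol(x) != state$d_h) stop("head_input width must equal d_h")
  if (n < 1L) stop("need at least one position")
  im <- if (n == 1L) 1L else c(1L, 1L:(n - 1L))   # replicate pad left
  ip <- if (n == 1L) 1L else c(2L:n, n)           # replicate pad right
  raw <- x[im, , drop = FALSE] %*% state$W[1, , ] +
    x %*% state$W[2, , ] +
    x[ip, , drop = FALSE] %*% state$W[3, , ]
  raw <- sweep(raw, 2L, state$b, "+")
  P <- state$P
  omega <- 0.5 * stats::plogis(raw[, seq_len(P), drop = FALSE])
  theta <- pi * tanh(raw[, P + seq_len(P), drop = FALSE])
  rotation_params(t(omega), t(theta))
}

#' Construct rotation parameters
#'
#' @param omega P x N matrix of frequencies (cycles per step) in `[0, 0.5]`.
#' @param theta P x N matrix of phases (radians) in `(-pi, pi]`.
#' @return An object of class `rotation_params`.
#' @export
rotation_params <- function(omega, theta) {
  omega <- as.matrix(omega); theta <- as.matrix(theta)
  if (!all(dim(omega) == dim(theta))) stop("omega and theta shapes differ")
  if (any(omega < 0 | omega > 0.5)) stop("omega must lie in [0, 0.5]")
  structure(list(omega = omega, theta = theta), class = "rotation_params")
}

zero_rotation <- function(P, n) rotation_params(matrix(0, P, n), matrix(0, P, n))

# Angle of plane p at 0-based position m: 2*pi*omega[p, m+1]*m + theta[p, m+1]
position_angles <- function(rp, n) {
  m <- matrix(0:(n - 1), nrow(rp$omega), n, byrow = TRUE)
  2 * pi * rp$omega * m + rp$theta
}

#' Rotated softmax-kernel attention scores
#'
#' The unnormalized attention score between query position m (0-based) and
#' key position n is
#' \deqn{exp( \langle R_q(m) q_m, R_k(n) k_n \rangle / \sqrt{d_h} )}
#' where the rotations apply angle `2 pi omega[p, m] m + theta[p, m]` in
#' plane p (and likewise for keys). With all frequencies and phases zero the
#' scores reduce to the standard scaled exponential dot-product kernel.
#' Every call adds `nrow(q) * nrow(k)` to the score-evaluation counter (see
#' [lra_score_count()]).
#'
#' @param q N x d_h query matrix.
#' @param k L x d_h key matrix.
#' @param rp_q,rp_k [rotation_params()] for queries and keys (defaults: zero
#'   rotation).
#' @return N x L matrix of strictly positive scores.
#' @export
lra_scores <- function(q, k, rp_q = NULL, rp_k = NULL) {
  q <- as.matrix(q); k <- as.matrix(k)
  d_h <- ncol(q)
  if (ncol(k) != d_h) stop("query and key widths differ")
  if (d_h %% 2L != 0L) stop("head width d_h must be even")
  P <- d_h %/% 2L
  if (is.null(rp_q)) rp_q <- zero_rotation(P, nrow(q))
  if (is.null(rp_k)) rp_k <- zero_rotation(P, nrow(k))
  if (nrow(rp_q$omega) != P || nrow(rp_k$omega) != P)
    stop("rotation plane count must equal d_h/2")
  qr <- rotate_pairs(q, position_angles(rp_q, nrow(q)))
  kr <- rotate_pairs(k, position_angles(rp_k, nrow(k)))
  counter_add(nrow(q) * nrow(k))
  exp(qr %*% t(kr) / sqrt(d_h))
}

#' Learning-to-rotate attention
#'
#' Normalizes the rotated softmax-kernel scores row-wise into attention
#' weights (each row is a probability vector) and averages the values.
#'
#' @param q N x d_h queries.
#' @param k L x d_h keys.
#' @param v L x d_v values.
#' @param rp_q,rp_k Optional [rotation_params()].
#' @return N x d_v output matrix.
#' @export
lra_attention <- function(q, k, v, rp_q = NULL, rp_k = NULL) {
  k <- as.matrix(k); v <- as.matrix(v)
  if (nrow(k) == 0L) stop("empty key sequence")
  if (nrow(k) != nrow(v)) stop("keys and values must have equal length")
  s <- lra_scores(q, k, rp_q, rp_k)
  w <- s / rowSums(s)
  w %*% v
}

#' Decoupled attention through a global memory
#'
#' Instead of letting N queries attend to L keys directly (N*L scores), the
#' key-value sequence is first compressed into `c` memory slots,
#' `M' = LRA(memory, kv, kv)`, and the queries attend to the compressed
#' summary, `H = LRA(queries, M', M')`. The score-evaluation count is
#' `c*L + N*c`, linear in both sequence lengths for fixed `c`.
#'
#' @param queries N x d matrix.
#' @param kv L x d key-value matrix.
#' @param memory c x d matrix of memory slots (c >= 1).
#' @param rp_mem,rp_kv,rp_q,rp_mprime Optional [rotation_params()] for the
#'   two attention calls (compression: memory vs kv; readout: queries vs
#'   compressed slots).
#' @return List with `H` (N x d) and `M_prime` (c x d).
#' @export
decoupled_lra <- function(queries, kv, memory,
                          rp_mem = NULL, rp_kv = NULL,
                          rp_q = NULL, rp_mprime = NULL) {
  memory <- as.matrix(memory)
  if (nrow(memory) < 1L) stop("memory must have at least one slot (c >= 1)")
  m_prime <- lra_attention(memory, kv, kv, rp_mem, rp_kv)
  h <- lra_attention(queries, m_prime, m_prime, rp_q, rp_mprime)
  list(H = h, M_prime = m_prime)
}

.counters <- new.env(parent = emptyenv())
.counters$scores <- 0

counter_add <- function(n) .counters$scores <- .counters$scores + n

#' Score-evaluation counter
#'
#' Instrumentation for the complexity of the attention mechanism: every
#' score-matrix computation adds (number of queries) x (number of keys) to a
#' package-level counter. `lra_score_reset()` zeroes it, `lra_score_count()`
#' reads it.
#'
#' @return `lra_score_count()` returns the number of score evaluations since
#'   the last reset.
#' @export
lra_score_count <- function() .counters$scores

#' @rdname lra_score_count
#' @export
lra_score_reset <- function() { .counters$scores <- 0; invisible(NULL) }

#' Trend normalization
#'
#' Layer normalization adapted to slowly drifting hidden sequences: per
#' channel, a straight line over positions (the trend `Tr`) is fitted by
#' least squares; the residual is standardized and the trend re-added with a
#' learnable scale,
#' \deqn{out = \gamma (h - Tr) / (sd(h - Tr) + \epsilon) + \beta + \rho Tr.}
#' The fitted slope of `out - rho * Tr` is zero by construction. An exactly
#' linear-in-time input with `rho = 1, beta = 0` is returned unchanged.
#'
#' @param hidden N x d matrix, N >= 2.
#' @param gamma,beta Gain and shift (scalar or length-d).
#' @param rho Trend re-scaling (scalar).
#' @param eps Standardization floor.
#' @return N x d matrix.
#' @export
trend_normalize <- function(hidden, gamma = 1, beta = 0, rho = 1,
                            eps = 1e-5) {
  h <- as.matrix(hidden)
  n <- nrow(h)
  if (n < 2L) stop("trend normalization needs at least 2 positions")
  tr <- trend_projector(n) %*% h
  r <- h - tr
  s <- sqrt(colMeans(r^2))
  z <- sweep(r, 2L, s + eps, "/")
  z <- sweep(z, 2L, rep_len(gamma, ncol(h)), "*")
  z <- sweep(z, 2L, rep_len(beta, ncol(h)), "+")
  z + rho * tr
}

# Hat matrix of the per-channel regression on (intercept, position).
trend_projector <- function(n) {
  x <- cbind(1, seq_len(n))
  x %*% solve(crossprod(x), t(x))
}

#' Frequency smoothness regularizer
#'
#' Mean squared first difference of the latent frequency sequences:
#' \deqn{L_\omega = \frac{1}{P(N-1)} \sum_{p=1}^P \sum_{n=0}^{N-2}
#'   (\omega_p^{(n+1)} - \omega_p^{(n)})^2.}
#'
#' @param omega P x N matrix (rows = planes, columns = positions), N >= 2.
#' @return Non-negative scalar.
#' @examples
#' omega_regularizer(matrix(c(0, 1, 3), 1))  # 2.5
#' @export
omega_regularizer <- function(omega) {
  omega <- as.matrix(omega)
  if (ncol(omega) < 2L) stop("omega needs at least 2 positions")
  d <- omega[, -1L, drop = FALSE] - omega[, -ncol(omega), drop = FALSE]
  sum(d^2) / (nrow(omega) * (ncol(omega) - 1L))
}

#' Phase sparsity regularizer
#'
#' Mean absolute latent phase:
#' \deqn{L_\theta = \frac{1}{PN} \sum_{p=1}^P \sum_{n=0}^{N-1}
#'   |\theta_p^{(n)}|.}
#'
#' @param theta P x N matrix.
#' @return Non-negative scalar.
#' @examples
#' theta_regularizer(matrix(c(1, -1), 1))  # 1
#' @export
theta_regularizer <- function(theta) {
  theta <- as.matrix(theta)
  if (length(theta) == 0L) stop("theta must be non-empty")
  mean(abs(theta))
}

#' Total training loss
#'
#' Prediction mean squared error plus the rotation regularizers:
#' \deqn{L = L_{pred} + \lambda_1 L_\omega + \lambda_2 L_\theta,}
#' where the regularizers are averaged over all supplied frequency/phase
#' matrices (query- and key-side parameter sets of every attention layer).
#'
#' @param pred,target Prediction and target vectors, equal length.
#' @param omegas,thetas Lists of P x N matrices.
#' @param lambda1,lambda2 Non-negative regularization weights.
#' @return Non-negative scalar loss.
#' @export
total_loss <- function(pred, target, omegas = list(), thetas = list(),
                       lambda1 = 0.01, lambda2 = 0.01) {
  if (length(pred) != length(target)) stop("pred and target lengths differ")
  if (lambda1 < 0 || lambda2 < 0) stop("lambda1 and lambda2 must be >= 0")
  l_pred <- mean((pred - target)^2)
  l_om <- if (length(omegas)) mean(vapply(omegas, omega_regularizer, numeric(1))) else 0
  l_th <- if (length(thetas)) mean(vapply(thetas, theta_regularizer, numeric(1))) else 0
  l_pred + lambda1 * l_om + lambda2 * l_th
}
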