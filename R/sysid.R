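# PRBS excitation and linear state-space identification of the plant around
# the primary position.
#
# The plant's dominant dynamics are its rigid-body inertia, so the local
# linear model is taken to have 6 states (3 orientation + 3 velocity
# coordinates) with 3 motor inputs and the 3 rotation-vector outputs:
#   x[t+1] = A x[t] + B u[t],   r[t] = C x[t] + E u[t]
# at the 10 ms control tick.  Identification is deterministic MOESP-style
# subspace estimation (past inputs/outputs as instruments, SVD truncation at
# the model order, then least squares for B, E and the initial state); a
# high-order ARX fit followed by a Ho-Kalman balanced realization is provided
# as an independent cross-check route.

#' Pseudo-random binary excitation signal
#'
#' Three-channel two-level sequence of fixed amplitude and random bit flips
#' (bit length `bit_period` ticks), uncorrelated between channels: each
#' channel draws its bits from its own seeded stream.
#'
#' @param duration_s signal length, s.
#' @param amplitude level, rad of motor rotation (samples are +/- amplitude).
#' @param bit_period bit length in ticks.
#' @param dt tick, s.
#' @param seed integer seed; channel k uses substream `prbs<k>`.
#' @return n x 3 matrix of motor commands with attributes `amplitude`,
#'   `bit_period`, `seed`.
#' @export
prbs <- function(duration_s = 180, amplitude = 0.25, bit_period = 5,
                 dt = 0.01, seed = 1) {
  stopifnot(duration_s > 0, amplitude > 0, bit_period >= 1)
  n <- round(duration_s / dt)
  U <- sapply(1:3, function(ch) {
    set.seed(substream_seed(seed, paste0("prbs", ch)))
    bits <- sample(c(-1, 1), ceiling(n / bit_period), replace = TRUE)
    rep(bits, each = bit_period)[seq_len(n)] * amplitude
  })
  attr(U, "amplitude") <- amplitude
  attr(U, "bit_period") <- bit_period
  attr(U, "seed") <- seed
  U
}

#' Normalized root-mean-squared-error fitness (%)
#'
#' `100 * (1 - ||r - rhat|| / ||r - rbar||)` per output: 100 for a perfect
#' prediction, 0 for the mean predictor, negative for worse than the mean.
#'
#' @param truth n x p matrix (or vector) of reference outputs.
#' @param pred matched predictions.
#' @return named numeric vector, one fitness value per output column.
#' @export
nrmse <- function(truth, pred) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  stopifnot(identical(dim(truth), dim(pred)))
  vapply(seq_len(ncol(truth)), function(j) {
    r <- truth[, j]
    denom <- sqrt(sum((r - mean(r))^2))
    if (denom == 0) stop("constant reference output: NRMSE undefined")
    100 * (1 - sqrt(sum((r - pred[, j])^2)) / denom)
  }, numeric(1)) |> setNames(colnames(truth))
}

# Block-Hankel matrix with `blk` block rows of the (transposed) series:
# column j holds rows first + j - 1 ... first + j - 1 + blk - 1 stacked.
block_hankel <- function(x, first, blk, ncols) {
  p <- ncol(x)
  out <- matrix(0, blk * p, ncols)
  for (b in seq_len(blk))
    out[((b - 1) * p + 1):(b * p), ] <-
      t(x[(first + b - 1):(first + b - 2 + ncols), , drop = FALSE])
  out
}

#' Fit a discrete linear state-space model from input/output data
#'
#' Deterministic subspace identification (`method = "moesp"`): an LQ
#' factorization of the stacked future-input / past-data / future-output
#' block-Hankel matrices isolates the column space of the extended
#' observability matrix (past inputs and outputs serve as instruments
#' against the equation error left by the nonlinear plant), an SVD truncated
#' at `order` yields `C` and, via its shift structure, `A`; `B`, `E` and the
#' initial state then follow from an ordinary least-squares fit of the
#' simulated response to the training outputs.  `method = "arx"` is the
#' cross-check route: a high-order vector-ARX least-squares fit whose
#' impulse-response (Markov) parameters are realized by Ho-Kalman balanced
#' truncation.
#'
#' @param u n x m input series (ticks of `dt`).
#' @param y n x l output series, aligned so `y[t]` is the response measured
#'   at the end of tick t (the tick during which `u[t]` acted).
#' @param order state dimension (6: three orientations + three velocities).
#' @param horizon number of block rows in the Hankel matrices.
#' @param method `"moesp"` or `"arx"`.
#' @param dt tick, s (metadata).
#' @return an `ss_model`: list with matrices `A, B, C, E`, estimated initial
#'   state `x0`, and metadata.
#' @export
ss_identify <- function(u, y, order = 6, horizon = 15,
                        method = c("moesp", "arx"), dt = 0.01) {
  method <- match.arg(method)
  u <- as.matrix(u); y <- as.matrix(y)
  stopifnot(nrow(u) == nrow(y), nrow(u) >= 20 * order)
  fit <- switch(method,
    moesp = moesp_fit(u, y, order, horizon),
    arx = arx_fit(u, y, order))
  fit$dt <- dt
  fit$order <- order
  fit$method <- method
  class(fit) <- "ss_model"
  # x0 and (for arx, refreshed) B/E by least squares on the training data
  fit <- ss_refit_bde(fit, u, y)
  fit
}

moesp_fit <- function(u, y, order, i) {
  m <- ncol(u); l <- ncol(y)
  N <- nrow(u)
  j <- N - 2 * i + 1
  if (j < 10 * (2 * i * (m + l))) i <- max(5, min(i, floor(N / 40)))
  j <- N - 2 * i + 1
  Up <- block_hankel(u, 1, i, j)
  Uf <- block_hankel(u, i + 1, i, j)
  Yp <- block_hankel(y, 1, i, j)
  Yf <- block_hankel(y, i + 1, i, j)
  W <- rbind(Uf, Up, Yp, Yf)
  R <- qr.R(qr(t(W)))
  L <- t(R)
  iu <- i * m; iz <- i * (m + l); iy <- i * l
  L32 <- L[(iu + iz + 1):(iu + iz + iy), (iu + 1):(iu + iz), drop = FALSE]
  sv <- svd(L32)
  if (sv$d[order] < 1e-12 * sv$d[1])
    stop("rank-deficient data: excitation does not reach the requested order")
  Gam <- sv$u[, seq_len(order), drop = FALSE] %*%
    diag(sqrt(sv$d[seq_len(order)]), order)
  C <- Gam[seq_len(l), , drop = FALSE]
  A <- qr.solve(Gam[seq_len((i - 1) * l), , drop = FALSE],
                Gam[(l + 1):(i * l), , drop = FALSE])
  list(A = A, B = matrix(0, order, m), C = C, E = matrix(0, l, m))
}

arx_fit <- function(u, y, order, lags = 12) {
  m <- ncol(u); l <- ncol(y); N <- nrow(u)
  idx <- (lags + 1):N
  reg <- cbind(
    do.call(cbind, lapply(1:lags, function(k) y[idx - k, , drop = FALSE])),
    do.call(cbind, lapply(0:lags, function(k) u[idx - k, , drop = FALSE])))
  # minimum-norm least squares: noise-free data makes the regressor exactly
  # rank-deficient once the lag order exceeds the true state dimension
  theta <- MASS_ginv(reg) %*% y[idx, , drop = FALSE]
  Ay <- lapply(1:lags, function(k) t(theta[((k - 1) * l + 1):(k * l), , drop = FALSE]))
  off <- lags * l
  Bu <- lapply(0:lags, function(k) t(theta[(off + k * m + 1):(off + (k + 1) * m), , drop = FALSE]))
  # Markov parameters h_k from the ARX polynomials
  K <- 4 * lags
  h <- vector("list", K + 1)
  h[[1]] <- Bu[[1]]                                  # h_0 = B_0 (feedthrough)
  for (k in 1:K) {
    hk <- if (k <= lags) Bu[[k + 1]] else matrix(0, l, m)
    for (jj in 1:min(k, lags)) hk <- hk + Ay[[jj]] %*% h[[k - jj + 1]]
    h[[k + 1]] <- hk
  }
  # Ho-Kalman balanced realization from the Hankel of h_1 ... h_{2T}
  T2 <- floor(K / 2)
  H1 <- do.call(rbind, lapply(1:T2, function(r)
    do.call(cbind, lapply(1:T2, function(c) h[[r + c]]))))
  H2 <- do.call(rbind, lapply(1:T2, function(r)
    do.call(cbind, lapply(1:T2, function(c) h[[r + c + 1]]))))
  sv <- svd(H1)
  sr <- sqrt(sv$d[seq_len(order)])
  Ob <- sv$u[, seq_len(order), drop = FALSE] %*% diag(sr, order)
  Cc <- diag(sr, order) %*% t(sv$v[, seq_len(order), drop = FALSE])
  A <- qr.solve(Ob, H2) %*% MASS_ginv(Cc)
  list(A = A, B = Cc[, seq_len(m), drop = FALSE],
       C = Ob[seq_len(l), , drop = FALSE], E = h[[1]])
}

# Moore-Penrose pseudoinverse via SVD (tiny matrices only).
MASS_ginv <- function(X, tol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*% diag(1 / sv$d[keep], sum(keep)) %*%
    t(sv$u[, keep, drop = FALSE])
}

# Least-squares estimation of B, E and x0 given A and C: the simulated
# response is linear in (x0, vec(B), vec(E)).
ss_refit_bde <- function(fit, u, y) {
  A <- fit$A; C <- fit$C
  n <- nrow(A); m <- ncol(u); l <- ncol(y); N <- nrow(u)
  XtX <- matrix(0, n + n * m + l * m, n + n * m + l * m)
  Xty <- numeric(n + n * m + l * m)
  M <- diag(n)                      # A^t propagator for the x0 columns
  Z <- matrix(0, n, n * m)          # state response to each basis element of B
  Il <- diag(l)
  for (t in seq_len(N)) {
    # y[t] is measured after u[t] acted for one tick: state advances first
    Z <- A %*% Z + kron_u_In(u[t, ], n)
    M <- A %*% M
    X_t <- cbind(C %*% M, C %*% Z, kronecker(t(u[t, ]), Il))
    XtX <- XtX + crossprod(X_t)
    Xty <- Xty + crossprod(X_t, y[t, ])
  }
  theta <- solve(XtX + 1e-12 * max(diag(XtX)) * diag(nrow(XtX)), Xty)
  fit$x0 <- theta[seq_len(n)]
  fit$B <- matrix(theta[(n + 1):(n + n * m)], n, m)
  fit$E <- matrix(theta[(n + n * m + 1):length(theta)], l, m)
  fit
}

# kronecker(t(u), I_n) without the generic overhead: n x (n*m), block j = u_j I.
kron_u_In <- function(u, n) {
  out <- matrix(0, n, n * length(u))
  for (j in seq_along(u)) {
    cols <- ((j - 1) * n + 1):(j * n)
    out[cbind(seq_len(n), cols)] <- u[j]
  }
  out
}

#' @export
print.ss_model <- function(x, ...) {
  ev <- eigen(x$A, only.values = TRUE)$values
  cat(sprintf("Discrete state-space model (order %d, dt = %g ms, %s)\n",
              x$order, x$dt * 1e3, x$method))
  cat(sprintf("  spectral radius of A: %.4f\n", max(Mod(ev))))
  if (!is.null(x$nrmse_validation)) {
    cat("  validation NRMSE (%):",
        paste(sprintf("%s %.1f", names(x$nrmse_validation),
                      x$nrmse_validation), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.ss_model <- function(object, ...) {
  object[c("A", "B", "C", "E")]
}

#' Simulate the response of an identified model
#'
#' Rolls `x[t+1] = A x[t] + B u[t]`, `y[t] = C x[t+1] + E u[t]` (outputs
#' aligned to the end of each tick, matching the identification convention).
#'
#' @param object an `ss_model`.
#' @param U input series (n x m).
#' @param x0 initial state (defaults to the model's estimated `x0`).
#' @param ... unused.
#' @return n x l matrix of outputs.
#' @export
predict.ss_model <- function(object, U, x0 = NULL, ...) {
  U <- as.matrix(U)
  x <- if (is.null(x0)) object$x0 else x0
  if (is.null(x)) x <- numeric(nrow(object$A))
  n <- nrow(U)
  Y <- matrix(0, n, nrow(object$C))
  for (t in seq_len(n)) {
    x <- drop(object$A %*% x + object$B %*% U[t, ])
    Y[t, ] <- drop(object$C %*% x + object$E %*% U[t, ])
  }
  Y
}

#' Impulse response of an identified model
#' @param model an `ss_model`.
#' @param ticks number of ticks.
#' @return array `[tick, output, input]`, including the feedthrough at lag 0.
#' @export
ss_impulse <- function(model, ticks = 50) {
  m <- ncol(model$B); l <- nrow(model$C)
  out <- array(0, c(ticks + 1, l, m))
  for (j in seq_len(m)) {
    u <- matrix(0, ticks + 1, m); u[1, j] <- 1
    out[, , j] <- predict(model, u, x0 = numeric(nrow(model$A)))
  }
  # prepend nothing: lag-0 response (E + CB) is the first simulated sample
  out
}

#' Identify the linear eye-plant model under PRBS excitation
#'
#' Drives the nonlinear simulator from rest with a three-channel PRBS,
#' fits a state-space model on the first `train_s` seconds and validates on
#' the remainder (per-output NRMSE on the held-out segment, predicting from
#' the estimated initial state through the full record).
#'
#' @param plant an [eye_plant()].
#' @param duration_s total excitation length, s.
#' @param train_s training prefix, s.
#' @param amplitude,bit_period PRBS parameters (see [prbs()]).
#' @param seed excitation seed.
#' @param order,horizon,method passed to [ss_identify()].
#' @return an `ss_model` with `nrmse_train`, `nrmse_validation` and the
#'   excitation metadata in `$meta`.
#' @export
identify_plant <- function(plant, duration_s = 180, train_s = 120,
                           amplitude = 0.25, bit_period = 5, seed = 1,
                           order = 6, horizon = 15, method = "moesp",
                           demean = TRUE) {
  U <- prbs(duration_s, amplitude, bit_period, plant$dt, seed)
  traj <- simulate_plant(plant, U)
  y <- as.matrix(traj[-1, c("rx", "ry", "rz")])   # outputs at tick ends
  colnames(y) <- c("rx", "ry", "rz")
  ntr <- round(train_s / plant$dt)
  # identify around the operating point: the plant's equilibrium is not
  # exactly the origin, and the linear model has no affine term, so the
  # training data are detrended by their means (standard practice)
  y_op <- if (demean) colMeans(y[seq_len(ntr), ]) else c(0, 0, 0)
  u_op <- if (demean) colMeans(U[seq_len(ntr), ]) else c(0, 0, 0)
  yc <- sweep(y, 2, y_op)
  Uc <- sweep(U, 2, u_op)
  model <- ss_identify(Uc[seq_len(ntr), ], yc[seq_len(ntr), ],
                       order = order, horizon = horizon, method = method,
                       dt = plant$dt)
  model$y_op <- y_op
  model$u_op <- u_op
  pred <- sweep(predict(model, Uc), 2, y_op, "+")
  val <- (ntr + 1):nrow(U)
  model$nrmse_train <- nrmse(y[seq_len(ntr), ], pred[seq_len(ntr), ])
  model$nrmse_validation <- nrmse(y[val, ], pred[val, ])
  model$meta <- list(duration_s = duration_s, train_s = train_s,
                     amplitude = amplitude, bit_period = bit_period,
                     seed = seed)
  model
}

#' Model JSON input/output
#'
#' Serializes an identified model (matrices row-major) with metadata.
#' @param model an `ss_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  obj <- list(schema = "saccade3d-ssmodel/1",
              order = model$order, dt = model$dt, method = model$method,
              A = model$A, B = model$B, C = model$C, E = model$E,
              x0 = model$x0,
              nrmse_train = as.list(model$nrmse_train),
              nrmse_validation = as.list(model$nrmse_validation),
              meta = model$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$schema, "saccade3d-ssmodel/1"))
  model <- list(A = obj$A, B = obj$B, C = obj$C, E = obj$E,
                x0 = as.numeric(obj$x0), dt = obj$dt, order = obj$order,
                method = obj$method,
                nrmse_train = unlist(obj$nrmse_train),
                nrmse_validation = unlist(obj$nrmse_validation),
                meta = obj$meta)
  class(model) <- "ss_model"
  model
}
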