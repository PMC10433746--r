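# Two-way orthogonal PLS (O2PLS) for a pair of sample-matched data blocks.
# Estimation follows the standard route: the joint subspace comes from the
# singular value decomposition of the cross-covariance t(X) %*% Y; per-block
# orthogonal (block-unique) variation is extracted from the residual of the
# joint fit and projected out of the block; the joint parts are then refit on
# the deflated blocks. With no orthogonal components the joint loadings are
# exactly the leading singular vectors of the cross-covariance.

#' Fit an O2PLS model to paired data blocks
#'
#' @param X,Y Numeric matrices, samples in rows (identical ids, identical
#'   order) and features in columns. Columns are mean-centered before fitting;
#'   set `scale. = TRUE` for unit-variance scaling as well.
#' @param n_joint Number of joint components (default 1; with six samples more
#'   components are barely identifiable).
#' @param n_orth_x,n_orth_y Numbers of block-orthogonal components for X and Y
#'   (default 0).
#' @param scale. Scale columns to unit variance after centering.
#' @return An `O2plsModel`: list with joint loadings `W` (X block) and `C`
#'   (Y block, both with unit-norm columns), joint scores `T` and `U`,
#'   orthogonal loadings/scores `W_orth`, `T_orth`, `P_orth` and `C_orth`,
#'   `U_orth`, `Q_orth`, inner-relation coefficients `B` (regression of U on
#'   T), the centering/scaling vectors, and fit metadata. The sign of each
#'   loading column is fixed deterministically: its largest-magnitude element
#'   is made positive.
#' @details The orthogonal step for the X block takes the residual
#'   `E = X - T W'`, finds the directions of `E` most covarying with the joint
#'   scores (SVD of `E'T`), and removes the resulting score subspace from `X`
#'   by orthogonal projection; symmetrically for Y. Because the refit joint
#'   loadings live in the orthocomplement of the removed directions, the
#'   joint, orthogonal and residual parts form an exact orthogonal
#'   decomposition of each centered block (see [variance_explained()]).
#' @export
fit_o2pls <- function(X, Y, n_joint = 1, n_orth_x = 0, n_orth_y = 0,
                      scale. = FALSE) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) {
    cry_abort("X and Y must have the same number of samples (rows)", "alignment")
  }
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
    !identical(rownames(X), rownames(Y))) {
    cry_abort("X and Y sample ids must match in order", "alignment")
  }
  if (!is_count(n_joint)) cry_abort("n_joint must be a positive integer", "domain")
  n <- nrow(X)
  if (n_joint + max(n_orth_x, n_orth_y) >= n) {
    cry_abort("n_joint plus orthogonal components must be below the sample count", "domain")
  }
  center_scale <- function(M) {
    mu <- colMeans(M)
    Mc <- sweep(M, 2, mu)
    sd <- rep(1, ncol(M))
    if (scale.) {
      sd <- apply(Mc, 2, stats::sd)
      if (any(sd == 0)) {
        cry_abort("cannot unit-variance scale a zero-variance column", "domain")
      }
      Mc <- sweep(Mc, 2, sd, "/")
    }
    list(M = Mc, center = mu, sd = sd)
  }
  xs <- center_scale(X)
  ys <- center_scale(Y)
  Xc <- xs$M
  Yc <- ys$M
  if (sum(Xc^2) == 0 || sum(Yc^2) == 0) {
    cry_abort("a data block has no variance", "domain")
  }
  rank_x <- qr(Xc)$rank
  rank_y <- qr(Yc)$rank
  if (n_joint + n_orth_x > rank_x || n_joint + n_orth_y > rank_y) {
    cry_abort(sprintf(
      "requested components exceed block rank (rank X = %d, rank Y = %d)",
      rank_x, rank_y
    ), "rank")
  }

  # Deterministic sign convention: largest-|.| element of each column positive.
  fix_signs <- function(L, S) {
    for (j in seq_len(ncol(L))) {
      i <- which.max(abs(L[, j]))
      if (L[i, j] < 0) {
        L[, j] <- -L[, j]
        S[, j] <- -S[, j]
      }
    }
    list(L = L, S = S)
  }
  joint_fit <- function(A, B) {
    sv <- svd(crossprod(A, B), nu = n_joint, nv = n_joint)
    list(W = sv$u, C = sv$v, d = sv$d[seq_len(n_joint)])
  }

  jf <- joint_fit(Xc, Yc)
  Tt <- Xc %*% jf$W
  U <- Yc %*% jf$C

  # Orthogonal (block-unique) variation: directions of the joint-fit residual
  # that covary with the own-block joint scores; the score subspace is then
  # projected out of the block.
  orth_step <- function(M, scores, W_joint, n_orth) {
    if (n_orth == 0) {
      return(list(
        M = M, W = matrix(0, ncol(M), 0), Tt = matrix(0, nrow(M), 0),
        P = matrix(0, ncol(M), 0)
      ))
    }
    E <- M - scores %*% t(W_joint)
    sv <- svd(crossprod(E, scores), nu = n_orth)
    W_o <- sv$u
    T_o <- M %*% W_o
    P_o <- crossprod(M, T_o) %*% solve(crossprod(T_o))
    M_def <- M - T_o %*% solve(crossprod(T_o)) %*% crossprod(T_o, M)
    list(M = M_def, W = W_o, Tt = T_o, P = P_o)
  }
  ox <- orth_step(Xc, Tt, jf$W, n_orth_x)
  oy <- orth_step(Yc, U, jf$C, n_orth_y)

  # Refit the joint parts on the deflated blocks.
  if (n_orth_x > 0 || n_orth_y > 0) jf <- joint_fit(ox$M, oy$M)
  W <- jf$W
  C <- jf$C
  Tt <- ox$M %*% W
  U <- oy$M %*% C
  fw <- fix_signs(W, Tt)
  W <- fw$L
  Tt <- fw$S
  fc <- fix_signs(C, U)
  C <- fc$L
  U <- fc$S
  dimnames(W) <- list(colnames(X), paste0("joint", seq_len(n_joint)))
  dimnames(C) <- list(colnames(Y), paste0("joint", seq_len(n_joint)))
  dimnames(Tt) <- list(rownames(X), colnames(W))
  dimnames(U) <- list(rownames(Y), colnames(C))
  B <- solve(crossprod(Tt), crossprod(Tt, U))

  structure(list(
    W = W, C = C, T = Tt, U = U, B = B,
    W_orth = ox$W, T_orth = ox$Tt, P_orth = ox$P,
    C_orth = oy$W, U_orth = oy$Tt, Q_orth = oy$P,
    x_center = xs$center, y_center = ys$center,
    x_scale = xs$sd, y_scale = ys$sd,
    n_joint = n_joint, n_orth_x = n_orth_x, n_orth_y = n_orth_y,
    scaled = scale., singular_values = jf$d,
    meta = list(
      n_samples = n,
      sign_convention = "largest-|loading| element positive",
      scaling = if (scale.) "center + unit variance" else "center only"
    )
  ), class = "O2plsModel")
}

#' @export
print.O2plsModel <- function(x, ...) {
  cat(sprintf(
    "O2plsModel: %d joint, %d/%d orthogonal components over %d samples (%s)\n",
    x$n_joint, x$n_orth_x, x$n_orth_y, x$meta$n_samples, x$meta$scaling
  ))
  invisible(x)
}

#' Top joint-loading features per block
#'
#' Ranks the features of each block by their maximum absolute loading across
#' the joint components (ties broken lexicographically by feature id) and
#' returns the top `k` of each block: the integration candidates contributed
#' by the O2PLS screen.
#'
#' @param model A fitted [fit_o2pls()] model.
#' @param k Number of features per block (default 25). If `k` exceeds the
#'   feature count the full ranking is returned.
#' @return List with data frames `x` and `y`, each with columns `feature`,
#'   `loading` (the signed loading of the maximizing component), and
#'   `abs_loading`.
#' @export
top_joint_loadings <- function(model, k = 25) {
  stopifnot(inherits(model, "O2plsModel"))
  rank_block <- function(L) {
    a <- apply(abs(L), 1, max)
    j <- apply(abs(L), 1, which.max)
    signed <- L[cbind(seq_len(nrow(L)), j)]
    ord <- order(-a, rownames(L))
    utils::head(data.frame(
      feature = rownames(L)[ord], loading = signed[ord], abs_loading = a[ord],
      stringsAsFactors = FALSE, row.names = NULL
    ), k)
  }
  list(x = rank_block(model$W), y = rank_block(model$C))
}

#' Variance decomposition of an O2PLS fit
#'
#' Partitions the total sum of squares of each centered (and, if requested,
#' scaled) block into joint, orthogonal and residual parts. Because the three
#' parts are mutually orthogonal by construction, their R-squared values sum
#' to 1 per block.
#'
#' @param model A fitted [fit_o2pls()] model.
#' @param X,Y The original data blocks the model was fitted to.
#' @return Data frame with columns `block`, `part`, `r2`.
#' @export
variance_explained <- function(model, X, Y) {
  stopifnot(inherits(model, "O2plsModel"))
  prep <- function(M, center, sd) sweep(sweep(as.matrix(M), 2, center), 2, sd, "/")
  Xc <- prep(X, model$x_center, model$x_scale)
  Yc <- prep(Y, model$y_center, model$y_scale)
  part_r2 <- function(M, Tt, W, T_o) {
    tot <- sum(M^2)
    if (tot == 0) cry_abort("a data block has no variance", "domain")
    joint <- sum((Tt %*% t(W))^2) / tot
    orth <- if (ncol(T_o) > 0) {
      sum((T_o %*% solve(crossprod(T_o)) %*% crossprod(T_o, M))^2) / tot
    } else {
      0
    }
    resid <- sum((M - Tt %*% t(W) -
      (if (ncol(T_o) > 0) T_o %*% solve(crossprod(T_o)) %*% crossprod(T_o, M) else 0))^2) / tot
    c(joint = joint, orthogonal = orth, residual = resid)
  }
  rx <- part_r2(Xc, model$T, model$W, model$T_orth)
  ry <- part_r2(Yc, model$U, model$C, model$U_orth)
  data.frame(
    block = rep(c("X", "Y"), each = 3),
    part = rep(c("joint", "orthogonal", "residual"), 2),
    r2 = c(rx, ry), stringsAsFactors = FALSE
  )
}
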