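#' Autoscale a data matrix
#'
#' Centers every column to mean zero and scales to unit standard deviation
#' (n - 1 denominator). Constant columns cannot be scaled and are dropped
#' with a warning.
#'
#' @param X numeric matrix or data frame (rows = samples).
#' @return autoscaled matrix; attributes `center`, `scale`, `dropped`.
#' @export
autoscale <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("autoscaling needs at least two rows")
  sds <- apply(X, 2, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
  }
  Xk <- X[, !drop, drop = FALSE]
  out <- scale(Xk)
  attr(out, "center") <- attr(out, "scaled:center")
  attr(out, "scale") <- attr(out, "scaled:scale")
  attr(out, "dropped") <- colnames(X)[drop]
  out
}

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis,
#' NIPALS-style: `n_orth` y-orthogonal components are estimated and removed
#' from `X`, then a single predictive PLS component is fitted on the
#' deflated matrix. R2X/R2Y are reconstruction fractions; Q2 is estimated
#' by stratified k-fold cross-validation of the class prediction.
#'
#' @param X autoscaled predictor matrix (use [autoscale()]).
#' @param y two-class factor/character/numeric vector.
#' @param n_orth number of orthogonal components (default 1).
#' @param cv_folds cross-validation folds for Q2 (default 7).
#' @param seed integer seed for the CV fold assignment.
#' @return object of class `oplsda`: predictive scores `t`, loadings `p`,
#'   weights `w`, regression coefficient `c`, orthogonal `T_o`, `P_o`,
#'   `W_o`, `R2X`, `R2Y`, `Q2`, class labels and encoding.
#' @export
oplsda_fit <- function(X, y, n_orth = 1, cv_folds = 7, seed = 1L) {
  X <- as.matrix(X)
  classes <- sort(unique(as.character(y)))
  if (length(classes) != 2) stop("OPLS-DA requires exactly two classes")
  if (min(table(y)) < 3) stop("need at least 3 samples per class")
  if (n_orth >= qr(X)$rank) stop("n_orth must be below the rank of X")
  yv <- ifelse(as.character(y) == classes[2], 1, -1)
  yc <- yv - mean(yv)
  fit <- .opls_core(X, yc, n_orth)
  ssx <- sum(X^2); ssy <- sum(yc^2)
  R2X <- (sum((fit$t %*% t(fit$p))^2) +
            if (n_orth > 0) sum((fit$T_o %*% t(fit$P_o))^2) else 0) / ssx
  R2Y <- 1 - sum((yc - fit$t * fit$c)^2) / ssy
  # stratified k-fold CV for Q2
  set.seed(seed)
  fold <- integer(length(yv))
  for (cl in classes) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
  }
  press <- 0
  for (f in seq_len(cv_folds)) {
    tr <- fold != f; te <- !tr
    if (sum(te) == 0 || length(unique(y[tr])) < 2) next
    ytr <- yv[tr] - mean(yv[tr])
    ft <- .opls_core(X[tr, , drop = FALSE], ytr, n_orth)
    yhat <- .opls_predict_core(ft, X[te, , drop = FALSE]) + mean(yv[tr])
    press <- press + sum((yv[te] - yhat)^2)
  }
  Q2 <- 1 - press / sum((yv - mean(yv))^2)
  structure(list(t = fit$t, p = fit$p, w = fit$w, c = fit$c,
                 T_o = fit$T_o, P_o = fit$P_o, W_o = fit$W_o,
                 n_orth = n_orth, R2X = R2X, R2Y = R2Y, Q2 = Q2,
                 classes = classes, y = yv, var_names = colnames(X)),
            class = "oplsda")
}

# core OPLS estimation on centered y
.opls_core <- function(X, yc, n_orth) {
  T_o <- NULL; P_o <- NULL; W_o <- NULL
  Xd <- X
  for (a in seq_len(n_orth)) {
    w <- as.numeric(crossprod(Xd, yc)); w <- w / sqrt(sum(w^2))
    t_ <- as.numeric(Xd %*% w)
    p_ <- as.numeric(crossprod(Xd, t_)) / sum(t_^2)
    w_o <- p_ - sum(w * p_) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break
    w_o <- w_o / nrm
    t_o <- as.numeric(Xd %*% w_o)
    p_o <- as.numeric(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - t_o %*% t(p_o)
    T_o <- cbind(T_o, t_o); P_o <- cbind(P_o, p_o); W_o <- cbind(W_o, w_o)
  }
  w <- as.numeric(crossprod(Xd, yc)); w <- w / sqrt(sum(w^2))
  t_ <- as.numeric(Xd %*% w)
  p_ <- as.numeric(crossprod(Xd, t_)) / sum(t_^2)
  c_ <- sum(yc * t_) / sum(t_^2)
  list(w = w, t = t_, p = p_, c = c_, T_o = T_o, P_o = P_o, W_o = W_o)
}

.opls_predict_core <- function(fit, Xnew) {
  Xd <- Xnew
  if (!is.null(fit$W_o)) {
    for (a in seq_len(ncol(fit$W_o))) {
      t_o <- as.numeric(Xd %*% fit$W_o[, a])
      Xd <- Xd - t_o %*% t(fit$P_o[, a])
    }
  }
  as.numeric(Xd %*% fit$w) * fit$c
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("OPLS-DA (%s vs %s): 1 predictive + %d orthogonal component(s)\n",
              x$classes[1], x$classes[2], x$n_orth))
  cat(sprintf("  R2X %.3f | R2Y %.3f | Q2 %.3f\n", x$R2X, x$R2Y, x$Q2))
  invisible(x)
}

#' @export
predict.oplsda <- function(object, newdata, ...) {
  sc <- .opls_predict_core(object, as.matrix(newdata))
  cls <- object$classes[ifelse(sc + mean(object$y) > 0, 2, 1)]
  data.frame(score = sc, class = cls, stringsAsFactors = FALSE)
}

#' Variable importance in projection (VIP) scores
#'
#' VIP over the predictive component(s):
#' `VIP_j = sqrt(p * sum_a(SSY_a w_aj^2) / sum_a SSY_a)` with normalized
#' weight vectors, so `sum(VIP^2) = p` (the number of variables).
#'
#' @param model a fitted [oplsda_fit()] model.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "oplsda")) stop("model must be a fitted oplsda object")
  w <- model$w / sqrt(sum(model$w^2))
  p <- length(w)
  vip <- sqrt(p * w^2)
  names(vip) <- model$var_names
  vip
}
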