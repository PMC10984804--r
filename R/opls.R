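#' Fit an OPLS regression model
#'
#' Orthogonal projections to latent structures with a single predictive
#' component and `n_ortho` orthogonal (response-uncorrelated) components.
#' Predictors are centered and unit-variance scaled, the response centered.
#' The predictive weight vector is `w = X'y / ||X'y||`; each orthogonal
#' component removes from X the part of the loading `p* = X't/(t't)` that is
#' orthogonal to `w` (`w_o = p* - (w'p*) w`, normalized), deflating
#' `X <- X - t_o p_o'`. The final predictive score is `t = X w` with the
#' regression coefficient `b = t'y / (t't)`.
#'
#' @param X numeric matrix, samples x predictors (>= 5 samples). Constant
#'   predictors are dropped with a warning.
#' @param y numeric response with nonzero variance.
#' @param n_ortho number of orthogonal components (default 1; 0 reduces the
#'   model to single-component PLS1).
#' @return an `xt_opls` object holding the weights (`w`), loadings
#'   (`p_load`), scores (`scores`), coefficient `b`, orthogonal blocks
#'   (`W_o`, `P_o`, `T_o`), centering/scaling vectors, `r2x`, `r2y`, `vip`
#'   and fitted values.
#' @references Trygg J, Wold S (2002). Orthogonal projections to latent
#'   structures (O-PLS). Journal of Chemometrics 16:119-128.
#' @seealso [fit_oplsda()], [opls_cv()], [opls_vip()]
#' @export
fit_opls <- function(X, y, n_ortho = 1L) {
  X <- as.matrix(X)
  .assert(nrow(X) >= 5, "need at least 5 samples")
  .assert(length(y) == nrow(X), "length(y) must match nrow(X)")
  .assert(n_ortho >= 0, "`n_ortho` must be >= 0")
  if (var(y) == 0) stop("`y` has zero variance", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- sprintf("X%d", seq_len(ncol(X)))
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning(length(dropped), " constant predictor(s) dropped")
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  p <- ncol(X)
  .assert(p >= 1, "no variable predictors left")
  mx <- colMeans(X)
  Xs <- sweep(sweep(X, 2, mx), 2, sds, "/")
  my <- mean(y)
  yc <- y - my

  w <- drop(crossprod(Xs, yc))
  wn <- sqrt(sum(w^2))
  if (wn < 1e-12) stop("X'y is numerically zero; no predictive direction", call. = FALSE)
  w <- w / wn

  W_o <- P_o <- matrix(0, p, 0)
  T_o <- matrix(0, nrow(X), 0)
  Xd <- Xs
  for (j in seq_len(n_ortho)) {
    tt <- drop(Xd %*% w)
    pstar <- drop(crossprod(Xd, tt)) / sum(tt^2)
    wo <- pstar - sum(w * pstar) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) {
      stop("n_ortho exceeds the orthogonal rank of X", call. = FALSE)
    }
    wo <- wo / nwo
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    W_o <- cbind(W_o, wo)
    P_o <- cbind(P_o, po)
    T_o <- cbind(T_o, to)
  }
  scores <- drop(Xd %*% w)
  b <- sum(scores * yc) / sum(scores^2)
  p_load <- drop(crossprod(Xd, scores)) / sum(scores^2)
  fitted <- b * scores + my
  r2y <- 1 - sum((y - fitted)^2) / sum(yc^2)
  ssx <- sum(Xs^2)
  r2x <- (sum(tcrossprod(scores, p_load)^2) +
            if (ncol(T_o)) sum((T_o %*% t(P_o))^2) else 0) / ssx
  vip <- sqrt(p) * abs(w)
  names(vip) <- names(w) <- names(p_load) <- colnames(X)
  structure(list(
    predictor_ids = colnames(X), dropped = dropped,
    center = mx, scale = sds, y_center = my,
    w = w, p_load = p_load, scores = scores, b = b,
    W_o = W_o, P_o = P_o, T_o = T_o, n_ortho = as.integer(n_ortho),
    r2x = r2x, r2y = r2y, vip = vip, fitted = fitted,
    is_discriminant = FALSE
  ), class = "xt_opls")
}

#' @export
print.xt_opls <- function(x, ...) {
  cat(sprintf("<xt_opls%s>: %d predictors, %d orthogonal component(s), R2Y = %.3f, R2X = %.3f\n",
              if (x$is_discriminant) "-DA" else "", length(x$w), x$n_ortho,
              x$r2y, x$r2x))
  invisible(x)
}

#' Predict from an OPLS model
#'
#' Applies the training centering/scaling, removes the orthogonal components
#' sequentially, and returns either predicted responses or predictive scores.
#'
#' @param object an `xt_opls` model.
#' @param newdata samples x predictors matrix containing the model's
#'   predictors.
#' @param type `"response"` (default) or `"score"`.
#' @param ... unused.
#' @export
predict.xt_opls <- function(object, newdata, type = c("response", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (is.null(colnames(X))) colnames(X) <- sprintf("X%d", seq_len(ncol(X)))
  X <- X[, object$predictor_ids, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  for (j in seq_len(object$n_ortho)) {
    to <- drop(Xs %*% object$W_o[, j])
    Xs <- Xs - tcrossprod(to, object$P_o[, j])
  }
  scores <- drop(Xs %*% object$w)
  if (type == "score") return(scores)
  object$b * scores + object$y_center
}

#' Variable importance in projection
#'
#' For the single predictive component, `VIP_j = sqrt(p) * |w_j| / ||w||`
#' (with `||w|| = 1`), so the squared VIPs always average to 1 and VIP > 1
#' marks predictors of above-average importance.
#'
#' @param model an `xt_opls` model.
#' @return named numeric vector of VIP scores.
#' @export
opls_vip <- function(model) {
  .assert(inherits(model, "xt_opls"), "`model` must be an xt_opls")
  model$vip
}

#' Fit an OPLS-DA model for a binary class response
#'
#' Encodes the two classes as a centered 0/1 dummy response and delegates to
#' [fit_opls()]. The fitted predictive score is the classification score used
#' for ROC analysis.
#'
#' @inheritParams fit_opls
#' @param class_labels binary class vector (factor, logical or two-valued);
#'   each class must have at least 3 samples.
#' @return an `xt_opls` with `is_discriminant = TRUE`, `classes` (the two
#'   levels; the second is the positive class) and `labels`.
#' @export
fit_oplsda <- function(X, class_labels, n_ortho = 1L) {
  f <- factor(class_labels)
  .assert(nlevels(f) == 2, "class_labels must have exactly 2 classes")
  .assert(all(table(f) >= 3), "each class needs at least 3 samples")
  y <- as.numeric(f == levels(f)[2])
  model <- fit_opls(X, y, n_ortho = n_ortho)
  model$is_discriminant <- TRUE
  model$classes <- levels(f)
  model$labels <- f
  model
}

#' Area under the ROC curve
#'
#' Mann-Whitney identity: the fraction of (positive, negative) pairs in which
#' the positive sample outscores the negative one, ties counted 1/2.
#'
#' @param scores numeric classification scores (higher = more positive).
#' @param labels binary labels; the second factor level (or `TRUE`, or the
#'   larger of two values) is the positive class.
#' @return list with `auroc`, `n_pos`, `n_neg`.
#' @export
auroc <- function(scores, labels) {
  f <- factor(labels)
  .assert(nlevels(f) == 2, "`labels` must contain exactly 2 classes")
  pos <- f == levels(f)[2]
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(auroc = auc, n_pos = n_pos, n_neg = n_neg)
}
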