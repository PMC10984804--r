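# Monte-Carlo cross-validation and permutation testing for OPLS models.

# Train-and-predict for many response columns at once. Xtr/Xte are already
# centered and scaled with training parameters; Ytr is column-centered.
# Each column of Ytr is an independent single-y OPLS model sharing Xtr.
# For n_ortho = 0 and n_ortho = 1 every step is expressible in matrix form;
# higher orders loop because the deflated X differs per response column.
.opls_multi_predict <- function(Xtr, Ytr, Xte, n_ortho) {
  .assert(n_ortho <= 1L, "vectorized path supports n_ortho of 0 or 1")
  W <- crossprod(Xtr, Ytr)
  wn <- sqrt(colSums(W^2))
  wn[wn < 1e-12] <- 1
  W <- sweep(W, 2, wn, "/")
  if (n_ortho == 0L) {
    Tn <- Xtr %*% W
    Tne <- Xte %*% W
  } else {
    T1 <- Xtr %*% W
    ss_t <- colSums(T1^2)
    ss_t[ss_t < 1e-24] <- 1
    Pstar <- sweep(crossprod(Xtr, T1), 2, ss_t, "/")
    cc <- colSums(W * Pstar)
    Wo <- Pstar - sweep(W, 2, cc, "*")
    nwo <- sqrt(colSums(Wo^2))
    ortho_ok <- nwo > 1e-10
    nwo[!ortho_ok] <- 1
    Wo <- sweep(Wo, 2, nwo, "/")
    Wo[, !ortho_ok] <- 0
    To <- Xtr %*% Wo
    ss_to <- colSums(To^2)
    ss_to[ss_to < 1e-24] <- 1
    Po <- sweep(crossprod(Xtr, To), 2, ss_to, "/")
    pw <- colSums(Po * W)
    Tn <- T1 - sweep(To, 2, pw, "*")
    Tne <- (Xte %*% W) - sweep(Xte %*% Wo, 2, pw, "*")
  }
  ss_tn <- colSums(Tn^2)
  ss_tn[ss_tn < 1e-24] <- 1
  b <- colSums(Tn * Ytr) / ss_tn
  sweep(Tne, 2, b, "*")
}

#' Monte-Carlo cross-validation with permutation q-value
#'
#' Repeatedly holds out a random fraction of samples, refits the OPLS model
#' on the remainder and predicts the holdout. The cross-validated predictive
#' R-squared is `Q2 = 1 - PRESS / TSS`, with the squared prediction error
#' (PRESS) and total sum of squares (against the training mean) aggregated
#' over all repeats. Significance is assessed by refitting under response
#' permutations with the identical holdout scheme: the q-value is the
#' add-one-smoothed fraction of permutations whose Q2 reaches the observed
#' one, `q = (1 + #\{Q2_perm >= Q2\}) / (1 + n_permutations)`.
#'
#' @param X samples x predictors matrix.
#' @param y numeric response (a 0/1 dummy for a discriminant model).
#' @param n_ortho orthogonal components in each refit (default 1).
#' @param n_repeats number of random holdouts (default 1000).
#' @param holdout_fraction fraction held out per repeat (default 1/7,
#'   at least 2 samples).
#' @param n_permutations response permutations for the q-value
#'   (default 1000).
#' @param seed integer seed; identical inputs and seed give identical
#'   results.
#' @return an `xt_cv` object: `q2`, `q_value`, `q2_null` summary (mean, sd,
#'   quantiles), `n_repeats`, `n_permutations`, `holdout_size`,
#'   `n_degenerate` (holdouts resampled because the training response was
#'   constant), `seed`.
#' @export
opls_cv <- function(X, y, n_ortho = 1L, n_repeats = 1000L,
                    holdout_fraction = 1 / 7, n_permutations = 1000L,
                    seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  .assert(length(y) == n, "length(y) must match nrow(X)")
  h <- max(2L, round(n * holdout_fraction))
  .assert(n - h >= 5, "too few samples left for training after holdout")
  .assert(n_ortho <= 1L, "opls_cv supports n_ortho of 0 or 1")
  .with_seed(seed, {
    perms <- vapply(seq_len(n_permutations), function(i) sample(y), numeric(n))
    Yall <- cbind(y, perms)
    press <- tss <- numeric(ncol(Yall))
    n_degenerate <- 0L
    for (rep in seq_len(n_repeats)) {
      repeat {
        te <- sample.int(n, h)
        if (sd(y[-te]) > 0) break
        n_degenerate <- n_degenerate + 1L
      }
      Xtr <- X[-te, , drop = FALSE]
      Xte <- X[te, , drop = FALSE]
      mx <- colMeans(Xtr)
      sx <- apply(Xtr, 2, sd)
      sx[sx == 0] <- 1 # constant-in-training predictors carry no signal
      Xtr <- sweep(sweep(Xtr, 2, mx), 2, sx, "/")
      Xte <- sweep(sweep(Xte, 2, mx), 2, sx, "/")
      my <- colMeans(Yall[-te, , drop = FALSE])
      Ytr <- sweep(Yall[-te, , drop = FALSE], 2, my)
      pred <- sweep(.opls_multi_predict(Xtr, Ytr, Xte, n_ortho), 2, my, "+")
      obs <- Yall[te, , drop = FALSE]
      press <- press + colSums((obs - pred)^2)
      tss <- tss + colSums(sweep(obs, 2, my)^2)
    }
    q2_all <- 1 - press / tss
    q2 <- q2_all[1]
    q2_null <- q2_all[-1]
    q_value <- (1 + sum(q2_null >= q2)) / (1 + n_permutations)
    structure(list(
      q2 = unname(q2),
      q_value = q_value,
      q2_null = list(mean = mean(q2_null), sd = sd(q2_null),
                     quantiles = quantile(q2_null, c(0.025, 0.5, 0.975))),
      n_repeats = as.integer(n_repeats),
      n_permutations = as.integer(n_permutations),
      holdout_size = h,
      n_degenerate = n_degenerate,
      seed = as.integer(seed)
    ), class = "xt_cv")
  })
}

#' @export
print.xt_cv <- function(x, ...) {
  cat(sprintf("<xt_cv>: Q2 = %.3f over %d holdouts; permutation q-value = %.4g (%d permutations)\n",
              x$q2, x$n_repeats, x$q_value, x$n_permutations))
  invisible(x)
}
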