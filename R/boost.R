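## Component-wise gradient boosting with penalized least-squares base
## learners.  Each iteration fits every learner to the negative gradient of
## the loss, selects the one with the smallest residual sum of squares and
## adds a small multiple (the step size) of its fit to the model.  The
## stopping iteration is chosen by cross-validation over observational
## units, which is the only source of randomness.

#' Construct a penalized least-squares base learner
#'
#' The ridge amount is calibrated so the effective degrees of freedom (trace
#' of the smoother matrix `X (X'X + lambda P)^{-1} X'`) equal `df`; an
#' unpenalized learner (`penalty = NULL`) has df equal to its column count.
#'
#' @param X design matrix for the fitting rows.
#' @param penalty positive semidefinite penalty matrix, or `NULL`.
#' @param df target effective degrees of freedom (ignored when
#'   `penalty = NULL`).
#' @param name learner label.
#' @return An object of class `base_learner`.
#' @export
base_learner <- function(X, penalty = NULL, df = NULL, name = "learner") {
  X <- as.matrix(X)
  p <- ncol(X)
  XtX <- crossprod(X)
  if (is.null(penalty)) {
    lambda <- 0
    K <- XtX + diag(1e-10 * mean(diag(XtX)), p)
    edf <- p
  } else {
    stopifnot(!is.null(df), nrow(penalty) == p, ncol(penalty) == p)
    # eigenvalue form: trace(lambda) = sum_i 1 / (1 + lambda * e_i) with
    # e_i the eigenvalues of R^-T P R^-1, X'X = R'R (tiny ridge keeps R
    # well defined for degenerate designs)
    ridge <- diag(1e-8 * mean(diag(XtX)), p)
    R <- chol(XtX + ridge)
    A <- backsolve(R, t(backsolve(R, t(penalty), transpose = TRUE)),
                   transpose = TRUE)
    e <- pmax(eigen((A + t(A)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values, 0)
    null_dim <- sum(e < 1e-10)
    if (df >= p)
      stop(sprintf("df target %.1f unreachable (penalty null space %d, basis %d)",
                   df, null_dim, p))
    trace_fun <- function(loglam) sum(1 / (1 + 10^loglam * e)) - df
    if (trace_fun(-12) < 0) {
      # degenerate design: the target df exceeds the information in X even
      # at a vanishing penalty; use the weakest penalty instead
      lambda <- 1e-12
    } else if (df <= null_dim) {
      stop(sprintf("df target %.1f unreachable (penalty null space %d, basis %d)",
                   df, null_dim, p))
    } else {
      lambda <- 10^uniroot(trace_fun, c(-12, 12), tol = 1e-10)$root
    }
    K <- XtX + lambda * penalty + ridge
    edf <- sum(1 / (1 + lambda * e))
  }
  structure(list(X = X, K_chol = chol(K), lambda = lambda, df = edf,
                 penalty = penalty, name = name),
            class = "base_learner")
}

## Penalized LS coefficients of a learner fitted to working response u on
## rows `rows` (K_chol must match those rows)
learner_solve <- function(chol_K, Xt_u) {
  backsolve(chol_K, backsolve(chol_K, Xt_u, transpose = TRUE))
}

## Cubic P-spline learner: B-spline basis with equispaced interior knots and
## a second-order difference penalty on the coefficients.
pspline_learner <- function(x, n_knots, df, degree = 3L,
                            boundary = range(x), name = "pspline") {
  knots <- seq(boundary[1L], boundary[2L],
               length.out = n_knots + 2L)[-c(1L, n_knots + 2L)]
  B <- bspline_design(x, knots, degree, boundary)
  D <- diff(diag(ncol(B)), differences = 2L)
  base_learner(B, crossprod(D), df = df, name = name)
}

#' Component-wise gradient boosting
#'
#' @param y response vector.
#' @param learners list of [base_learner()]s built on the fitting rows.
#' @param family `"poisson"` (log link, negative log-likelihood loss) or
#'   `"gaussian"` (squared error).
#' @param nu step size.
#' @param mstop number of boosting iterations.
#' @param offset optional starting fit; defaults to the loss-minimizing
#'   constant.
#' @return An object of class `boost_fit`: per-learner aggregated
#'   coefficients (`$coef`), selection sequence, training loss per
#'   iteration (non-increasing), the final linear predictor `$f` and the
#'   constant `$f0`.
#' @export
boost <- function(y, learners, family = c("poisson", "gaussian"),
                  nu = 0.1, mstop = 100L, offset = NULL) {
  family <- match.arg(family)
  stopifnot(length(learners) >= 1L)
  n <- length(y)
  if (n == 0L) stop("empty data")
  for (l in learners) stopifnot(nrow(l$X) == n)
  f0 <- if (is.null(offset)) {
    if (family == "poisson") log(max(mean(y), 1e-12)) else mean(y)
  } else offset
  f <- rep(f0, n)
  loss_fun <- if (family == "poisson") {
    function(f) sum(exp(f) - y * f)
  } else function(f) 0.5 * sum((y - f)^2)
  # Poisson gradient is scaled by the baseline Fisher weight exp(f0), so a
  # step acts on the log-link scale regardless of the count level (raw
  # response-scale gradients make the fixed step size unstable for large
  # means); the stationary point is unchanged
  w0 <- if (family == "poisson") exp(f0) else 1
  grad_fun <- if (family == "poisson") {
    function(f) (y - exp(f)) / w0
  } else function(f) y - f
  coefs <- lapply(learners, function(l) numeric(ncol(l$X)))
  names(coefs) <- vapply(learners, `[[`, character(1L), "name")
  selected <- integer(mstop)
  losses <- numeric(mstop + 1L)
  losses[1L] <- loss_fun(f)
  if (!is.finite(losses[1L])) stop("non-finite loss at initialization")
  m <- 0L
  while (m < mstop) {
    m <- m + 1L
    u <- grad_fun(f)
    best <- NULL
    for (j in seq_along(learners)) {
      l <- learners[[j]]
      b <- learner_solve(l$K_chol, crossprod(l$X, u))
      pred <- drop(l$X %*% b)
      rss <- sum((u - pred)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(j = j, b = b, pred = pred, rss = rss)
    }
    coefs[[best$j]] <- coefs[[best$j]] + nu * drop(best$b)
    f <- f + nu * best$pred
    selected[m] <- best$j
    losses[m + 1L] <- loss_fun(f)
  }
  structure(list(coef = coefs, f = f, f0 = f0, selected = selected,
                 losses = losses, nu = nu, mstop = mstop, family = family),
            class = "boost_fit")
}

#' @export
print.boost_fit <- function(x, ...) {
  sel <- table(factor(x$selected, levels = seq_along(x$coef),
                      labels = names(x$coef)))
  cat(sprintf("<boost_fit: %s loss, %d iterations, step %.2f>\n",
              x$family, x$mstop, x$nu))
  cat("  selections:", paste(names(sel), sel, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Choose the stopping iteration by cross-validation
#'
#' Units (e.g. years or days) are randomly assigned to folds under the
#' seed; each fold's learners are re-solved on the training rows (with the
#' ridge amounts calibrated on the full data) and the held-out loss is
#' tracked at every iteration. The selected `mstop` minimizes the mean
#' held-out loss, and may be 0 (offset-only model).
#'
#' @param y response.
#' @param learners list of [base_learner()]s on all rows.
#' @param unit_id vector assigning each row to a cross-validation unit.
#' @param n_folds number of folds (capped at the number of units).
#' @param family,nu,mstop_max as in [boost()].
#' @param seed integer seed for the fold assignment.
#' @return A list with `mstop`, `cv_risk` (mean held-out loss per iteration
#'   count `0..mstop_max`) and `fold_id` per unit.
#' @export
cv_mstop <- function(y, learners, unit_id, n_folds = 10L,
                     family = c("poisson", "gaussian"), nu = 0.1,
                     mstop_max = 100L, seed = 1L) {
  family <- match.arg(family)
  units <- unique(unit_id)
  n_folds <- min(n_folds, length(units))
  fold_of_unit <- with_seed(seed,
    setNames(sample(rep_len(seq_len(n_folds), length(units))), units))
  fold_id <- fold_of_unit[as.character(unit_id)]
  loss_fun <- if (family == "poisson") {
    function(f, yy) sum(exp(f) - yy * f)
  } else function(f, yy) 0.5 * sum((yy - f)^2)
  grad_fun <- if (family == "poisson") {
    function(f, yy, w0) (yy - exp(f)) / w0
  } else function(f, yy, w0) yy - f
  risk <- matrix(0, n_folds, mstop_max + 1L)
  for (k in seq_len(n_folds)) {
    val <- which(fold_id == k)
    trn <- which(fold_id != k)
    yt <- y[trn]; yv <- y[val]
    # re-solve each learner on the training rows, keeping lambda fixed
    Xts <- lapply(learners, function(l) l$X[trn, , drop = FALSE])
    Xvs <- lapply(learners, function(l) l$X[val, , drop = FALSE])
    chols <- lapply(seq_along(learners), function(j) {
      XtX <- crossprod(Xts[[j]])
      K <- XtX + diag(1e-8 * mean(diag(XtX)), ncol(XtX))
      if (!is.null(learners[[j]]$penalty))
        K <- K + learners[[j]]$lambda * learners[[j]]$penalty
      chol(K)
    })
    f0 <- if (family == "poisson") log(max(mean(yt), 1e-12)) else mean(yt)
    w0 <- if (family == "poisson") exp(f0) else 1
    ft <- rep(f0, length(trn)); fv <- rep(f0, length(val))
    risk[k, 1L] <- loss_fun(fv, yv)
    for (m in seq_len(mstop_max)) {
      u <- grad_fun(ft, yt, w0)
      best <- NULL
      for (j in seq_along(learners)) {
        b <- learner_solve(chols[[j]], crossprod(Xts[[j]], u))
        pred <- drop(Xts[[j]] %*% b)
        rss <- sum((u - pred)^2)
        if (is.null(best) || rss < best$rss)
          best <- list(j = j, b = b, pred = pred, rss = rss)
      }
      ft <- ft + nu * best$pred
      fv <- fv + nu * drop(Xvs[[best$j]] %*% best$b)
      risk[k, m + 1L] <- loss_fun(fv, yv)
    }
  }
  cv_risk <- colMeans(risk / tabulate(fold_id, n_folds))
  list(mstop = which.min(cv_risk) - 1L, cv_risk = cv_risk,
       fold_id = fold_id)
}
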