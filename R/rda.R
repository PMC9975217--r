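# Redundancy analysis of component abundances on environmental variables.
# RDA is the PCA of the fitted values of the multivariate regression of
# the (column-centred) community matrix Y on the (centred, standardized)
# explanatory matrix X. Significance is assessed by permuting the rows of
# Y and comparing pseudo-F statistics.

#' Fit a redundancy analysis
#'
#' Rows of `X` or `Y` with missing values are dropped from both matrices
#' (complete-case analysis). `Y` columns are centred; `X` columns are
#' centred and scaled to unit variance, so the fit is invariant to the
#' measurement units of the explanatory variables. Fitted values are
#' `Yhat = X (X'X)^-1 X' Y`; the singular value decomposition of `Yhat`
#' gives the canonical axes.
#'
#' @param Y Community matrix, samples x components (response).
#' @param X Environmental matrix, samples x variables (explanatory).
#' @param hellinger Apply the Hellinger transform (square root of
#'   row-normalized abundances) to `Y` before centring?
#' @return Object of class `"rda_fit"`: list with
#'   `constrained_proportion`, `axis_proportions`, `site_scores`,
#'   `variable_scores`, `pseudo_F`, `eig`, plus the processed matrices
#'   (`Yc`, `Xs`) and degrees of freedom used by [rda_anova()].
#' @export
rda_fit <- function(Y, X, hellinger = FALSE) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must have the same rows")
  cc <- stats::complete.cases(X) & stats::complete.cases(Y)
  Y <- Y[cc, , drop = FALSE]
  X <- X[cc, , drop = FALSE]
  n <- nrow(Y); q <- ncol(X)
  if (n <= q + 1L) stop("need more samples than explanatory variables")
  if (hellinger) {
    rs <- rowSums(Y)
    rs[rs == 0] <- 1
    Y <- sqrt(Y / rs)
  }
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    stop("constant explanatory column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  Xs <- scale(X)
  qrX <- qr(Xs)
  if (qrX$rank < q) {
    dep <- colnames(Xs)[qrX$pivot[(qrX$rank + 1L):q]]
    stop("collinear explanatory column(s): ", paste(dep, collapse = ", "))
  }
  Yhat <- qr.fitted(qrX, Yc)
  ss_tot <- sum(Yc^2)
  ss_fit <- sum(Yhat^2)
  sv <- svd(Yhat)
  keep <- sv$d > max(sv$d[1L], 1) * 1e-10
  d <- sv$d[keep]
  eig <- d^2 / (n - 1)
  axis_prop <- d^2 / ss_tot
  site_scores <- sv$u[, seq_along(d), drop = FALSE] %*% diag(d, length(d))
  var_scores <- crossprod(Xs, sv$u[, seq_along(d), drop = FALSE]) / (n - 1)
  rownames(site_scores) <- rownames(Y)
  rownames(var_scores) <- colnames(X)
  ss_res <- max(ss_tot - ss_fit, 0)
  pseudo_F <- (ss_fit / q) / (ss_res / (n - q - 1L))
  structure(list(constrained_proportion = min(ss_fit / ss_tot, 1),
                 axis_proportions = axis_prop,
                 site_scores = site_scores,
                 variable_scores = var_scores,
                 pseudo_F = pseudo_F, eig = eig,
                 Yc = Yc, Xs = Xs, n = n, q = q,
                 ss_tot = ss_tot, ss_fit = ss_fit),
            class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("Redundancy analysis:", x$n, "samples,", x$q,
      "explanatory variables\n")
  cat(sprintf("  constrained proportion: %.4f (pseudo-F = %.3f)\n",
              x$constrained_proportion, x$pseudo_F))
  cat("  axis proportions:",
      paste(sprintf("%.4f", utils::head(x$axis_proportions, 6L)),
            collapse = " "), "\n")
  invisible(x)
}

.rda_pseudo_F <- function(Yc, qrX, q, n) {
  Yhat <- qr.fitted(qrX, Yc)
  ss_fit <- sum(Yhat^2)
  ss_res <- max(sum(Yc^2) - ss_fit, 0)
  (ss_fit / q) / (ss_res / (n - q - 1L))
}

#' Permutation ANOVA for a redundancy analysis
#'
#' Global test: the observed pseudo-F
#' `F = (SS(Yhat)/q) / (SS(Y - Yhat)/(n - q - 1))` is compared against the
#' distribution obtained by permuting the rows of `Y`;
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`. Axis tests are
#' sequential: axis k is tested on the residual of `Y` after removing the
#' previous canonical axes, with the first canonical eigenvalue of each
#' permuted refit as the reference statistic.
#'
#' @param fit An `"rda_fit"` object.
#' @param n_perm Number of permutations (>= 99).
#' @param scope `"global"` for the overall test, `"axes"` to also test
#'   the first `n_axes` canonical axes.
#' @param n_axes Number of leading axes to test when `scope = "axes"`.
#' @return Named numeric vector of p-values (`global`, then `RDA1`, ...).
#' @export
rda_anova <- function(fit, n_perm = 999, scope = c("global", "axes"),
                      n_axes = 2L) {
  scope <- match.arg(scope)
  stopifnot(inherits(fit, "rda_fit"), n_perm >= 99)
  Yc <- fit$Yc; Xs <- fit$Xs; n <- fit$n; q <- fit$q
  qrX <- qr(Xs)
  F_obs <- fit$pseudo_F
  hits <- 0L
  for (b in seq_len(n_perm)) {
    Yp <- Yc[sample.int(n), , drop = FALSE]
    if (.rda_pseudo_F(Yp, qrX, q, n) >= F_obs) hits <- hits + 1L
  }
  p <- c(global = (1 + hits) / (1 + n_perm))
  if (scope == "axes") {
    n_axes <- min(n_axes, length(fit$eig))
    Yres <- Yc
    for (k in seq_len(n_axes)) {
      Yhat <- qr.fitted(qrX, Yres)
      sv <- svd(Yhat, nu = 1L, nv = 0L)
      lam_obs <- sv$d[1L]^2
      hits <- 0L
      for (b in seq_len(n_perm)) {
        Yp <- Yres[sample.int(n), , drop = FALSE]
        d1 <- svd(qr.fitted(qrX, Yp), nu = 0L, nv = 0L)$d[1L]
        if (d1^2 >= lam_obs) hits <- hits + 1L
      }
      p[paste0("RDA", k)] <- (1 + hits) / (1 + n_perm)
      # remove axis k before testing axis k + 1
      u1 <- svd(Yhat, nu = 1L, nv = 0L)$u
      Yres <- Yres - u1 %*% crossprod(u1, Yres)
    }
  }
  p
}

#' Forward selection of environmental variables for RDA
#'
#' Greedy forward selection: at each step the candidate variable adding
#' the most constrained variance is tested by permutation (partialling out
#' nothing beyond the current model refit); it enters the model when its
#' permutation p-value is below `alpha`, otherwise selection stops.
#'
#' @param Y Community matrix (samples x components).
#' @param X Environmental matrix (samples x variables).
#' @param alpha Entry significance level.
#' @param n_perm Permutations per entry test.
#' @return Character vector of selected variable names, in entry order
#'   (empty when no variable qualifies).
#' @export
forward_select_env <- function(Y, X, alpha = 0.05, n_perm = 199) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  cc <- stats::complete.cases(X) & stats::complete.cases(Y)
  Y <- Y[cc, , drop = FALSE]; X <- X[cc, , drop = FALSE]
  selected <- character(0)
  repeat {
    cand <- setdiff(colnames(X), selected)
    if (length(cand) == 0L) break
    gains <- vapply(cand, function(v) {
      cols <- c(selected, v)
      Xs <- X[, cols, drop = FALSE]
      if (qr(scale(Xs))$rank < length(cols)) return(-Inf)
      rda_fit(Y, Xs)$constrained_proportion
    }, 0)
    if (all(!is.finite(gains))) break
    best <- cand[which.max(gains)]
    # permutation test of the gain from adding `best`
    fit <- rda_fit(Y, X[, c(selected, best), drop = FALSE])
    base_prop <- if (length(selected))
      rda_fit(Y, X[, selected, drop = FALSE])$constrained_proportion
    else 0
    gain_obs <- fit$constrained_proportion - base_prop
    n <- nrow(Y)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      Yp <- Y[sample.int(n), , drop = FALSE]
      gp <- rda_fit(Yp, X[, c(selected, best), drop = FALSE])$constrained_proportion -
        (if (length(selected))
          rda_fit(Yp, X[, selected, drop = FALSE])$constrained_proportion
         else 0)
      if (gp >= gain_obs) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
    if (p < alpha) selected <- c(selected, best) else break
  }
  selected
}
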