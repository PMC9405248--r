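## Multi-marker panel selection: L1-penalised logistic regression over
## log2 ratio features, lambda chosen by stratified cross-validation, and
## an unpenalised refit of the selected signature for scoring.
##
## The penalised objective is  -loglik(b0, beta)/n + lambda * sum(|beta|),
## minimised by iteratively reweighted least squares with cyclic
## coordinate descent on the quadratic approximation (the intercept is
## unpenalised).  Columns are standardised internally; coefficients are
## reported on the standardised scale together with the centring/scaling
## used.

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

standardize_columns <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  Xc <- sweep(X, 2L, center, "-")
  if (is.null(scale)) scale <- sqrt(colMeans(Xc^2))
  scale[scale < 1e-12] <- 1
  list(X = sweep(Xc, 2L, scale, "/"), center = center, scale = scale)
}

#' Smallest penalty that zeroes every coefficient
#'
#' On standardised columns, `lambda_max = max_j |x_j' (y - mean(y))| / n`:
#' at any lambda at or above it the null model satisfies the KKT
#' conditions of the penalised logistic objective.
#'
#' @param X standardised design matrix (samples x features).
#' @param y binary 0/1 response.
#' @return the scalar entry point of the regularisation path.
#' @export
lambda_max <- function(X, y) {
  max(abs(crossprod(X, y - mean(y)))) / nrow(X)
}

#' L1-penalised logistic regression at a fixed penalty
#'
#' @param X numeric matrix, samples x features (log2 ratios); standardised
#'   internally unless `standardize = FALSE`.
#' @param y binary response (0/1 or logical).
#' @param lambda penalty >= 0.
#' @param standardize standardise columns internally.
#' @param tol convergence tolerance on the maximum KKT residual.
#' @param max_iter maximum outer (IRLS) iterations.
#' @param beta0,b0 optional warm start on the standardised scale.
#' @return list with `beta` (named, standardised scale), `intercept`,
#'   `lambda`, `center`, `scale`, `kkt` (maximum KKT residual),
#'   `selected` (feature names with non-zero coefficient), `converged`.
#' @export
lasso_logistic <- function(X, y, lambda, standardize = TRUE,
                           tol = 1e-8, max_iter = 500L,
                           beta0 = NULL, b0 = NULL) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y), lambda >= 0)
  if (all(y == 0) || all(y == 1)) {
    stop("both classes must be present", call. = FALSE)
  }
  std <- if (standardize) standardize_columns(X) else
    list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  Xs <- std$X
  n <- nrow(Xs); p <- ncol(Xs)
  beta <- if (is.null(beta0)) rep(0, p) else beta0
  b0 <- if (is.null(b0)) log(mean(y) / (1 - mean(y))) else b0
  eta <- drop(Xs %*% beta) + b0

  wmin <- 1e-5
  for (iter in seq_len(max_iter)) {
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), wmin)
    z <- eta + (y - mu) / w
    wx2 <- colSums(w * Xs^2) / n
    sw <- sum(w)
    r <- w * (z - eta)  # weighted working residual, maintained in place
    # coordinate descent on the weighted quadratic approximation; full
    # sweeps alternate with sweeps over the active set only
    cd_sweep <- function(js) {
      delta <- 0
      for (j in js) {
        xj <- Xs[, j]
        rho <- sum(xj * r) / n + wx2[j] * beta[j]
        a <- abs(rho) - lambda
        # the > 1e-14 guard keeps the exact entry point (|g| == lambda)
        # from producing float-dust coefficients
        bnew <- if (a > 1e-14) sign(rho) * a / wx2[j] else 0
        if (bnew != beta[j]) {
          r <<- r - (w * xj) * (bnew - beta[j])
          delta <- max(delta, abs(bnew - beta[j]))
          beta[j] <<- bnew
        }
      }
      shift <- sum(r) / sw
      r <<- r - w * shift
      b0 <<- b0 + shift
      max(delta, abs(shift))
    }
    for (cycle in 1:200) {
      d_full <- cd_sweep(seq_len(p))
      if (d_full < tol / 10) break
      active <- which(beta != 0)
      if (length(active)) {
        for (s2 in 1:1000) {
          if (cd_sweep(active) < tol / 10) break
        }
      }
    }
    eta <- z - r / w
    beta[abs(beta) < 1e-10] <- 0  # drop float dust from boundary updates
    res <- kkt_residual(Xs, y, beta, b0, lambda)
    if (res < tol) {
      names(beta) <- colnames(X)
      return(list(beta = beta, intercept = b0, lambda = lambda,
                  center = std$center, scale = std$scale, kkt = res,
                  selected = colnames(X)[beta != 0], converged = TRUE))
    }
  }
  stop("lasso_logistic failed to converge: lambda = ", lambda,
       ", final KKT residual = ", signif(kkt_residual(Xs, y, beta, b0,
                                                      lambda), 3),
       call. = FALSE)
}

#' Maximum KKT residual of a penalised logistic solution
#'
#' For active coordinates the stationarity residual is
#' `|g_j - lambda * sign(beta_j)|` with `g_j = x_j'(y - mu)/n`; for zero
#' coordinates it is `max(0, |g_j| - lambda)`; the intercept contributes
#' `|mean(y - mu)|`.
#'
#' @param X standardised design, `y` response, `beta`/`b0` solution,
#'   `lambda` penalty.
#' @return the maximum residual (0 at an exact optimum).
#' @export
kkt_residual <- function(X, y, beta, b0, lambda) {
  mu <- 1 / (1 + exp(-(drop(X %*% beta) + b0)))
  g <- drop(crossprod(X, y - mu)) / nrow(X)
  active <- beta != 0
  r_active <- if (any(active)) {
    max(abs(g[active] - lambda * sign(beta[active])))
  } else 0
  r_zero <- if (any(!active)) max(pmax(abs(g[!active]) - lambda, 0)) else 0
  max(r_active, r_zero, abs(mean(y - mu)))
}

make_stratified_folds <- function(y, nfolds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  fold
}

binomial_deviance <- function(y, prob) {
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(prob) + (1 - y) * log(1 - prob))
}

# fit the whole path at a lambda grid with warm starts (standardised X)
lasso_path <- function(Xs, y, lambdas, tol = 1e-8) {
  beta <- rep(0, ncol(Xs)); b0 <- NULL
  lapply(lambdas, function(l) {
    fit <- lasso_logistic(Xs, y, l, standardize = FALSE, tol = tol,
                          beta0 = beta, b0 = b0)
    beta <<- fit$beta; b0 <<- fit$intercept
    fit
  })
}

#' Choose the LASSO penalty by stratified cross-validation
#'
#' A log-spaced lambda grid descends from [lambda_max()]; per fold,
#' standardisation is computed on the training samples only and the path
#' is fitted with warm starts; held-out binomial deviance selects
#' `lambda_min` (its minimiser) and `lambda_1se` (the largest lambda
#' within one standard error of the minimum, the sparser conventional
#' choice used as the default downstream).
#'
#' @param X samples x features matrix (log2 ratios, unstandardised).
#' @param y binary response.
#' @param nlambda grid size.
#' @param lambda_min_ratio smallest grid lambda as a fraction of
#'   `lambda_max`.
#' @param nfolds stratified CV folds (>= 3).
#' @param seed integer seed (fold assignment).
#' @return list with `lambda_min`, `lambda_1se`, `grid`, `cvm`, `cvsd`,
#'   `nonzero` (selected-feature count along the grid on the full data).
#' @export
choose_lambda <- function(X, y, nlambda = 30L, lambda_min_ratio = 0.05,
                          nfolds = 5L, seed = 1L) {
  y <- as.numeric(y)
  if (nfolds < 3L) stop("nfolds must be >= 3", call. = FALSE)
  if (min(table(y)) < nfolds) {
    nfolds <- max(3L, min(table(y)))
  }
  std_all <- standardize_columns(X)
  lmax <- lambda_max(std_all$X, y)
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = nlambda))
  with_seed(seed, {
    fold <- make_stratified_folds(y, nfolds)
    # per-observation held-out deviance, as the reference CV convention
    devobs <- matrix(NA_real_, nrow = length(y), ncol = nlambda)
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      std <- standardize_columns(X[tr, , drop = FALSE])
      Xte <- standardize_columns(X[!tr, , drop = FALSE],
                                 center = std$center, scale = std$scale)$X
      fits <- lasso_path(std$X, y[tr], grid)
      for (k in seq_len(nlambda)) {
        eta <- drop(Xte %*% fits[[k]]$beta) + fits[[k]]$intercept
        prob <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
        devobs[!tr, k] <- -2 * (y[!tr] * log(prob) +
                                  (1 - y[!tr]) * log(1 - prob))
      }
    }
    cvm <- colMeans(devobs)
    cvsd <- sqrt(colMeans(sweep(devobs, 2L, cvm)^2) / (length(y) - 1))
    k_min <- which.min(cvm)
    within <- which(cvm <= cvm[k_min] + cvsd[k_min])
    k_1se <- min(within)  # grid descends from lambda_max
    full <- lasso_path(std_all$X, y, grid)
    list(lambda_min = grid[k_min], lambda_1se = grid[k_1se],
         grid = grid, cvm = cvm, cvsd = cvsd,
         nonzero = vapply(full, function(f) length(f$selected), integer(1)))
  })
}

# L2-stabilised logistic fit (used when the refit separates perfectly)
ridge_logistic <- function(X, y, lambda_ridge = 1e-6, max_iter = 100L) {
  X1 <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(X1))
  pen <- c(0, rep(lambda_ridge * nrow(X), ncol(X)))
  for (i in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1 * w, X1) + diag(pen, ncol(X1))
    g <- crossprod(X1, y - mu) - pen * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

#' Refit the selected signature and score the panel
#'
#' Unpenalised logistic regression on the selected features; the linear
#' predictor is the panel score and its ROC/AUC the panel performance.  A
#' perfectly separating refit falls back to a ridge-stabilised fit
#' (`lambda_ridge = 1e-6`) with a warning.
#'
#' @param X samples x features matrix (log2 ratios).
#' @param y binary response (logical or 0/1), TRUE/1 = positive class.
#' @param features selected feature names (>= 1).
#' @return object of class `panel_model`: list with `features`,
#'   `coefficients` (includes intercept), `scores` (per-sample linear
#'   predictor), `auc` (in-sample panel AUC), `roc`.
#' @export
refit_and_score <- function(X, y, features) {
  y <- as.numeric(y)
  if (length(features) < 1L) {
    stop("panel refit needs >= 1 selected feature", call. = FALSE)
  }
  Xp <- X[, features, drop = FALSE]
  fit <- suppressWarnings(glm(y ~ ., data = as.data.frame(Xp),
                              family = binomial()))
  separated <- !fit$converged || any(abs(coef(fit)) > 1e3) ||
    anyNA(coef(fit))
  if (separated) {
    warning("perfect separation in panel refit; ",
            "using ridge-stabilised coefficients")
    cf <- drop(ridge_logistic(as.matrix(Xp), y))
    names(cf) <- c("(Intercept)", features)
  } else {
    cf <- coef(fit)
    names(cf) <- c("(Intercept)", features)
  }
  scores <- drop(as.matrix(Xp) %*% cf[-1L]) + cf[1L]
  roc <- roc_auc(scores, y == 1)
  structure(list(features = features, coefficients = cf, scores = scores,
                 auc = roc$auc, roc = roc),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat("panel of", length(x$features), "feature(s), in-sample AUC",
      sprintf("%.3f", x$auc), "\n")
  invisible(x)
}

#' Fit a multi-marker panel for one comparison
#'
#' End-to-end: normalise, pick the reference feature, form log2 ratio
#' features, choose lambda by stratified CV, fit the LASSO, refit the
#' selected signature unpenalised, and additionally report a
#' cross-validated panel AUC (signature refitted within each fold; scores
#' pooled out of fold).  When the penalised fit selects nothing (a
#' realistic outcome on null cohorts) the panel is empty and AUCs are NA.
#'
#' @param m count matrix.
#' @param samples sample table.
#' @param comparison comparison name.
#' @param rule `"min"` (CV deviance minimiser, default) or `"1se"`
#'   (sparser) lambda rule.
#' @param seed integer seed.
#' @param reference_gene optional reference-feature override.
#' @param max_features cap on the number of candidate features entering
#'   the penalised fit; when exceeded, features are pre-screened by
#'   log-ratio variance (a label-blind filter, so downstream inference is
#'   not biased by outcome peeking).  isomiR-resolution matrices carry
#'   thousands of mostly-flat variants; the cap keeps the coordinate
#'   descent at interactive scale.
#' @return list with `panel` (a `panel_model` or NULL), `lambda`,
#'   `selected`, `auc_insample`, `auc_cv`, `reference_gene`, `comparison`.
#' @export
fit_panel <- function(m, samples, comparison, rule = c("min", "1se"),
                      seed = 1L, reference_gene = NULL,
                      max_features = 200L) {
  rule <- match.arg(rule)
  cs <- comparison_samples(samples, comparison)
  mf <- filter_expressed(m, cs$sample_id)[, cs$sample_id, drop = FALSE]
  sf <- size_factors(mf, type = "poscounts")
  z <- normalize_counts(mf, sf)
  ref_id <- if (is.null(reference_gene)) {
    select_reference_gene(z, cs$sample_id)
  } else {
    reference_gene
  }
  ratios <- ratio_features(z, ref_id)
  ratios <- ratios[rownames(ratios) != ref_id, , drop = FALSE]
  X <- t(log2(ratios))
  X <- X[, apply(X, 2L, sd) > 0, drop = FALSE]
  if (ncol(X) > max_features) {
    v <- apply(X, 2L, var)
    keep <- order(-v, colnames(X), method = "radix")[seq_len(max_features)]
    X <- X[, sort(keep), drop = FALSE]
  }
  y <- as.numeric(cs$label)

  cv <- choose_lambda(X, y, seed = derive_seed(seed, "cv"))
  lambda <- if (rule == "1se") cv$lambda_1se else cv$lambda_min
  std <- standardize_columns(X)
  fit <- lasso_logistic(std$X, y, lambda, standardize = FALSE)
  selected <- colnames(X)[fit$beta != 0]

  panel <- NULL; auc_in <- NA_real_; auc_cv <- NA_real_
  if (length(selected)) {
    panel <- refit_and_score(X, y, selected)
    auc_in <- panel$auc
    # out-of-fold AUC of the fixed signature
    auc_cv <- with_seed(derive_seed(seed, "cvauc"), {
      fold <- make_stratified_folds(y, 5L)
      scores <- rep(NA_real_, length(y))
      for (f in unique(fold)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L) next
        pm <- tryCatch(refit_and_score(X[tr, , drop = FALSE], y[tr],
                                       selected),
                       warning = function(w) suppressWarnings(
                         refit_and_score(X[tr, , drop = FALSE], y[tr],
                                         selected)))
        cf <- pm$coefficients
        scores[!tr] <- drop(X[!tr, selected, drop = FALSE] %*% cf[-1L]) +
          cf[1L]
      }
      if (anyNA(scores)) NA_real_ else roc_auc(scores, y == 1)$auc
    })
  }
  list(panel = panel, lambda = lambda, selected = selected,
       auc_insample = auc_in, auc_cv = auc_cv,
       reference_gene = ref_id, comparison = cs$comparison)
}
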