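#' Genomic relationship matrix
#'
#' Mean-imputes missing dosages, standardizes each marker as
#' `(x - 2p) / sqrt(2p(1-p))` with `p` the alt-allele frequency, and
#' returns `K = Z Z' / m` over the `m` polymorphic markers (the VanRaden
#' genomic relationship matrix). Monomorphic markers are skipped with a
#' message.
#'
#' @param g a [genotype_matrix()] with >= 2 accessions.
#' @return A symmetric positive semi-definite accession x accession matrix.
#' @export
compute_grm <- function(g) {
  stopifnot(n_accessions(g) >= 2)
  x <- impute_dosage(g$dosage)
  p <- colMeans(x) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic; cannot compute a GRM")
  if (any(!poly)) message(sum(!poly), " monomorphic marker(s) skipped")
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(x, 2, 2 * p, "-")
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  k <- tcrossprod(z) / ncol(z)
  dimnames(k) <- list(g$accessions, g$accessions)
  k
}

# Drop collinear design columns (keeps the first of each dependent set).
drop_collinear <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    message("dropped collinear fixed-effect column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

# REML criterion for V = tau*K + W^-1 (binary working model) given the
# working response z; returns -2 * restricted log-likelihood (to minimize).
reml_crit_general <- function(tau, K, Winv, X, z) {
  V <- tau * K
  diag(V) <- diag(V) + Winv
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  Vi_z <- backsolve(R, forwardsolve(t(R), z))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_z))
  r <- z - X %*% beta
  Vi_r <- backsolve(R, forwardsolve(t(R), r))
  ldV <- 2 * sum(log(diag(R)))
  ldX <- determinant(XtViX, logarithm = TRUE)$modulus
  as.numeric(ldV + ldX + crossprod(r, Vi_r))
}

#' Fit the null mixed model for association scanning
#'
#' Fits the no-marker ("null") model once so that per-marker score tests
#' can reuse its variance components. For a quantitative response this is
#' the standard Gaussian linear mixed model `y = X b + u + e` with
#' `u ~ N(0, tau K)`, fitted by restricted maximum likelihood via the
#' eigendecomposition of `K` (profile over the variance ratio). For a
#' binary response it is a logistic linear mixed model fitted by penalized
#' quasi-likelihood: iterate a working Gaussian LMM on the adjusted
#' response `z = eta + (y - mu)/W`, re-estimating `tau` by REML at each
#' step, until the linear predictor converges.
#'
#' The "quantitative" response applied to a 0/1 coding reproduces the
#' Gaussian-LMM fallback some pipelines use when the logistic conditional
#' model misbehaves.
#'
#' @param y numeric response vector; binary responses coded 0/1. `NA`s are
#'   excluded (together with the matching rows of `K` and covariates).
#' @param K genomic relationship matrix aligned with `y`.
#' @param covariates optional numeric matrix of fixed-effect covariates
#'   (an intercept is always included); collinear columns are dropped with
#'   a message.
#' @param response `"binary"` or `"quantitative"`.
#' @param tau_fixed optionally fix the polygenic variance `tau` instead of
#'   estimating it (e.g. `tau_fixed = 0` reduces the binary model to plain
#'   logistic regression).
#' @param tol convergence tolerance on the linear predictor. Default 1e-6.
#' @param maxit maximum PQL iterations. Default 100.
#' @return A `null_model` list: `response`, `X`, `beta`, `tau`, `sigma2`
#'   (quantitative), `P` (projection matrix of the working GLS problem),
#'   `Py` (projected working response, so a marker's score is `g' Py`),
#'   `keep` (indices of used observations), convergence info.
#' @export
fit_null_model <- function(y, K, covariates = NULL,
                           response = c("binary", "quantitative"),
                           tau_fixed = NULL, tol = 1e-6, maxit = 100) {
  response <- match.arg(response)
  y <- as.numeric(y)
  keep <- which(!is.na(y))
  if (length(keep) < 3) stop("need at least 3 non-missing phenotypes")
  yk <- y[keep]
  Kk <- K[keep, keep, drop = FALSE]
  n <- length(yk)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
    X <- cbind(X, covariates[keep, , drop = FALSE])
  }
  X <- drop_collinear(X)
  if (stats::var(yk) == 0) stop("response is constant")
  if (response == "binary" && !all(yk %in% c(0, 1))) {
    stop("binary response must be coded 0/1")
  }

  if (response == "quantitative") {
    eig <- eigen(Kk, symmetric = TRUE)
    U <- eig$vectors
    dvals <- pmax(eig$values, 0)
    yt <- crossprod(U, yk)
    Xt <- crossprod(U, X)
    p <- ncol(X)
    # -2 REML log-likelihood profiled in sigma2, as a function of
    # lambda = tau / sigma2
    crit <- function(log_lambda) {
      lam <- exp(log_lambda)
      v <- lam * dvals + 1
      w <- 1 / v
      XtWX <- crossprod(Xt, Xt * w)
      beta <- solve(XtWX, crossprod(Xt, yt * w))
      r <- yt - Xt %*% beta
      rss <- sum(w * r^2)
      s2 <- rss / (n - p)
      as.numeric((n - p) * log(s2) + sum(log(v)) +
                   determinant(XtWX, logarithm = TRUE)$modulus)
    }
    if (is.null(tau_fixed)) {
      opt <- stats::optimize(crit, c(log(1e-9), log(1e9)))
      lam <- exp(opt$minimum)
      # compare against the boundary lambda -> 0 (tau = 0)
      if (crit(log(1e-9)) <= opt$objective) lam <- 0
    } else {
      # tau fixed: solve lambda from tau = lambda * sigma2 by fixed point;
      # adequate for the common case tau_fixed = 0
      if (tau_fixed == 0) lam <- 0 else {
        lam <- stats::uniroot(function(ll) {
          l <- exp(ll); v <- l * dvals + 1; w <- 1 / v
          XtWX <- crossprod(Xt, Xt * w)
          beta <- solve(XtWX, crossprod(Xt, yt * w))
          r <- yt - Xt %*% beta
          s2 <- sum(w * r^2) / (n - p)
          l * s2 - tau_fixed
        }, c(log(1e-9), log(1e9)))$root
        lam <- exp(lam)
      }
    }
    v <- lam * dvals + 1
    w <- 1 / v
    XtWX <- crossprod(Xt, Xt * w)
    beta <- solve(XtWX, crossprod(Xt, yt * w))
    r <- yt - Xt %*% beta
    sigma2 <- sum(w * r^2) / (n - p)
    tau <- lam * sigma2
    # P on the original scale, scaled by 1/sigma2 so score variance is right
    Vi <- U %*% (t(U) * w) / sigma2
    P <- Vi - Vi %*% X %*% solve(crossprod(X, Vi %*% X), crossprod(X, Vi))
    out <- list(response = response, X = X, beta = drop(beta), tau = tau,
                sigma2 = sigma2, P = P, Py = drop(P %*% yk), y = yk,
                keep = keep, converged = TRUE, n_iter = 1L)
  } else {
    mu <- (yk + 0.5) / 2
    eta <- stats::qlogis(mu)
    tau <- if (is.null(tau_fixed)) 0.5 else tau_fixed
    converged <- FALSE
    it <- 0
    while (it < maxit) {
      it <- it + 1
      W <- pmax(mu * (1 - mu), 1e-8)
      z <- eta + (yk - mu) / W
      Winv <- 1 / W
      if (is.null(tau_fixed)) {
        opt <- stats::optimize(function(lt) {
          reml_crit_general(exp(lt), Kk, Winv, X, z)
        }, c(log(1e-8), log(1e4)))
        tau <- exp(opt$minimum)
        if (reml_crit_general(0, Kk, Winv, X, z) <= opt$objective) tau <- 0
      }
      V <- tau * Kk
      diag(V) <- diag(V) + Winv
      R <- chol(V)
      Vi_X <- backsolve(R, forwardsolve(t(R), X))
      Vi_z <- backsolve(R, forwardsolve(t(R), z))
      XtViX <- crossprod(X, Vi_X)
      beta <- solve(XtViX, crossprod(X, Vi_z))
      r <- z - X %*% beta
      Vi_r <- backsolve(R, forwardsolve(t(R), r))
      eta_new <- drop(X %*% beta + tau * (Kk %*% Vi_r))
      delta <- max(abs(eta_new - eta))
      eta <- eta_new
      mu <- stats::plogis(eta)
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      stop("PQL did not converge in ", maxit,
           " iterations (last max |d eta| = ", format(delta), ")")
    }
    W <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (yk - mu) / W
    V <- tau * Kk
    diag(V) <- diag(V) + 1 / W
    Vi <- chol2inv(chol(V))
    P <- Vi - Vi %*% X %*% solve(crossprod(X, Vi %*% X), crossprod(X, Vi))
    out <- list(response = response, X = X, beta = drop(beta), tau = tau,
                sigma2 = NA_real_, P = P, Py = drop(P %*% z), y = yk,
                keep = keep, converged = converged, n_iter = it)
  }
  class(out) <- "null_model"
  out
}

#' Mixed-model association scan by score tests
#'
#' Tests each marker by adding its (mean-imputed) dosage to the null
#' model's fixed effects and computing the score statistic
#' `U^2 / Var(U)` with the variance components held at their null
#' estimates: `U = g' P y*` and `Var(U) = g' P g`, where `P` is the null
#' model's projection matrix and `y*` its (working) response. The
#' statistic is asymptotically chi-squared with 1 df under the null.
#' Markers that are monomorphic after imputation get a missing p-value.
#'
#' Results carry Benjamini-Hochberg q-values and the `-log10(p)` threshold
#' lines for the suggestive (FDR 0.05) and significant (FDR 0.01) levels.
#'
#' @param g a [genotype_matrix()] whose markers already passed the GWAS
#'   filters (MAF > 0.05, missing rate <= 0.20 by convention).
#' @param null_fit a `null_model` from [fit_null_model()].
#' @param exclude optional integer vector of marker columns to skip (used
#'   by [conditional_scan()] for the conditioning markers).
#' @param chunk_size markers per vectorized block. Default 20000.
#' @return An `assoc_result` data frame: one row per tested marker with
#'   `chrom`, `pos`, `ref`, `alt`, `effect` (one-step estimate `U/Var(U)`),
#'   `stat`, `p`, `minus_log10_p`, `q`; threshold lines and model info in
#'   `attr(, "thresholds")` and `attr(, "model")`.
#' @export
association_scan <- function(g, null_fit, exclude = NULL, chunk_size = 20000) {
  test_cols <- setdiff(seq_len(n_markers(g)), exclude)
  m <- length(test_cols)
  u <- numeric(m); vg <- numeric(m)
  P <- null_fit$P
  Py <- null_fit$Py
  keep <- null_fit$keep
  for (start in seq(1, m, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1, m)
    G <- impute_dosage(g$dosage[keep, test_cols[idx], drop = FALSE])
    u[idx] <- crossprod(G, Py)
    vg[idx] <- colSums(G * (P %*% G))
  }
  ok <- vg > 1e-12
  if (any(!ok)) message(sum(!ok), " zero-variance marker(s): p set missing")
  stat <- ifelse(ok, u^2 / vg, NA_real_)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[ok & p == 0] <- .Machine$double.xmin  # keep -log10(p) finite
  res <- data.frame(
    chrom = g$markers$chrom[test_cols],
    pos = g$markers$pos[test_cols],
    ref = g$markers$ref[test_cols],
    alt = g$markers$alt[test_cols],
    effect = ifelse(ok, u / vg, NA_real_),
    stat = stat,
    p = p,
    minus_log10_p = -log10(p),
    stringsAsFactors = FALSE
  )
  res$q <- adjust_fdr(res$p)
  class(res) <- c("assoc_result", "data.frame")
  attr(res, "model") <- list(response = null_fit$response,
                             tau = null_fit$tau, n = length(keep))
  attr(res, "thresholds") <- list(
    suggestive_alpha = 0.05, significant_alpha = 0.01,
    suggestive = fdr_threshold(res, 0.05),
    significant = fdr_threshold(res, 0.01)
  )
  res
}

#' Association scan conditional on named markers
#'
#' Re-runs [association_scan()] with the dosages of the named markers
#' appended to the fixed-effect design (mean-imputed; constant columns are
#' rejected), excluding those markers from the scan itself. Conditioning on
#' a region's causal marker removes the association signal of its LD
#' proxies.
#'
#' @param g a [genotype_matrix()].
#' @param y phenotype vector aligned with `g$accessions` (0/1 for binary).
#' @param covariate_markers character vector of `"chrom:pos"` marker ids to
#'   condition on.
#' @param K genomic relationship matrix.
#' @param response `"binary"` or `"quantitative"`. Binary conditional
#'   scans can show genome-wide p-value inflation; the quantitative
#'   (Gaussian-on-0/1) response is the standard fallback.
#' @param ... passed to [fit_null_model()].
#' @return An `assoc_result` (see [association_scan()]).
#' @export
conditional_scan <- function(g, y, covariate_markers, K,
                             response = c("binary", "quantitative"), ...) {
  response <- match.arg(response)
  idx <- match_marker_ids(g, covariate_markers)
  cov <- impute_dosage2(g$dosage[, idx, drop = FALSE])
  colnames(cov) <- covariate_markers
  fit <- fit_null_model(y, K, covariates = cov, response = response, ...)
  association_scan(g, fit, exclude = idx)
}

# impute, but error on all-missing and on constant conditioning columns
impute_dosage2 <- function(dosage) {
  if (any(colSums(!is.na(dosage)) == 0)) {
    stop("conditioning marker has all-missing genotypes")
  }
  x <- impute_dosage(dosage)
  if (any(apply(x, 2, stats::var) == 0)) {
    stop("conditioning marker is constant")
  }
  x
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j>=i) (m p_(j) / j)` capped at 1,
#' mapped back to input order. Missing p-values get missing q-values and do
#' not count toward `m`.
#'
#' @param p p-values in (0, 1], `NA` allowed.
#' @return q-values, same length and order.
#' @export
adjust_fdr <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "fdr")
  q
}

#' FDR threshold as a -log10(p) line
#'
#' The Benjamini-Hochberg rejection boundary rendered as a horizontal
#' Manhattan-plot line: the `-log10(p)` of the largest p whose q-value is
#' at or below `alpha`. When no marker passes, the line is placed just
#' above the maximum observed score so that zero markers sit at or above
#' it.
#'
#' @param result an `assoc_result` (or any data frame with `p`, `q`,
#'   `minus_log10_p`).
#' @param alpha FDR level.
#' @return The threshold in `-log10(p)` units.
#' @export
fdr_threshold <- function(result, alpha) {
  ok <- !is.na(result$q)
  pass <- ok & result$q <= alpha
  if (!any(pass)) {
    return(max(result$minus_log10_p[ok]) + 1)
  }
  -log10(max(result$p[pass]))
}
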