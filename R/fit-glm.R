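#' Fit an ROI-level GLM with contrasts
#'
#' Ordinary least squares of one region's BOLD series on a design matrix,
#' with optional Cochrane-Orcutt AR(1) prewhitening, returning per-contrast
#' t statistics `t = c'b / sqrt(s2 * c'(X'X)^- c)`.
#'
#' @param y Numeric BOLD series (length = volumes).
#' @param design A `design_matrix` from [build_design_matrix()], or a plain
#'   numeric matrix.
#' @param contrasts Named list of contrast vectors. Each vector is either
#'   full length (one weight per column) or named by design columns (other
#'   columns 0).
#' @param prewhiten Apply one Cochrane-Orcutt AR(1) step (estimate lag-1
#'   residual autocorrelation, quasi-difference, refit)?
#' @return Object of class `glm_fit`: `coefficients` (named), `sigma2`,
#'   `df`, `residuals`, `contrasts` tibble (`contrast`, `estimate`, `se`,
#'   `statistic`, `p.value`), `rank_deficient`, `rho` (NA unless
#'   prewhitened).
#' @export
fit_glm <- function(y, design, contrasts = list(), prewhiten = FALSE) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (length(y) != nrow(X)) abort("`y` length must equal design rows")
  cn <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  colnames(X) <- cn

  resolve_contrast <- function(cv) {
    if (!is.null(names(cv)) && !all(names(cv) == "")) {
      full <- stats::setNames(numeric(ncol(X)), cn)
      bad <- setdiff(names(cv), cn)
      if (length(bad)) abort(sprintf("unknown contrast column(s): %s",
                                     paste(bad, collapse = ", ")))
      full[names(cv)] <- cv
      full
    } else {
      if (length(cv) != ncol(X)) abort("contrast length must match design columns")
      cv
    }
  }

  ols <- function(X, y) {
    qrx <- qr(X)
    rank_def <- qrx$rank < ncol(X)
    if (rank_def) {
      warn("design matrix is rank deficient; using minimum-norm solution")
      sv <- svd(X)
      pos <- sv$d > max(sv$d) * 1e-12
      beta <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
      beta <- drop(beta)
      xtx_inv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$v[, pos, drop = FALSE]) / sv$d[pos]^2)
      df <- length(y) - sum(pos)
    } else {
      beta <- qr.coef(qrx, y)
      xtx_inv <- chol2inv(qr.R(qrx))
      df <- length(y) - ncol(X)
    }
    res <- y - drop(X %*% beta)
    list(beta = beta, xtx_inv = xtx_inv, df = df, res = res,
         rank_def = rank_def)
  }

  rho <- NA_real_
  fit <- ols(X, y)
  if (prewhiten) {
    r <- fit$res
    rho <- sum(r[-1] * r[-length(r)]) / sum(r^2)
    yw <- y[-1] - rho * y[-length(y)]
    Xw <- X[-1, , drop = FALSE] - rho * X[-nrow(X), , drop = FALSE]
    fit <- ols(Xw, yw)
  }

  sigma2 <- sum(fit$res^2) / fit$df
  beta <- stats::setNames(fit$beta, cn)

  ctab <- purrr::imap_dfr(contrasts, function(cv, nm) {
    cvec <- resolve_contrast(cv)
    est <- sum(cvec * beta)
    se <- sqrt(sigma2 * drop(t(cvec) %*% fit$xtx_inv %*% cvec))
    tstat <- est / se
    tibble(contrast = nm, estimate = est, se = se, statistic = tstat,
           p.value = 2 * pt(-abs(tstat), fit$df))
  })

  structure(
    list(coefficients = beta, sigma2 = sigma2, df = fit$df,
         residuals = fit$res, contrasts = ctab,
         rank_deficient = fit$rank_def, rho = rho),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d df, sigma2 = %.4g%s\n", x$df, x$sigma2,
              if (x$rank_deficient) " (rank deficient)" else ""))
  if (nrow(x$contrasts)) print(x$contrasts)
  invisible(x)
}

#' @method tidy glm_fit
#' @export
tidy.glm_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @method glance glm_fit
#' @export
glance.glm_fit <- function(x, ...) {
  tibble(df = x$df, sigma2 = x$sigma2, rank_deficient = x$rank_deficient,
         rho = x$rho)
}
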