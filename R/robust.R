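#' Wilcoxon scores
#'
#' Linear (Wilcoxon) rank scores `a(i) = sqrt(12) * (i/(n+1) - 1/2)`,
#' standardized to mean zero and unit asymptotic variance.
#'
#' @param n Sample size.
#' @return Numeric vector of length `n`.
#' @export
wilcoxon_scores <- function(n) {
  sqrt(12) * (seq_len(n) / (n + 1) - 0.5)
}

#' Jaeckel rank dispersion of residuals
#'
#' `D(e) = sum_i a(R(e_i)) * e_i` with Wilcoxon scores; average ranks are
#' used for ties. Non-negative, location-invariant, and zero iff all
#' residuals are equal.
#'
#' @param e Numeric residual vector.
#' @return Dispersion value.
#' @export
rank_dispersion <- function(e) {
  n <- length(e)
  a <- sqrt(12) * (rank(e, ties.method = "average") / (n + 1) - 0.5)
  sum(a * e)
}

#' Rank-based linear model fit (Jaeckel / Wilcoxon)
#'
#' Estimates regression coefficients by minimizing Jaeckel's rank
#' dispersion of the residuals with Wilcoxon scores — the rank-based
#' analogue of least squares underlying robust ANOVA. The dispersion is
#' invariant to the intercept, which is estimated afterwards as the median
#' residual. The scale parameter tau needed for inference is estimated
#' from the fitted residuals by a Koul-Sievers-McKean-style
#' pairwise-difference density estimate (see [tau_ksm()]).
#'
#' Minimization starts from the least-squares solution and polishes with
#' Nelder-Mead restarts on the convex dispersion surface.
#'
#' @param formula Model formula, e.g. `y ~ volume + depth_cat`.
#' @param data Data frame with the model variables.
#' @return Object of class `"rank_fit"`: coefficients (slopes), intercept,
#'   residuals, fitted values, dispersion at the minimum, `tauhat`, the
#'   centered design matrix and bookkeeping for [rank_anova()] /
#'   [posthoc_pairwise()].
#' @export
rank_fit <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!is.numeric(y)) stop("rank_fit: response must be numeric")
  if (diff(range(y)) == 0) stop("rank_fit: constant response, dispersion degenerate")
  mm <- stats::model.matrix(attr(mf, "terms"), mf)
  has_int <- "(Intercept)" %in% colnames(mm)
  X <- mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
  if (ncol(X) == 0L) stop("rank_fit: model has no non-intercept terms")
  if (qr(X)$rank < ncol(X)) stop("rank_fit: singular design")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1L) stop("rank_fit: need n > number of parameters")

  beta <- fit_dispersion(y, Xc)
  e <- drop(y - Xc %*% beta)
  alpha <- stats::median(e)
  res <- e - alpha
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    intercept = alpha,
    residuals = res,
    fitted = y - res,
    dispersion = rank_dispersion(e),
    tauhat = tau_ksm(res, p),
    x_centered = Xc,
    formula = formula,
    terms = attr(mf, "terms"),
    model_frame = mf,
    n = n, p = p
  ), class = "rank_fit")
}

# minimize D(y - Xc b) over b: least-squares start + Nelder-Mead polish
# with one restart (D is convex piecewise-linear in b)
fit_dispersion <- function(y, Xc) {
  obj <- function(b) rank_dispersion(y - drop(Xc %*% b))
  b0 <- stats::coef(stats::lm.fit(Xc, y - mean(y)))
  b0[is.na(b0)] <- 0
  if (ncol(Xc) == 1L) {
    opt <- stats::optimize(function(b) obj(b), interval = b0 + c(-1, 1) *
                             (4 * stats::sd(y) + abs(b0) + 1), tol = 1e-10)
    return(opt$minimum)
  }
  opt <- stats::optim(b0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  opt$par
}

#' Scale parameter tau for rank-based inference
#'
#' Estimates `tau = 1 / (sqrt(12) * integral(f^2))` from fitted residuals
#' via the Koul-Sievers-McKean pairwise-difference approach: the density of
#' residual differences at zero is estimated by the fraction of pairwise
#' absolute differences below a shrinking quantile bandwidth
#' `t_delta / sqrt(n)`, with a degrees-of-freedom correction
#' `sqrt(n / (n - p - 1))`.
#'
#' @param e Residual vector from a rank fit.
#' @param p Number of fitted slope parameters.
#' @param delta Bandwidth quantile; 0.8 by default, 0.95 for small `n/p`.
#' @return Estimate of tau.
#' @export
tau_ksm <- function(e, p, delta = if (length(e) / max(p, 1) > 5) 0.8 else 0.95) {
  n <- length(e)
  d <- abs(outer(e, e, "-"))
  d <- sort(d[lower.tri(d)])
  if (length(d) > p) d <- d[(p + 1L):length(d)]  # drop fit-induced near-zeros
  if (max(d) == 0) stop("tau_ksm: residuals are all equal")
  td <- stats::quantile(d, delta, names = FALSE) / sqrt(n)
  m <- mean(d < td)
  if (m == 0) {  # bandwidth fell below the smallest gap; widen minimally
    td <- min(d[d > 0]) * (1 + 1e-8)
    m <- mean(d < td)
  }
  sqrt(n / (n - p - 1)) * 2 * td / (sqrt(12) * m)
}

#' Rank-based ANOVA via drop in dispersion
#'
#' Tests each model term by comparing the full rank fit against the
#' reduced fit without that term: `F = (drop in dispersion / df) /
#' (tauhat / 2)`, referred to an F distribution with `(df_term,
#' n - p - 1)` degrees of freedom.
#'
#' @param fit A [rank_fit()] object.
#' @return Data frame of class `"rank_anova"`: one row per term with
#'   `term`, `df1`, `df2`, `F`, `p_value`.
#' @export
rank_anova <- function(fit) {
  stopifnot(inherits(fit, "rank_fit"))
  trm <- fit$terms
  labels <- attr(trm, "term.labels")
  if (length(labels) == 0L) stop("rank_anova: no terms to test")
  mf <- fit$model_frame
  y <- stats::model.response(mf)
  D_full <- fit$dispersion
  rows <- lapply(labels, function(lab) {
    if (length(labels) == 1L) {
      Xr <- matrix(numeric(0), nrow = fit$n, ncol = 0L)
    } else {
      red_trm <- stats::drop.terms(trm, dropx = match(lab, labels),
                                   keep.response = TRUE)
      mm_red <- stats::model.matrix(red_trm, mf)
      Xr <- mm_red[, setdiff(colnames(mm_red), "(Intercept)"), drop = FALSE]
    }
    if (ncol(Xr) == 0L) {
      D_red <- rank_dispersion(y)
      q <- fit$p
    } else {
      Xrc <- scale(Xr, center = TRUE, scale = FALSE)
      br <- fit_dispersion(y, Xrc)
      D_red <- rank_dispersion(y - drop(Xrc %*% br))
      q <- fit$p - ncol(Xr)
    }
    RD <- max(D_red - D_full, 0)
    Fstat <- (RD / q) / (fit$tauhat / 2)
    df2 <- fit$n - fit$p - 1L
    data.frame(term = lab, df1 = q, df2 = df2, F = Fstat,
               p_value = stats::pf(Fstat, q, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("rank_anova", "data.frame")
  out
}

#' Post-hoc pairwise contrasts after a rank fit
#'
#' Wald tests of all level pairs of one factor, using the rank-fit
#' coefficient estimates and their asymptotic covariance
#' `tauhat^2 (Xc'Xc)^{-1}`; p-values are multiplicity-adjusted (Holm by
#' default).
#'
#' @param fit A [rank_fit()] object.
#' @param factor_name Name of a factor in the model with >= 2 levels.
#' @param adjust Adjustment method passed to [stats::p.adjust()].
#' @return Data frame: `level_1`, `level_2`, `estimate`, `se`, `t`,
#'   `p_value`, `p_adjusted`.
#' @export
posthoc_pairwise <- function(fit, factor_name, adjust = "holm") {
  stopifnot(inherits(fit, "rank_fit"))
  mf <- fit$model_frame
  if (!factor_name %in% names(mf)) {
    stop("posthoc_pairwise: '", factor_name, "' is not in the model")
  }
  f <- mf[[factor_name]]
  if (!is.factor(f)) f <- factor(f)
  levs <- levels(f)
  if (length(levs) < 2L) stop("posthoc_pairwise: factor needs >= 2 levels")
  Xc <- fit$x_centered
  V <- fit$tauhat^2 * solve(crossprod(Xc))
  # coefficient vector per level: reference level = 0
  coef_names <- paste0(factor_name, levs)
  coef_of_level <- function(lev) {
    v <- rep(0, fit$p)
    nm <- paste0(factor_name, lev)
    if (nm %in% names(fit$coefficients)) v[match(nm, names(fit$coefficients))] <- 1
    v
  }
  prs <- utils::combn(levs, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(j) {
    c1 <- coef_of_level(prs[1L, j])
    c2 <- coef_of_level(prs[2L, j])
    ctr <- c1 - c2
    est <- sum(ctr * fit$coefficients)
    se <- sqrt(drop(t(ctr) %*% V %*% ctr))
    tstat <- est / se
    df2 <- fit$n - fit$p - 1L
    data.frame(level_1 = prs[1L, j], level_2 = prs[2L, j], estimate = est,
               se = se, t = tstat,
               p_value = 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  out
}

#' Levene's test for homogeneity of variance
#'
#' Classic Levene test: one-way ANOVA F statistic on absolute deviations
#' from the group center (mean by default; median gives the Brown-Forsythe
#' variant).
#'
#' @param values Numeric observations.
#' @param group Grouping factor (>= 2 groups, each with >= 2 observations).
#' @param center `"mean"` or `"median"`.
#' @return List of class `"levene_test"`: `W` (the F statistic), `df`
#'   (numerator, denominator), `p_value`, `center`.
#' @export
levene_test <- function(values, group, center = c("mean", "median")) {
  center <- match.arg(center)
  group <- droplevels(factor(group))
  if (nlevels(group) < 2L) stop("levene_test: need >= 2 groups")
  if (any(table(group) < 2L)) stop("levene_test: every group needs >= 2 observations")
  cfun <- if (center == "mean") mean else stats::median
  centers <- tapply(values, group, cfun)
  ad <- abs(values - centers[group])
  if (all(ad == 0)) {
    stop("levene_test: zero within-group deviation everywhere, test degenerate")
  }
  fit <- stats::anova(stats::lm(ad ~ group))
  structure(list(W = fit$`F value`[1L],
                 df = c(fit$Df[1L], fit$Df[2L]),
                 p_value = fit$`Pr(>F)`[1L],
                 center = center),
            class = "levene_test")
}

#' @export
print.levene_test <- function(x, ...) {
  cat("Levene's test (", x$center, "-centered)\n", sep = "")
  cat("W =", format(x$W, digits = 5), " df = (", x$df[1L], ",", x$df[2L],
      ") p =", format.pval(x$p_value), "\n")
  invisible(x)
}

#' @export
print.rank_fit <- function(x, ...) {
  cat("Rank-based fit (Wilcoxon scores)\n")
  cat("Intercept (median residual):", format(x$intercept, digits = 5), "\n")
  print(x$coefficients)
  cat("tauhat:", format(x$tauhat, digits = 5),
      " dispersion:", format(x$dispersion, digits = 5), "\n")
  invisible(x)
}
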