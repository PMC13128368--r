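#' Fit a one-way random-intercept linear mixed model
#'
#' The shared engine behind the axis-gradient and subregion-composition
#' analyses: Gaussian response with named fixed-effect columns and a random
#' intercept per group (hemisphere), maximising the (restricted) likelihood
#' via \code{lme4::lmer}. Inference on fixed effects is by Wald z (normal)
#' tests, appropriate at the observation counts these analyses run at. If the
#' mixed fit cannot be computed the model falls back to its ordinary
#' least-squares limit (random-intercept variance zero) with a warning.
#'
#' @param response numeric response vector.
#' @param fixed_design numeric matrix with named columns (include an
#'   intercept column explicitly, e.g. \code{"(Intercept)"}).
#' @param group vector of group tokens (the random-intercept factor).
#' @param method \code{"ML"} (default, matching the published fits) or
#'   \code{"REML"}.
#' @return an object of class \code{lme_ri}: \code{coefficients}, \code{se},
#'   \code{z}, \code{p} (named vectors), \code{vcov}, \code{sigma_u2},
#'   \code{sigma_e2}, \code{loglik}, \code{n_obs}, \code{n_groups},
#'   \code{converged}, \code{singular}, \code{method}.
#' @export
fit_random_intercept <- function(response, fixed_design, group,
                                 method = c("ML", "REML")) {
  method <- match.arg(method)
  fixed_design <- as.matrix(fixed_design)
  if (is.null(colnames(fixed_design)))
    stopf("fixed_design must have named columns")
  n <- length(response)
  if (nrow(fixed_design) != n || length(group) != n)
    stopf("response, fixed_design and group dimensions disagree")
  qrX <- qr(fixed_design)
  if (qrX$rank < ncol(fixed_design)) {
    bad <- colnames(fixed_design)[qrX$pivot[(qrX$rank + 1):ncol(fixed_design)]]
    stopf("fixed design is rank-deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  orig_names <- colnames(fixed_design)
  safe <- paste0("X", seq_along(orig_names))
  dat <- as.data.frame(fixed_design)
  names(dat) <- safe
  dat$.y <- as.numeric(response)
  dat$.g <- factor(group)

  fml <- stats::as.formula(paste(".y ~ 0 +", paste(safe, collapse = " + "),
                                 "+ (1 | .g)"))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(fml, data = dat, REML = (method == "REML"))),
    error = function(e) e)

  if (inherits(fit, "error")) {
    warnf("mixed fit failed (%s); falling back to its OLS limit",
          conditionMessage(fit))
    ols <- stats::lm(stats::as.formula(
      paste(".y ~ 0 +", paste(safe, collapse = " + "))), data = dat)
    b <- stats::coef(ols); V <- stats::vcov(ols)
    sm <- summary(ols)
    out <- list(coefficients = b, vcov = V, sigma_u2 = 0,
                sigma_e2 = sm$sigma^2, loglik = as.numeric(stats::logLik(ols)),
                n_obs = n, n_groups = length(unique(group)),
                converged = FALSE, singular = TRUE, method = method)
  } else {
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_u2 <- vc$vcov[vc$grp == ".g"][1]
    sigma_e2 <- vc$vcov[vc$grp == "Residual"][1]
    conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L
    out <- list(coefficients = lme4::fixef(fit),
                vcov = as.matrix(stats::vcov(fit)),
                sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                loglik = as.numeric(stats::logLik(fit)),
                n_obs = n, n_groups = nlevels(dat$.g),
                converged = conv, singular = lme4::isSingular(fit),
                method = method)
  }
  names(out$coefficients) <- orig_names
  dimnames(out$vcov) <- list(orig_names, orig_names)
  out$se <- sqrt(diag(out$vcov))
  out$z <- out$coefficients / out$se
  out$p <- 2 * stats::pnorm(-abs(out$z))
  class(out) <- "lme_ri"
  out
}

#' @export
print.lme_ri <- function(x, ...) {
  cat(sprintf("<lme_ri> random-intercept LMM (%s), %d obs in %d groups%s\n",
              x$method, x$n_obs, x$n_groups,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(cbind(estimate = x$coefficients, se = x$se, z = x$z, p = x$p), 6))
  cat(sprintf("  sigma_u^2 = %.4g   sigma_e^2 = %.4g   logLik = %.3f\n",
              x$sigma_u2, x$sigma_e2, x$loglik))
  invisible(x)
}

#' @export
summary.lme_ri <- function(object, ...) {
  data.frame(term = names(object$coefficients),
             estimate = unname(object$coefficients),
             se = unname(object$se), z = unname(object$z),
             p = unname(object$p), row.names = NULL)
}

#' @export
coef.lme_ri <- function(object, ...) object$coefficients

#' @export
vcov.lme_ri <- function(object, ...) object$vcov

#' @export
logLik.lme_ri <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 2L,
            class = "logLik")
}

#' @export
confint.lme_ri <- function(object, parm, level = 0.95, ...) {
  if (missing(parm)) parm <- names(object$coefficients)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lower = object$coefficients[parm] - zq * object$se[parm],
        upper = object$coefficients[parm] + zq * object$se[parm])
}

#' Wald test of a linear combination of fixed effects
#'
#' @param fit an \code{lme_ri}.
#' @param contrast named numeric vector of weights; names must be coefficient
#'   names (missing coefficients get weight zero).
#' @return one-row data.frame: estimate, se, z, p (two-sided normal).
#' @export
wald_contrast <- function(fit, contrast) {
  unknown <- setdiff(names(contrast), names(fit$coefficients))
  if (length(unknown) > 0L)
    stopf("unknown coefficient(s) in contrast: %s",
          paste(unknown, collapse = ", "))
  w <- stats::setNames(numeric(length(fit$coefficients)),
                       names(fit$coefficients))
  w[names(contrast)] <- contrast
  est <- sum(w * fit$coefficients)
  se <- sqrt(drop(t(w) %*% fit$vcov %*% w))
  if (se == 0) {
    z <- 0; p <- 1
  } else {
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  data.frame(estimate = est, se = se, z = z, p = p)
}

#' Joint Wald chi-square test of several fixed effects
#'
#' @param fit an \code{lme_ri}.
#' @param terms coefficient names tested jointly against zero.
#' @return one-row data.frame: chisq, df, p.
#' @export
wald_joint <- function(fit, terms) {
  unknown <- setdiff(terms, names(fit$coefficients))
  if (length(unknown) > 0L)
    stopf("unknown coefficient(s): %s", paste(unknown, collapse = ", "))
  b <- fit$coefficients[terms]
  V <- fit$vcov[terms, terms, drop = FALSE]
  stat <- drop(t(b) %*% solve(V) %*% b)
  df <- length(terms)
  data.frame(chisq = stat, df = df,
             p = stats::pchisq(stat, df, lower.tail = FALSE))
}
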