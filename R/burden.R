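#' Fit the asymptotic depth-response curve for mutation burden
#'
#' Observed mutation burden rises with sequencing depth and saturates once
#' most true variants are detectable. The curve
#' \deqn{f(x) = b_0 + b_1 (1 - \exp(-\exp(lrc) \cdot x))}
#' is fitted to per-colony burden versus mean depth by nonlinear least
#' squares, with starting values from [stats::NLSstAsymptotic()].
#'
#' @param depths,burdens Numeric vectors (>= 4 distinct positive depths).
#' @return Object of class `depth_response` with elements b0, b1, lrc,
#'   `fit` (the nls fit, or NULL for the degenerate constant-burden case)
#'   and `converged`.
#' @export
fit_depth_response <- function(depths, burdens) {
  stopifnot(length(depths) == length(burdens))
  if (length(unique(depths)) < 4L) stop("need at least 4 distinct depths")
  if (any(depths <= 0)) stop("depths must be positive")
  if (stats::sd(burdens) < 1e-10) {
    # constant burden: flat curve
    out <- list(b0 = mean(burdens), b1 = 0, lrc = 0, fit = NULL,
                converged = TRUE)
    return(structure(out, class = "depth_response"))
  }
  xy <- stats::sortedXyData(depths, burdens)
  start <- tryCatch(stats::NLSstAsymptotic(xy),
                    error = function(e) c(b0 = min(burdens),
                                          b1 = diff(range(burdens)),
                                          lrc = log(1 / mean(depths))))
  # Levenberg-Marquardt: robust to the zero-residual (noiseless) case
  fit <- minpack.lm::nls.lm(
    par = as.list(start[c("b0", "b1", "lrc")]),
    fn = function(p) burdens - (p$b0 + p$b1 * (1 - exp(-exp(p$lrc) * depths))),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (fit$info %in% c(0L, 5L)) {
    stop("depth-response fit did not converge: ", fit$message,
         " (best iterate: b0=", round(fit$par$b0, 2),
         ", b1=", round(fit$par$b1, 2),
         ", lrc=", round(fit$par$lrc, 3), ")")
  }
  structure(list(b0 = fit$par$b0, b1 = fit$par$b1, lrc = fit$par$lrc,
                 fit = fit, converged = TRUE),
            class = "depth_response")
}

#' Evaluate a fitted depth-response curve
#' @param object A `depth_response`.
#' @param depth Depths at which to evaluate.
#' @param ... Unused.
#' @export
predict.depth_response <- function(object, depth, ...) {
  object$b0 + object$b1 * (1 - exp(-exp(object$lrc) * depth))
}

#' @export
print.depth_response <- function(x, ...) {
  cat(sprintf("Asymptotic depth response: b0=%.2f, b1=%.2f, lrc=%.3f\n",
              x$b0, x$b1, x$lrc))
  cat(sprintf("  saturating at %.1f; f(30)=%.1f\n",
              x$b0 + x$b1, predict(x, 30)))
  invisible(x)
}

#' Adjust an observed burden to a reference sequencing depth
#'
#' Rescales the observed count by the fitted curve ratio
#' f(ref_depth)/f(depth), so colonies sequenced shallowly are corrected
#' upward and the adjustment is the identity at the reference depth.
#'
#' @param n Observed burden (mutation count).
#' @param depth Mean sequencing depth of the colony.
#' @param dr A [fit_depth_response()] object.
#' @param ref_depth Reference depth (default 30).
#' @return Adjusted burden.
#' @export
adjust_to_reference_depth <- function(n, depth, dr, ref_depth = 30) {
  if (any(depth <= 0)) stop("depth must be positive")
  fd <- predict(dr, depth)
  if (any(fd <= 0)) stop("fitted curve non-positive at the observed depth")
  n * predict(dr, ref_depth) / fd
}

#' Fit the mixed-effects model of burden on age and cell type
#'
#' Maximum-likelihood fit of burden ~ age * cell_type with a random
#' intercept for donor-by-cell-type and a separate residual variance per
#' cell type (nlme::lme with varIdent weights). Reports per-cell-type age
#' slopes and intercept offsets relative to the reference (first) cell
#' type, each with Wald 95% confidence intervals, the per-cell-type
#' residual standard deviations, the donor random-effect standard
#' deviation, and a likelihood-ratio p-value for the age x cell-type
#' interaction.
#'
#' @param data data.frame with columns burden, age, cell_type, donor.
#' @param reference Reference cell type (default "HSPC" when present,
#'   otherwise the first level).
#' @return Object of class `burden_fit`.
#' @export
fit_burden_age_model <- function(data, reference = NULL) {
  need <- c("burden", "age", "cell_type", "donor")
  if (!all(need %in% names(data))) {
    stop("data must have columns ", paste(need, collapse = ", "))
  }
  if (length(unique(data$donor)) < 2L) stop("unidentifiable design: need >= 2 donors")
  if (length(unique(data$age)) < 2L) stop("unidentifiable design: need >= 2 ages")
  if (length(unique(data$cell_type)) < 2L) {
    stop("unidentifiable design: need >= 2 cell types")
  }
  if (is.null(reference)) {
    reference <- if ("HSPC" %in% data$cell_type) "HSPC" else
      sort(unique(data$cell_type))[1]
  }
  data$cell_type <- stats::relevel(factor(data$cell_type), ref = reference)
  data$dgrp <- interaction(data$donor, data$cell_type, drop = TRUE)

  # degenerate noiseless data: the fixed effects are exactly determined
  ols <- stats::lm(burden ~ age * cell_type, data = data)
  if (stats::sd(stats::residuals(ols)) < 1e-8) {
    fe <- stats::coef(ols)
    types <- levels(data$cell_type)
    pick <- function(base, int) {
      vapply(types, function(ty) {
        v <- fe[[base]]
        term <- sprintf(int, ty)
        if (ty != reference && term %in% names(fe)) v <- v + fe[[term]]
        v
      }, numeric(1))
    }
    sl <- pick("age", "age:cell_type%s")
    of <- vapply(types, function(ty) {
      if (ty == reference) 0 else fe[[paste0("cell_type", ty)]]
    }, numeric(1))
    mk <- function(v) data.frame(cell_type = types, estimate = unname(v),
                                 lower = unname(v), upper = unname(v))
    return(structure(list(
      slopes = mk(sl), offsets = mk(of), intercepts = mk(pick("(Intercept)",
                                                              "cell_type%s")),
      resid_sd = stats::setNames(rep(0, length(types)), types),
      donor_sd = 0, interaction_p = NA_real_, reference = reference,
      fit = ols
    ), class = "burden_fit"))
  }

  ctrl <- nlme::lmeControl(opt = "optim", maxIter = 200, msMaxIter = 200)
  fit <- nlme::lme(burden ~ age * cell_type, random = ~ 1 | dgrp,
                   weights = nlme::varIdent(form = ~ 1 | cell_type),
                   data = data, method = "ML", control = ctrl)
  # variance components for the Wald intervals come from an REML refit
  # (ML components are biased low with few donors)
  fit_reml <- nlme::lme(burden ~ age * cell_type, random = ~ 1 | dgrp,
                        weights = nlme::varIdent(form = ~ 1 | cell_type),
                        data = data, method = "REML", control = ctrl)
  fe <- nlme::fixef(fit)
  V <- stats::vcov(fit_reml)
  # donor-level t quantile: age and cell-type contrasts are identified
  # across donors, not colonies
  n_donors <- length(unique(data$donor))
  tq <- stats::qt(0.975, max(n_donors - 2L, 1L))
  types <- levels(data$cell_type)

  per_type <- function(kind) {
    out <- data.frame(cell_type = types, estimate = NA_real_,
                      lower = NA_real_, upper = NA_real_)
    for (i in seq_along(types)) {
      ty <- types[i]
      base_term <- if (kind == "slope") "age" else "(Intercept)"
      int_term <- if (kind == "slope") paste0("age:cell_type", ty) else
        paste0("cell_type", ty)
      w <- stats::setNames(numeric(length(fe)), names(fe))
      w[base_term] <- 1
      if (ty != reference && int_term %in% names(fe)) w[int_term] <- 1
      est <- sum(w * fe)
      se <- sqrt(drop(t(w) %*% V %*% w))
      out[i, 2:4] <- c(est, est - tq * se, est + tq * se)
    }
    out
  }
  slopes <- per_type("slope")
  inter <- per_type("intercept")
  # offsets vs the reference type: drop the shared intercept
  offsets <- data.frame(cell_type = types, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_)
  for (i in seq_along(types)) {
    ty <- types[i]
    if (ty == reference) { offsets[i, 2:4] <- 0; next }
    term <- paste0("cell_type", ty)
    est <- fe[[term]]
    se <- sqrt(V[term, term])
    offsets[i, 2:4] <- c(est, est - tq * se, est + tq * se)
  }

  # variance components (REML: unbiased with few donors); residual s.d.
  # per cell type from the varIdent structure
  sig <- fit_reml$sigma
  vw <- stats::coef(fit_reml$modelStruct$varStruct, unconstrained = FALSE,
                    allCoef = TRUE)
  resid_sd <- stats::setNames(sig * vw[types], types)

  donor_sd <- as.numeric(nlme::VarCorr(fit_reml)["(Intercept)", "StdDev"])

  # LRT for the age x cell-type interaction
  fit0 <- nlme::lme(burden ~ age + cell_type, random = ~ 1 | dgrp,
                    weights = nlme::varIdent(form = ~ 1 | cell_type),
                    data = data, method = "ML",
                    control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                               msMaxIter = 200))
  lrt <- 2 * (as.numeric(stats::logLik(fit)) - as.numeric(stats::logLik(fit0)))
  df <- length(types) - 1L
  p_int <- stats::pchisq(max(lrt, 0), df, lower.tail = FALSE)

  structure(list(slopes = slopes, offsets = offsets, intercepts = inter,
                 resid_sd = resid_sd, donor_sd = donor_sd,
                 interaction_p = p_int, reference = reference, fit = fit),
            class = "burden_fit")
}

#' @export
print.burden_fit <- function(x, ...) {
  cat("Mixed-effects burden model (burden ~ age * cell_type)\n")
  cat("  age slopes (SNVs/cell/year, 95% CI):\n")
  for (i in seq_len(nrow(x$slopes))) {
    cat(sprintf("    %-8s %6.1f (%.1f-%.1f)\n", x$slopes$cell_type[i],
                x$slopes$estimate[i], x$slopes$lower[i], x$slopes$upper[i]))
  }
  cat(sprintf("  offsets vs %s (SNVs, 95%% CI):\n", x$reference))
  for (i in seq_len(nrow(x$offsets))) {
    if (x$offsets$cell_type[i] == x$reference) next
    cat(sprintf("    %-8s %6.0f (%.0f-%.0f)\n", x$offsets$cell_type[i],
                x$offsets$estimate[i], x$offsets$lower[i], x$offsets$upper[i]))
  }
  cat("  residual s.d. per type:",
      paste(sprintf("%s=%.0f", names(x$resid_sd), x$resid_sd), collapse = ", "),
      "\n")
  cat(sprintf("  donor s.d.: %.0f;  age x cell-type interaction p = %.2g\n",
              x$donor_sd, x$interaction_p))
  invisible(x)
}

#' @export
coef.burden_fit <- function(object, ...) {
  stats::setNames(object$slopes$estimate, object$slopes$cell_type)
}

#' Likelihood-ratio test for variance heterogeneity across cell types
#'
#' Compares the heteroscedastic model (separate residual variance per cell
#' type) with the nested homoscedastic model on the same data, chi-square
#' with (number of cell types - 1) degrees of freedom.
#'
#' @param data As in [fit_burden_age_model()].
#' @param reference Reference cell type.
#' @return List: stat, df, p, and the two log-likelihoods.
#' @export
variance_heterogeneity_test <- function(data, reference = NULL) {
  bf <- fit_burden_age_model(data, reference)
  fit1 <- bf$fit
  data$cell_type <- stats::relevel(factor(data$cell_type), ref = bf$reference)
  data$dgrp <- interaction(data$donor, data$cell_type, drop = TRUE)
  fit0 <- nlme::lme(burden ~ age * cell_type, random = ~ 1 | dgrp,
                    data = data, method = "ML",
                    control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                               msMaxIter = 200))
  ll1 <- as.numeric(stats::logLik(fit1))
  ll0 <- as.numeric(stats::logLik(fit0))
  df <- nlevels(factor(data$cell_type)) - 1L
  stat <- max(2 * (ll1 - ll0), 0)
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       logLik_het = ll1, logLik_hom = ll0)
}
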