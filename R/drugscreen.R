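#' Four-parameter logistic viability curve
#'
#' `v(c) = bottom + (top - bottom) / (1 + 10^(hill * (log10 c - log10 ic50)))`
#' so that `hill > 0` describes viability decreasing with concentration and
#' `ic50` is the curve midpoint (relative EC50).
#'
#' @param conc concentrations (nM), positive.
#' @param top,bottom asymptotic viability fractions (`top >= bottom`).
#' @param hill Hill slope.
#' @param ic50 midpoint concentration (nM).
#' @return predicted viability.
#' @export
fourpl <- function(conc, top, bottom, hill, ic50) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - log10(ic50))))
}

fourpl_ss <- function(par, logc, v) {
  pred <- par[2] + (par[1] - par[2]) / (1 + 10^(par[3] * (logc - par[4])))
  sum((v - pred)^2)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least squares on log10-transformed dose with a deterministic multi-start
#' grid (hill in +/-{0.5, 1, 2}, log10 IC50 at the tested-dose quartiles;
#' best starts polished with Nelder-Mead). The fit is normalized so that
#' `top >= bottom`. The IC50 is reported as censored (`censored = TRUE`,
#' "greater than the top tested dose") when the fitted midpoint exceeds the
#' highest concentration, when the curve does not decrease (`hill <= 0`), or
#' when the fitted dynamic range is below 0.05 viability units (flat data).
#'
#' @param data dose-response records (compound, culture, concentration_nM,
#'   replicate, viability).
#' @param compound,culture which curve to fit.
#' @return object of class `dose_response_fit`: top, bottom, hill, ic50,
#'   r_squared, censored, cmax, converged.
#' @export
fit_4pl <- function(data, compound, culture) {
  d <- data[data$compound == compound & data$culture == culture, ]
  if (nrow(d) == 0) stop("no records for ", compound, " / ", culture)
  if (any(d$concentration_nM <= 0)) stop("concentrations must be positive")
  if (length(unique(d$concentration_nM)) < 2L)
    stop("at least 2 distinct concentrations are required")
  logc <- log10(d$concentration_nM)
  v <- d$viability
  cmax <- max(d$concentration_nM)

  top0 <- max(tapply(v, logc, mean))
  bot0 <- min(tapply(v, logc, mean))
  starts <- expand.grid(hill = c(-2, -1, -0.5, 0.5, 1, 2),
                        l10ic50 = unname(quantile(logc, c(0.25, 0.5, 0.75))))
  ss0 <- apply(starts, 1, function(s)
    fourpl_ss(c(top0, bot0, s[1], s[2]), logc, v))
  keep <- order(ss0)[seq_len(min(4L, nrow(starts)))]

  best <- NULL
  for (i in keep) {
    fit <- tryCatch({
      nm <- optim(c(top0, bot0, starts$hill[i], starts$l10ic50[i]), fourpl_ss,
                  logc = logc, v = v, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-10))
      # quasi-Newton polish; keep whichever is better
      qn <- tryCatch(optim(nm$par, fourpl_ss, logc = logc, v = v,
                           method = "BFGS",
                           control = list(maxit = 500, reltol = 1e-12)),
                     error = function(e) NULL)
      if (!is.null(qn) && qn$value <= nm$value) qn else nm
    }, error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    out <- list(compound = compound, culture = culture, top = NA_real_,
                bottom = NA_real_, hill = NA_real_, ic50 = NA_real_,
                r_squared = NA_real_, censored = TRUE, cmax = cmax,
                converged = FALSE)
    class(out) <- "dose_response_fit"
    return(out)
  }
  par <- best$par
  if (par[1] < par[2]) {        # same curve with the asymptotes swapped
    par <- c(par[2], par[1], -par[3], par[4])
  }
  top <- par[1]; bottom <- par[2]; hill <- par[3]; ic50 <- 10^par[4]
  sstot <- sum((v - mean(v))^2)
  r2 <- if (sstot > 1e-12) 1 - best$value / sstot else 0
  converged <- best$convergence == 0 && is.finite(ic50)
  censored <- !converged || hill <= 0 || (top - bottom) < 0.05 ||
    ic50 > cmax
  out <- list(compound = compound, culture = culture, top = top,
              bottom = bottom, hill = hill, ic50 = ic50,
              r_squared = max(min(r2, 1), 0), censored = censored,
              cmax = cmax, converged = converged)
  class(out) <- "dose_response_fit"
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  ic <- if (x$censored) sprintf("> %g", x$cmax) else sprintf("%.4g", x$ic50)
  cat(sprintf("4PL fit %s/%s: IC50 = %s nM, R^2 = %.3f, hill = %.2f\n",
              x$compound, x$culture, ic, x$r_squared, x$hill))
  invisible(x)
}

#' Parametric bootstrap confidence interval for a fitted IC50
#'
#' Residual-based parametric bootstrap: viability is resampled from the
#' fitted curve plus Gaussian noise at the residual standard deviation, each
#' replicate is refit starting from the original solution, and the
#' percentile interval of the bootstrap IC50s is returned.
#'
#' @param data dose-response records.
#' @param compound,culture which curve.
#' @param level confidence level (default 0.95).
#' @param B bootstrap replicates (default 199).
#' @return named numeric c(lower, upper) in nM, with the bootstrap draws in
#'   attribute `"boot"` and the original fit in attribute `"fit"`.
#' @export
ic50_bootstrap_ci <- function(data, compound, culture, level = 0.95,
                              B = 199L) {
  fit <- fit_4pl(data, compound, culture)
  if (!fit$converged) stop("cannot bootstrap a non-converged fit")
  d <- data[data$compound == compound & data$culture == culture, ]
  logc <- log10(d$concentration_nM)
  pred <- fourpl(d$concentration_nM, fit$top, fit$bottom, fit$hill, fit$ic50)
  dof <- max(length(pred) - 4L, 1L)
  sig <- sqrt(sum((d$viability - pred)^2) / dof)
  start <- c(fit$top, fit$bottom, fit$hill, log10(fit$ic50))
  bt <- vapply(seq_len(B), function(b) {
    vb <- pred + rnorm(length(pred), 0, sig)
    o <- optim(start, fourpl_ss, logc = logc, v = vb,
               method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-8))
    10^o$par[4]
  }, numeric(1))
  a <- (1 - level) / 2
  out <- quantile(bt, c(a, 1 - a), names = FALSE)
  names(out) <- c("lower", "upper")
  attr(out, "boot") <- bt
  attr(out, "fit") <- fit
  out
}

#' Call compound efficacy from a dose-response fit
#'
#' Effective means: converged, uncensored IC50 below `ic50_max` and fit
#' quality `r_squared > r2_min`. The reason records the first failing
#' condition.
#'
#' @param fit a [fit_4pl()] result.
#' @param ic50_max efficacy IC50 threshold in nM (default 1000, i.e. 1 uM).
#' @param r2_min minimum curve-fit R^2 (default 0.6).
#' @return object of class `efficacy_call`: compound, culture, effective,
#'   reason, ic50, r_squared, censored.
#' @export
call_efficacy <- function(fit, ic50_max = 1000, r2_min = 0.6) {
  stopifnot(inherits(fit, "dose_response_fit"))
  reason <- if (fit$censored) "ic50_censored"
    else if (!fit$converged) "not_converged"
    else if (fit$r_squared <= r2_min) "fit_quality"
    else if (fit$ic50 >= ic50_max) "ic50_above_threshold"
    else "ok"
  structure(list(compound = fit$compound, culture = fit$culture,
                 effective = reason == "ok", reason = reason,
                 ic50 = fit$ic50, r_squared = fit$r_squared,
                 censored = fit$censored, cmax = fit$cmax),
            class = "efficacy_call")
}

#' Fit and call every compound/culture pair of a screen
#'
#' @param data dose-response records.
#' @param ic50_max,r2_min thresholds passed to [call_efficacy()].
#' @return data.frame: compound, culture, ic50_nM, r_squared, censored,
#'   effective, reason. IC50s of censored fits are reported as `NA` with
#'   `censored = TRUE` (written as "> cmax" by [write_fits()]).
#' @export
screen_efficacy <- function(data, ic50_max = 1000, r2_min = 0.6) {
  pairs <- unique(data[, c("compound", "culture")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    fit <- fit_4pl(data, pairs$compound[i], pairs$culture[i])
    call <- call_efficacy(fit, ic50_max, r2_min)
    data.frame(compound = fit$compound, culture = fit$culture,
               ic50_nM = if (fit$censored) NA_real_ else fit$ic50,
               r_squared = fit$r_squared, cmax = fit$cmax,
               censored = fit$censored, effective = call$effective,
               reason = call$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$compound, out$culture), , drop = FALSE]
}

#' Median-effect (Chou-Talalay) fit
#'
#' Linear regression of `log10(fa / (1 - fa))` on `log10(dose)` where
#' `fa = 1 - viability`; the slope is `m` and the x-intercept back-transform
#' gives the median-effect dose `Dm`. Points with `fa <= 0` or `fa >= 1` are
#' dropped with a warning.
#'
#' @param data dose-response records.
#' @param compound,culture which curve to fit.
#' @return object of class `median_effect_fit`: Dm (nM), m, r.
#' @export
median_effect_fit <- function(data, compound, culture) {
  d <- data[data$compound == compound & data$culture == culture, ]
  if (nrow(d) == 0) stop("no records for ", compound, " / ", culture)
  fa <- 1 - d$viability
  usable <- fa > 0 & fa < 1
  if (any(!usable))
    warning(sum(!usable), " point(s) with fa outside (0,1) dropped")
  d <- d[usable, ]
  fa <- fa[usable]
  if (nrow(d) < 2L || length(unique(d$concentration_nM)) < 2L)
    stop("fewer than 2 usable doses for the median-effect fit")
  x <- log10(d$concentration_nM)
  y <- log10(fa / (1 - fa))
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2])
  if (!is.finite(m) || abs(m) < 1e-8)
    stop("median-effect slope is zero; Dm undefined")
  Dm <- 10^(-unname(coef(fit)[1]) / m)
  structure(list(compound = compound, culture = culture, Dm = Dm, m = m,
                 r = suppressWarnings(cor(x, y))),
            class = "median_effect_fit")
}

#' Chou-Talalay combination index
#'
#' `Dx_i = Dm_i * (fa / (1 - fa))^(1 / m_i)` is the single-agent dose of
#' drug i achieving affected fraction `fa`; the combination index of doses
#' actually used is `CI = d1 / Dx1 + d2 / Dx2`. CI below 1 indicates
#' synergy, 1 additivity, above 1 antagonism; the synergy call uses the
#' `ci_threshold` (default 0.7).
#'
#' @param fit1,fit2 [median_effect_fit()] objects for the two agents.
#' @param d1,d2 doses used in combination (nM).
#' @param fa_combo affected fraction observed for the combination, in (0,1).
#' @param ci_threshold CI at or below which synergy is called.
#' @return object of class `combination_result`: fa, d1, d2, Dx1, Dx2, CI,
#'   synergy_call.
#' @export
combination_index <- function(fit1, fit2, d1, d2, fa_combo,
                              ci_threshold = 0.7) {
  stopifnot(inherits(fit1, "median_effect_fit"),
            inherits(fit2, "median_effect_fit"))
  if (!is.finite(fa_combo) || fa_combo <= 0 || fa_combo >= 1)
    stop("'fa_combo' must lie strictly inside (0, 1)")
  ratio <- fa_combo / (1 - fa_combo)
  Dx1 <- fit1$Dm * ratio^(1 / fit1$m)
  Dx2 <- fit2$Dm * ratio^(1 / fit2$m)
  CI <- d1 / Dx1 + d2 / Dx2
  structure(list(fa = fa_combo, d1 = d1, d2 = d2, Dx1 = Dx1, Dx2 = Dx2,
                 CI = CI, synergy_call = CI <= ci_threshold,
                 ci_threshold = ci_threshold),
            class = "combination_result")
}

#' Deconvolve recurrent kinase targets of effective compounds
#'
#' A compound "hits" a kinase when its inhibition score reaches
#' `inhibition_min`. For each kinase the number of effective compounds
#' hitting it is scored against a hypergeometric null (upper tail: drawing
#' the effective compounds at random from the panel).
#'
#' @param calls [screen_efficacy()] data.frame, or a list of
#'   [call_efficacy()] objects.
#' @param target_matrix compound x kinase inhibition matrix.
#' @param inhibition_min score threshold counting as a hit (default 50,
#'   i.e. 50 percent inhibition).
#' @return data.frame of class `target_score`: kinase,
#'   n_effective_hitting, n_panel_hitting, enrichment_p, sorted by count
#'   descending, then p, then name. Compounds absent from the matrix are
#'   skipped and listed in attribute `"skipped"`.
#' @export
target_deconvolution <- function(calls, target_matrix, inhibition_min = 50) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- do.call(rbind, lapply(calls, function(x)
      data.frame(compound = x$compound, effective = x$effective,
                 stringsAsFactors = FALSE)))
  }
  eff_cmp <- unique(calls$compound[calls$effective])
  skipped <- setdiff(eff_cmp, rownames(target_matrix))
  eff_cmp <- intersect(eff_cmp, rownames(target_matrix))

  hits <- target_matrix >= inhibition_min
  N <- nrow(target_matrix)
  n_eff <- length(eff_cmp)
  K <- colSums(hits)
  k <- if (n_eff > 0) colSums(hits[eff_cmp, , drop = FALSE]) else
    setNames(rep(0L, ncol(hits)), colnames(hits))
  p <- phyper(k - 1, K, N - K, n_eff, lower.tail = FALSE)
  out <- data.frame(kinase = colnames(target_matrix),
                    n_effective_hitting = as.integer(k),
                    n_panel_hitting = as.integer(K),
                    enrichment_p = pmin(p, 1),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_effective_hitting, out$enrichment_p, out$kinase), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("target_score", "data.frame")
  out
}
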