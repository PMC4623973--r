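# Titration analysis: per-site deprotonated fractions versus pH, Hill-equation
# fits for microscopic pKa values and Hill coefficients, conformer populations,
# and autocorrelation-aware effective sample sizes for the sampled fractions.

#' Hill equation
#'
#' Fraction of deprotonated species `s = 1 / (1 + 10^(n * (pKa - pH)))`.
#' `n = 1` is independent (Henderson-Hasselbalch) titration; `n < 1`
#' indicates anticooperative, coupled titration.
#'
#' @param pH Numeric vector.
#' @param pKa Titration midpoint.
#' @param n Hill coefficient (> 0).
#' @return Deprotonated fraction in `[0, 1]`.
#' @export
hill_s <- function(pH, pKa, n = 1) 1 / (1 + 10^(n * (pKa - pH)))

# internal: per-(pH, pattern) counts -> per-site deprotonated counts
.stream_site_counts <- function(stream, sites) {
  tab <- table(stream$protonation)
  pats <- names(tab)
  counts <- as.integer(tab)
  bits <- matrix(0L, length(pats), length(sites))
  for (k in seq_along(pats)) {
    bits[k, ] <- as.integer(strsplit(pats[k], "", fixed = TRUE)[[1]])
  }
  n_total <- sum(counts)
  n_deprot <- colSums(counts * (1L - bits))
  list(n_total = n_total, n_deprot = setNames(n_deprot, sites))
}

#' Titration curve of one site from per-pH streams
#'
#' @param streams A `ph_streams` list from [demultiplex()].
#' @param site_id Site to tabulate.
#' @return A data frame (`titration_curve`) with columns `site`, `pH`,
#'   `n_deprot`, `n_total`, `s`; pH values with empty streams are omitted
#'   with a warning.
#' @export
site_fractions <- function(streams, site_id) {
  curves <- titration_curves(streams)
  out <- curves[curves$site == site_id, , drop = FALSE]
  if (!nrow(out)) stop(sprintf("unknown site_id '%s'", site_id))
  rownames(out) <- NULL
  out
}

#' Titration curves of every site from per-pH streams
#'
#' @param streams A `ph_streams` list from [demultiplex()].
#' @return Long data frame with columns `site`, `pH`, `n_deprot`, `n_total`,
#'   `s` (ascending pH within site).
#' @export
titration_curves <- function(streams) {
  stopifnot(inherits(streams, "ph_streams"))
  sites <- attr(streams, "sites")
  ph <- as.numeric(names(streams))
  rows <- list()
  for (k in seq_along(streams)) {
    if (!nrow(streams[[k]])) {
      warning(sprintf("empty stream at pH %g omitted", ph[k]))
      next
    }
    sc <- .stream_site_counts(streams[[k]], sites)
    rows[[length(rows) + 1L]] <- data.frame(
      site = sites, pH = ph[k], n_deprot = as.integer(sc$n_deprot),
      n_total = sc$n_total, s = sc$n_deprot / sc$n_total,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$site, out$pH), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the Hill equation to a titration curve
#'
#' Unweighted nonlinear least squares of `s = 1/(1 + 10^(n*(pKa - pH)))`
#' (bounded Levenberg-Marquardt). Start values: pKa at the grid point where
#' `|s - 0.5|` is smallest, n = 1; bounds `n` in (0.05, 5],
#' `pKa` in `[min(pH) - 5, max(pH) + 5]`. Standard errors come from the
#' asymptotic covariance of the unweighted estimator: when the curve carries
#' per-point sample counts (`n_total`), the heteroscedasticity-consistent
#' sandwich covariance with binomial per-point variances
#' `s(1-s)/n_total` is used (fraction data are strongly heteroscedastic, so
#' the homoscedastic residual covariance would be badly anti-conservative);
#' otherwise the classic residual-based covariance is reported. A curve that
#' does not span both `s < 0.2` and `s > 0.8`, or that is degenerate (all
#' `s < 0.05` or all `s > 0.95`), is returned flagged non-converged rather
#' than raising.
#'
#' @param curve Data frame with columns `pH` and `s`, optionally `n_total`
#'   (point order is irrelevant), e.g. from [site_fractions()] or
#'   [exact_titration_curves()].
#' @return A `hill_fit` list: `pKa`, `n`, `se_pKa`, `se_n`, `rss`,
#'   `converged`.
#' @export
fit_hill <- function(curve) {
  stopifnot(all(c("pH", "s") %in% names(curve)))
  df <- data.frame(pH = as.numeric(curve$pH), s = as.numeric(curve$s))
  if (!is.null(curve$n_total)) df$n_total <- as.numeric(curve$n_total)
  df <- df[order(df$pH), , drop = FALSE]
  if (nrow(df) < 3L) stop("titration curve needs at least 3 pH points")
  if (any(df$s < -1e-9 | df$s > 1 + 1e-9)) stop("s must lie in [0, 1]")

  spans <- any(df$s < 0.2) && any(df$s > 0.8)
  degenerate <- all(df$s < 0.05) || all(df$s > 0.95)
  bad <- function() structure(list(pKa = NA_real_, n = NA_real_,
                                   se_pKa = NA_real_, se_n = NA_real_,
                                   rss = NA_real_, converged = FALSE),
                              class = "hill_fit")
  if (degenerate) return(bad())

  start <- list(pKa = df$pH[which.min(abs(df$s - 0.5))], n = 1)
  lo <- c(pKa = min(df$pH) - 5, n = 0.05 + 1e-9)
  hi <- c(pKa = max(df$pH) + 5, n = 5)
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ 1 / (1 + 10^(n * (pKa - pH))), data = df,
                      start = start, lower = lo, upper = hi,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad())
  co <- coef(fit)
  se <- tryCatch(.hill_se(df, co), error = function(e) {
    tryCatch(sqrt(pmax(diag(vcov(fit)), 0)),
             error = function(e2) c(pKa = NA_real_, n = NA_real_))
  })
  structure(list(pKa = unname(co[["pKa"]]), n = unname(co[["n"]]),
                 se_pKa = unname(se[["pKa"]]), se_n = unname(se[["n"]]),
                 rss = sum(stats::resid(fit)^2),
                 converged = spans),
            class = "hill_fit")
}

# internal: asymptotic standard errors of the unweighted LS Hill estimator.
# With counts: sandwich covariance (J'J)^-1 J'VJ (J'J)^-1, V the fitted
# binomial variances; without counts: homoscedastic residual covariance.
.hill_se <- function(df, co) {
  pKa <- co[["pKa"]]
  n <- co[["n"]]
  shat <- hill_s(df$pH, pKa, n)
  g <- log(10) * shat * (1 - shat)
  J <- cbind(pKa = -n * g, n = -(pKa - df$pH) * g)
  A <- solve(crossprod(J))
  if (!is.null(df$n_total) && all(is.finite(df$n_total)) && all(df$n_total > 0)) {
    V <- pmax(shat * (1 - shat), 0) / df$n_total
    covm <- A %*% (t(J) %*% (V * J)) %*% A
  } else {
    dof <- max(nrow(df) - 2L, 1L)
    sigma2 <- sum((df$s - shat)^2) / dof
    covm <- sigma2 * A
  }
  sqrt(pmax(diag(covm), 0))
}

#' @export
print.hill_fit <- function(x, ...) {
  if (is.na(x$pKa)) {
    cat("<hill_fit> degenerate curve (non-converged)\n")
  } else {
    cat(sprintf("<hill_fit> pKa = %.3f +/- %.3f (n = %.2f +/- %.2f)%s\n",
                x$pKa, x$se_pKa, x$n, x$se_n,
                if (x$converged) "" else " [non-converged]"))
  }
  invisible(x)
}

#' Table of Hill fits per titratable site
#'
#' Fits every site's titration curve and renders the standard
#' "pKa +/- se (Hill n)" summary.
#'
#' @param x A `sample_ledger`, a `ph_streams` list, or a long curve data
#'   frame with columns `site`, `pH`, `s`.
#' @return Data frame (`pka_table`) with columns `site`, `pKa`, `se_pKa`,
#'   `hill_n`, `se_n`, `rss`, `converged`. Non-convergence is a flag, never
#'   an error, so the table always renders.
#' @export
pka_table <- function(x) {
  curves <- if (inherits(x, "sample_ledger")) {
    titration_curves(demultiplex(x))
  } else if (inherits(x, "ph_streams")) {
    titration_curves(x)
  } else {
    stopifnot(all(c("site", "pH", "s") %in% names(x)))
    x
  }
  sites <- unique(curves$site)
  rows <- lapply(sites, function(sid) {
    f <- fit_hill(curves[curves$site == sid, , drop = FALSE])
    data.frame(site = sid, pKa = f$pKa, se_pKa = f$se_pKa, hill_n = f$n,
               se_n = f$se_n, rss = f$rss, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pka_table", "data.frame")
  out
}

#' @export
print.pka_table <- function(x, ...) {
  cat("Hill-fit microscopic pKa values\n")
  for (k in seq_len(nrow(x))) {
    if (is.na(x$pKa[k])) {
      cat(sprintf("  %-10s (degenerate curve)\n", x$site[k]))
    } else {
      cat(sprintf("  %-10s %5.2f +/- %.2f (%.2f)%s\n", x$site[k], x$pKa[k],
                  x$se_pKa[k], x$hill_n[k],
                  if (x$converged[k]) "" else "  [non-converged]"))
    }
  }
  invisible(x)
}

#' Conformer populations versus pH
#'
#' @param streams A `ph_streams` list from [demultiplex()].
#' @return Data frame with columns `pH`, `conformer`, `population`;
#'   populations sum to 1 at each pH. Single-conformer models yield a
#'   trivial table with population 1.
#' @export
conformer_populations <- function(streams) {
  stopifnot(inherits(streams, "ph_streams"))
  ph <- as.numeric(names(streams))
  confs <- sort(unique(unlist(lapply(streams, function(d) unique(d$conformer)))))
  rows <- lapply(seq_along(streams), function(k) {
    tot <- nrow(streams[[k]])
    pop <- vapply(confs, function(cf) sum(streams[[k]]$conformer == cf) / tot,
                  numeric(1))
    data.frame(pH = ph[k], conformer = confs, population = pop,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effective sample size of an autocorrelated series
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated by
#' Geyer's initial-positive-sequence rule (pairs `rho_{2k} + rho_{2k+1}`
#' accumulated while positive), which is mildly conservative for reversible
#' Markov chains. Used to convert Monte Carlo fraction estimates into honest
#' binomial standard errors.
#'
#' @param x Numeric (typically 0/1) series in sampling order.
#' @param lag_max Maximum lag examined (default `min(n - 1, 2000)`).
#' @return Effective sample size, between 1 and `length(x)`.
#' @export
effective_sample_size <- function(x, lag_max = NULL) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(n)
  if (is.null(lag_max)) lag_max <- min(n - 1L, 2000L)
  rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)[-1]
  tau <- 1
  k <- 1L
  while (k <= length(rho)) {
    pair <- rho[k] + if (k + 1L <= length(rho)) rho[k + 1L] else 0
    if (pair <= 0) break
    tau <- tau + 2 * pair
    k <- k + 2L
  }
  max(1, min(n, n / tau))
}

#' Monte Carlo titration curves with autocorrelation-corrected errors
#'
#' Like [titration_curves()] but adds a per-point standard error
#' `sqrt(s (1 - s) / ess)` where `ess` is the per-site, per-pH effective
#' sample size of the recorded 0/1 occupancy series (ordered by attempt).
#'
#' @param streams A `ph_streams` list.
#' @return The [titration_curves()] data frame with extra columns `ess` and
#'   `se`.
#' @export
titration_curves_se <- function(streams) {
  stopifnot(inherits(streams, "ph_streams"))
  sites <- attr(streams, "sites")
  curves <- titration_curves(streams)
  curves$ess <- NA_real_
  for (k in seq_along(streams)) {
    st <- streams[[k]]
    if (!nrow(st)) next
    ph <- as.numeric(names(streams))[k]
    bm <- do.call(rbind, strsplit(st$protonation, "", fixed = TRUE))
    for (j in seq_along(sites)) {
      bits <- as.integer(bm[, j] == "0")
      idx <- curves$site == sites[j] & curves$pH == ph
      curves$ess[idx] <- effective_sample_size(bits)
    }
  }
  curves$se <- sqrt(pmax(curves$s * (1 - curves$s), 0) / curves$ess)
  curves
}
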