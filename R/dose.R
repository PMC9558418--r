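#' Three-parameter log-logistic dose-response analysis
#'
#' Viability after suicide-gene activation (e.g. HSV-TK + ganciclovir) is
#' modelled with the three-parameter log-logistic curve
#' \deqn{f(x) = d / (1 + \exp(b (\ln x - \ln e)))}
#' with lower asymptote fixed at 0: \code{d} is the upper asymptote (response
#' at vanishing dose, as a fraction of vehicle control), \code{b > 0} the
#' slope (response decreases with dose), and \code{e} the ED50 in micromolar
#' -- the dose at which \code{f(e) = d/2} exactly. Confidence intervals are
#' nonparametric bootstrap over replicates, robust at the typical 4
#' replicates per dose.
#'
#' @name dose-response
NULL

ll3 <- function(x, d, b, e) d / (1 + exp(b * (log(x) - log(e))))

#' Fit a three-parameter log-logistic curve
#'
#' Least squares on the positive-dose rows; vehicle rows (dose 0) are
#' excluded from the fit (they are the normalization reference, expected to
#' sit near the upper asymptote). Initialization: \code{d0} = largest
#' per-dose mean response, \code{e0} = dose whose mean response is nearest
#' \code{d0/2}, \code{b0} = 1; box bounds \code{d} in (0, 1.5 max response],
#' \code{b} in [0.1, 20], \code{e} in (0, 1000 max dose]. Curves with no
#' kill (per-dose mean response non-decreasing in dose, or an ED50 estimate
#' beyond the tested range) are censored: \code{converged = FALSE},
#' \code{censored = TRUE} and \code{ed50} set to the maximum tested dose,
#' to be read as "ED50 > max dose".
#'
#' @param data data.frame with \code{dose} (micromolar; 0 allowed for
#'   vehicle) and \code{response} (fraction of vehicle control).
#' @param boot bootstrap resamples for the 95\% CI (default 1000; 0 skips).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return object of class \code{ll3_fit}: \code{d}, \code{b}, \code{e}
#'   (= ED50), \code{converged}, \code{censored}, \code{rss}, \code{n},
#'   \code{ci} (parameter x lower/upper, when bootstrapped).
#' @examples
#' x <- rep(10^seq(-3, 2, length.out = 8), each = 4)
#' y <- 1 / (1 + exp(1 * (log(x) - log(0.4))))
#' fit <- fit_ll3(data.frame(dose = x, response = y))
#' fit$e   # 0.4
#' @export
fit_ll3 <- function(data, boot = 1000L, seed = NULL, conf = 0.95) {
  stopifnot(is.data.frame(data), all(c("dose", "response") %in% names(data)))
  if (any(!is.finite(data$response))) stop("responses must be finite")
  if (any(data$dose < 0)) stop("doses must be non-negative (0 = vehicle)")
  fitdat <- data[data$dose > 0, , drop = FALSE]
  if (length(unique(fitdat$dose)) < 3L) {
    stop("need at least 3 distinct positive doses (one per parameter), got ",
         length(unique(fitdat$dose)))
  }
  est <- ll3_core(fitdat)
  ci <- NULL
  if (!est$censored && boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    bs <- matrix(NA_real_, nrow = boot, ncol = 3L,
                 dimnames = list(NULL, c("d", "b", "e")))
    split_by_dose <- split(seq_len(nrow(fitdat)), fitdat$dose)
    for (i in seq_len(boot)) {
      idx <- unlist(lapply(split_by_dose, function(ii) {
        ii[sample.int(length(ii), length(ii), replace = TRUE)]
      }), use.names = FALSE)
      bfit <- try(ll3_core(fitdat[idx, , drop = FALSE]), silent = TRUE)
      if (!inherits(bfit, "try-error") && !bfit$censored) {
        bs[i, ] <- c(bfit$d, bfit$b, bfit$e)
      }
    }
    a <- (1 - conf) / 2
    ci <- t(apply(bs, 2L, quantile, probs = c(a, 1 - a), na.rm = TRUE))
    colnames(ci) <- c("lower", "upper")
  }
  structure(c(est, list(ci = ci, n = nrow(fitdat), boot = boot, conf = conf,
                        data = data)),
            class = "ll3_fit")
}

## single least-squares fit on positive-dose data
ll3_core <- function(fitdat) {
  x <- fitdat$dose; y <- fitdat$response
  mm <- tapply(y, x, mean)
  dd <- sort(unique(x))
  max_dose <- max(dd)
  ## no-kill censoring: per-dose means never decrease along the dose axis
  if (all(diff(mm[as.character(dd)]) >= 0)) {
    return(list(d = unname(max(mm)), b = NA_real_, e = max_dose,
                converged = FALSE, censored = TRUE, rss = NA_real_))
  }
  d0 <- max(mm)
  e0 <- dd[which.min(abs(mm[as.character(dd)] - d0 / 2))]
  obj <- function(p) {
    r <- y - ll3(x, p[1L], p[2L], exp(p[3L]))
    sum(r * r)
  }
  upper_e <- 1e3 * max_dose
  lower <- c(1e-8, 0.1, log(upper_e) - 60)
  upper <- c(1.5 * max(y), 20, log(upper_e))
  opt <- optim(c(d0, 1, log(e0)), obj, method = "L-BFGS-B",
               lower = lower, upper = upper)
  ## Nelder-Mead polish for tight identifiability on clean data; kept only
  ## when it improves the fit and respects the box
  polish <- optim(opt$par, obj, method = "Nelder-Mead",
                  control = list(reltol = 1e-14, maxit = 2000L))
  if (polish$value <= opt$value &&
      all(polish$par >= lower) && all(polish$par <= upper)) {
    opt <- polish
  }
  e_hat <- exp(opt$par[3L])
  if (e_hat > max_dose) {
    return(list(d = opt$par[1L], b = opt$par[2L], e = max_dose,
                converged = FALSE, censored = TRUE, rss = opt$value))
  }
  list(d = opt$par[1L], b = opt$par[2L], e = e_hat,
       converged = opt$convergence == 0L, censored = FALSE, rss = opt$value)
}

#' @export
print.ll3_fit <- function(x, ...) {
  cat("3-parameter log-logistic fit (n =", x$n, ")\n")
  if (x$censored) {
    cat("  censored: no kill observed; ED50 >", x$e, "uM\n")
  } else {
    cat(sprintf("  upper d = %.4g  slope b = %.4g  ED50 e = %.4g uM\n",
                x$d, x$b, x$e))
    if (!is.null(x$ci)) {
      cat(sprintf("  ED50 %d%% CI: [%.4g, %.4g] (bootstrap, B = %d)\n",
                  round(100 * x$conf), x$ci["e", "lower"],
                  x$ci["e", "upper"], x$boot))
    }
  }
  invisible(x)
}

#' @export
coef.ll3_fit <- function(object, ...) {
  c(d = object$d, b = object$b, e = object$e)
}

#' @export
predict.ll3_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$dose else newdata
  ll3(x, object$d, object$b, object$e)
}

#' ED50 fold change between two groups of fits
#'
#' Ratio of geometric-mean ED50s, group B over group A (so a sensitized
#' group A against resistant controls B yields a ratio > 1, e.g. the
#' ~100-fold separation between suicide-gene-transduced fusion-positive
#' lines and controls). Censored or non-converged fits are excluded with a
#' warning; the CI resamples fits within each group.
#'
#' @param fits_A,fits_B lists of \code{\link{fit_ll3}} objects (a single fit
#'   is accepted).
#' @param n_boot resamples for the CI (default 1000; 0 skips).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list with \code{ratio}, \code{ci} (length-2 or NULL),
#'   \code{n_A}, \code{n_B} (converged fits used).
#' @export
ed50_fold_change <- function(fits_A, fits_B, n_boot = 1000L, seed = NULL,
                             conf = 0.95) {
  eA <- usable_ed50s(fits_A, "A")
  eB <- usable_ed50s(fits_B, "B")
  ratio <- gmean(eB) / gmean(eA)
  ci <- NULL
  if (n_boot > 0L && (length(eA) > 1L || length(eB) > 1L)) {
    if (!is.null(seed)) set.seed(seed)
    rr <- vapply(seq_len(n_boot), function(i) {
      gmean(sample(eB, replace = TRUE)) / gmean(sample(eA, replace = TRUE))
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- unname(quantile(rr, c(a, 1 - a)))
  }
  list(ratio = ratio, ci = ci, n_A = length(eA), n_B = length(eB))
}

usable_ed50s <- function(fits, label) {
  if (inherits(fits, "ll3_fit")) fits <- list(fits)
  ok <- vapply(fits, function(f) isTRUE(f$converged) && !isTRUE(f$censored),
               logical(1))
  if (!all(ok)) {
    warning(sum(!ok), " censored/non-converged fit(s) excluded from group ",
            label)
  }
  if (!any(ok)) stop("all fits in group ", label, " are censored")
  vapply(fits[ok], function(f) f$e, numeric(1))
}
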