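#' Maximum-likelihood cumulative-Gaussian psychometric fit
#'
#' Fits `P(forward | d) = lapse/2 + (1 - lapse) * Phi((d - pss) / jnd)` to
#' per-trial forward/backward reports by maximising the Bernoulli likelihood.
#' The mean of the cumulative Gaussian is the point of subjective
#' stationarity (PSS, a bias measure, forward-positive) and its SD the
#' just-noticeable difference (JND, a precision measure). The lapse rate is
#' fixed at 0 by default or estimated within [0, 0.05]. Optimisation uses
#' L-BFGS-B on (pss, log jnd [, lapse]) from five deterministic starts laid
#' out on a grid over the data range.
#'
#' @param levels Displacement level per trial, degrees (forward-positive).
#' @param reports Character vector, `"forward"`/`"backward"` per trial
#'   (trials with `"none"` must be removed beforehand).
#' @param estimate_lapse If `TRUE`, estimate the lapse rate in [0, 0.05];
#'   otherwise fix it at `lapse`.
#' @param lapse Fixed lapse rate when `estimate_lapse = FALSE`.
#' @param min_trials Minimum number of trials required (default 20).
#' @return An object of class `psychometric_fit` with elements `pss`, `jnd`,
#'   `lapse`, `log_likelihood`, `n_trials`, `converged`, `separated` (JND at
#'   its lower bound under complete separation) and a per-level count table.
#' @export
fit_cumulative_gaussian <- function(levels, reports, estimate_lapse = FALSE,
                                    lapse = 0, min_trials = 20) {
  stopifnot(length(levels) == length(reports))
  keep <- reports %in% c("forward", "backward")
  levels <- levels[keep]
  reports <- reports[keep]
  y <- as.integer(reports == "forward")
  if (length(unique(levels)) < 2) {
    stop("degenerate data: need at least 2 distinct levels", call. = FALSE)
  }
  if (length(y) < min_trials) {
    stop(sprintf("degenerate data: fewer than %d trials", min_trials),
         call. = FALSE)
  }
  if (all(y == 1L) || all(y == 0L)) {
    stop("degenerate data: all responses identical", call. = FALSE)
  }
  counts <- stats::aggregate(y, by = list(level = levels),
                             FUN = function(z) c(n = length(z), k = sum(z)))
  counts <- data.frame(level = counts$level,
                       n = counts$x[, "n"], n_forward = counts$x[, "k"])
  jnd_lo <- 1e-2
  jnd_hi <- 50
  nll <- function(par) {
    pss <- par[1]; jnd <- exp(par[2])
    lam <- if (estimate_lapse) par[3] else lapse
    p <- lam / 2 + (1 - lam) * stats::pnorm((levels - pss) / jnd)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  rng_lev <- range(levels)
  starts <- list(
    c(mean(rng_lev), log(diff(rng_lev) / 4 + 0.1)),
    c(rng_lev[1] / 2, log(1)),
    c(rng_lev[2] / 2, log(1)),
    c(0, log(0.5)),
    c(0, log(2)))
  lower <- c(-Inf, log(jnd_lo)); upper <- c(Inf, log(jnd_hi))
  if (estimate_lapse) {
    starts <- lapply(starts, c, 0.01)
    lower <- c(lower, 0); upper <- c(upper, 0.05)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e2, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("optimisation failed from every start", call. = FALSE)
  pss <- best$par[1]
  jnd <- exp(best$par[2])
  lam <- if (estimate_lapse) best$par[3] else lapse
  # complete separation: every backward report lies below every forward one,
  # so the slope is unidentified and the JND collapses toward its bound
  separated <- max(levels[y == 0L]) < min(levels[y == 1L])
  structure(list(pss = pss, jnd = jnd, lapse = lam,
                 log_likelihood = -best$value,
                 n_trials = length(y),
                 converged = best$convergence == 0,
                 separated = separated,
                 counts = counts),
            class = "psychometric_fit")
}

#' Predicted probability of a forward report
#'
#' @param fit A `psychometric_fit` (or a list with `pss`, `jnd`, `lapse`).
#' @param d Displacement, degrees (forward-positive).
#' @return `P(forward | d)` under the fitted function.
#' @export
predict_forward <- function(fit, d) {
  fit$lapse / 2 + (1 - fit$lapse) * stats::pnorm((d - fit$pss) / fit$jnd)
}

#' Percent-correct conversion of a psychometric function
#'
#' Folds the fitted function about zero, discarding the null displacement:
#' `PC(|d|) = (F(|d|) + 1 - F(-|d|)) / 2`, where `F` is the fitted
#' probability of a forward report. Defined for `|d| > 0` only.
#'
#' @param fit A `psychometric_fit`.
#' @return A function of the absolute displacement returning the proportion
#'   correct.
#' @export
percent_correct_curve <- function(fit) {
  function(ad) {
    if (any(ad <= 0)) {
      stop("percent correct is undefined at null displacement", call. = FALSE)
    }
    (predict_forward(fit, ad) + 1 - predict_forward(fit, -ad)) / 2
  }
}

#' 75 percent-correct displacement threshold
#'
#' The smallest absolute displacement at which the folded percent-correct
#' curve reaches 0.75, found by bracketed root finding. At `pss = 0` and
#' `lapse = 0` this equals `qnorm(0.75) * jnd` (about 0.6745 JND).
#'
#' @param fit A `psychometric_fit`.
#' @param tol Root-finding tolerance in degrees (default 1e-6).
#' @return Threshold in degrees.
#' @export
threshold_75 <- function(fit, tol = 1e-6) {
  pc <- percent_correct_curve(fit)
  asym <- 1 - fit$lapse / 2
  if (asym <= 0.75) stop("no threshold: asymptote below 75%", call. = FALSE)
  lo <- 1e-9
  hi <- max(4 * fit$jnd + 2 * abs(fit$pss), 1)
  while (pc(hi) < 0.75) {
    hi <- hi * 2
    if (hi > 1e6) stop("no threshold: curve never reaches 75%", call. = FALSE)
  }
  if (pc(lo) >= 0.75) return(0)
  stats::uniroot(function(x) pc(x) - 0.75, c(lo, hi), tol = tol)$root
}

#' Fit psychometric functions for every condition x direction cell
#'
#' @param trials A trial table (one subject) with `condition`, `direction`,
#'   `displacement`, `report` columns; `report == "none"` rows are dropped.
#' @param ... Passed to `fit_cumulative_gaussian()`.
#' @return A data frame with one row per cell: pss, jnd, lapse, threshold,
#'   n, converged.
#' @export
fit_subject <- function(trials, ...) {
  cells <- unique(trials[c("condition", "direction")])
  do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    sel <- trials$condition == cells$condition[k] &
      trials$direction == cells$direction[k] &
      trials$report != "none"
    fit <- fit_cumulative_gaussian(trials$displacement[sel],
                                   trials$report[sel], ...)
    data.frame(condition = cells$condition[k],
               direction = cells$direction[k],
               pss = fit$pss, jnd = fit$jnd, lapse = fit$lapse,
               threshold = threshold_75(fit),
               n = fit$n_trials, converged = fit$converged,
               stringsAsFactors = FALSE)
  }))
}
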