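#' Assemble survival records from a synthetic cohort
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param endpoint Endpoint column excluded from the covariates.
#' @return A list of class `surv_records`: `time`, `status`, `X`
#'   (covariate matrix).
#' @export
surv_records <- function(cohort, endpoint = cohort$spec$endpoint) {
  X <- cohort$table[, setdiff(colnames(cohort$table), endpoint), drop = FALSE]
  structure(list(time = cohort$survival$time,
                 status = cohort$survival$status, X = X),
            class = "surv_records")
}

#' Build survival records from raw vectors
#'
#' @param time Positive follow-up times.
#' @param status 0/1 event indicators.
#' @param X Covariate matrix (one column per variable).
#' @return A `surv_records` list.
#' @export
as_surv_records <- function(time, status, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  if (any(!status %in% c(0, 1))) stop("status must be 0/1", call. = FALSE)
  if (length(time) != length(status) || length(time) != nrow(X)) {
    stop("time, status and X must have matching lengths", call. = FALSE)
  }
  structure(list(time = as.numeric(time), status = as.integer(status), X = X),
            class = "surv_records")
}

# Partial log-likelihood, score and information at beta, with Breslow or
# Efron handling of tied event times.  Data must be pre-sorted by
# decreasing time.  Risk-set sums are prefix sums in that order, so the
# Breslow terms vectorize over the event-time blocks; Efron adjusts the
# (usually few) blocks with two or more tied events.
cox_derivs <- function(time, status, X, beta, ties) {
  n <- length(time)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  r <- exp(eta)
  S0 <- cumsum(r)
  Xr <- X * r
  S1 <- apply(Xr, 2, cumsum)
  if (!is.matrix(S1)) S1 <- matrix(S1, ncol = p)
  XX <- matrix(0, n, p * p)
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      XX[, (a - 1) * p + b] <- X[, a] * Xr[, b]
    }
  }
  S2 <- apply(XX, 2, cumsum)
  if (!is.matrix(S2)) S2 <- matrix(S2, ncol = p * p)

  # blocks of equal (tied) times; block b spans rows (e[b-1], e[b]]
  e_end <- c(which(diff(time) != 0), n)
  blk <- rep(seq_along(e_end), times = diff(c(0L, e_end)))
  d <- drop(rowsum(status, blk, reorder = FALSE))
  ev_blk <- which(d > 0)

  j <- e_end[ev_blk]                       # risk-set boundary per event block
  db <- d[ev_blk]
  s0 <- S0[j]
  u <- S1[j, , drop = FALSE] / s0          # m x p, S1/S0 per block
  loglik <- sum(eta[status == 1]) - sum(db * log(s0))
  xsum <- rowsum(X * status, blk, reorder = FALSE)[ev_blk, , drop = FALSE]
  grad <- colSums(xsum) - colSums(u * db)
  info <- matrix(colSums(S2[j, , drop = FALSE] * (db / s0)), p, p) -
    crossprod(u, u * db)

  if (ties == "efron" && any(db > 1)) {
    # replace the Breslow contribution of multi-event blocks
    for (bi in ev_blk[d[ev_blk] > 1]) {
      rows <- which(blk == bi)
      ev <- rows[status[rows] == 1]
      dd <- length(ev)
      jj <- e_end[bi]
      s0b <- S0[jj]; s1b <- S1[jj, ]; s2b <- matrix(S2[jj, ], p, p)
      ub <- s1b / s0b
      loglik <- loglik + dd * log(s0b)
      grad <- grad + dd * ub
      info <- info - dd * (s2b / s0b - tcrossprod(ub))
      rd <- sum(r[ev])
      s1d <- colSums(X[ev, , drop = FALSE] * r[ev])
      s2d <- matrix(0, p, p)
      for (ei in ev) s2d <- s2d + r[ei] * tcrossprod(X[ei, ])
      for (l in 0:(dd - 1)) {
        f <- l / dd
        s0l <- s0b - f * rd
        s1l <- s1b - f * s1d
        s2l <- s2b - f * s2d
        loglik <- loglik - log(s0l)
        grad <- grad - s1l / s0l
        info <- info + s2l / s0l - tcrossprod(s1l / s0l)
      }
    }
  }
  list(loglik = loglik, grad = grad, info = info)
}

#' Fit a Cox proportional-hazards model by Newton-Raphson
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling by default,
#' Efron optionally) with Newton-Raphson and step-halving whenever a step
#' would decrease the likelihood.  Convergence is declared when the
#' max-norm of the score vector falls below `tol`.  Standard errors come
#' from the inverse observed information; 95% confidence intervals are
#' Wald intervals on the log scale.
#'
#' @param data A `surv_records` list.
#' @param covariates Character vector of covariate names to include
#'   (default: all columns of `data$X`).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param tol Gradient max-norm tolerance (default 1e-9).
#' @param max_iter Maximum Newton iterations (default 50); hitting it
#'   flags the fit as non-converged instead of raising an error.
#' @return An object of class `cox_fit`: `coefficients` data.frame
#'   (`variable`, `beta`, `se`, `hr`, `ci_low`, `ci_high`, `wald_p`),
#'   `loglik`, `converged`, `iterations`, `vcov`.
#' @export
fit_cox <- function(data, covariates = NULL, ties = c("breslow", "efron"),
                    tol = 1e-9, max_iter = 50) {
  ties <- match.arg(ties)
  stopifnot(inherits(data, "surv_records"))
  if (is.null(covariates)) covariates <- colnames(data$X)
  if (!all(covariates %in% colnames(data$X))) {
    stop("unknown covariate(s): ",
         paste(setdiff(covariates, colnames(data$X)), collapse = ", "),
         call. = FALSE)
  }
  if (sum(data$status) < 1) stop("no events in the data", call. = FALSE)
  X <- data$X[, covariates, drop = FALSE]
  storage.mode(X) <- "double"
  const <- covariates[apply(X, 2, function(v) length(unique(v)) < 2)]
  if (length(const)) {
    stop(sprintf("constant covariate(s): %s", paste(const, collapse = ", ")),
         call. = FALSE)
  }
  ord <- order(-data$time)
  time <- data$time[ord]; status <- data$status[ord]
  X <- X[ord, , drop = FALSE]
  p <- ncol(X)
  beta <- numeric(p)
  d0 <- cox_derivs(time, status, X, beta, ties)
  ll <- d0$loglik
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    if (max(abs(d0$grad)) <= tol) { converged <- TRUE; break }
    if (iter > max_iter) { iter <- max_iter; break }
    step <- tryCatch(solve(d0$info, d0$grad), error = function(e) NULL)
    if (is.null(step)) {
      stop("singular information matrix (possible monotone likelihood) for: ",
           paste(covariates, collapse = ", "), call. = FALSE)
    }
    halve <- 0
    repeat {
      cand <- beta + step / 2^halve
      dc <- cox_derivs(time, status, X, cand, ties)
      if (dc$loglik >= ll - 1e-12 || halve >= 20) break
      halve <- halve + 1
    }
    beta <- cand
    if (any(abs(beta) > 15)) {
      stop("monotone partial likelihood (complete separation) involving: ",
           paste(covariates[abs(beta) > 15], collapse = ", "), call. = FALSE)
    }
    ll <- dc$loglik
    d0 <- dc
  }
  vcov <- solve(d0$info)
  se <- sqrt(diag(vcov))
  z <- beta / se
  coef <- data.frame(
    variable = covariates, beta = beta, se = se, hr = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    wald_p = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(coefficients = coef, loglik = ll, converged = converged,
                 iterations = iter, ties = ties, vcov = vcov,
                 n = length(time), n_events = sum(status)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): n = %d, events = %d, loglik = %.3f, %s in %d iter\n",
              x$ties, x$n, x$n_events, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Cox score test at beta = 0
#'
#' The score (Rao) test statistic of a single covariate evaluated at
#' \eqn{\beta = 0}; on two-group data without tied event times it equals
#' the log-rank chi-squared statistic.
#'
#' @param data A `surv_records` list.
#' @param covariate Covariate name.
#' @return List with `statistic` (chi-squared, 1 df) and `p`.
#' @export
cox_score_test <- function(data, covariate) {
  ord <- order(-data$time)
  X <- data$X[ord, covariate, drop = FALSE]
  storage.mode(X) <- "double"
  d <- cox_derivs(data$time[ord], data$status[ord], X, 0, "breslow")
  stat <- d$grad^2 / d$info[1, 1]
  list(statistic = as.numeric(stat), p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Univariate Cox screen over all covariates
#'
#' Fits one single-covariate model per variable; per-variable failures
#' (e.g. constant covariates or separation) are captured and reported
#' without aborting the rest of the screen.
#'
#' @inheritParams fit_cox
#' @return A list of class `cox_screen`: `table` (one row per variable:
#'   `variable`, `beta`, `se`, `hr`, `ci_low`, `ci_high`, `wald_p`,
#'   `converged`, `error`), `fits` (named list of `cox_fit` or `NULL`).
#' @export
univariate_screen <- function(data, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  vars <- colnames(data$X)
  fits <- stats::setNames(vector("list", length(vars)), vars)
  rows <- lapply(vars, function(v) {
    fit <- tryCatch(fit_cox(data, covariates = v, ties = ties),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(variable = v, beta = NA_real_, se = NA_real_, hr = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, wald_p = NA_real_,
                 converged = FALSE, error = conditionMessage(fit),
                 stringsAsFactors = FALSE)
    } else {
      fits[[v]] <<- fit
      cbind(fit$coefficients, converged = fit$converged, error = NA_character_,
            stringsAsFactors = FALSE)
    }
  })
  structure(list(table = do.call(rbind, rows), fits = fits),
            class = "cox_screen")
}

#' Write a hazard-ratio table as delimited text
#'
#' @param x A `cox_fit` or `cox_screen`.
#' @param path Output file.
#' @param sep Field separator.
#' @export
write_hr_table <- function(x, path, sep = "\t") {
  tab <- if (inherits(x, "cox_screen")) x$table else
    cbind(x$coefficients, converged = x$converged)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
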