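#' Poisson regression by iteratively reweighted least squares
#'
#' Maximum-likelihood Poisson regression with a log link and an offset,
#' implemented directly so the fixed-effects reference path of the
#' occurrence model is self-contained and transparent. Convergence when the
#' maximum absolute score (gradient of the log-likelihood) falls below
#' `tol`, or after `max_iter` iterations.
#'
#' @param X Design matrix (full column rank).
#' @param y Nonnegative integer counts.
#' @param offset Offset vector on the linear-predictor (log) scale.
#' @param tol Score convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return List `coef` (named), `vcov` (inverse Fisher information),
#'   `fitted` (response-scale means), `iter`, `converged`,
#'   `pearson_dispersion` (Pearson chi-square / residual df).
#' @export
fit_poisson_fixed <- function(X, y, offset = rep(0, length(y)),
                              tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  if (any(y < 0) || any(y != round(y))) stop("counts must be nonnegative integers")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- numeric(ncol(X))
  # sensible intercept start when the first column is constant
  if (all(X[, 1] == 1)) beta[1] <- log(mean(y / exp(offset)) + 1e-12)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- as.numeric(X %*% beta) + offset
    mu <- exp(eta)
    score <- as.numeric(crossprod(X, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    XtWX <- crossprod(X * mu, X)
    beta <- beta + solve(XtWX, score)
  }
  eta <- as.numeric(X %*% beta) + offset
  mu <- exp(eta)
  names(beta) <- colnames(X)
  vcov <- solve(crossprod(X * mu, X))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  df_res <- length(y) - ncol(X)
  list(coef = beta, vcov = vcov, fitted = mu, iter = iter,
       converged = converged,
       pearson_dispersion = sum((y - mu)^2 / mu) / max(df_res, 1L))
}

#' Build the occurrence-model design
#'
#' Fixed effects: full factorial of observer-distance stratum (reference
#' `far`, dummy for `close`), continuous tolerance, and year, up to the
#' three-way interaction. Predictors are used as-is (no centering or
#' scaling: stratum and year are categorical and tolerance is already a
#' deviation from the population mean).
#'
#' @param counts Occurrence-count table ([count_occurrences()]) for one
#'   buffer, both strata and all years.
#' @param tolerances Data frame `individual_id, tolerance` (e.g. from
#'   [conditional_modes()]).
#' @return List `data` (merged model frame), `X` (design matrix), `y`,
#'   `offset` (log exposure).
#' @export
occurrence_design <- function(counts, tolerances) {
  dat <- merge(counts, tolerances[, c("individual_id", "tolerance")],
               by = "individual_id", sort = FALSE)
  if (anyNA(dat$tolerance)) stop("missing tolerance for some individuals")
  if (any(dat$exposure <= 0)) stop("non-positive exposure")
  dat$stratum <- factor(dat$stratum, levels = c("far", "close"))
  dat$year <- factor(dat$year)
  X <- stats::model.matrix(~ stratum * tolerance * year, dat)
  list(data = dat, X = X, y = dat$count, offset = log(dat$exposure))
}

#' Fit the occurrence model for one proximity buffer
#'
#' Poisson regression of per-individual neighbour-occurrence counts on the
#' stratum x tolerance x year factorial with a log-exposure offset, plus an
#' uncertainty layer yielding a draws table consumed by
#' [summarize_draws()]:
#'
#' * `backend = "bootstrap"` (default, self-contained): maximum-likelihood
#'   fit by [fit_poisson_fixed()], with a nonparametric cluster bootstrap
#'   over individuals (respecting the repeated far/close x year measures per
#'   animal) providing the draws.
#' * `backend = "glmm"`: Poisson GLMM via `glmmTMB` with the full correlated
#'   random-slope structure over individual identity (intercept, stratum,
#'   tolerance, stratum:tolerance, year); draws are sampled from the
#'   Gaussian approximation to the fixed-effect posterior (estimate +
#'   covariance from the Laplace fit).
#'
#' @param counts Occurrence-count table for one buffer.
#' @param tolerances Data frame `individual_id, tolerance`.
#' @param backend `"bootstrap"` or `"glmm"`.
#' @param n_draws Bootstrap resamples / posterior draws (default 1000).
#' @param seed Integer seed for the resampling or draw stream.
#' @return List of class `occurrence_fit`: `coef`, `vcov`, `draws` (matrix
#'   draws x terms), `summary` (from [summarize_draws()]), `r2` (Bayesian
#'   R-squared list), `dispersion`, `backend`, `buffer`.
#' @export
fit_occurrence_model <- function(counts, tolerances,
                                 backend = c("bootstrap", "glmm"),
                                 n_draws = 1000L, seed = 1L) {
  backend <- match.arg(backend)
  buffer <- unique(counts$buffer)
  if (length(buffer) != 1) stop("counts must cover exactly one buffer")
  des <- occurrence_design(counts, tolerances)
  base <- fit_poisson_fixed(des$X, des$y, des$offset)

  set.seed(seed)
  if (backend == "bootstrap") {
    ids <- unique(des$data$individual_id)
    rows_of <- split(seq_len(nrow(des$data)), des$data$individual_id)
    draws <- matrix(NA_real_, n_draws, ncol(des$X),
                    dimnames = list(NULL, colnames(des$X)))
    pred <- matrix(NA_real_, n_draws, nrow(des$data))
    for (b in seq_len(n_draws)) {
      take <- unlist(rows_of[sample(ids, length(ids), replace = TRUE)],
                     use.names = FALSE)
      fb <- try(fit_poisson_fixed(des$X[take, , drop = FALSE], des$y[take],
                                  des$offset[take]), silent = TRUE)
      if (inherits(fb, "try-error")) next  # rank-deficient resample: redraw
      draws[b, ] <- fb$coef
      pred[b, ] <- exp(as.numeric(des$X %*% fb$coef) + des$offset)
    }
    ok <- !is.na(draws[, 1])
    draws <- draws[ok, , drop = FALSE]
    pred <- pred[ok, , drop = FALSE]
    coef <- base$coef
    vcov <- stats::cov(draws)
  } else {
    if (!requireNamespace("glmmTMB", quietly = TRUE)) {
      stop("backend 'glmm' needs the glmmTMB package")
    }
    des$data$.off <- des$offset
    fit <- glmmTMB::glmmTMB(
      count ~ stratum * tolerance * year + offset(.off) +
        (1 + stratum + tolerance + stratum:tolerance + year | individual_id),
      family = stats::poisson(), data = des$data)
    coef <- glmmTMB::fixef(fit)$cond
    vcov <- stats::vcov(fit)$cond
    L <- chol(as.matrix(vcov))
    z <- matrix(stats::rnorm(n_draws * length(coef)), n_draws)
    draws <- sweep(z %*% L, 2L, coef, "+")
    colnames(draws) <- names(coef)
    pred <- exp(draws %*% t(des$X[, names(coef), drop = FALSE]) +
                  matrix(des$offset, n_draws, nrow(des$X), byrow = TRUE))
  }

  # Poisson residual variance per draw: the modelled conditional variance
  # of a future count equals its mean, so the draw's residual variance is
  # the average fitted mean.
  r2 <- bayes_r2(pred, rowMeans(pred))
  structure(list(coef = coef, vcov = vcov, draws = draws,
                 summary = summarize_draws(draws),
                 r2 = r2[c("mean", "sd")],
                 dispersion = base$pearson_dispersion,
                 backend = backend, buffer = buffer,
                 n_draws = nrow(draws), seed = seed),
            class = "occurrence_fit")
}

#' @export
print.occurrence_fit <- function(x, ...) {
  cat("Occurrence model (", x$buffer, " buffer, backend = ", x$backend,
      ", ", x$n_draws, " draws)\n", sep = "")
  cat(sprintf("Bayesian R2: %.2f (%.2f)   Pearson dispersion: %.2f\n",
              x$r2$mean, x$r2$sd, x$dispersion))
  s <- x$summary
  s[, sapply(s, is.numeric)] <- round(s[, sapply(s, is.numeric)], 3)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write a draws table to CSV
#'
#' Long format: `term, draw, value`.
#'
#' @param fit An `occurrence_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_draws_csv <- function(fit, path) {
  d <- fit$draws
  long <- data.frame(term = rep(colnames(d), each = nrow(d)),
                     draw = rep(seq_len(nrow(d)), ncol(d)),
                     value = as.numeric(d))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
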