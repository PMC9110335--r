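#' Highest density interval of a sample
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' draws (sliding-window search; assumes a unimodal sample — for multimodal
#' posteriors the shortest *contiguous* interval can overstate density
#' regions).
#'
#' @param draws Numeric vector of posterior draws (>= 10 for a meaningful
#'   interval; >= 1 accepted).
#' @param mass Probability mass, in (0, 1). Default 0.89.
#' @return Numeric `c(low, high)`.
#' @export
#' @examples
#' hdi(1:100)  # c(1, 89)
hdi <- function(draws, mass = 0.89) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  if (!n) stop("no finite draws")
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1])
}

#' Probability of direction
#'
#' The proportion of the posterior with the dominant sign, as a percentage
#' in \[50, 100\]; draws exactly at zero are split evenly between signs.
#'
#' @param draws Numeric vector, length >= 1.
#' @return Percentage in \[50, 100\].
#' @export
#' @examples
#' pd(c(-1, 2, 3, 4))  # 75
pd <- function(draws) {
  x <- draws[is.finite(draws)]
  if (!length(x)) stop("no finite draws")
  pz <- mean(x == 0) / 2
  100 * max(mean(x > 0) + pz, mean(x < 0) + pz)
}

#' Fraction of the posterior inside the region of practical equivalence
#'
#' By default the proportion of draws *inside the 89% HDI* that also lie in
#' the ROPE (the convention used when an HDI-based ROPE percentage is
#' quoted); `within_hdi = FALSE` uses the full posterior instead.
#'
#' @param draws Numeric vector.
#' @param rope Interval equated with the null; default `c(-0.1, 0.1)`.
#' @param mass HDI mass when `within_hdi` is `TRUE`.
#' @param within_hdi Restrict to draws inside the HDI (default `TRUE`).
#' @return Proportion in \[0, 1\].
#' @export
rope_fraction <- function(draws, rope = c(-0.1, 0.1), mass = 0.89,
                          within_hdi = TRUE) {
  x <- draws[is.finite(draws)]
  if (within_hdi) {
    h <- hdi(x, mass)
    x <- x[x >= h[1] & x <= h[2]]
  }
  mean(x >= rope[1] & x <= rope[2])
}

#' Bayesian R-squared from predictive draws
#'
#' Per draw, R2 = Var(predicted means) / (Var(predicted means) + residual
#' variance): the proportion of variance a model is expected to explain in
#' future observations. Reported as mean and SD over draws.
#'
#' @param pred_draws Matrix of predicted means, draws x observations.
#' @param resid_var_draws Numeric vector: modelled residual variance per
#'   draw (same length as `nrow(pred_draws)`).
#' @return List `mean`, `sd`, `draws` (per-draw R2 values).
#' @export
bayes_r2 <- function(pred_draws, resid_var_draws) {
  pred_draws <- as.matrix(pred_draws)
  stopifnot(nrow(pred_draws) == length(resid_var_draws))
  vp <- apply(pred_draws, 1L, stats::var)
  tot <- vp + resid_var_draws
  if (any(tot <= 0)) stop("zero total variance in at least one draw")
  r2 <- vp / tot
  list(mean = mean(r2), sd = stats::sd(r2), draws = r2)
}

#' Summarize posterior (or bootstrap) draws per model term
#'
#' @param draws Matrix, draws x terms (named columns), or a data frame.
#' @param mass HDI mass (default 0.89).
#' @param rope ROPE interval (default `c(-0.1, 0.1)`).
#' @return Data frame with one row per term: `estimate` (posterior median),
#'   `mean`, `hdi_low`, `hdi_high`, `rope_fraction`, `pd`.
#' @export
summarize_draws <- function(draws, mass = 0.89, rope = c(-0.1, 0.1)) {
  draws <- as.matrix(draws)
  out <- do.call(rbind, lapply(colnames(draws), function(term) {
    x <- draws[, term]
    h <- hdi(x, mass)
    data.frame(term = term,
               estimate = stats::median(x),
               mean = mean(x),
               hdi_low = h[1], hdi_high = h[2],
               rope_fraction = rope_fraction(x, rope, mass),
               pd = pd(x),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
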