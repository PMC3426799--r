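# Bootstrap resampling as case weights. Both schemes are normalized to a
# total mass of N so that every count position and penalty term in the
# scoring metrics sees the same effective sample size as the original data.

#' Bootstrap case weights
#'
#' \describe{
#'   \item{ordinary}{integer weights \eqn{w \sim} Multinomial(\eqn{N},
#'     uniform): the classical draw-with-replacement bootstrap expressed as
#'     per-case occurrence counts. About \eqn{(1-1/N)^N \to 1/e \approx 37\%}
#'     of cases receive weight 0 in any one resample.}
#'   \item{bayesian}{continuous weights \eqn{w = N g} with
#'     \eqn{g \sim} Dirichlet(1, ..., 1): the Bayesian bootstrap. All
#'     weights are positive almost surely, so no case is ever excluded —
#'     every inter-case relationship is preserved in reweighted form.}
#' }
#'
#' @param n number of cases.
#' @param type \code{"ordinary"} or \code{"bayesian"}.
#' @return numeric weight vector summing to \code{n}.
#' @examples
#' set.seed(1)
#' w <- bootstrap_weights(1000, "ordinary")
#' mean(w == 0)  # about 1/e
#' @export
bootstrap_weights <- function(n, type = c("bayesian", "ordinary")) {
  type <- match.arg(type)
  if (n < 1) stop("n must be >= 1")
  if (type == "ordinary") {
    as.numeric(tabulate(sample.int(n, n, replace = TRUE), nbins = n))
  } else {
    g <- stats::rexp(n)          # Dirichlet(1,...,1) via normalized Exp(1)
    n * g / sum(g)
  }
}

#' Sampling variance of a bagged feature probability
#'
#' Treating each resample's feature indicator as Bernoulli(\eqn{p}), the
#' bagged probability over \eqn{B} resamples is approximately normal with
#' variance \eqn{p(1-p)/B}; the worst case over \eqn{p} is \eqn{0.25/B}.
#'
#' @param p true feature probability in \eqn{[0,1]}.
#' @param B number of bootstrap resamples.
#' @return the variance \eqn{p(1-p)/B}.
#' @seealso [required_resamples()]
#' @export
resample_variance <- function(p, B) {
  stopifnot(p >= 0, p <= 1, B >= 1)
  p * (1 - p) / B
}

#' Resamples needed for a target standard deviation
#'
#' Inverts \eqn{p(1-p)/B = \sigma^2}: \eqn{B = \lceil p(1-p)/\sigma^2
#' \rceil}. At the worst case \eqn{p = 0.5} and \eqn{\sigma = 0.01} this
#' gives 2500 resamples — an order of magnitude more than the 200 commonly
#' used, which is why the bagging default here is 2500.
#'
#' @param p feature probability the bound is evaluated at.
#' @param sigma target standard deviation of the bagged probability.
#' @return integer number of resamples.
#' @export
required_resamples <- function(p, sigma) {
  stopifnot(p >= 0, p <= 1, sigma > 0)
  as.integer(ceiling(p * (1 - p) / sigma^2))
}
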