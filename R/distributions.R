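#' Beta-binomial density
#'
#' Density of the beta-binomial distribution parameterized by a success
#' probability `prob` and an intra-class correlation `rho` in [0, 1).
#' `rho = 0` reduces exactly to the binomial. Allele-support counts at
#' heterozygous sites are modelled this way: `prob` is the expected allele
#' fraction (k copies out of c) and `rho` absorbs overdispersion from
#' mapping bias and library artifacts.
#'
#' @param x number of successes (alt-supporting reads)
#' @param size number of trials (total site depth)
#' @param prob expected success fraction in (0, 1)
#' @param rho overdispersion (intra-class correlation) in [0, 1)
#' @param log return log-density?
#' @return numeric vector of (log-)densities, recycled to common length
#' @export
dbetabinom <- function(x, size, prob, rho = 0, log = FALSE) {
  stopifnot(all(prob > 0 & prob < 1), all(rho >= 0 & rho < 1))
  if (all(rho == 0)) {
    return(stats::dbinom(x, size, prob, log = log))
  }
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  ld <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
  ld[x < 0 | x > size] <- -Inf
  if (log) ld else exp(ld)
}

#' Beta-binomial random deviates
#'
#' @param n number of deviates
#' @param size number of trials (vector recycled)
#' @param prob expected success fraction
#' @param rho overdispersion in [0, 1); 0 gives binomial draws
#' @return integer vector of counts
#' @export
rbetabinom <- function(n, size, prob, rho = 0) {
  if (rho == 0) {
    return(stats::rbinom(n, size, prob))
  }
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p <- stats::rbeta(n, a, b)
  stats::rbinom(n, size, p)
}
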