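#' Highest-density interval of a sample
#'
#' Shortest interval containing a given fraction of the draws, computed by an
#' exhaustive scan over contiguous windows of the sorted sample. For unimodal
#' posteriors this is the usual HDI; for a 89% interval at least 100 draws are
#' required for the window scan to be stable.
#'
#' @param x numeric vector of posterior draws.
#' @param credible fraction of mass the interval must contain (default 0.89).
#' @return named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, credible = 0.89) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 100) {
    stop("hdi() needs at least 100 draws for a stable interval; got ", n,
         ". Draw more posterior samples.", call. = FALSE)
  }
  stopifnot(credible > 0, credible < 1)
  s <- sort(x)
  n_in <- ceiling(credible * n)
  k <- n - n_in + 1L
  widths <- s[n_in:n] - s[1:k]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + n_in - 1L])
}

#' Probability of direction
#'
#' Proportion of the posterior lying on the median's side of the null value,
#' expressed as a percentage between 50 and 100. An index of effect
#' existence: 50% means the posterior is evenly split around the null, 100%
#' means every draw shares the median's sign.
#'
#' @param x numeric vector of posterior draws.
#' @param null the null value of the scale (0 for differences, 1 for ratios).
#' @return scalar percentage in `[50, 100]`.
#' @export
prob_direction <- function(x, null = 0) {
  x <- x[is.finite(x)]
  stopifnot(length(x) > 0)
  p <- mean(x > null)
  100 * max(p, 1 - p)
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin Rhat computed after splitting each chain in half, the
#' convergence diagnostic used to flag chains that have not mixed
#' (flagged when Rhat >= 1.1).
#'
#' @param draws matrix of draws for one parameter, one column per chain.
#' @return scalar Rhat (NA if fewer than 4 draws per split chain).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 8) return(NA_real_)
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  n2 <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, var)
  b <- n2 * var(means)
  w <- mean(vars)
  if (w == 0) return(1)
  v_hat <- (n2 - 1) / n2 * w + b / n2
  sqrt(v_hat / w)
}

#' Shifted-lognormal parameters from a target mean and SD
#'
#' Solves for the lognormal location and scale so that
#' `shift + exp(Normal(meanlog, sdlog))` has the requested mean and standard
#' deviation (closed form via the lognormal moment equations).
#'
#' @param mean,sd target mean and SD of the shifted variable (ms).
#' @param shift fixed shift (ms), must be `< mean`.
#' @return list with `meanlog`, `sdlog`, `shift`.
#' @export
shifted_lognormal_pars <- function(mean, sd, shift = 150) {
  stopifnot(mean > shift, sd > 0)
  m <- mean - shift
  cv2 <- (sd / m)^2
  sdlog2 <- log(1 + cv2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2), shift = shift)
}

## Deterministically derive k child seeds from one master seed, keeping every
## seed inside the 32-bit integer range R requires.
derive_seeds <- function(master_seed, k) {
  withr::with_seed(as.integer(master_seed), sample.int(.Machine$integer.max - 1L, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
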