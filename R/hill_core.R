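#' Incidence-frequency sufficient statistics
#'
#' Reduces a phenotype-by-sampling-unit incidence matrix to the sufficient
#' statistics all incidence-based estimators consume: the number of sampling
#' units T, the incidence frequencies Q_i (number of units containing
#' phenotype i), the singleton and doubleton counts Q1 and Q2, the total
#' number of incidences U = sum(Q_i), and the observed richness S_obs.
#'
#' @param m an [incidence_matrix()], or a binary matrix.
#' @return An object of class `incfreq`: list with fields `T`, `Q` (named
#'   vector, only phenotypes with Q_i > 0), `Q1`, `Q2`, `U`, `S_obs`,
#'   `habitat`.
#' @export
incidence_frequencies <- function(m) {
  if (inherits(m, "incidence_matrix")) {
    habitat <- m$habitat
    m <- m$presence
  } else {
    habitat <- NA_character_
    m <- as.matrix(m)
  }
  if (length(m) == 0 || ncol(m) < 1) stop("empty incidence matrix")
  if (!all(m %in% c(0, 1))) stop("incidence entries must be 0/1")
  Q <- rowSums(m)
  Q <- Q[Q > 0]
  incfreq(Q, ncol(m), habitat = habitat)
}

#' Construct incidence frequencies directly
#'
#' @param Q vector of incidence frequencies Q_i (zeros are dropped).
#' @param T number of sampling units.
#' @param habitat optional habitat label.
#' @return An `incfreq` object; see [incidence_frequencies()].
#' @export
incfreq <- function(Q, T, habitat = NA_character_) {
  T <- as.integer(T)
  if (T < 1) stop("T must be >= 1")
  Q <- Q[Q > 0]
  if (any(Q > T)) stop("Q_i cannot exceed T")
  if (any(Q != round(Q))) stop("Q_i must be integers")
  structure(
    list(T = T, Q = Q, Q1 = sum(Q == 1), Q2 = sum(Q == 2),
         U = sum(Q), S_obs = length(Q), habitat = habitat),
    class = "incfreq"
  )
}

#' @export
print.incfreq <- function(x, ...) {
  cat("<incfreq> T=", x$T, " S_obs=", x$S_obs, " U=", x$U,
      " Q1=", x$Q1, " Q2=", x$Q2, "\n", sep = "")
  invisible(x)
}

#' Empirical Hill numbers from incidence frequencies
#'
#' The effective number of equally frequent phenotypes of order q, computed
#' from the relative incidences p_i = Q_i / U: for q != 1,
#' \eqn{{}^qD = (\sum_i p_i^q)^{1/(1-q)}}; at q = 1 the limit
#' \eqn{\exp(-\sum_i p_i \log p_i)}; q = 0 is the observed richness.
#'
#' @param f an `incfreq` object.
#' @param q diversity order(s), q >= 0 (vectorised).
#' @return Numeric vector of empirical Hill numbers.
#' @export
empirical_hill <- function(f, q) {
  stopifnot(inherits(f, "incfreq"))
  if (f$S_obs < 1) stop("no observed phenotypes")
  if (any(q < 0)) stop("q must be >= 0")
  p <- f$Q / f$U
  vapply(q, function(qq) {
    if (qq == 0) return(as.numeric(f$S_obs))
    if (qq == 1) return(exp(-sum(p * log(p))))
    sum(p^qq)^(1 / (1 - qq))
  }, numeric(1))
}

#' Chao2 asymptotic richness estimator
#'
#' Lower-bound estimate of true phenotype richness from singleton and
#' doubleton incidence counts:
#' \eqn{\hat S = S_{obs} + \frac{T-1}{T}\frac{Q_1^2}{2 Q_2}} when Q2 > 0, the
#' bias-corrected \eqn{S_{obs} + \frac{T-1}{T}\frac{Q_1 (Q_1 - 1)}{2}} when
#' Q2 = 0, and S_obs when there are no singletons.
#'
#' @param f an `incfreq` object with T >= 2.
#' @return Estimated richness (scalar).
#' @export
chao2_richness <- function(f) {
  stopifnot(inherits(f, "incfreq"))
  if (f$T < 2) stop("Chao2 requires T >= 2 sampling units")
  k <- (f$T - 1) / f$T
  if (f$Q1 == 0) return(as.numeric(f$S_obs))
  if (f$Q2 > 0) f$S_obs + k * f$Q1^2 / (2 * f$Q2)
  else f$S_obs + k * f$Q1 * (f$Q1 - 1) / 2
}

#' Estimated sample coverage of the reference sample
#'
#' The estimated fraction of total incidence probability attributable to the
#' phenotypes detected in the T sampling units:
#' \eqn{\hat C = 1 - \frac{Q_1}{U}\left[\frac{(T-1) Q_1}{(T-1) Q_1 + 2 Q_2}\right]}.
#'
#' @param f an `incfreq` object with U > 0.
#' @return Coverage in `[0, 1]`.
#' @export
sample_coverage <- function(f) {
  stopifnot(inherits(f, "incfreq"))
  if (f$U <= 0) stop("U must be > 0")
  if (f$Q1 == 0) return(1)
  A <- (f$T - 1) * f$Q1 / ((f$T - 1) * f$Q1 + 2 * f$Q2)
  1 - (f$Q1 / f$U) * A
}

## Estimated full assemblage underlying the sample: adjusted detection rates
## for the observed phenotypes plus Q0_hat undetected phenotypes sharing the
## coverage deficit equally. This single construction backs the bootstrap,
## the completeness profile and general-q asymptotic diversity.
##   lambda_hat_i = (Q_i/T) [1 - tau (1 - Q_i/T)^T],  tau s.t.
##   sum(lambda_hat) = (U/T) Chat;   undetected mass = (U/T)(1 - Chat).
estimate_assemblage <- function(f) {
  stopifnot(inherits(f, "incfreq"))
  Chat <- sample_coverage(f)
  Q0 <- chao2_richness(f) - f$S_obs
  lam <- f$Q / f$T
  deficit <- (f$U / f$T) * (1 - Chat)
  denom <- sum(lam * (1 - lam)^f$T)
  tau <- if (denom > 0) deficit / denom else 0
  lam_obs <- lam * (1 - tau * (1 - lam)^f$T)
  lam0 <- if (Q0 > 0) deficit / Q0 else 0
  list(lambda_obs = lam_obs, Q0 = Q0, lambda_undet = lam0,
       coverage = Chat, total_rate = f$U / f$T)
}

#' Asymptotic Hill numbers for incidence data
#'
#' Estimates the true (hypothetical complete-sampling) diversity of order q.
#' Order 0 is the Chao2 richness estimate. Order 1 exponentiates the
#' incidence analogue of the Chao-Wang-Jost entropy estimator (incidence
#' frequencies Q_i and sampling units T substituted for abundances and
#' individuals); order 2 uses the unbiased inverse-Simpson analogue
#' \eqn{U^2 (T-1) / (T \sum_i Q_i (Q_i - 1))}. Other orders evaluate the Hill
#' number of the estimated full assemblage (observed phenotypes with adjusted
#' detection rates plus the estimated undetected phenotypes sharing the
#' coverage deficit).
#'
#' @param f an `incfreq` object.
#' @param q diversity order(s), q >= 0 (vectorised).
#' @return Numeric vector of asymptotic Hill estimates.
#' @export
asymptotic_hill <- function(f, q) {
  stopifnot(inherits(f, "incfreq"))
  if (any(q < 0)) stop("q must be >= 0")
  vapply(q, function(qq) {
    if (qq == 0) return(chao2_richness(f))
    if (qq == 1) return(asy_shannon(f))
    if (qq == 2) return(asy_simpson(f))
    asy_general(f, qq)
  }, numeric(1))
}

## Incidence analogue of the Chao-Wang-Jost asymptotic entropy estimator.
## H_raw estimates -sum lambda_i log lambda_i over detection rates
## lambda_i ~ Q_i/T; converting to the entropy of relative incidences
## pi_i = lambda_i / Lambda with Lambda estimated by U/T gives
## H = (T/U) H_raw + log(U/T), and ^1D = exp(H).
asy_shannon <- function(f) {
  T <- f$T; Q <- f$Q; U <- f$U
  if (T < 2) return(empirical_hill(f, 1))
  part1 <- sum((Q / T) * (digamma(T) - digamma(Q)))
  if (f$Q1 > 0) {
    A <- if (f$Q2 > 0) 2 * f$Q2 / ((T - 1) * f$Q1 + 2 * f$Q2)
         else if (f$Q1 > 1) 2 / ((T - 1) * (f$Q1 - 1) + 2)
         else 1
    part2 <- if (A < 1) {
      r <- 1:(T - 1)
      (f$Q1 / T) * (1 - A)^(1 - T) * (-log(A) - sum((1 - A)^r / r))
    } else 0
  } else part2 <- 0
  H <- (T / U) * (part1 + part2) + log(U / T)
  exp(H)
}

asy_simpson <- function(f) {
  T <- f$T; Q <- f$Q; U <- f$U
  s2 <- sum(Q * (Q - 1))
  if (s2 == 0 || T < 2) return(empirical_hill(f, 2))
  U^2 * (T - 1) / (T * s2)
}

asy_general <- function(f, q) {
  a <- estimate_assemblage(f)
  lam <- c(a$lambda_obs, rep(a$lambda_undet, max(0L, ceiling(a$Q0))))
  lam <- lam[lam > 0]
  p <- lam / sum(lam)
  if (abs(q - 1) < 1e-10) exp(-sum(p * log(p))) else sum(p^q)^(1 / (1 - q))
}

#' Sample-completeness profile
#'
#' The estimated fraction of order-q diversity detected by the sample, as a
#' function of q. Completeness at q = 0 is the ratio of observed to Chao2
#' richness, completeness at q = 1 is the sample coverage; for general q the
#' profile evaluates the detected share of \eqn{\sum_i \lambda_i^q} under the
#' estimated full assemblage (whose construction reproduces both anchors
#' exactly). Profiles that increase with q indicate undetected rare
#' diversity.
#'
#' @param f an `incfreq` object.
#' @param q_grid orders at which to evaluate, in `[0, 2]` by convention.
#' @return Data frame with columns `q` and `completeness`.
#' @export
completeness_profile <- function(f, q_grid = seq(0, 2, by = 0.05)) {
  stopifnot(inherits(f, "incfreq"))
  a <- estimate_assemblage(f)
  comp <- vapply(q_grid, function(q) {
    obs <- sum(a$lambda_obs^q)
    undet <- if (a$Q0 > 0 && a$lambda_undet > 0) a$Q0 * a$lambda_undet^q else 0
    obs / (obs + undet)
  }, numeric(1))
  data.frame(q = q_grid, completeness = comp)
}
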