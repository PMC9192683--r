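#' Rarefied phenotype richness
#'
#' Expected richness of a subsample of t of the T sampling units (sampling
#' without replacement):
#' \eqn{S(t) = S_{obs} - \sum_i \binom{T - Q_i}{t} / \binom{T}{t}}.
#'
#' @param f an `incfreq` object.
#' @param t number of sampling units, 1 <= t <= T (vectorised).
#' @return Expected richness at each t.
#' @export
rarefy_richness <- function(f, t) {
  stopifnot(inherits(f, "incfreq"))
  if (any(t < 1 | t > f$T)) stop("t must satisfy 1 <= t <= T")
  vapply(t, function(tt) {
    f$S_obs - sum(exp(lchoose(f$T - f$Q, tt) - lchoose(f$T, tt)))
  }, numeric(1))
}

#' Extrapolated phenotype richness
#'
#' Predicted richness when t_star additional sampling units are collected:
#' \eqn{S(T + t^*) = S_{obs} + \hat Q_0 [1 - (1 - Q_1 / (T \hat Q_0 + Q_1))^{t^*}]}
#' with \eqn{\hat Q_0} the Chao2 estimate of undetected richness. The
#' t_star -> Inf limit is the Chao2 richness.
#'
#' @param f an `incfreq` object.
#' @param t_star number of additional units, >= 0 (vectorised).
#' @return Predicted richness at each T + t_star.
#' @export
extrapolate_richness <- function(f, t_star) {
  stopifnot(inherits(f, "incfreq"))
  if (any(t_star < 0)) stop("t_star must be >= 0")
  Q0 <- chao2_richness(f) - f$S_obs
  if (f$Q1 == 0 || Q0 <= 0) return(rep(as.numeric(f$S_obs), length(t_star)))
  f$S_obs + Q0 * (1 - (1 - f$Q1 / (f$T * Q0 + f$Q1))^t_star)
}

#' Expected sample coverage at a given sample size
#'
#' Coverage of a hypothetical sample of t units: rarefied for t < T via
#' \eqn{\hat C(t) = 1 - \sum_i (Q_i/U) \binom{T-Q_i}{t} / \binom{T-1}{t}},
#' equal to [sample_coverage()] at t = T, and extrapolated for t > T as
#' \eqn{1 - (Q_1/U) A^{t - T + 1}} with
#' \eqn{A = (T-1)Q_1 / ((T-1)Q_1 + 2 Q_2)}. The curve is non-decreasing in t
#' and continuous across the reference size.
#'
#' @param f an `incfreq` object.
#' @param t sample sizes (vectorised), t >= 1.
#' @return Expected coverage at each t.
#' @export
coverage_at_size <- function(f, t) {
  stopifnot(inherits(f, "incfreq"))
  if (any(t < 1)) stop("t must be >= 1")
  A <- if (f$Q1 > 0) (f$T - 1) * f$Q1 / ((f$T - 1) * f$Q1 + 2 * f$Q2) else 0
  vapply(t, function(tt) {
    if (tt < f$T) {
      1 - sum((f$Q / f$U) * exp(lchoose(f$T - f$Q, tt) - lchoose(f$T - 1, tt)))
    } else if (f$Q1 == 0) {
      1
    } else {
      1 - (f$Q1 / f$U) * A^(tt - f$T + 1)
    }
  }, numeric(1))
}

## Expected frequency counts of a subsample of t <= T units: K_i follows a
## hypergeometric draw of t units among T. Returns, for one species with
## incidence Qi, the probability vector over k = 0..t.
## Size-based q = 1 and q = 2 estimates via expected frequency counts.
## For t <= T the subsampled incidence K_i is hypergeometric and the plug-in
## Hill number of the expected frequency counts is used (it reproduces the
## empirical value exactly at t = T). q = 2 additionally has a closed form
## valid at every t (rarefied and extrapolated):
##   ^2D(t) = (tU/T)^2 / [ tU/T + t(t-1) sum Q_i(Q_i-1) / (T(T-1)) ].
size_based_q2 <- function(f, t) {
  U <- f$U; T <- f$T
  s2 <- sum(f$Q * (f$Q - 1))
  vapply(t, function(tt) {
    Ut <- tt * U / T
    denom <- Ut + tt * (tt - 1) * s2 / (T * (T - 1))
    if (denom <= 0) return(as.numeric(f$S_obs))
    Ut^2 / denom
  }, numeric(1))
}

## Plug-in Hill number of expected frequency counts: given, for each
## phenotype, a pmf over subsample incidence k = 1..t, evaluates
## ^qD = (sum_k (k/U_t)^q E[S_k])^(1/(1-q)) (entropy limit at q = 1).
hill_of_expected_counts <- function(q, Ut, per_species) {
  acc <- 0
  for (sp in per_species) {
    k <- sp$k; pk <- sp$pk
    acc <- acc + if (abs(q - 1) < 1e-10)
      -sum(pk * (k / Ut) * log(k / Ut))
    else
      sum(pk * (k / Ut)^q)
  }
  if (abs(q - 1) < 1e-10) exp(acc) else acc^(1 / (1 - q))
}

## Rarefied diversity of general order q <= reference size: the subsampled
## incidence K_i is hypergeometric; the plug-in over expected frequency
## counts equals the empirical Hill number exactly at t = T.
size_based_qgen_rare <- function(f, q, t) {
  U <- f$U; T <- f$T
  vapply(t, function(tt) {
    if (tt == T) return(empirical_hill(f, q))
    per <- lapply(f$Q, function(Qi) {
      k <- seq_len(min(Qi, tt))
      list(k = k, pk = stats::dhyper(k, Qi, T - Qi, tt))
    })
    hill_of_expected_counts(q, tt * U / T, per)
  }, numeric(1))
}

## General-q extrapolation: expected plug-in diversity of the estimated full
## assemblage under independent Bernoulli sampling of t units, shifted so
## the curve is continuous at t = T (anchor: empirical ^qD).
size_based_qgen_extrap <- function(f, q, t) {
  a <- estimate_assemblage(f)
  m0 <- max(0L, ceiling(a$Q0))
  lam <- c(a$lambda_obs, if (m0 > 0) rep(a$Q0 * a$lambda_undet / m0, m0))
  lam <- lam[lam > 0]
  d_binom <- function(tt) {
    per <- lapply(lam, function(p) {
      k <- seq_len(tt)
      pk <- stats::dbinom(k, tt, p)
      keep <- pk > 1e-12
      list(k = k[keep], pk = pk[keep])
    })
    hill_of_expected_counts(q, tt * sum(lam), per)
  }
  shift <- empirical_hill(f, q) - d_binom(f$T)
  vapply(t, function(tt) d_binom(tt) + shift, numeric(1))
}

#' Size-based rarefaction/extrapolation curve
#'
#' Diversity of order q as a function of the number of sampling units t over
#' `[1, 2T]`: interpolated (rarefied) below the reference size T and
#' extrapolated above it, with the curve passing exactly through the
#' empirical Hill number at t = T. Extrapolation is restricted to double the
#' reference size, beyond which richness extrapolation is unreliable.
#'
#' @param f an `incfreq` object.
#' @param q diversity order (>= 0; the workflow plots 0, 1 and 2).
#' @param knots approximate number of t values (integers, endpoints and T
#'   always included).
#' @return Data frame with columns `t`, `q`, `estimate`, `coverage`,
#'   `extrapolated`.
#' @export
re_curve <- function(f, q = 0, knots = 40) {
  stopifnot(inherits(f, "incfreq"))
  if (knots < 2) stop("knots must be >= 2")
  if (q < 0) stop("q must be >= 0")
  t_grid <- sort(unique(c(1L, f$T, 2L * f$T,
                          as.integer(round(seq(1, 2 * f$T, length.out = knots))))))
  est <- re_curve_at(f, q, t_grid)
  data.frame(t = t_grid, q = q, estimate = est,
             coverage = coverage_at_size(f, t_grid),
             extrapolated = t_grid > f$T)
}

## Size-based estimate at arbitrary integer t in [1, 2T] (workhorse behind
## re_curve and coverage standardization).
re_curve_at <- function(f, q, t) {
  t <- as.integer(t)
  rare <- t[t <= f$T]
  ext <- t[t > f$T]
  out <- numeric(length(t))
  if (q == 0) {
    if (length(rare)) out[t <= f$T] <- rarefy_richness(f, rare)
    if (length(ext)) out[t > f$T] <- extrapolate_richness(f, ext - f$T)
  } else if (q == 2) {
    out <- size_based_q2(f, t)
  } else {
    if (length(rare)) out[t <= f$T] <- size_based_qgen_rare(f, q, rare)
    if (length(ext)) out[t > f$T] <- size_based_qgen_extrap(f, q, ext)
  }
  out
}

#' Maximum standardizable coverage across habitats
#'
#' The coverage level used to standardize diversity comparisons: the minimum,
#' over habitats, of the expected coverage when each habitat's sample is
#' extrapolated to double its own number of sampling units.
#'
#' @param habitats list of `incfreq` objects (one per habitat).
#' @return C_max, a fraction in `(0, 1]`.
#' @export
cmax <- function(habitats) {
  if (inherits(habitats, "incfreq")) habitats <- list(habitats)
  if (!length(habitats)) stop("need at least one habitat")
  min(vapply(habitats, function(f) coverage_at_size(f, 2 * f$T), numeric(1)))
}

#' Coverage-standardized diversity estimate
#'
#' Inverts the coverage-size relationship to find the (possibly fractional)
#' sample size t(C_target) whose expected coverage equals `C_target`, and
#' evaluates the size-based diversity curve there (linear interpolation
#' between the two bracketing integer sizes). Standardization refuses to
#' extrapolate beyond twice the reference sample size.
#'
#' @param f an `incfreq` object.
#' @param q diversity order (>= 0).
#' @param C_target target coverage, at most `coverage_at_size(f, 2T)`.
#' @return List with `estimate`, `t`, `C_target`, `q`.
#' @export
estimate_at_coverage <- function(f, q, C_target) {
  stopifnot(inherits(f, "incfreq"))
  cov2T <- coverage_at_size(f, 2 * f$T)
  if (C_target > cov2T + 1e-12)
    stop("C_target ", signif(C_target, 4), " exceeds coverage at 2T (",
         signif(cov2T, 4), "); refusing to extrapolate further")
  t_grid <- seq_len(2 * f$T)
  covs <- coverage_at_size(f, t_grid)
  if (C_target <= covs[1]) {
    t_lo <- t_hi <- 1L; w <- 0
  } else {
    i <- max(which(covs <= C_target + 1e-12))
    if (i >= 2 * f$T) {
      t_lo <- t_hi <- 2L * f$T; w <- 0
    } else {
      t_lo <- i; t_hi <- i + 1L
      w <- (C_target - covs[i]) / (covs[i + 1] - covs[i])
      if (!is.finite(w)) w <- 0
    }
  }
  ests <- re_curve_at(f, q, unique(c(t_lo, t_hi)))
  est <- if (t_lo == t_hi) ests[1] else (1 - w) * ests[1] + w * ests[2]
  list(estimate = est, t = t_lo + w * (t_hi > t_lo), C_target = C_target, q = q)
}

#' Incidence bootstrap confidence bands
#'
#' Nonparametric bootstrap for any statistic of incidence frequencies. An
#' estimated full assemblage is constructed (observed phenotypes with
#' adjusted detection probabilities, plus the estimated number of undetected
#' phenotypes sharing the coverage deficit equally); each replicate draws T
#' independent Bernoulli sampling units from it, i.e. replicate incidence
#' frequencies Q_i* ~ Binomial(T, p_i). The confidence interval is the point
#' estimate plus/minus `z` bootstrap standard deviations.
#'
#' @param f an `incfreq` object.
#' @param statistic function mapping an `incfreq` to a numeric scalar or
#'   vector (constant length).
#' @param B number of bootstrap replicates (>= 50; the workflow default is
#'   500).
#' @param seed integer seed; required for reproducibility.
#' @param level confidence level (default 0.95).
#' @return List with `estimate`, `se`, `ci_low`, `ci_high`, `B_used`.
#' @export
incidence_bootstrap <- function(f, statistic, B = 500, seed = 1, level = 0.95) {
  stopifnot(inherits(f, "incfreq"), is.function(statistic))
  if (B < 50) stop("B must be >= 50")
  a <- estimate_assemblage(f)
  m0 <- max(0L, ceiling(a$Q0))
  p <- c(a$lambda_obs, if (m0 > 0) rep(a$Q0 * a$lambda_undet / m0, m0))
  p <- pmin(pmax(p, 0), 1)
  est <- statistic(f)
  set.seed(seed)
  reps <- vector("list", B)
  fails <- 0L
  for (b in seq_len(B)) {
    Qb <- stats::rbinom(length(p), f$T, p)
    r <- tryCatch({
      if (all(Qb == 0)) stop("empty bootstrap assemblage")
      statistic(incfreq(Qb[Qb > 0], f$T))
    }, error = function(e) NULL)
    if (is.null(r)) fails <- fails + 1L else reps[[b]] <- r
  }
  if (fails > 0.1 * B)
    stop("more than 10% of bootstrap replicates failed (", fails, "/", B, ")")
  if (fails > 0)
    message("incidence_bootstrap: dropped ", fails, " failed replicate(s)")
  mat <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  se <- apply(mat, 2, stats::sd)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = est, se = se,
       ci_low = est - z * se, ci_high = est + z * se,
       B_used = B - fails)
}
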