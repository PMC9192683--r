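#' Hill-number evenness profile
#'
#' Evenness of order q from the normalised slope of the Hill-number diversity
#' profile between q = 0 and q: \eqn{E(q) = ({}^qD - 1)/({}^0D - 1)}. A
#' perfectly even assemblage has E(q) = 1 for all q; increasing dominance
#' drives E(q) towards 0. In the four-step workflow the Hill numbers entering
#' this profile are standardized at the common coverage C_max.
#'
#' @param hill_values Hill numbers \eqn{{}^qD} at the orders `q_grid`.
#' @param richness the order-0 Hill number \eqn{{}^0D} (> 1).
#' @param q_grid orders (> 0) matching `hill_values`.
#' @return Data frame with columns `q` and `evenness`.
#' @export
evenness_profile <- function(hill_values, richness, q_grid) {
  if (length(hill_values) != length(q_grid))
    stop("hill_values and q_grid must have equal length")
  if (any(q_grid <= 0)) stop("evenness is defined for q > 0 only")
  if (richness <= 1) stop("evenness undefined for richness <= 1")
  data.frame(q = q_grid, evenness = (hill_values - 1) / (richness - 1))
}

#' Pielou's J from Hill numbers
#'
#' Evenness as the ratio of Shannon entropy to its maximum at the observed
#' richness, expressed through Hill numbers of orders 0 and 1:
#' \eqn{J = \ln({}^1D) / \ln({}^0D)}.
#'
#' @param d0 richness \eqn{{}^0D} (> 1).
#' @param d1 Shannon diversity \eqn{{}^1D}, with 1 <= d1 <= d0.
#' @return J in `[0, 1]`.
#' @export
pielou_j <- function(d0, d1) {
  if (d0 <= 1) stop("Pielou's J undefined for d0 <= 1")
  if (d1 < 1 - 1e-9 || d1 > d0 * (1 + 1e-9)) stop("require 1 <= d1 <= d0")
  log(d1) / log(d0)
}

#' Classical diversity indices over higher taxa
#'
#' The cross-study comparison indices computed from the number of phenotypes
#' per higher taxon, n_i, with proportions p_i = n_i / N where N = sum(n_i):
#' Shannon index \eqn{H' = -\sum_i p_i \log_2 p_i} (base 2), Simpson
#' concentration \eqn{D = \sum_i n_i (n_i - 1) / (N (N - 1))} (small values =
#' diverse), and evenness \eqn{J = (-\sum_i p_i \ln p_i) / \ln(k)} where k is
#' the number of taxa present.
#'
#' @param taxon_counts non-negative vector of phenotype counts per taxon.
#' @return List with `n_taxa`, `N_total`, `shannon_log2`, `simpson`,
#'   `evenness`.
#' @export
classical_indices <- function(taxon_counts) {
  if (any(taxon_counts < 0)) stop("taxon counts must be non-negative")
  n <- taxon_counts[taxon_counts > 0]
  k <- length(n)
  N <- sum(n)
  if (k < 1) stop("no taxa present")
  p <- n / N
  h2 <- -sum(p * log2(p))
  simpson <- if (N > 1) sum(n * (n - 1)) / (N * (N - 1)) else 1
  evenness <- if (k >= 2) -sum(p * log(p)) / log(k) else {
    stop("evenness undefined for a single taxon")
  }
  list(n_taxa = k, N_total = N, shannon_log2 = h2, simpson = simpson,
       evenness = evenness)
}

#' Evenness from a printed Shannon index and taxon count
#'
#' Because the Shannon index (base 2) and the evenness index share the same
#' proportions, evenness is a deterministic function of the two printed
#' values: \eqn{J = H' \ln(2) / \ln(k)}. This is the identity used to
#' cross-validate published index tables.
#'
#' @param h_log2 Shannon index in log base 2 (>= 0).
#' @param n_taxa number of taxa (>= 2).
#' @return Evenness J.
#' @export
evenness_from_shannon <- function(h_log2, n_taxa) {
  if (any(n_taxa < 2)) stop("n_taxa must be >= 2")
  if (any(h_log2 < 0)) stop("h_log2 must be >= 0")
  h_log2 * log(2) / log(n_taxa)
}
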