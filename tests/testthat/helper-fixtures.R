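# Shared fixtures: a hand-checkable toy assemblage and random generators
# used by the property-style tests.

# Toy with T = 4 units and occurrence frequencies (4, 2, 1, 1):
# U = 8, S_obs = 4, Q1 = 2, Q2 = 1. All worked values below were derived by
# hand from these counts.
toy_freq <- function() incfreq(c(a = 4, b = 2, c = 1, d = 1), 4)

toy_incidence <- function() {
  m <- rbind(
    a = c(1, 1, 1, 1),
    b = c(1, 0, 1, 0),
    c = c(0, 1, 0, 0),
    d = c(0, 0, 0, 1)
  )
  colnames(m) <- paste0("u", 1:4)
  incidence_matrix(m)
}

# Random incidence frequencies for property tests (always at least one
# phenotype present).
random_freq <- function(S = 30, T = 10) {
  p <- stats::rbeta(S, 0.6, 2)
  Q <- stats::rbinom(S, T, p)
  if (all(Q == 0)) Q[1] <- 1L
  incfreq(Q[Q > 0], T)
}

# Synthetic world with known detection probabilities, for estimator-oracle
# tests: returns the probabilities and one sampled incfreq.
random_world <- function(S = 60, T = 40, meanlog = -2, sdlog = 0.8) {
  p <- pmin(exp(stats::rnorm(S, meanlog, sdlog)), 1)
  Q <- stats::rbinom(S, T, p)
  list(p = p, f = incfreq(Q[Q > 0], T))
}

# Long-dialect CSV fixture written to a temp file.
write_long_csv <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(
      phenotype_id = c("p1", "p1", "p2"),
      taxon = c("Bryozoa", "Bryozoa", "Porifera"),
      sample_id = c("s1", "s2", "s1"),
      habitat = "PC_mat",
      count = c(2L, 0L, 5L)
    )
  }
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}
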