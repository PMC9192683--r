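#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities between samples,
#' \eqn{d_{jk} = \sum_i |y_{ij} - y_{ik}| / \sum_i (y_{ij} + y_{ik})}, on
#' optionally transformed counts. The square-root transform damps the
#' influence of dominant phenotypes; the presence transform reduces
#' Bray-Curtis to the Sorensen dissimilarity used for incidence ordinations.
#'
#' @param counts a [count_table()], [incidence_matrix()], or a
#'   phenotype-by-sample matrix.
#' @param transform one of `"sqrt"`, `"none"`, `"presence"`.
#' @param groups optional vector of habitat labels per sample, stored with
#'   the result.
#' @return A `dist` object with a `groups` attribute.
#' @export
bray_curtis <- function(counts, transform = c("sqrt", "none", "presence"),
                        groups = NULL) {
  transform <- match.arg(transform)
  m <- if (inherits(counts, "count_table")) counts$counts
       else if (inherits(counts, "incidence_matrix")) counts$presence
       else as.matrix(counts)
  x <- t(m)  # samples in rows
  if (nrow(x) < 2) stop("need >= 2 samples")
  zero <- rowSums(x) == 0
  if (sum(zero) >= 2)
    stop("Bray-Curtis undefined for pairs of all-zero samples: ",
         paste(rownames(x)[zero], collapse = ", "))
  x <- switch(transform, sqrt = sqrt(x), none = x, presence = (x > 0) * 1)
  d <- vegan::vegdist(x, method = "bray")
  if (!is.null(groups)) {
    if (length(groups) != nrow(x)) stop("groups must have one label per sample")
    attr(d, "groups") <- as.character(groups)
  }
  d
}

## One-way PERMANOVA sums of squares from a dissimilarity matrix (Anderson's
## partition): SS_total = (1/n) sum_{i<j} d_ij^2, SS_within = sum over groups
## of (1/n_g) of the within-group pair sums; pseudo-F = (SS_A/(a-1)) /
## (SS_W/(n-a)).
pseudo_f <- function(d2, grouping) {
  n <- nrow(d2)
  groups <- unique(grouping)
  a <- length(groups)
  ss_t <- sum(d2[lower.tri(d2)]) / n
  ss_w <- 0
  for (g in groups) {
    idx <- which(grouping == g)
    ss_w <- ss_w + sum(d2[idx, idx][lower.tri(d2[idx, idx, drop = FALSE])]) / length(idx)
  }
  ss_a <- ss_t - ss_w
  (ss_a / (a - 1)) / (ss_w / (n - a))
}

## All distinct permutations of a label vector (for exact tests on tiny
## designs). Returns a matrix with one permutation per row.
distinct_label_perms <- function(labels) {
  rec <- function(lab) {
    if (length(lab) <= 1) return(matrix(lab, nrow = 1))
    out <- NULL
    for (u in unique(lab)) {
      i <- match(u, lab)
      sub <- rec(lab[-i])
      out <- rbind(out, cbind(u, sub, deparse.level = 0))
    }
    out
  }
  rec(labels)
}

#' One-way PERMANOVA with pairwise tests
#'
#' Permutational multivariate analysis of variance on a dissimilarity matrix
#' with a single grouping factor. The pseudo-F statistic partitions the total
#' sum of squared dissimilarities into between- and within-group components;
#' significance is assessed by unrestricted permutation of sample labels,
#' with `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`. When the design
#' admits fewer distinct label permutations than requested, the exact
#' permutation distribution is enumerated instead (with a warning). Pairwise
#' tests repeat the procedure on each pair of groups.
#'
#' @param d `dist` object (e.g. from [bray_curtis()]).
#' @param groups vector of group labels per sample (defaults to the `groups`
#'   attribute of `d`).
#' @param n_perm number of permutations (the workflow default is 999).
#' @param seed integer seed.
#' @param pairwise also run all pairwise comparisons?
#' @return List with `pseudo_F`, `df_between`, `df_within`, `p_perm`,
#'   `n_perm`, `exact`, and (optionally) a `pairwise` data frame.
#' @export
permanova <- function(d, groups = attr(d, "groups"), n_perm = 999, seed = 1,
                      pairwise = TRUE) {
  if (is.null(groups)) stop("no group labels supplied")
  groups <- as.character(groups)
  n <- attr(d, "Size")
  if (length(groups) != n) stop("groups must have one label per sample")
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("each group needs >= 2 samples")
  d2 <- as.matrix(d)^2
  f_obs <- pseudo_f(d2, groups)
  n_distinct <- round(exp(lfactorial(n) - sum(lfactorial(tab))))
  if (n_distinct <= n_perm && n <= 12) {
    warning("only ", n_distinct, " distinct label arrangements; ",
            "using exact enumeration")
    perms <- distinct_label_perms(groups)
    f_perm <- apply(perms, 1, function(g) pseudo_f(d2, g))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- nrow(perms)
    exact <- TRUE
  } else {
    set.seed(seed)
    f_perm <- replicate(n_perm, pseudo_f(d2, sample(groups)))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
    exact <- FALSE
  }
  out <- list(pseudo_F = f_obs, df_between = length(tab) - 1,
              df_within = n - length(tab), p_perm = p, n_perm = n_used,
              exact = exact)
  if (pairwise && length(tab) > 2) {
    prs <- utils::combn(names(tab), 2)
    pw <- apply(prs, 2, function(pr) {
      idx <- groups %in% pr
      dd <- stats::as.dist(as.matrix(d)[idx, idx])
      r <- permanova(dd, groups[idx], n_perm = n_perm, seed = seed,
                     pairwise = FALSE)
      c(F = r$pseudo_F, p = r$p_perm)
    })
    out$pairwise <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                               pseudo_F = pw["F", ], p_perm = pw["p", ],
                               row.names = NULL)
  }
  out
}

#' Homogeneity of multivariate dispersion
#'
#' Tests whether group differences found by [permanova()] could be driven by
#' unequal within-group spread rather than location: samples are embedded by
#' principal coordinates (with imaginary-part correction for non-Euclidean
#' dissimilarities), distances to group centroids are computed, and an
#' ANOVA-type F on those distances is assessed by permutation.
#'
#' @inheritParams permanova
#' @return List with `F`, `p_perm`, `n_perm` and the underlying
#'   `vegan::betadisper` fit.
#' @export
dispersion_check <- function(d, groups = attr(d, "groups"), n_perm = 999,
                             seed = 1) {
  if (is.null(groups)) stop("no group labels supplied")
  bd <- vegan::betadisper(d, as.factor(groups))
  set.seed(seed)
  pt <- vegan::permutest(bd, permutations = n_perm)
  list(F = pt$tab$F[1], p_perm = pt$tab$`Pr(>F)`[1], n_perm = n_perm, fit = bd)
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 nMDS ordination with multiple random restarts (best
#' configuration retained), deterministic for a given seed.
#'
#' @param d `dist` object.
#' @param dims number of ordination dimensions (default 2).
#' @param restarts number of random restarts (>= 20 recommended).
#' @param seed integer seed.
#' @return List with `points` (samples x dims), `stress`, `converged`.
#' @export
nmds <- function(d, dims = 2, restarts = 20, seed = 1) {
  if (attr(d, "Size") < 4) stop("nMDS needs >= 4 samples")
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = dims, try = restarts, trymax = max(restarts, 20),
                        trace = 0, autotransform = FALSE, wascores = FALSE)
  if (is.null(fit$points)) stop("nMDS failed to produce a configuration")
  list(points = fit$points, stress = fit$stress, converged = fit$converged > 0)
}

#' Venn partition of phenotype sets
#'
#' Exact set-algebra counts of total, shared and unique phenotypes across two
#' or three habitats.
#'
#' @param sets named list of 2 or 3 character vectors of phenotype ids.
#' @return List with `totals`, `pairwise_shared`, `shared_all`, `unique`, and
#'   `union_total`.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3)
    stop("need a list of 2 or 3 phenotype sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  totals <- vapply(sets, length, integer(1))
  prs <- utils::combn(nm, 2)
  pairwise <- apply(prs, 2, function(pr)
    length(intersect(sets[[pr[1]]], sets[[pr[2]]])))
  names(pairwise) <- apply(prs, 2, paste, collapse = "&")
  shared_all <- length(Reduce(intersect, sets))
  uniq <- vapply(nm, function(a)
    length(setdiff(sets[[a]], unlist(sets[setdiff(nm, a)]))), integer(1))
  list(totals = totals, pairwise_shared = pairwise, shared_all = shared_all,
       unique = uniq, union_total = length(unique(unlist(sets))))
}
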