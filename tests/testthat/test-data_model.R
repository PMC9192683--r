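test_that("long CSV reads into a validated count table", {
  path <- write_long_csv()
  ct <- read_count_table(path, "long")
  expect_s3_class(ct, "count_table")
  expect_equal(dim(ct$counts), c(2, 2))
  expect_equal(ct$counts["p1", "s1"], 2)
  expect_equal(ct$counts["p2", "s2"], 0)  # missing combination is zero
  expect_equal(ct$habitat, "PC_mat")
})

test_that("wide CSV round-trips through write/read unchanged", {
  ct <- count_table(matrix(c(0, 3, 1, 0, 2, 7), nrow = 3,
                           dimnames = list(c("p1", "p2", "p3"), c("s1", "s2"))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_count_table(ct, path)
  back <- read_count_table(path, "wide")
  expect_identical(unname(back$counts), unname(ct$counts))
  expect_identical(dimnames(back$counts), dimnames(ct$counts))
})

test_that("validation rejects unknown taxa and negative counts", {
  df <- data.frame(phenotype_id = "p1", taxon = "Insecta", sample_id = "s1",
                   habitat = "PC_mat", count = 1L)
  expect_error(read_count_table(write_long_csv(df), "long"), "taxon")
  df2 <- data.frame(phenotype_id = "p1", taxon = "Bryozoa", sample_id = "s1",
                    habitat = "PC_mat", count = -3L)
  expect_error(read_count_table(write_long_csv(df2), "long"), "negative")
  expect_error(count_table(matrix(-1, 1, 1)), "non-negative")
})

test_that("to_incidence binarizes counts and retains all-zero rows", {
  ct <- count_table(matrix(c(0, 1, 3, 0), 2,
                           dimnames = list(c("p1", "p2"), c("s1", "s2"))))
  inc <- to_incidence(ct)
  expect_equal(unname(inc$presence), rbind(c(0, 1), c(1, 0)))

  ct0 <- count_table(matrix(c(2, 0, 5, 0), 2,
                            dimnames = list(c("p1", "pz"), c("s1", "s2"))))
  expect_message(inc0 <- to_incidence(ct0), "all-zero")
  expect_equal(unname(inc0$presence["pz", ]), c(0, 0))
  # retained zero rows contribute nothing downstream
  expect_equal(incidence_frequencies(inc0)$S_obs, 1)
})

test_that("to_incidence is idempotent", {
  set.seed(42)
  cnt <- matrix(rpois(40, 1), 8, 5,
                dimnames = list(paste0("p", 1:8), paste0("s", 1:5)))
  inc1 <- to_incidence(count_table(cnt))
  inc2 <- suppressMessages(to_incidence(count_table(inc1$presence)))
  expect_identical(inc1$presence, inc2$presence)
})

test_that("holobiont concatenates units and unions phenotypes", {
  l <- incidence_matrix(matrix(1, 3, 29, dimnames = list(paste0("L", 1:3),
                                                         paste0("leaf", 1:29))),
                        "PO_leaves")
  r <- incidence_matrix(matrix(1, 4, 20, dimnames = list(paste0("R", 1:4),
                                                         paste0("rhi", 1:20))),
                        "PO_rhizomes")
  h <- derive_holobiont(l, r)
  expect_equal(ncol(h$presence), 49)  # 29 leaves + 20 rhizomes
  expect_equal(nrow(h$presence), 7)   # disjoint pools of 3 and 4
  expect_equal(h$habitat, "PO_holobiont")

  # identical single-phenotype matrices -> richness 1
  l1 <- incidence_matrix(matrix(1, 1, 2, dimnames = list("x", c("a", "b"))),
                         "PO_leaves")
  r1 <- incidence_matrix(matrix(1, 1, 2, dimnames = list("x", c("c", "d"))),
                         "PO_rhizomes")
  expect_equal(nrow(derive_holobiont(l1, r1)$presence), 1)

  # overlapping sample ids rejected
  r_bad <- incidence_matrix(matrix(1, 1, 2, dimnames = list("y", c("b", "e"))),
                            "PO_rhizomes")
  expect_error(derive_holobiont(l1, r_bad), "overlapping")
})

test_that("holobiont richness equals the set union on random pools", {
  set.seed(7)
  for (i in 1:20) {
    lp <- sample(paste0("p", 1:15), sample(3:10, 1))
    rp <- sample(paste0("p", 1:15), sample(3:10, 1))
    l <- incidence_matrix(matrix(1, length(lp), 2,
                                 dimnames = list(lp, c("l1", "l2"))), "PO_leaves")
    r <- incidence_matrix(matrix(1, length(rp), 2,
                                 dimnames = list(rp, c("r1", "r2"))), "PO_rhizomes")
    expect_equal(nrow(derive_holobiont(l, r)$presence),
                 length(union(lp, rp)))
  }
})

test_that("abundance normalization follows the per-sample EF arithmetic", {
  ct <- count_table(matrix(100, 1, 1, dimnames = list("p1", "s1")),
                    sample_area_3d = 0.5, enlargement_factor = 2)
  ab <- normalize_abundance(ct)
  expect_equal(unname(ab$ind_per_habitat_m2["mean"]), 200)
  expect_equal(unname(ab$ind_per_seafloor_m2["mean"]), 400)

  # EF = 1 leaves density unchanged
  ct1 <- count_table(matrix(c(10, 20), 1, dimnames = list("p1", c("s1", "s2"))),
                     sample_area_3d = c(1, 2), enlargement_factor = 1)
  ab1 <- normalize_abundance(ct1)
  expect_equal(ab1$ind_per_habitat_m2, ab1$ind_per_seafloor_m2)
  # mean over per-sample densities (10/1, 20/2), se = sd/sqrt(n)
  expect_equal(unname(ab1$ind_per_habitat_m2["mean"]), 10)
  expect_equal(unname(ab1$ind_per_habitat_m2["se"]), 0)

  expect_error(count_table(matrix(1, 1, 1), sample_area_3d = 0), "positive")
})

test_that("normalization is linear in counts", {
  set.seed(11)
  cnt <- matrix(rpois(15, 4), 3, 5,
                dimnames = list(paste0("p", 1:3), paste0("s", 1:5)))
  ct <- count_table(cnt, sample_area_3d = runif(5, 0.2, 0.6),
                    enlargement_factor = 4.9)
  ct2 <- count_table(cnt * 2L, sample_area_3d = ct$sample_area_3d,
                     enlargement_factor = 4.9)
  a1 <- normalize_abundance(ct); a2 <- normalize_abundance(ct2)
  expect_equal(2 * a1$ind_per_habitat_m2["mean"], a2$ind_per_habitat_m2["mean"])
  expect_equal(2 * a1$ind_per_seafloor_m2["mean"], a2$ind_per_seafloor_m2["mean"])
})
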