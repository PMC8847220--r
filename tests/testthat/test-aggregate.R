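vec_tbl <- function(sample, hap, m) {
  dplyr::bind_cols(tibble::tibble(sample = sample, hap = hap),
                   tibble::as_tibble(m, .name_repair = ~ paste0("v", seq_along(.x))))
}

test_that("personal vectors average haplotype pairs and pass haploid through", {
  m <- rbind(rep(0, 3), rep(2, 3))
  pv <- personal_vectors(vec_tbl("S1", c("a", "b"), m))
  expect_equal(as.numeric(pv[1, -1]), rep(1, 3))

  single <- personal_vectors(vec_tbl("S1", "a", rbind(c(4, 5, 6))))
  expect_equal(as.numeric(single[1, -1]), c(4, 5, 6))

  dup <- personal_vectors(vec_tbl("S1", c("a", "b"), rbind(1:3, 1:3)))
  expect_equal(as.numeric(dup[1, -1]), 1:3)

  expect_error(personal_vectors(
    vec_tbl("S1", c("a", "b", "c"), rbind(1:3, 1:3, 1:3))), "more than 2")
})

test_that("duplicating a haplotype and averaging returns the original vector", {
  withr::with_seed(31, v <- runif(12))
  pv <- personal_vectors(vec_tbl("S", c("a", "b"), rbind(v, v)))
  expect_equal(as.numeric(pv[1, -1]), v)
})

test_that("population centroids are unweighted member means", {
  panel <- tibble::tibble(sample = c("S1", "S2", "S3"),
                          population = c("P1", "P1", "P2"))
  pers <- vec_tbl(c("S1", "S2", "S3"), "a", rbind(c(0, 2), c(4, 6), c(9, 9)))
  pers$hap <- NULL
  cen <- population_centroids(pers, panel)
  expect_equal(cen$member_count, c(2L, 1L))
  expect_equal(as.numeric(cen[cen$population == "P1", c("v1", "v2")]), c(2, 4))
  expect_equal(as.numeric(cen[cen$population == "P2", c("v1", "v2")]), c(9, 9))

  # permutation invariance and singleton identity
  cen2 <- population_centroids(pers[c(3, 1, 2), ], panel)
  expect_equal(dplyr::arrange(cen, population), dplyr::arrange(cen2, population))

  # identical members collapse to that vector
  many <- vec_tbl(sprintf("S%d", 1:96), "a",
                  matrix(rep(c(1, 2, 3), each = 96), ncol = 3))
  many$hap <- NULL
  cen3 <- population_centroids(many,
    tibble::tibble(sample = many$sample, population = "ACB"))
  expect_equal(as.numeric(cen3[1, c("v1", "v2", "v3")]), c(1, 2, 3))
})

test_that("samples absent from the panel are dropped with a warning", {
  pers <- vec_tbl(c("S1", "S2"), "a", rbind(c(0, 0), c(1, 1)))
  pers$hap <- NULL
  panel <- tibble::tibble(sample = "S1", population = "P1")
  expect_warning(cen <- population_centroids(pers, panel), "absent")
  expect_equal(cen$member_count, 1L)
})

test_that("grand mean equals the member-count-weighted mean of centroids", {
  withr::with_seed(37, {
    n <- c(P1 = 3, P2 = 7, P3 = 2)
    pers <- vec_tbl(sprintf("S%02d", 1:12), "a", matrix(runif(12 * 5), 12))
    pers$hap <- NULL
    panel <- tibble::tibble(sample = pers$sample,
                            population = rep(names(n), n))
  })
  cen <- population_centroids(pers, panel)
  num <- as.matrix(dplyr::select(cen, dplyr::starts_with("v")))
  weighted <- colSums(num * cen$member_count) / sum(cen$member_count)
  grand <- colMeans(as.matrix(dplyr::select(pers, dplyr::starts_with("v"))))
  expect_equal(unname(weighted), unname(grand))
})

test_that("distance_matrix is a valid Euclidean matrix", {
  cen <- tibble::tibble(population = c("P1", "P2"), v1 = c(0, 3), v2 = c(0, 4))
  m <- distance_matrix(cen)
  expect_equal(m["P1", "P2"], 5)
  expect_equal(diag(unclass(m)), c(P1 = 0, P2 = 0))

  same <- tibble::tibble(population = c("A", "B", "C"), v1 = 1, v2 = 2)
  expect_true(all(unclass(distance_matrix(same)) == 0))

  expect_error(distance_matrix(
    tibble::tibble(population = c("A", "A"), v1 = 1:2)), "duplicate")
})

test_that("emitted distance matrices satisfy metric properties", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      k <- sample(3:8, 1)
      cen <- dplyr::bind_cols(
        tibble::tibble(population = sprintf("P%d", 1:k)),
        tibble::as_tibble(matrix(runif(k * 6), k),
                          .name_repair = ~ paste0("v", 1:6)))
      m <- unclass(distance_matrix(cen))
      expect_equal(m, t(m))
      expect_true(all(diag(m) == 0))
      for (a in 1:k) for (b in 1:k) for (c in 1:k) {
        expect_lte(m[a, b], m[a, c] + m[c, b] + 1e-12)
      }
    }
  })
})

test_that("sum_matrices aligns by label and errors on mismatch", {
  withr::with_seed(43, {
    pts <- matrix(runif(8), 4, dimnames = list(c("A", "B", "C", "D"), NULL))
  })
  m <- points_matrix(pts)
  zero <- m * 0
  expect_equal(unclass(sum_matrices(list(m, zero))), m, ignore_attr = TRUE)

  s22 <- sum_matrices(rep(list(m), 22))
  expect_equal(unclass(s22), 22 * m, ignore_attr = TRUE)
  expect_equal(unclass(sum_matrices(rep(list(m), 22), average = TRUE)), m,
               ignore_attr = TRUE)

  perm <- m[c(3, 1, 4, 2), c(3, 1, 4, 2)]
  expect_equal(unclass(sum_matrices(list(m, perm))),
               unclass(sum_matrices(list(m, m)))[rownames(m), rownames(m)],
               ignore_attr = TRUE)

  bad <- m; rownames(bad) <- colnames(bad) <- c("A", "B", "C", "E")
  expect_error(sum_matrices(list(m, bad)), "E")
})

test_that("within-population mean distance enumerates all pairs", {
  same <- tibble::tibble(v1 = c(1, 1, 1), v2 = 0)
  expect_equal(within_population_mean_distance(same), 0)

  two <- tibble::tibble(v1 = c(0, 3), v2 = c(0, 4))
  expect_equal(within_population_mean_distance(two), 5)

  # collinear members at 0, 1, 2: pairs (1,1,2), mean 4/3
  three <- tibble::tibble(v1 = c(0, 1, 2))
  expect_equal(within_population_mean_distance(three), 4 / 3)

  expect_error(within_population_mean_distance(tibble::tibble(v1 = 1)),
               "at least 2")

  pers <- tibble::tibble(sample = c("a", "b", "c"),
                         population = c("P", "P", "Q"),
                         v1 = c(0, 2, 9))
  res <- within_population_distances(pers)
  expect_equal(res$population, "P")  # singleton Q has no pairs
  expect_equal(res$mean_distance, 2)
})

test_that("matrix validation catches asymmetry, labels and diagonal", {
  m <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_silent(validate_labeled_matrix(m))
  bad <- m; bad[1, 2] <- 2
  expect_error(validate_labeled_matrix(bad), "symmetric")
  bad <- m; diag(bad) <- 1e-6
  expect_error(validate_labeled_matrix(bad), "diagonal")
  expect_error(validate_labeled_matrix(unname(m)), "labels")
})

test_that("tidy() on a distance matrix emits one row per unordered pair", {
  withr::with_seed(47, {
    pts <- matrix(runif(6), 3, dimnames = list(c("A", "B", "C"), NULL))
  })
  m <- distance_matrix(tibble::tibble(
    population = rownames(pts), v1 = pts[, 1], v2 = pts[, 2]))
  td <- tidy(m)
  expect_equal(nrow(td), 3)
  expect_equal(td$distance[td$from == "A" & td$to == "B"], m["A", "B"])
})
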