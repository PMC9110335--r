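
test_that("association weights match exhaustive hand counts on the toy", {
  rec <- toy_records()
  A <- build_association_matrix(rec, "n5", "close", "2018")
  # focal efforts: A 2, B 1, C 0
  expect_equal(as.integer(A$focal_effort), c(2L, 1L, 0L))
  # counts: A-B from A's two focals + B's one; B-C none; A-C from B's focal? no:
  # B's focal lists A and C as neighbours of B, so dyads (B,A) and (B,C)
  expect_equal(A$counts["A", "B"], 3L)
  expect_equal(A$counts["B", "C"], 1L)
  expect_equal(A$counts["A", "C"], 0L)
  expect_equal(A$weights["A", "B"], 3 / (2 + 1))
  expect_equal(A$weights["B", "C"], 1 / (1 + 0))
  expect_equal(A$weights, t(A$weights))
  expect_equal(unname(diag(A$weights)), rep(0, 3))
  expect_true(all(A$weights >= 0 & A$weights <= 1))
  # raw count recoverable: weight * dyad exposure is an integer
  back <- A$weights * A$dyad_exposure
  expect_equal(back[upper.tri(back)], round(back[upper.tri(back)]),
               tolerance = 1e-9)
})

test_that("dyads where both members lack focals are flagged, not invented", {
  rec <- toy_records()
  A <- build_association_matrix(rec, "n5", "close", "2018",
                                ids = c("A", "B", "C", "D"))
  expect_true(A$undefined["C", "D"])
  expect_false(A$undefined["A", "B"])
  expect_equal(A$weights["C", "D"], 0)
})

test_that("a dyad co-occurring in every focal of both members has weight 1", {
  rec <- data.frame(focal_id = c("A", "B"), year = "2018", time_period = 1L,
                    end_observer_distance_m = 3,
                    n5 = c("B", "A"), n2_5 = "", n1 = "", touch = "",
                    stringsAsFactors = FALSE)
  rec$stratum <- factor("close", levels = c("far", "close"))
  A <- build_association_matrix(rec, "n5", "close", "2018")
  expect_equal(A$weights["A", "B"], 1)
})

test_that("mantel recovers identity, refuses degeneracy, hits the p floor", {
  M <- sym_matrix(10, seed = 2)
  res <- mantel(M, M, n_perm = 999, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0.001)  # (1 + 0) / (1 + 999): no permutation ties r = 1
  expect_error(mantel(M, matrix(0.5, 10, 10) - diag(0.5, 10)), "degenerate")
  expect_error(mantel(M, sym_matrix(9)), "dimensions")
})

test_that("exact mantel p equals the 4!-relabeling oracle", {
  A <- sym_matrix(4, seed = 5)
  B <- sym_matrix(4, seed = 6)
  res <- mantel(A, B, method = "spearman", exact = TRUE)
  expect_equal(res$n_perm, 24)

  perms <- list()
  for (i in 1:4) for (j in setdiff(1:4, i)) for (k in setdiff(1:4, c(i, j)))
    perms[[length(perms) + 1]] <- c(i, j, k, setdiff(1:4, c(i, j, k)))
  tri <- upper.tri(A)
  r_of <- function(p) spearman_oracle(A[tri], B[p, p][tri])
  r_all <- vapply(perms, r_of, numeric(1))
  expect_equal(res$r, spearman_oracle(A[tri], B[tri]), tolerance = 1e-12)
  expect_equal(res$p, mean(r_all >= res$r - 1e-12))
})

test_that("mantel agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  foc <- split_by_distance(small_study(seed = 44)$focals)
  A <- build_association_matrix(foc, "n5", "close", "2018")
  B <- build_association_matrix(foc, "n5", "far", "2018")
  ours <- mantel(A, B, n_perm = 999, seed = 3)
  ref <- vegan::mantel(as.dist(A$weights), as.dist(B$weights),
                       method = "spearman", permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
  # both p-values are Monte-Carlo estimates of the same tail probability
  expect_lt(abs(ours$p - ref$signif), 0.08)
})

test_that("mantel r is exactly invariant to joint relabeling and scaling", {
  A <- sym_matrix(8, seed = 7)
  B <- sym_matrix(8, seed = 8)
  r0 <- mantel(A, B, n_perm = 9, seed = 1)$r
  p <- sample(8)
  expect_equal(mantel(A[p, p], B[p, p], n_perm = 9, seed = 1)$r, r0,
               tolerance = 1e-12)
  expect_equal(mantel(A * 17, B * 0.03, n_perm = 9, seed = 1)$r, r0,
               tolerance = 1e-12)
})

test_that("mantel p is uniform under independence (null calibration, small)", {
  p_vals <- vapply(1:60, function(seed) {
    A <- sym_matrix(20, seed = 1000 + seed)
    B <- sym_matrix(20, seed = 5000 + seed)
    mantel(A, B, n_perm = 199, seed = seed)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p_vals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("centralities hit analytic anchors on simple graphs", {
  ring <- matrix(0, 3, 3)
  ring[cbind(c(1, 2, 3), c(2, 3, 1))] <- 0.5
  ring <- ring + t(ring)
  cen <- centralities(ring)
  expect_equal(cen$degree, rep(2L, 3))
  expect_equal(cen$betweenness, rep(0, 3))
  expect_equal(cen$strength, rep(1, 3))
  expect_equal(cen$closeness, rep(2 / 1, 3))  # (n-1)/sum(d) = 2/(0.5+0.5)

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- 0.3
  path[2, 3] <- path[3, 2] <- 0.4
  cen <- centralities(path)
  expect_equal(cen$betweenness, c(0, 1, 0))
  expect_equal(cen$closeness[1], 2 / (0.3 + 0.7))

  # betweenness in a complete uniform-weight graph is 0 everywhere
  K <- matrix(0.2, 5, 5); diag(K) <- 0
  expect_equal(centralities(K)$betweenness, rep(0, 5))

  expect_error(centralities(matrix(c(0, -1, -1, 0), 2)), "negative")
})

test_that("weighted closeness and betweenness match the all-paths oracle", {
  set.seed(10)
  for (rep in 1:3) {
    W <- sym_matrix(5, seed = 100 + rep)
    W[W < 0.3] <- 0  # structural zeros (symmetric threshold of a symmetric W)
    if (all(W == 0)) next
    orc <- path_oracle(W)
    cen <- centralities(W)
    expect_equal(cen$closeness, orc$closeness, tolerance = 1e-9)
    expect_equal(cen$betweenness, orc$betweenness, tolerance = 1e-9)
  }
})

test_that("inverse-distance option flips which animals are 'central'", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.9   # strong dyad
  W[2, 3] <- W[3, 2] <- 0.1   # weak dyad
  direct <- centralities(W)
  inv <- centralities(W, distance = "inverse")
  # weights-as-distances: the weak edge is the short one
  expect_gt(direct$closeness[3], direct$closeness[1])
  expect_gt(inv$closeness[1], inv$closeness[3])
})

test_that("rank concordance matches a Pearson-on-ranks oracle and flags ties", {
  x <- data.frame(individual_id = letters[1:8],
                  degree = c(3L, 1L, 4L, 4L, 2L, 5L, 1L, 3L),
                  closeness = c(0.2, 0.1, 0.4, 0.4, 0.15, 0.5, 0.1, 0.2),
                  betweenness = rep(0, 8))
  y <- data.frame(individual_id = letters[1:8],
                  degree = c(2L, 2L, 5L, 3L, 1L, 4L, 2L, 3L),
                  closeness = c(0.15, 0.12, 0.5, 0.3, 0.1, 0.45, 0.12, 0.3),
                  betweenness = seq(0, 0.7, 0.1))
  out <- compare_centralities(x, y)
  expect_equal(out$rho[out$metric == "degree"],
               spearman_oracle(x$degree, y$degree), tolerance = 1e-12)
  expect_false(out$defined[out$metric == "betweenness"])
  expect_true(is.na(out$rho[out$metric == "betweenness"]))
  expect_true(all(out$df == 6))

  # perfect and reversed concordance anchors
  same <- compare_centralities(y, y)
  expect_equal(same$rho, rep(1, 3))
  rev_y <- y
  rev_y$degree <- -y$degree
  rev_y$closeness <- -y$closeness
  rev_y$betweenness <- -y$betweenness
  opp <- compare_centralities(y, rev_y)
  expect_equal(opp$rho, rep(-1, 3))
})

test_that("matrix exports round-trip", {
  foc <- split_by_distance(small_study(seed = 50)$focals)
  A <- build_association_matrix(foc, "n5", "close", "2018")
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(A, p1)
  back <- as.matrix(utils::read.csv(p1, row.names = 1))
  expect_equal(unname(back), unname(A$weights), tolerance = 1e-12)

  p2 <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(A, p2)
  g <- igraph::read_graph(p2, format = "graphml")
  expect_equal(igraph::ecount(g), sum(A$weights[upper.tri(A$weights)] > 0))

  p3 <- withr::local_tempfile(fileext = ".csv")
  write_edgelist_csv(A, p3)
  el <- utils::read.csv(p3)
  expect_equal(nrow(el), sum(A$weights[upper.tri(A$weights)] > 0))
})
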