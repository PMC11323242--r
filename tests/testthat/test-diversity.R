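# The 3-point "chain": d(a,b) = d(b,c) = 0.6, d(a,c) = 0.9.
chain_dm <- matrix(c(0, 0.6, 0.9,
                     0.6, 0, 0.6,
                     0.9, 0.6, 0), 3, 3)

test_that("exact #Circles solves small cases by enumeration logic", {
  expect_identical(n_circles_exact(list(), D = 0.5)$count, 0L)
  one <- n_circles_exact(list(c(1L, 2L)), D = 0.5)
  expect_identical(one$count, 1L)
  expect_identical(one$selected, 1L)

  r <- n_circles_exact(as.list(1:3), matrix_dist(chain_dm), D = 0.7)
  expect_identical(r$count, 2L)
  expect_identical(r$selected, c(1L, 3L))
  expect_identical(r$method, "exact")
})

test_that("exact #Circles equals brute-force enumeration on random fingerprints", {
  set.seed(42)
  for (rep in 1:12) {
    fps <- random_fp_set(12)
    D <- sample(c(0.3, 0.5, 0.7), 1)
    r <- n_circles_exact(fps, D = D)
    expect_identical(r$count, as.integer(brute_force_circles(fps, tanimoto_distance, D)))
    # result invariants: pairwise separation and maximality
    sel <- r$selected
    if (length(sel) >= 2) for (i in sel) for (j in sel) if (i < j)
      expect_gt(tanimoto_distance(fps[[i]], fps[[j]]), D)
    for (k in setdiff(seq_along(fps), sel))
      expect_true(any(vapply(sel, function(s)
        tanimoto_distance(fps[[k]], fps[[s]]) <= D, TRUE)))
  }
})

test_that("the exact solver refuses oversized inputs and points to greedy", {
  fps <- random_fp_set(30)
  expect_error(n_circles_exact(fps, D = 0.5), "greedy")
})

test_that("greedy sphere exclusion is order-dependent and bounded by exact", {
  d <- matrix_dist(chain_dm)
  expect_identical(n_circles_greedy(as.list(1:3), d, 0.7, order = c(2, 1, 3))$count, 1L)
  expect_identical(n_circles_greedy(as.list(1:3), d, 0.7, order = 1:3)$count, 2L)

  # no exclusions / all-excluded extremes
  far <- matrix(1, 4, 4); diag(far) <- 0
  expect_identical(n_circles_greedy(as.list(1:4), matrix_dist(far), 0.7)$count, 4L)
  near <- matrix(0.1, 4, 4); diag(near) <- 0
  expect_identical(n_circles_greedy(as.list(1:4), matrix_dist(near), 0.7)$count, 1L)

  set.seed(7)
  for (rep in 1:20) {
    fps <- random_fp_set(12)
    D <- sample(c(0.3, 0.5, 0.7), 1)
    expect_lte(n_circles_greedy(fps, D = D)$count,
               n_circles_exact(fps, D = D)$count)
  }
})

test_that("exact #Circles is monotone under adding items", {
  set.seed(8)
  for (rep in 1:5) {
    fps <- random_fp_set(15)
    counts <- vapply(3:15, function(k)
      n_circles_exact(fps[seq_len(k)], D = 0.5)$count, 1L)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("#Circles respects the strict-inequality threshold convention", {
  # distances exactly at D conflict; D = 0 separates distinct fingerprints
  two <- matrix(c(0, 0.7, 0.7, 0), 2, 2)
  expect_identical(n_circles_exact(as.list(1:2), matrix_dist(two), D = 0.7)$count, 1L)
  fps <- list(c(1L, 2L), c(1L, 2L), c(3L, 4L), c(5L, 6L))
  expect_identical(n_circles_exact(fps, D = 0)$count, 3L)  # distinct fingerprints
  expect_identical(n_circles_exact(fps, D = 1)$count, 1L)  # D >= max distance
})

test_that("internal diversity is the mean pairwise distance, with known pathologies", {
  two <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_identical(internal_diversity(as.list(1:2), matrix_dist(two)), 1)
  ext <- matrix(c(0, 1, 0.1,
                  1, 0, 0.9,
                  0.1, 0.9, 0), 3, 3)
  expect_equal(internal_diversity(as.list(1:3), matrix_dist(ext)), 2 / 3)
  same <- list(c(1L, 2L), c(1L, 2L), c(1L, 2L))
  expect_identical(internal_diversity(same), 0)
  expect_error(internal_diversity(list(c(1L))), "fewer than 2")
})

test_that("cluster-inflated internal diversity is caught by #Circles", {
  # a broad covering set: 9 points at mutual distance 0.6
  cover <- matrix(0.6, 9, 9); diag(cover) <- 0
  # two tight clusters of two: IntDiv is higher, coverage is far lower
  cl <- make_clustered_points(2, 2, intra_d = 0.05, inter_d = 1.0)
  id_cover <- internal_diversity(as.list(1:9), matrix_dist(cover))
  id_clusters <- internal_diversity(cl$points, cl$dist)
  expect_gt(id_clusters, id_cover)
  nc_cover <- n_circles_exact(as.list(1:9), matrix_dist(cover), D = 0.3)$count
  nc_clusters <- n_circles_exact(cl$points, cl$dist, D = 0.3)$count
  expect_gt(nc_cover, nc_clusters)
})

test_that("unique molecules and Bemis-Murcko scaffolds are counted on canonical forms", {
  recs <- parse_molecules(c("C1=CC=CC=C1", "c1ccccc1"))
  expect_identical(count_unique(recs), 1L)
  expect_identical(count_unique(list()), 0L)

  tol_eb <- parse_molecules(c("Cc1ccccc1", "CCc1ccccc1"))
  expect_identical(count_scaffolds(tol_eb), 1L)  # both reduce to benzene
  expect_identical(murcko_scaffold("Cc1ccccc1"),
                   canonicalize("c1ccccc1")$canonical_smiles)

  # acyclic molecules share one empty-scaffold class
  acyclic <- parse_molecules(c("CCO", "CCCN"))
  expect_identical(count_scaffolds(acyclic), 1L)
  expect_identical(murcko_scaffold("CCO"), "")

  mixed <- parse_molecules(c("CCO", "zzz", "c1ccccc1"))
  expect_warning(u <- count_unique(mixed), "invalid")
  expect_identical(u, 2L)
})

test_that("maxmin ordering maximizes the minimum distance with index tie-breaks", {
  colinear <- matrix(c(0, 1, 2,
                       1, 0, 1,
                       2, 1, 0), 3, 3)
  expect_identical(maxmin_order(as.list(1:3), matrix_dist(colinear), start = 1),
                   c(1L, 3L, 2L))
  eq <- matrix(0.5, 4, 4); diag(eq) <- 0
  expect_identical(maxmin_order(as.list(1:4), matrix_dist(eq), start = 2),
                   c(2L, 1L, 3L, 4L))
  expect_identical(maxmin_order(list(c(1L, 5L)), start = 1), 1L)

  # greedy max-min property: each position's min-distance to predecessors is
  # the maximum achievable at that step
  set.seed(11)
  fps <- random_fp_set(10)
  ord <- maxmin_order(fps)
  for (k in 2:10) {
    prev <- ord[seq_len(k - 1L)]
    mind <- function(i) min(vapply(prev, function(p)
      tanimoto_distance(fps[[i]], fps[[p]]), 0))
    rest <- setdiff(seq_along(fps), prev)
    expect_equal(mind(ord[k]), max(vapply(rest, mind, 0)))
  }
})
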