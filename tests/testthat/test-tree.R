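test_that("nearest phenotyped neighbour uses patristic distance", {
  pt <- pheno_tree("((A:1,B:1):1,C:3);",
                   c(A = "strong", B = "wild_type", C = "wild_type"))
  nn <- nearest_phenotyped_neighbor(pt, "A")
  expect_identical(nn$neighbor, "B")
  expect_identical(nn$class, "wild_type")
  expect_equal(nn$distance, 2)
  # C is 5 from A, 5 from B
  expect_equal(nearest_phenotyped_neighbor(pt, "C")$distance, 5)
})

test_that("exact ties break lexicographically and two-tip trees work", {
  star <- pheno_tree("(A:1,B:1,C:1,D:1);",
                     c(A = "strong", B = "wild_type", C = "wild_type",
                       D = "wild_type"))
  expect_identical(nearest_phenotyped_neighbor(star, "A")$neighbor, "B")
  two <- pheno_tree("(A:1,B:1);", c(A = "strong", B = "wild_type"))
  nn <- nearest_phenotyped_neighbor(two, "A")
  expect_identical(nn$neighbor, "B")
  expect_equal(nn$distance, 2)
})

test_that("unphenotyped tips shape distances but are never neighbours", {
  pt <- pheno_tree("((A:1,X:1):1,B:4);", c(A = "strong", B = "wild_type"))
  nn <- nearest_phenotyped_neighbor(pt, "A")
  expect_identical(nn$neighbor, "B") # X is closer but unphenotyped
  only <- pheno_tree("((A:1,X:1):1,B:4);", c(A = "strong"))
  expect_error(nearest_phenotyped_neighbor(only, "A"), "no other")
  expect_error(nearest_phenotyped_neighbor(pt, "Z"), "not in the tree")
})

test_that("scatter statistic counts focal tips with wild-type neighbours", {
  # one strong tip among wild type: statistic 1
  pt <- pheno_tree("((A:1,B:1):1,(C:1,D:1):1);",
                   c(A = "strong", B = "wild_type", C = "wild_type",
                     D = "wild_type"))
  expect_identical(scatter_statistic(pt), 1L)
  # a clade of strong-only neighbours: statistic 0
  cl <- pheno_tree("((A:1,B:1):3,(C:1,D:1):3);",
                   c(A = "strong", B = "strong", C = "wild_type",
                     D = "wild_type"))
  expect_identical(scatter_statistic(cl), 0L)
  expect_error(scatter_statistic(pt, focal_class = "moderate"), "no tip")
})

test_that("patristic distances are symmetric and satisfy the triangle inequality", {
  set.seed(12)
  for (i in 1:5) {
    tr <- ape::rtree(12)
    cls <- setNames(sample(c("strong", "wild_type"), 12, replace = TRUE),
                    tr$tip.label)
    pt <- pheno_tree(tr, cls)
    d <- pt$dist
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    n <- nrow(d)
    for (a in 1:n) for (b in 1:n) {
      expect_true(all(d[a, b] <= d[a, ] + d[, b] + 1e-9))
    }
  }
})

test_that("the scatter statistic is invariant under re-rooting", {
  set.seed(42)
  tr <- ape::rtree(20)
  cls <- setNames(sample(c("strong", "wild_type"), 20, replace = TRUE,
                         prob = c(0.3, 0.7)), tr$tip.label)
  s0 <- scatter_statistic(pheno_tree(tr, cls))
  for (node in c(25, 30, 35)) {
    rerooted <- ape::root(tr, node = node, resolve.root = TRUE)
    expect_identical(scatter_statistic(pheno_tree(rerooted, cls)), s0)
  }
  expect_identical(scatter_statistic(pheno_tree(ape::unroot(tr), cls)), s0)
})

test_that("permutation p-values are smoothed away from zero and handle ties", {
  # all labels identical: every permutation ties the observed statistic
  pt <- pheno_tree("((A:1,B:1):1,(C:1,D:1):1);",
                   c(A = "strong", B = "strong", C = "strong",
                     D = "strong"))
  res <- scatter_permutation_test(pt, focal_class = "strong",
                                  n_permutations = 49, seed = 1)
  expect_equal(res$p.value, 1)
  # p can never be 0 by the +1 smoothing
  set.seed(3)
  tr <- ape::rtree(16)
  cls <- setNames(rep(c("strong", "wild_type"), each = 8), tr$tip.label)
  p <- scatter_permutation_test(pheno_tree(tr, cls),
                                n_permutations = 99, seed = 2)$p.value
  expect_gt(p, 0)
  expect_lte(p, 1)
})

test_that("clustered labels on a balanced tree yield a small clustering p", {
  # balanced 64-tip tree; the 8 focal tips form one clade
  tr <- ape::stree(64, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  cls <- setNames(rep("wild_type", 64), tr$tip.label)
  cls[1:8] <- "strong" # one subtree of the balanced topology
  pt <- pheno_tree(tr, cls)
  res <- scatter_permutation_test(pt, n_permutations = 499, seed = 7,
                                  alternative = "clustered")
  expect_lt(res$p.value, 0.05)
})

test_that("label-permutation null p-values are approximately uniform", {
  # enough focal tips that the count statistic takes many values;
  # with few tips its discreteness makes the p-value lumpy
  set.seed(8)
  tr <- ape::rtree(60)
  pvals <- vapply(1:300, function(i) {
    cls <- setNames(sample(c("strong", "wild_type"), 60, replace = TRUE,
                           prob = c(0.3, 0.7)), tr$tip.label)
    if (!any(cls == "strong")) cls[1] <- "strong"
    scatter_permutation_test(pheno_tree(tr, cls), n_permutations = 199,
                             seed = i)$p.value
  }, numeric(1))
  # valid level plus rough uniformity in the bulk (stat ties leave the
  # test mildly conservative)
  expect_gte(mean(pvals <= 0.05), 0.02)
  expect_lte(mean(pvals <= 0.05), 0.08)
  expect_gt(mean(pvals <= 0.5), 0.3)
})

test_that("hops distances give the topology-only alternative", {
  pt <- pheno_tree("((A:1,B:10):1,C:3);",
                   c(A = "strong", B = "wild_type", C = "wild_type"),
                   method = "hops")
  nn <- nearest_phenotyped_neighbor(pt, "A")
  expect_identical(nn$neighbor, "B") # 2 hops, vs 3 to C
  expect_equal(nn$distance, 2)
})

test_that("malformed annotation inputs are rejected", {
  expect_error(pheno_tree("(A:1,B:1);", c(Z = "strong")), "absent")
  expect_error(pheno_tree("(A:1,B:1);", c(A = "odd_class")), "unknown")
  expect_error(pheno_tree("(A:1,B:1);", "strong"), "named")
})
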