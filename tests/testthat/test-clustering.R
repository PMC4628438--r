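# UPGMA, locus bootstrap, consensus and significant-cluster counting.

test_that("upgma reproduces the hand-computed merge sequence", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 0.1
  d["A", "C"] <- d["B", "C"] <- 0.4
  d["A", "D"] <- d["B", "D"] <- d["C", "D"] <- 0.6
  d <- pmax(d, t(d))
  tr <- upgma(d)
  cl <- tree_clades(tr)
  key <- vapply(cl$clade, clade_key, "")
  expect_equal(cl$height[key == clade_key(c("A", "B"))], 0.05)
  expect_equal(cl$height[key == clade_key(c("A", "B", "C"))], 0.2)
  expect_equal(cl$height[key == clade_key(LETTERS[1:4])], 0.3)
  expect_equal(newick_string(tr), "(((A:0.05,B:0.05):0.15,C:0.2):0.1,D:0.3);")
})

test_that("degenerate all-zero matrices merge at height 0 with deterministic topology", {
  d <- matrix(0, 4, 4, dimnames = list(c("D", "B", "C", "A"), c("D", "B", "C", "A")))
  tr <- upgma(d)
  expect_true(all(tree_clades(tr)$height == 0))
  # lexicographic tie-break: A and B first, then C, then D
  expect_equal(newick_string(tr), "(((A:0.0,B:0.0):0.0,C:0.0):0.0,D:0.0);")
})

test_that("upgma equals the naive brute-force oracle on seeded random matrices", {
  set.seed(123)
  for (n in 3:7) {
    for (rep_i in 1:5) {
      d <- random_distance_matrix(n)
      tr <- upgma(d)
      cl <- tree_clades(tr)
      oracle <- naive_upgma(d)
      expect_equal(sort(cl$height), oracle$heights, tolerance = 1e-9)
      expect_identical(sort(vapply(cl$clade, clade_key, "")), oracle$clades)
    }
  }
})

test_that("upgma merge heights agree with hclust average linkage", {
  set.seed(21)
  d <- random_distance_matrix(9)
  tr <- upgma(d)
  hc <- hclust(as.dist(d), method = "average")
  expect_equal(sort(tree_clades(tr)$height), sort(hc$height / 2), tolerance = 1e-9)
})

test_that("upgma trees are ultrametric", {
  set.seed(31)
  for (rep_i in 1:5) {
    d <- random_distance_matrix(8)
    ph <- tree_to_phylo(upgma(d))
    depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
    expect_lt(max(depths) - min(depths), 1e-9)
  }
  expect_error(upgma(matrix(NaN, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))),
               "NA|NaN")
})

test_that("two fully differentiated blocks get 100% clade support", {
  m <- rbind(matrix(1L, 3, 15), matrix(0L, 3, 15))
  dimnames(m) <- list(c(paste0("X", 1:3), paste0("Y", 1:3)), paste0("L", 1:15))
  m[4:6, 1] <- 1L                                # avoid all-zero profiles
  m[1:3, 1] <- 0L
  bs <- bootstrap_support(m, bootstrap_config(n_replicates = 100, seed = 4))
  key <- vapply(tree_clades(bs$tree)$clade, clade_key, "")
  sup <- tree_clades(bs$tree)$support
  expect_equal(sup[key == clade_key(paste0("X", 1:3))], 100)
  expect_equal(sup[key == clade_key(paste0("Y", 1:3))], 100)
})

test_that("bootstrap supports are deterministic for a seed and {0,100} for one replicate", {
  set.seed(77)
  m <- random_binary_matrix(8, 12)
  b1 <- bootstrap_support(m, bootstrap_config(n_replicates = 60, seed = 9))
  b2 <- bootstrap_support(m, bootstrap_config(n_replicates = 60, seed = 9))
  expect_identical(newick_string(b1$tree), newick_string(b2$tree))
  expect_identical(b1$clade_support, b2$clade_support)
  one <- bootstrap_support(m, bootstrap_config(n_replicates = 1, seed = 3))
  expect_true(all(tree_clades(one$tree)$support %in% c(0, 100)))
})

test_that("supports are invariant under isolate relabeling", {
  set.seed(41)
  m <- random_binary_matrix(7, 14)
  b1 <- bootstrap_support(m, bootstrap_config(n_replicates = 50, seed = 6))
  # relabel by a fixed permutation of names (same partition structure)
  m2 <- m
  rownames(m2) <- paste0("Q", match(rownames(m), sort(rownames(m))))
  b2 <- bootstrap_support(m2, bootstrap_config(n_replicates = 50, seed = 6))
  relabel <- function(keys, map) {
    vapply(strsplit(keys, "\r", fixed = TRUE),
           function(s) clade_key(unname(map[s])), "")
  }
  map <- setNames(rownames(m2), rownames(m))
  k1 <- vapply(tree_clades(b1$tree)$clade, clade_key, "")
  s1 <- setNames(tree_clades(b1$tree)$support, relabel(k1, map))
  k2 <- vapply(tree_clades(b2$tree)$clade, clade_key, "")
  s2 <- setNames(tree_clades(b2$tree)$support, k2)
  expect_mapequal(as.list(s1), as.list(s2))
})

test_that("consensus holds exactly the >50% clades at their replicate frequencies", {
  set.seed(55)
  m <- random_binary_matrix(7, 10)
  bs <- bootstrap_support(m, bootstrap_config(n_replicates = 80, seed = 12))
  cons <- tree_clades(bs$consensus, include_root = FALSE)
  freq <- setNames(bs$clade_support$support,
                   vapply(bs$clade_support$clade, clade_key, ""))
  for (i in seq_len(nrow(cons))) {
    k <- clade_key(cons$clade[[i]])
    expect_gt(freq[[k]], 50)
    expect_equal(cons$support[i], unname(freq[[k]]))
  }
  # no >50% clade is missing from the consensus
  majority <- names(freq)[freq > 50]
  majority <- setdiff(majority, clade_key(tree_leaves(bs$tree)))
  expect_setequal(majority, vapply(cons$clade, clade_key, ""))
})

test_that("consensus topology matches the standard majority-rule implementation", {
  set.seed(66)
  m <- random_binary_matrix(6, 8)
  cfg <- bootstrap_config(n_replicates = 40, seed = 8)
  bs <- bootstrap_support(m, cfg)
  # rebuild the replicate trees and feed them to ape::consensus
  withr::with_seed(cfg$seed, {
    trees <- lapply(seq_len(cfg$n_replicates), function(r) {
      idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
      mr <- m[, idx, drop = FALSE]
      colnames(mr) <- sprintf("L%d", seq_along(idx))
      tree_to_phylo(upgma(dice_distance_matrix(mr)))
    })
  })
  ac <- ape::consensus(trees, p = 0.5, rooted = TRUE)
  parts <- ape::prop.part(ac)
  ac_keys <- sort(vapply(parts, function(idx) clade_key(attr(parts, "labels")[idx]), ""))
  my_keys <- sort(vapply(tree_clades(bs$consensus)$clade, clade_key, ""))
  expect_identical(my_keys, ac_keys)
})

test_that("significant clusters are counted above the threshold, root excluded", {
  ab <- aflpdiver:::.internal_node(list(aflpdiver:::.leaf_node("A"),
                                        aflpdiver:::.leaf_node("B")),
                                   height = 0.05, support = 97)
  abc <- aflpdiver:::.internal_node(list(ab, aflpdiver:::.leaf_node("C")),
                                    height = 0.1, support = 96)
  abcd <- aflpdiver:::.internal_node(list(abc, aflpdiver:::.leaf_node("D")),
                                     height = 0.15, support = 40)
  root <- aflpdiver:::.internal_node(list(abcd, aflpdiver:::.leaf_node("E")),
                                     height = 0.3, support = 100)
  tr <- aflpdiver:::.new_tree(root, LETTERS[1:5])
  expect_equal(count_significant_clusters(tr, 95), 2)
  expect_equal(count_significant_clusters(tr, 101), 0)
  bare <- upgma(random_distance_matrix(4))
  expect_error(count_significant_clusters(bare, 95), "support")
})

test_that("noise-free lineage simulation yields one significant cluster per lineage", {
  sim <- simulate_aflp(simulation_config(n_isolates = 12, n_lineages = 3,
                                         n_loci = 30, mutation_rate = 0,
                                         dropout_prob = 0, sigma_present = 0.05,
                                         sigma_absent = 0.05, seed = 1))
  res <- score_matrix(sim$intensities)
  m <- res$matrix[sprintf("ISO%03d", 1:12), ]       # real isolates only
  bs <- bootstrap_support(m, bootstrap_config(n_replicates = 100, seed = 1))
  # every lineage clade is present with full support
  key <- vapply(tree_clades(bs$tree)$clade, clade_key, "")
  sup <- tree_clades(bs$tree)$support
  for (lin in sort(unique(sim$truth$lineage_of))) {
    members <- names(sim$truth$lineage_of)[sim$truth$lineage_of == lin]
    expect_equal(sup[key == clade_key(members)], 100)
  }
  expect_equal(count_significant_clusters(bs$tree, 95), 3)
})
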