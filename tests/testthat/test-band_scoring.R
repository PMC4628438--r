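# Dual-replicate band calling and locus filtering.

test_that("score_band implements the dual-replicate threshold rule", {
  expect_equal(score_band(150, 120), 1L)   # both confident
  expect_equal(score_band(150, 60), 1L)    # disagreement, weaker still >= 50
  expect_equal(score_band(150, 40), 0L)    # weaker below the reliable minimum
  expect_equal(score_band(90, 95), 0L)     # neither confident
  expect_error(score_band(-1, 100), "non-negative")
})

test_that("closed form agrees with the literal verbal rule on the exhaustive grid", {
  grid <- c(0, 49, 50, 51, 99, 100, 101, 500)
  for (i1 in grid) for (i2 in grid) {
    expect_identical(score_band(i1, i2), verbal_score_band(i1, i2),
                     info = sprintf("(%g, %g)", i1, i2))
  }
})

test_that("score_band is symmetric and monotone with inclusive boundaries", {
  set.seed(1)
  i1 <- runif(200, 0, 300); i2 <- runif(200, 0, 300)
  expect_identical(score_band(i1, i2), score_band(i2, i1))
  # raising either intensity never flips 1 -> 0
  expect_true(all(score_band(i1 + 20, i2) >= score_band(i1, i2)))
  expect_true(all(score_band(i1, i2 + 20) >= score_band(i1, i2)))
  # boundary: >= at both thresholds
  expect_equal(score_band(100, 50), 1L)
  expect_equal(score_band(100, 49.999), 0L)
  expect_equal(score_band(99.999, 99.999), 0L)
})

test_that("score_matrix calls, flags polymorphism and counts strong conflicts", {
  df <- make_intensity_df(c("A", "B"), c("L1", "L2"))
  res <- score_matrix(df)
  expect_true(all(res$matrix == 1L))
  expect_false(any(res$quality$is_polymorphic))

  df2 <- set_intensity(df, "B", "L1", 10, 12)
  res2 <- score_matrix(df2)
  expect_equal(res2$matrix["A", "L1"], 1L)
  expect_equal(res2$matrix["B", "L1"], 0L)
  q <- res2$quality[res2$quality$locus_id == "L1", ]
  expect_true(q$is_polymorphic)
  expect_equal(q$conflict_fraction, 0)

  # one strong disagreement contributes 1/n_isolates
  df3 <- set_intensity(df, "A", "L2", 800, 20)
  res3 <- score_matrix(df3)
  expect_equal(res3$matrix["A", "L2"], 0L)
  expect_equal(res3$quality$conflict_fraction[res3$quality$locus_id == "L2"], 1 / 2)
})

test_that("loci missing from an isolate's records score as absent", {
  df <- make_intensity_df(c("A", "B"), c("L1", "L2"))
  # drop both replicates of B at L2: treated as intensity 0
  df <- df[!(df$isolate_id == "B" & df$locus_id == "L2"), ]
  res <- score_matrix(df)
  expect_equal(res$matrix["B", "L2"], 0L)
  # dropping a single replicate is an error naming isolate and locus
  df2 <- make_intensity_df(c("A", "B"), c("L1", "L2"))
  df2 <- df2[!(df2$isolate_id == "B" & df2$locus_id == "L2" & df2$replicate == 2), ]
  expect_error(score_matrix(df2), "B.*L2")
})

test_that("control-isolate plate copies drive the control-consistency flag", {
  df <- make_intensity_df(c("A", "A.p2", "B"), c("L1", "L2"))
  df <- set_intensity(df, "A.p2", "L2", 10, 10)      # control flips on plate 2
  res <- score_matrix(df, control_isolates = c("A", "A.p2"))
  expect_true(res$quality$control_consistent[res$quality$locus_id == "L1"])
  expect_false(res$quality$control_consistent[res$quality$locus_id == "L2"])
  expect_error(score_matrix(df, control_isolates = "ZZZ"), "control")
})

test_that("filter_loci applies thresholds, preserves order and is idempotent", {
  q <- data.frame(locus_id = paste0("L", 1:4),
                  conflict_fraction = c(0, 0.1, 0, 0),
                  is_polymorphic = c(TRUE, TRUE, TRUE, FALSE),
                  control_consistent = NA)
  m <- random_binary_matrix(5, 4)
  colnames(m) <- paste0("L", 1:4)
  m[, 1] <- c(1, 0, 1, 0, 1); m[, 3] <- c(0, 1, 0, 1, 0); m[, 4] <- 1
  m[, 2] <- c(1, 1, 0, 0, 1)
  kept <- filter_loci(m, q, max_conflict = 0)
  expect_identical(colnames(kept), c("L1", "L3"))      # L2 conflicted, L4 monomorphic
  kept2 <- filter_loci(m, q, max_conflict = 0.2, require_polymorphic = FALSE)
  expect_identical(colnames(kept2), paste0("L", 1:4))
  # three clean loci survive a max_conflict just above one dirty locus
  kept3 <- filter_loci(m, q, max_conflict = 0.1, require_polymorphic = FALSE)
  expect_equal(ncol(kept3), 4)
  # idempotence
  q13 <- q[q$locus_id %in% colnames(kept), ]
  expect_identical(filter_loci(kept, q13, max_conflict = 0), kept)
  # removing everything is an error, not an empty matrix
  qbad <- q; qbad$conflict_fraction <- 1
  expect_error(filter_loci(m, qbad, max_conflict = 0.5), "relax")
})

test_that("retained locus set matches an independent per-locus recount under dropout", {
  cfg <- simulation_config(n_isolates = 20, n_lineages = 5, n_loci = 30,
                           mutation_rate = 0, dropout_prob = 0, seed = 33)
  sim <- simulate_aflp(cfg)
  # inject heavy dropout on loci L001..L010 by zeroing replicate 2
  tab <- sim$intensities
  dirty <- sprintf("L%03d", 1:10)
  set.seed(99)
  sel <- tab$locus_id %in% dirty & tab$replicate == 2 & tab$intensity > 100 &
    runif(nrow(tab)) < 0.4
  tab$intensity[sel] <- 5
  res <- score_matrix(tab)
  kept <- filter_loci(res$matrix, res$quality, max_conflict = 0.05,
                      require_polymorphic = FALSE, require_control_consistent = FALSE)
  # independent recount: conflict = one rep >= 100, other < 50, per isolate x locus
  wide1 <- with(tab[tab$replicate == 1, ], tapply(intensity, list(isolate_id, locus_id), identity))
  wide2 <- with(tab[tab$replicate == 2, ], tapply(intensity, list(isolate_id, locus_id), identity))
  wide2 <- wide2[rownames(wide1), colnames(wide1)]
  conflict <- (pmax(wide1, wide2) >= 100) & (pmin(wide1, wide2) < 50)
  keep_oracle <- colnames(wide1)[colMeans(conflict) <= 0.05]
  expect_setequal(colnames(kept), keep_oracle)
  # clean loci all survive
  clean <- setdiff(sprintf("L%03d", 1:30), dirty)
  expect_true(all(clean %in% colnames(kept)))
})

test_that("noise-free simulations have zero conflict at every locus", {
  sim <- simulate_aflp(simulation_config(n_isolates = 15, n_lineages = 4,
                                         n_loci = 25, mutation_rate = 0,
                                         dropout_prob = 0, sigma_present = 0.05,
                                         sigma_absent = 0.05, seed = 2))
  res <- score_matrix(sim$intensities)
  expect_true(all(res$quality$conflict_fraction == 0))
})
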