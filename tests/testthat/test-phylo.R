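test_that("read_newick parses and repairs branch lengths", {
  p <- tempfile(fileext = ".nwk")
  writeLines("((A:2,B:1):1,C:3);", p)
  tr <- read_newick(p)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3))

  writeLines("((A,B),C);", p)
  expect_message(tr <- read_newick(p), "no branch lengths")
  expect_true(all(tr$edge.length == 1))

  writeLines("((A:0,B:1):1,C:3);", p)
  expect_message(tr <- read_newick(p), "1 non-positive")
  expect_true(all(tr$edge.length > 0))

  writeLines("((A:1,B:1", p)
  expect_error(read_newick(p), "malformed")
  expect_error(read_newick(tempfile()), "not found")
})

test_that("pruning conserves path lengths and collapses degree-2 nodes", {
  tr <- ape::read.tree(text = "((A:2,B:1):1,C:3);")
  pr <- prune_to_taxa(tr, c("A", "C"))
  expect_equal(sort(pr$tip.label), c("A", "C"))
  d <- ape::cophenetic.phylo(pr)
  expect_equal(d["A", "C"], 6)  # 2 + 1 + 3

  expect_warning(prune_to_taxa(tr, c("A", "C", "Zed")), "Zed")
  expect_error(prune_to_taxa(tr, "A"), "at least 2")

  # identity: pruning to all tips leaves distances untouched
  set.seed(31)
  tr <- random_tree(8)
  expect_equal(ape::cophenetic.phylo(prune_to_taxa(tr, tr$tip.label)),
               ape::cophenetic.phylo(tr))

  # random subsets: the kept-tip distance matrix is the oracle
  for (i in 1:10) {
    tr <- random_tree(8)
    keep <- sample(tr$tip.label, 4)
    d_full <- ape::cophenetic.phylo(tr)[keep, keep]
    d_pruned <- ape::cophenetic.phylo(prune_to_taxa(tr, keep))[keep, keep]
    expect_equal(d_pruned, d_full, tolerance = 1e-10)
  }
})

test_that("collapse_to_genera keeps type species when configured", {
  tr <- ape::read.tree(text = "((Pan_a:1,(Pan_b:1,Loro_x:1):1):1,(Chae_a:1,Chae_b:1):2);")
  out <- collapse_to_genera(tr)
  expect_setequal(out$tip.label, c("Pan", "Loro", "Chae"))
  out2 <- collapse_to_genera(tr, type_species = c("Pan_b", "Chae_b"))
  expect_setequal(out2$tip.label, c("Pan", "Loro", "Chae"))
  # type species retained: Pan tip sits where Pan_b was (sister to Loro_x)
  d <- ape::cophenetic.phylo(out2)
  expect_equal(d["Pan", "Loro"], 2)
})

test_that("tips_to_cartesian applies the shifted projection", {
  s <- data.frame(genus = c("a", "b", "c"), mu_deg = c(0, 90, 52),
                  r = c(1, 0.5, 0.74))
  xy <- tips_to_cartesian(s)
  expect_equal(xy$X, c(2, 1, 1.4556), tolerance = 1e-4)
  expect_equal(xy$Y, c(1, 1.5, 1.5831), tolerance = 1e-4)
  expect_true(all(xy$X >= 0 & xy$X <= 2 & xy$Y >= 0 & xy$Y <= 2))
  s$mu_deg[1] <- NA
  expect_error(tips_to_cartesian(s), "undefined mean direction")
})

test_that("weighted least-squares reconstruction: closed forms", {
  # cherry, symmetric: root at the midpoint
  tr <- ape::read.tree(text = "(A:1,B:1);")
  out <- pls_ancestral_states(tr, c(A = 0, B = 2))
  expect_equal(unname(out[3]), 1)

  # star tree: root is the 1/branch-length weighted mean
  tr <- ape::read.tree(text = "(A:1,B:2,C:4,D:8);")
  v <- c(A = 1, B = 3, C = -2, D = 10)
  w <- 1 / c(1, 2, 4, 8)
  expect_equal(unname(pls_ancestral_states(tr, v)[5]),
               sum(v * w) / sum(w), tolerance = 1e-12)

  expect_error(pls_ancestral_states(tr, c(A = 1, B = 2)), "missing tip")
  tr0 <- tr; tr0$edge.length[2] <- 0
  expect_error(pls_ancestral_states(tr0, v), "positive branch lengths")
})

test_that("reconstruction matches the brute-force minimizer on random trees", {
  set.seed(32)
  for (i in 1:25) {
    tr <- random_tree(sample(4:8, 1))
    v <- stats::setNames(rnorm(length(tr$tip.label), 1, 0.5), tr$tip.label)
    fast <- pls_ancestral_states(tr, v)
    slow <- pls_oracle(tr, v)
    expect_equal(unname(fast), slow, tolerance = 1e-6)
  }
})

test_that("reconstruction properties: affine equivariance, hull, separability", {
  set.seed(33)
  for (i in 1:10) {
    tr <- random_tree(7)
    v <- stats::setNames(runif(7, 0, 2), tr$tip.label)
    base <- pls_ancestral_states(tr, v)
    # affine equivariance (the +1 positivity shift is exactly neutral)
    a <- runif(1, 0.5, 3); b <- runif(1, -5, 5)
    expect_equal(pls_ancestral_states(tr, a * v + b), a * base + b,
                 tolerance = 1e-9)
    # root (and all internals) within the tip range
    internals <- base[-seq_len(7)]
    expect_true(all(internals >= min(v) - 1e-10 & internals <= max(v) + 1e-10))
  }
  # equal branch lengths: equals unweighted squared-change parsimony
  tr <- random_tree(6)
  tr$edge.length <- rep(1, nrow(tr$edge))
  v <- stats::setNames(rnorm(6), tr$tip.label)
  expect_equal(unname(pls_ancestral_states(tr, v)), pls_oracle(tr, v),
               tolerance = 1e-6)
})

test_that("states_to_angles: quadrant correction, sectors, axis labels", {
  out <- states_to_angles(c(2, 0, 1.5, 1), c(1, 1, 0.5, 1))
  expect_equal(out$angle_deg, c(0, 180, 315, NA))
  expect_equal(out$sector, c(0L, 4L, 7L, NA))
  expect_equal(out$N_label, c("centroid", "centroid", "15N-depleted", "centroid"))
  expect_equal(out$C_label, c("13C-enriched", "13C-depleted", "13C-enriched",
                              "centroid"))
  # sector bins are half-open [k*45, (k+1)*45)
  th <- seq(0, 359, by = 1) * pi / 180
  out <- states_to_angles(cos(th) + 1, sin(th) + 1)
  expect_equal(out$sector, as.integer(floor(out$angle_deg / 45)))
  expect_true(all(out$sector %in% 0:7))
})

test_that("axis transition counts match hand enumeration", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,(E:1,F:1):1):1);")
  s <- data.frame(genus = tr$tip.label,
                  mu_deg = c(A = 90, B = 270, C = 90, D = 90, E = 270, F = 270),
                  r = 0.8)
  rec <- ancestral_vector_states(tr, s)
  lab <- rec$states$N_label
  # hand count over the edge list
  hand <- sum(lab[rec$tree$edge[, 1]] != lab[rec$tree$edge[, 2]])
  out <- count_axis_transitions(rec$tree, rec$states, "N")
  expect_equal(out$transitions, hand)
  expect_equal(out$skipped, 0)
  expect_equal(nrow(out$branches), out$transitions)

  # all tips on the same side: zero transitions
  s$mu_deg <- 90
  rec <- ancestral_vector_states(tr, s)
  expect_equal(count_axis_transitions(rec$tree, rec$states, "N")$transitions, 0)

  # cherry with opposite sides: exactly one transition on the N axis
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  rec2 <- ancestral_vector_states(
    tr2, data.frame(genus = c("A", "B"), mu_deg = c(90, 270), r = c(0.9, 0.3))
  )
  expect_equal(count_axis_transitions(rec2$tree, rec2$states, "N")$transitions, 1)
})

test_that("ancestral_vector_states prunes or errors on orphan tips", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  s <- data.frame(genus = c("A", "B", "C"), mu_deg = c(10, 100, 200), r = 0.7)
  rec <- ancestral_vector_states(tr, s, prune = TRUE)
  expect_setequal(rec$tree$tip.label, c("A", "B", "C"))
  expect_error(ancestral_vector_states(tr, s, prune = FALSE), "D")

  # unit_lengths flag equals running on a tree with all lengths 1
  tr1 <- tr; tr1$edge.length <- rep(1, nrow(tr$edge))
  s4 <- data.frame(genus = c("A", "B", "C", "D"),
                   mu_deg = c(10, 100, 200, 300), r = 0.7)
  expect_equal(ancestral_vector_states(tr, s4, unit_lengths = TRUE)$states,
               ancestral_vector_states(tr1, s4)$states)
})
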