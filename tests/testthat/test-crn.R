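test_that("the limited-signalling network has the printed structure", {
  for (N in c(1, 2, 4, 6)) {
    cs <- crn_structure(build_model(3, mean_params(N = N)))
    expect_identical(cs$n_complexes, as.integer(N + 3))
    expect_identical(cs$linkage_classes, 1L)
    expect_identical(cs$rank, as.integer(N + 2))
    expect_identical(cs$deficiency, 0L)
    expect_true(cs$weakly_reversible)
  }
  cs2 <- crn_structure(build_model(3, mean_params(N = 2)))
  expect_setequal(cs2$complexes, c("L + R", "C0", "C1", "C2", "C3"))
})

test_that("hand-derived small networks come out right", {
  p <- mean_params()
  ## occupancy: two complexes, one reversible pair
  cs1 <- crn_structure(build_model(1, p))
  expect_identical(unclass(glance(cs1))[c("n_complexes", "linkage_classes",
                                          "rank", "deficiency")],
                   list(n_complexes = 2L, linkage_classes = 1L,
                        rank = 1L, deficiency = 0L))
  expect_true(cs1$weakly_reversible)

  ## textbook cycle A -> B -> C -> A: delta = 3 - 1 - 2 = 0
  cyc <- list(reaction(c(A = 1), c(B = 1), 1, "k1"),
              reaction(c(B = 1), c(C = 1), 1, "k2"),
              reaction(c(C = 1), c(A = 1), 1, "k3"))
  cs <- crn_structure(cyc)
  expect_identical(cs$deficiency, 0L)
  expect_identical(cs$rank, 2L)
  expect_true(cs$weakly_reversible)

  ## A -> B with no return path is not weakly reversible
  expect_false(crn_structure(list(reaction(c(A = 1), c(B = 1), 1, "k")))$
                 weakly_reversible)

  ## two disjoint reversible reactions: two linkage classes
  two <- list(reaction(c(A = 1), c(B = 1), 1, "k1"),
              reaction(c(B = 1), c(A = 1), 1, "k2"),
              reaction(c(C = 1), c(D = 1), 1, "k3"),
              reaction(c(D = 1), c(C = 1), 1, "k4"))
  expect_identical(crn_structure(two)$linkage_classes, 2L)

  ## empty reaction list
  expect_length(extract_complexes(list()), 0)
})

test_that("sustained-signalling models are deficiency-zero and weakly
           reversible in the structural view", {
  for (id in c(4, 9)) {
    for (N in 1:6) {
      cs <- crn_structure(build_model(id, mean_params(N = N)))
      expect_identical(cs$deficiency, 0L)
      expect_true(cs$weakly_reversible)
    }
  }
  ## the simulated (quantitative) network of model 4 is *not* weakly
  ## reversible: the reset D -> R has no return path
  cs_sim <- crn_structure(build_model(4, mean_params(N = 2)),
                          structural = FALSE)
  expect_false(cs_sim$weakly_reversible)
})

test_that("rank is exact and invariant to reordering and duplication", {
  p <- mean_params(N = 3)
  m <- build_model(3, p)
  base <- crn_structure(m)
  perm <- m
  set.seed(1)
  perm$reactions <- sample(m$reactions)
  dup <- m
  dup$reactions <- c(m$reactions, m$reactions[1:3])
  expect_identical(crn_structure(perm)$rank, base$rank)
  expect_identical(crn_structure(dup)$rank, base$rank)
  ## integer rank agrees with floating qr on a benign case
  vecs <- sapply(m$reactions, function(r) {
    v <- stats::setNames(numeric(length(m$species)), m$species)
    v[names(r$reactants)] <- v[names(r$reactants)] - r$reactants
    v[names(r$products)] <- v[names(r$products)] + r$products
    v
  })
  expect_identical(base$rank, qr(vecs)$rank)
})

test_that("deficiency is nonnegative on random small networks", {
  set.seed(99)
  for (k in 1:300) {
    net <- random_network(n_species = sample(3:5, 1), n_rxn = sample(2:6, 1))
    cs <- crn_structure(net)
    expect_gte(cs$deficiency, 0)
  }
})

test_that("verdict table covers all models with one row each", {
  v <- crn_verdicts(1:9, mean_params(N = 2))
  expect_identical(nrow(v), 9L)
  expect_identical(v$deficiency[v$model %in% c(1, 2, 3, 4, 6, 9)],
                   rep(0L, 6))
  expect_true(all(v$weakly_reversible[v$model %in% c(1, 2, 3, 4, 6, 9)]))
})
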