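test_that("degree rules, acyclicity and reachability are validated", {
  t <- random_binary_tree(5, seed = 1)
  expect_length(validate_network(t), 0)

  # (2, 2) node is rejected
  bad <- phylo_net(rbind(c("r", "a"), c("r", "x"), c("a", "x"),
                         c("x", "b"), c("x", "c"), c("a", "d")))
  expect_true(any(grepl("\\(2, 2\\)", validate_network(bad))))

  cyc <- phylo_net(rbind(c("r", "a"), c("r", "b"), c("a", "b"), c("b", "a")))
  expect_true(any(grepl("cycle", validate_network(cyc))))

  multi_root <- phylo_net(rbind(c("r", "a"), c("s", "a")))
  expect_true(any(grepl("indegree-0", validate_network(multi_root))))
})

test_that("reticulation count and level follow the biconnected structure", {
  t <- random_binary_tree(6, seed = 2)
  expect_equal(reticulation_count(t), 0)
  expect_equal(network_level(t), 0)

  N1 <- from_enewick("((a,(b)#H1),(#H1,c));")
  expect_equal(reticulation_count(N1), 1)
  expect_equal(network_level(N1), 1)

  # two independent single-reticulation blobs: 2 reticulations, level 1
  N2 <- from_enewick("(((a,(b)#H1),(#H1,c)),((d,(e)#H2),(#H2,f)));")
  expect_equal(reticulation_count(N2), 2)
  expect_equal(network_level(N2), 1)

  expect_error(network_level(phylo_net(rbind(c("r", "a"), c("s", "a")))),
               "invalid")
})

test_that("network heights minimize over lowest common ancestors", {
  # tree case: identical to the tree height function
  t <- random_binary_tree(6, seed = 3)
  expect_equal(network_height_function(t), tree_height_function(t))

  # a network and a tree sharing the same height function
  cat4 <- from_enewick("(((j,k),i),l);")
  ht <- tree_height_function(cat4)
  N <- network_from_height(ht, c("i", "j", "k", "l"), normalize = FALSE)
  hn <- network_height_function(N)
  expect_equal(hn$height, ht$height + 1L)

  # the counterexample network: consistent triplet without strict inequality
  w <- fix_height_counterexample()
  hv <- setNames(network_height_function(w$network)$height,
                 paste0(network_height_function(w$network)$taxon1,
                        network_height_function(w$network)$taxon2))
  expect_equal(unname(hv[c("ij", "ik", "jk")]), c(3, 3, 2))
  expect_true(triplet_consistent(w$network, w$triplet, use_heights = FALSE))
})

test_that("exact consistency agrees with the brute-force oracle", {
  for (s in 1:12) {
    N <- random_network(4, s %% 3, seed = s)
    labs <- network_leaves(N)
    trio <- t(utils::combn(labs, 3))
    for (r in seq_len(nrow(trio))) {
      for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 3, 1))) {
        tr <- triplets(trio[r, p[1]], trio[r, p[2]], trio[r, p[3]])
        expect_equal(
          triplet_consistent(N, tr, use_heights = FALSE),
          oracle_consistent(N, tr$cherry1, tr$cherry2, tr$outgroup),
          info = sprintf("seed %d triplet %s%s|%s", s, trio[r, p[1]],
                         trio[r, p[2]], trio[r, p[3]]))
        expect_equal(triplet_consistent(N, tr),
                     triplet_consistent(N, tr, use_heights = FALSE))
      }
    }
  }
})

test_that("missing labels raise errors", {
  t3 <- from_enewick("((i,j),k);")
  expect_error(triplet_consistent(t3, triplets("i", "j", "z")), "z")
})

test_that("consistent sets of binary trees are dense and BUILD-recoverable", {
  for (s in 1:4) {
    t <- random_binary_tree(5 + s %% 3, seed = s)
    ts <- consistent_triplet_set(t)
    expect_true(is_dense(ts))
    # exactly one triplet per 3-subset
    expect_equal(nrow(ts), choose(length(network_leaves(t)), 3))
    tb <- build_tree(ts)
    expect_true(identical(tree_clusters(tb, proper = FALSE),
                          tree_clusters(t, proper = FALSE)))
  }
  # the 5-taxon worked tree displays its defining triplets
  t5 <- build_tree(fix_tree5())
  full <- consistent_triplet_set(t5)
  keys <- paste(full$cherry1, full$cherry2, full$outgroup)
  expect_true(all(paste(fix_tree5()$cherry1, fix_tree5()$cherry2,
                        fix_tree5()$outgroup) %in% keys))
})

test_that("level never exceeds the reticulation count", {
  for (s in 1:8) {
    N <- random_network(5, s %% 4, seed = s + 20)
    expect_lte(network_level(N), reticulation_count(N))
  }
})

test_that("the height-raising construction normalizes to a valid network", {
  # constant heights: all pairs meet at the root
  hc <- tibble::tibble(taxon1 = c("a", "a", "b"), taxon2 = c("b", "c", "c"),
                       height = c(1L, 1L, 1L))
  N <- network_from_height(hc, c("a", "b", "c"))
  expect_length(validate_network(N), 0)

  # two taxa: a cherry
  h2 <- tibble::tibble(taxon1 = "a", taxon2 = "b", height = 1L)
  expect_equal(to_enewick(network_from_height(h2, c("a", "b"))), "(a,b);")

  # consistency of the raw construction is preserved by normalization
  for (s in 1:3) {
    t <- random_binary_tree(4, seed = s)
    h <- tree_height_function(t)
    raw <- network_from_height(h, network_leaves(t), normalize = FALSE)
    norm <- network_from_height(h, network_leaves(t))
    expect_length(validate_network(norm), 0)
    full <- consistent_triplet_set(raw)
    expect_true(all(triplet_consistent(norm, full)))
  }
})

test_that("eNewick and edge-list serializations round-trip", {
  t <- random_binary_tree(4, seed = 5)
  expect_false(grepl("#", to_enewick(t))) # plain Newick for trees
  expect_true(network_isomorphic(t, from_enewick(to_enewick(t))))

  N1 <- random_network(4, 1, seed = 6)
  txt <- to_enewick(N1)
  expect_equal(lengths(regmatches(txt, gregexpr("#H1", txt))), 2)

  for (s in 1:8) {
    N <- random_network(5, s %% 4, seed = s + 40)
    expect_true(network_isomorphic(N, from_enewick(to_enewick(N))))
    f <- withr::local_tempfile()
    write_edgelist(N, f)
    expect_true(network_isomorphic(N, read_edgelist(f)))
  }
})
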