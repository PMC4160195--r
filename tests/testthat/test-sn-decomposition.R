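test_that("the SN predicate reads ij|k literally", {
  ts <- fix_net15()
  expect_true(is_sn_set(c("n", "o"), ts))
  expect_true(is_sn_set("q", ts)) # singletons are vacuously SN
  # lo|k has l inside, o outside, outgroup k inside
  expect_false(is_sn_set(c("k", "l"), ts))
})

test_that("maximum-weight edge classes are removed whole", {
  e <- tibble::tibble(taxon1 = c("a", "a", "b"), taxon2 = c("b", "c", "c"),
                      weight = c(1, 1, 2))
  out <- remove_max_weight_edges(e)
  expect_equal(out$removed_weight, 2)
  expect_equal(nrow(out$edges), 2)

  all_eq <- tibble::tibble(taxon1 = c("a", "a"), taxon2 = c("b", "c"),
                           weight = c(3, 3))
  expect_equal(nrow(remove_max_weight_edges(all_eq)$edges), 0)

  expect_error(remove_max_weight_edges(e[0, ]), "no edges")
})

test_that("the worked 15-triplet example decomposes into the printed SN-sets", {
  ts <- fix_net15()
  h <- height_from_digraph(feedback_arc_removal(build_triplet_digraph(ts)))
  part <- sn_decompose(h, ts, leaf_set(ts))
  expect_equal(lapply(part, paste, collapse = ""),
               list("i", "j", "k", "l", "m", "no"))
})

test_that("tree-consistent sets decompose into the root split of BUILD", {
  for (s in 1:4) {
    t <- random_binary_tree(6, seed = s)
    ts <- triplets_from(t, 1, seed = s)
    h <- height_from_digraph(build_triplet_digraph(ts))
    part <- sn_decompose(h, ts, leaf_set(ts))
    # BUILD's top-level Aho components
    g <- aho_graph(ts)
    ig <- igraph::graph_from_data_frame(
      as.data.frame(g$edges, stringsAsFactors = FALSE), directed = FALSE,
      vertices = data.frame(name = g$vertices, stringsAsFactors = FALSE))
    comp <- igraph::components(ig)
    aho <- unname(split(sort(names(comp$membership)),
                        comp$membership[order(names(comp$membership))]))
    key <- function(p) sort(vapply(p, paste, character(1), collapse = ","))
    expect_equal(key(part), key(aho))
  }
  # a 2-taxon graph splits into singletons
  w2 <- setNames(1L, tripnet:::pair_key("a", "b"))
  expect_equal(sn_decompose(w2, triplets(), c("a", "b")), list("a", "b"))
})

test_that("contraction builds the reduced weighted instance", {
  ts <- fix_net15()
  h <- height_from_digraph(feedback_arc_removal(build_triplet_digraph(ts)))
  part <- sn_decompose(h, ts, leaf_set(ts))
  inst <- contract(part, ts, h)
  expect_s3_class(inst, "sn_instance")
  expect_equal(inst$names, c("i", "j", "k", "l", "m", "n+o"))
  # w_S is the minimum height over cross pairs
  hv <- tripnet:::height_lookup(h)
  expect_equal(unname(inst$w[tripnet:::pair_key("m", "n+o")]),
               min(hv[tripnet:::pair_key(c("m", "m"), c("n", "o"))]))
  # triplets with cherry inside one block vanish
  expect_false(any(inst$tau$cherry1 == "n" | inst$tau$cherry2 == "o"))

  # all-singleton partition is an isomorphic copy
  singles <- lapply(leaf_set(ts), identity)
  inst2 <- contract(singles, ts, h)
  expect_equal(inst2$names, leaf_set(ts))
  expect_equal(nrow(inst2$tau), nrow(ts))

  # a block holding every taxon leaves no triplets
  inst3 <- contract(list(leaf_set(ts)), ts, h)
  expect_equal(nrow(inst3$tau), 0)
})

test_that("the three criteria reproduce the worked cascade", {
  ts <- fix_net15()
  h <- height_from_digraph(feedback_arc_removal(build_triplet_digraph(ts)))
  part <- sn_decompose(h, ts, leaf_set(ts))
  inst <- contract(part, ts, h)
  R1 <- criterion_I(inst)
  expect_equal(R1, c("k", "l"))
  R2 <- criterion_II(inst, R1)
  expect_equal(R2, c("k", "l"))
  R3 <- criterion_III(inst, R2)
  expect_equal(R3, "l")

  sel <- select_reticulation(inst, "slow")
  expect_equal(sel$candidates, "l")
  expect_equal(sel$R1, c("k", "l"))
  expect_equal(sel$R2, c("k", "l"))
  expect_equal(sel$R3, "l")
})

test_that("criteria short-circuit on singletons and respect speed modes", {
  ts <- fix_net15()
  h <- height_from_digraph(feedback_arc_removal(build_triplet_digraph(ts)))
  part <- sn_decompose(h, ts, leaf_set(ts))
  inst <- contract(part, ts, h)

  expect_equal(criterion_II(inst, "k"), "k")
  expect_equal(criterion_III(inst, "l"), "l")

  # fast mode with a fixed seed is reproducible
  a <- select_reticulation(inst, "fast", seed = 11)
  b <- select_reticulation(inst, "fast", seed = 11)
  expect_identical(a, b)
  expect_length(a$candidates, 1)
})

test_that("every decomposition block satisfies the SN predicate", {
  for (s in 1:6) {
    N <- random_network(6, 1 + s %% 2, seed = s + 10)
    ts <- triplets_from(N, 1, seed = s)
    g <- feedback_arc_removal(build_triplet_digraph(ts))
    h <- height_from_digraph(g)
    part <- sn_decompose(h, ts, leaf_set(ts))
    expect_true(all(vapply(part, is_sn_set, logical(1), ts = ts)))
    expect_setequal(unlist(part), leaf_set(ts))
  }
})

test_that("contracted instances re-decompose into singleton blocks", {
  # the worked instance
  ts <- fix_net15()
  h <- height_from_digraph(feedback_arc_removal(build_triplet_digraph(ts)))
  part <- sn_decompose(h, ts, leaf_set(ts))
  inst <- contract(part, ts, h)
  part2 <- sn_decompose(inst$w, inst$tau, inst$names)
  expect_true(all(lengths(part2) == 1))

  # and random pipeline-produced instances
  for (s in 1:5) {
    N <- random_network(6, 1, seed = s + 30)
    ts <- triplets_from(N, 1, seed = s)
    fit <- tripnet(ts, speed = "fast", seed = s)
    for (rec in fit$log$instances) {
      p <- sn_decompose(rec$w, rec$tau, rec$names)
      expect_true(all(lengths(p) == 1))
    }
  }
})
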