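toy_net <- function(...) metabolic_network("toy", list(...))

test_that("scope computes hand-derived closures", {
  # empty network: fixed point immediately
  empty <- metabolic_network("empty", list())
  res <- scope(empty, seed_set(c("A", "B")))
  expect_setequal(res$producible, c("A", "B"))
  expect_equal(res$iterations, 0L)

  # linear chain A -> B -> C from seed A, two iterations
  chain <- toy_net(reaction("R1", c(A = 1), c(B = 1)),
                   reaction("R2", c(B = 1), c(C = 1)))
  res2 <- scope(chain, seed_set("A"))
  expect_setequal(res2$producible, c("A", "B", "C"))
  expect_equal(res2$iterations, 2L)
  expect_equal(unname(res2$first_iteration[c("A", "B", "C")]), c(0L, 1L, 2L))

  # reversible A + B <-> C fired backward from seed C
  rev <- toy_net(reaction("R1", c(A = 1, B = 1), c(C = 1), reversible = TRUE))
  res3 <- scope(rev, seed_set("C"))
  expect_setequal(res3$producible, c("A", "B", "C"))
  expect_identical(res3$fired_reactions$direction[1], "backward")

  # a missing terminal reaction keeps the end product out of scope
  truncated <- toy_net(reaction("R1", c(A = 1), c(B = 1)))
  expect_false("C" %in% scope(truncated, seed_set("A"))$producible)
})

test_that("scope is a monotone, order-independent closure", {
  for (sd in 1:15) {
    net <- random_toy_network(sample(5:30, 1), seed = sd)
    seeds <- seed_set(sample(net$metabolites$id, 3))
    res <- scope(net, seeds)
    # seeds contained; re-running from the result adds nothing
    expect_true(all(as.character(seeds) %in% res$producible))
    again <- scope(net, seed_set(res$producible))
    expect_identical(again$producible, res$producible)
    # adding a seed never shrinks the producible set
    extra <- seed_set(c(as.character(seeds),
                        sample(net$metabolites$id, 1)))
    expect_true(all(res$producible %in% scope(net, extra)$producible))
    # shuffling the reaction order leaves the result unchanged
    shuffled <- metabolic_network(net$organism_id,
                                  unname(net$reactions[sample(length(net$reactions))]))
    expect_identical(scope(shuffled, seeds)$producible, res$producible)
  }
})

test_that("community scope has mixed-bag semantics and is monotone in members", {
  b1 <- metabolic_network("b1", list(reaction("R1", c(A = 1), c(B = 1))))
  b2 <- metabolic_network("b2", list(reaction("R2", c(B = 1), c(C = 1))))
  expect_identical(community_scope(list(b1), seed_set("A"))$producible,
                   scope(b1, seed_set("A"))$producible)
  # neither bin alone produces C; the community does
  expect_false("C" %in% scope(b2, seed_set("A"))$producible)
  expect_true("C" %in% community_scope(list(b1, b2), seed_set("A"))$producible)

  # adding a member never shrinks the community scope
  for (sd in 1:8) {
    nets <- lapply(1:4, function(i) {
      n <- random_toy_network(sample(4:12, 1), seed = sd * 10 + i)
      metabolic_network(paste0("b", i), unname(n$reactions))
    })
    seeds <- seed_set(c("m1", "m2"))
    smaller <- community_scope(nets[1:2], seeds)$producible
    larger <- community_scope(nets[1:3], seeds)$producible
    expect_true(all(smaller %in% larger))
  }
})

test_that("added value captures precursor-dependency motifs", {
  host <- metabolic_network("host", list(
    reaction("HOST-VK", c(P = 1), c(VK = 1))))
  bacterium <- metabolic_network("b1", list(
    reaction("B1", c(GLC = 1), c(P = 1))))
  av <- added_value(host, list(bacterium), seed_set("GLC"))
  expect_true("VK" %in% av$added_value)
  expect_false("VK" %in% av$host_alone)
  expect_true(all(av$host_alone %in% av$host_with_community))
  expect_length(intersect(av$added_value, av$host_alone), 0L)
  # empty community: no added value
  av0 <- added_value(host, list(), seed_set("GLC"))
  expect_length(av0$added_value, 0L)
})

test_that("added value agrees with the naive oracle on random holobionts", {
  for (sd in 1:10) {
    host <- random_toy_network(sample(5:15, 1), seed = 1000 + sd)
    comm <- lapply(1:3, function(i) {
      n <- random_toy_network(sample(4:10, 1), seed = 2000 + sd * 5 + i)
      metabolic_network(paste0("c", i), unname(n$reactions))
    })
    seeds <- seed_set(c("m1", "m2", "m3"))
    av <- added_value(host, comm, seeds)
    # oracle: naive repeated-pass closures composed by the same definition
    host_alone <- oracle_scope(host, seeds)
    comm_prod <- oracle_scope(merge_networks(comm), seeds)
    host_with <- oracle_scope(host, union(as.character(seeds), comm_prod))
    expect_identical(av$host_alone, host_alone)
    expect_identical(av$community_producible, comm_prod)
    expect_identical(av$added_value, sort(setdiff(host_with, host_alone)))
  }
})

test_that("intersection tables partition the union upset-style", {
  r <- compare_producibility(list(c1 = c("A", "B"), c2 = c("B", "C")))
  expect_equal(sum(r$count), 3L)  # |union|
  both <- r[r$c1 & r$c2, ]
  expect_equal(both$count, 1L)
  expect_identical(both$members, "B")
  expect_equal(r$count[r$c1 & !r$c2], 1L)
  expect_equal(r$count[!r$c1 & r$c2], 1L)
  expect_equal(attr(r, "totals"), c(c1 = 2L, c2 = 2L))

  ident <- compare_producibility(list(a = letters[1:5], b = letters[1:5]))
  expect_identical(nrow(ident), 1L)
  expect_equal(ident$count, 5L)

  # pattern counts always partition the union
  set.seed(8)
  sets <- lapply(1:4, function(i) sample(letters, sample(5:15, 1)))
  names(sets) <- paste0("s", 1:4)
  rr <- compare_producibility(sets)
  expect_equal(sum(rr$count), length(unique(unlist(sets))))
  expect_error(compare_producibility(list(a = "x")),
               class = "holoscope_validation_error")
})
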