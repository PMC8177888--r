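test_that("upstream partners use inclusive per-pair thresholds, no pooling", {
  n <- make_neurons(c("x", "t1", "t2"), c("interneuron", "rpn", "rpn"))
  at_boundary <- connectome(n, make_edges("x", "t1", 3))
  expect_equal(upstream_partners(at_boundary, c("t1", "t2")), "x")

  split_across <- connectome(n, make_edges(c("x", "x"), c("t1", "t2"),
                                           c(2, 2)))
  expect_equal(upstream_partners(split_across, c("t1", "t2")),
               character())
  expect_equal(upstream_partners(split_across, c("t1", "t2"), threshold = 1),
               "x")
  expect_error(upstream_partners(split_across, character()),
               "may not be empty")
})

test_that("interneuron partition boundary sits at the threshold", {
  n <- make_neurons(c("s1", "i1", "i2"),
                    c("sensory", "interneuron", "interneuron"),
                    origins = c("enteric", NA, NA))
  x <- connectome(n, make_edges(c("s1", "s1"), c("i1", "i2"), c(2, 1)))
  p <- classify_interneurons(x, c("i1", "i2"), "s1")
  expect_equal(p$with_sensory, "i1")
  expect_equal(p$without_sensory, "i2")
  expect_error(classify_interneurons(x, c("i1", "s1"), "s1"), "disjoint")
})

test_that("thresholded operations match exhaustive brute-force scans", {
  for (seed in 1:8) {
    withr::local_seed(seed)
    x <- random_connectome()
    sens <- neuron_ids(x, "sensory")
    inter <- neuron_ids(x, "interneuron")
    rpns <- neuron_ids(x, "rpn")
    expect_identical(upstream_partners(x, rpns, 3), brute_upstream(x, rpns, 3))
    expect_identical(classify_interneurons(x, inter, sens, 2),
                     brute_classify(x, inter, sens, 2))
    expect_same_paths(enumerate_paths(x, sens, inter, rpns),
                      brute_paths(x, sens, inter, rpns))
  }
})

test_that("sensory profiles follow the two normalisation bases", {
  n <- rbind(make_neurons(c("e1", "p1"), c("sensory", "sensory"),
                          origins = c("enteric", "pharyngeal")),
             make_neurons(c("i0", "subj"), c("interneuron", "interneuron")))
  x <- connectome(n, make_edges(c("e1", "p1", "i0"), rep("subj", 3),
                                c(30, 10, 60)))
  wa <- input_fractions(x)
  total <- sensory_profile(wa, x$neurons, "subj", "of_total_input")
  expect_equal(total$fractions[["enteric"]], 0.30)
  expect_equal(total$fractions[["pharyngeal"]], 0.10)
  sens_only <- sensory_profile(wa, x$neurons, "subj", "of_sensory_input")
  expect_equal(sens_only$fractions[["enteric"]], 0.75)
  expect_equal(sens_only$fractions[["pharyngeal"]], 0.25)
  expect_equal(sum(sens_only$fractions), 1)

  # no sensory input -> empty of_sensory_input profile
  only_inter <- connectome(n, make_edges("i0", "subj", 60))
  pr <- sensory_profile(input_fractions(only_inter), n, "subj",
                        "of_sensory_input")
  expect_length(pr$fractions, 0)
  # zero input -> warning flag
  expect_warning(pr0 <- sensory_profile(wa, x$neurons, "i0"), "zero input")
  expect_true(pr0$zero_input)
})

test_that("group profiles equal the profile of pooled input counts", {
  for (seed in 1:5) {
    withr::local_seed(seed)
    x <- random_connectome()
    wa <- input_fractions(x)
    members <- neuron_ids(x, "rpn")[1:3]
    got <- sensory_profile(wa, x$neurons, members, "of_total_input")

    # oracle: add a pooled pseudo-neuron receiving copies of every edge that
    # targets a member (including edges from fellow members)
    pooled_id <- "POOLED"
    n2 <- rbind(x$neurons, make_neurons(pooled_id, "rpn"))
    incoming <- x$edges[x$edges$post %in% members, , drop = FALSE]
    incoming$post <- pooled_id
    y <- suppressMessages(connectome(n2, rbind(x$edges, incoming)))
    want <- sensory_profile(input_fractions(y), y$neurons, pooled_id,
                            "of_total_input", label = got$subject)
    expect_equal(got$fractions, want$fractions)
  }
})

test_that("path enumeration respects per-hop thresholds on a chain", {
  x <- chain_connectome(s_count = 5, i_count = 4)
  sens <- "s"; inter <- "i"; rpns <- "r"
  paths <- enumerate_paths(x, sens, inter, rpns)
  expect_equal(nrow(paths), 1L)
  expect_equal(paths$hop1_count, 5L)
  expect_equal(paths$hop2_count, 4L)
  expect_equal(paths$origin, "CO2")

  weak_first_hop <- chain_connectome(s_count = 1, i_count = 10)
  expect_equal(nrow(enumerate_paths(weak_first_hop, sens, inter, rpns)), 0L)
})

test_that("raising any threshold never adds paths", {
  withr::local_seed(42)
  for (rep in 1:5) {
    x <- random_connectome(density = 0.25)
    sens <- neuron_ids(x, "sensory")
    inter <- neuron_ids(x, "interneuron")
    rpns <- neuron_ids(x, "rpn")
    base <- enumerate_paths(x, sens, inter, rpns, 2, 1, 2)
    key <- function(p) paste(p$sensory_id, p$interneuron_id, p$rpn_id)
    for (bump in list(c(3, 1, 2), c(2, 2, 2), c(2, 1, 3))) {
      tighter <- enumerate_paths(x, sens, inter, rpns,
                                 bump[1], bump[2], bump[3])
      expect_true(all(key(tighter) %in% key(base)))
    }
  }
})

test_that("path enumeration is invariant under neuron relabeling", {
  withr::local_seed(7)
  x <- random_connectome()
  relabel <- setNames(paste0("z", rev(x$neurons$id)), x$neurons$id)
  n2 <- x$neurons
  n2$id <- unname(relabel[n2$id])
  n2$name <- n2$id
  e2 <- x$edges
  e2$pre <- unname(relabel[e2$pre])
  e2$post <- unname(relabel[e2$post])
  y <- suppressMessages(connectome(n2, e2))

  args <- function(c_) list(c_, neuron_ids(c_, "sensory"),
                            neuron_ids(c_, "interneuron"),
                            neuron_ids(c_, "rpn"))
  p1 <- do.call(enumerate_paths, args(x))
  p2 <- do.call(enumerate_paths, args(y))
  canon <- function(p, map = identity) {
    k <- paste(map(p$sensory_id),
               ifelse(is.na(p$interneuron_id), "-", map(p$interneuron_id)),
               map(p$rpn_id), p$hop1_count, p$hop2_count)
    sort(k)
  }
  expect_identical(canon(p1, function(i) unname(relabel[i])), canon(p2))
})

test_that("2-hop interneurons are upstream partners of their RPN", {
  withr::local_seed(13)
  x <- random_connectome(density = 0.25)
  sens <- neuron_ids(x, "sensory")
  inter <- neuron_ids(x, "interneuron")
  rpns <- neuron_ids(x, "rpn")
  paths <- enumerate_paths(x, sens, inter, rpns)
  di <- paths[!is.na(paths$interneuron_id), , drop = FALSE]
  for (r in unique(di$rpn_id)) {
    expect_true(all(di$interneuron_id[di$rpn_id == r] %in%
                      upstream_partners(x, r, threshold = 3)))
  }
})

test_that("hive edge table equals the thresholded subnetwork edge list", {
  n <- make_neurons(c("a", "b", "c"), rep("other", 3))
  x <- connectome(n, make_edges(c("a", "b", "c"), c("b", "c", "a"),
                                c(4, 5, 6)))
  h <- hive_edge_table(x, 5)
  expect_setequal(h$count, c(5L, 6L))
  expect_identical(h, subnetwork(x, min_count = 5)$edges)

  empty <- connectome(n, NULL)
  expect_equal(nrow(hive_edge_table(empty)), 0L)

  withr::local_seed(3)
  y <- random_connectome()
  expect_identical(hive_edge_table(y, 5), subnetwork(y, min_count = 5)$edges)
})
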