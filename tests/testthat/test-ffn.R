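test_that("ramp activation follows the onset/saturation form", {
  p <- ffn_params()
  expect_equal(ffn_activation(0.03, p), 0)
  expect_equal(ffn_activation(0.6, p), 1)
  expect_equal(ffn_activation(0.275, p), 0.5) # midpoint of [0.05, 0.5]
  # continuity at both knots
  eps <- 1e-13
  expect_lt(abs(ffn_activation(0.05 + eps, p) - ffn_activation(0.05, p)),
            1e-12)
  expect_lt(abs(ffn_activation(0.5 - eps, p) - ffn_activation(0.5, p)),
            1e-12)
  expect_equal(ffn_activation(0.05, p), 0)
  expect_equal(ffn_activation(0.5, p), 1)
  expect_error(ffn_activation(-0.1, p), "nonnegative")
  expect_error(ffn_params(a = 0.5, b = 0.5), "a < b")
})

test_that("layering keeps only feed-forward edges", {
  # chain s -> i -> r: three layers, one forward edge each
  n <- rbind(make_neurons("s", "sensory", origins = "CO2"),
             make_neurons(c("i", "i2"), rep("interneuron", 2)),
             make_neurons("r", "rpn", clusters = "CRZ"))
  x <- connectome(n, make_edges(c("s", "i"), c("i", "r"), c(5, 5)))
  ffn <- build_ffn(x, input_fractions(x), "s", "r")
  expect_equal(ffn$layers$sensory, "s")
  expect_equal(ffn$layers$hop1, "i")
  expect_equal(ffn$layers$hop2, "r")
  expect_equal(nrow(ffn$forward_edges), 2L)

  # intra-layer interneuron edge is dropped and reported
  y <- connectome(n, make_edges(c("s", "s", "i", "i2"),
                                c("i", "i2", "i2", "r"), c(5, 5, 7, 5)))
  expect_message(ffn2 <- build_ffn(y, input_fractions(y), "s", "r"),
                 "dropped 1 non-feed-forward")
  expect_false(any(ffn2$forward_edges$pre == "i" &
                     ffn2$forward_edges$post == "i2"))
  expect_equal(ffn2$dropped_edges$pre, "i")

  # direct s -> r edge keeps r as a layer-1 target (monosynaptic route)
  z <- connectome(n, make_edges(c("s", "s", "i"), c("i", "r", "r"),
                                c(5, 3, 5)))
  ffn3 <- build_ffn(z, input_fractions(z), "s", "r")
  expect_true("r" %in% ffn3$layers$hop1)
  expect_length(ffn3$layers$hop2, 0)
  mono <- enumerate_paths(z, "s", "i", "r")
  expect_true("r" %in% mono$rpn_id[is.na(mono$interneuron_id)])
  # ... and both path lengths reach r: sensory and interneuron edges retained
  expect_setequal(ffn3$forward_edges$pre[ffn3$forward_edges$post == "r"],
                  c("s", "i"))

  edgeless <- connectome(n, make_edges("i", "r", 5))
  expect_error(build_ffn(edgeless, input_fractions(edgeless), "s", "r"),
               "empty network")
})

test_that("propagation computes the hand-derived ramp values", {
  # s (factor 2) -> i with weight 0.1: x = 0.2, f = (0.2-0.05)/0.45 = 1/3
  x <- chain_connectome(s_count = 5, other_i = 45, i_count = 5, other_r = 5)
  wa <- input_fractions(x)
  ffn <- build_ffn(x, wa, "s", "r")
  st <- ffn_propagate(ffn, "CO2")
  expect_equal(unname(activity_of(st, "s")), 2)
  expect_equal(unname(activity_of(st, "i")), 1 / 3)
  expect_error(ffn_propagate(ffn, "olfactory"), "unknown sensory origin")

  # two saturating sources: x = 2 * 0.5 * 2 = 2 >= b -> activity 1
  n <- rbind(make_neurons(c("s1", "s2"), rep("sensory", 2),
                          origins = c("CO2", "CO2")),
             make_neurons("i", "interneuron"))
  sat <- connectome(n, make_edges(c("s1", "s2"), c("i", "i"), c(10, 10)))
  st2 <- ffn_propagate(build_ffn(sat, input_fractions(sat),
                                 c("s1", "s2"), character()), "CO2")
  expect_equal(unname(activity_of(st2, "i")), 1)
})

test_that("chain activity matches the closed form f(w2 * f(2 w1))", {
  p <- ffn_params()
  f <- function(v) ffn_activation(v, p)
  for (seed in 1:10) {
    withr::local_seed(seed)
    s_count <- sample.int(20, 1)
    other_i <- sample.int(60, 1)
    i_count <- sample.int(20, 1)
    other_r <- sample.int(60, 1)
    x <- chain_connectome(s_count, other_i, i_count, other_r)
    w1 <- s_count / (s_count + other_i)
    w2 <- i_count / (i_count + other_r)
    ffn <- build_ffn(x, input_fractions(x), "s", "r")
    st <- ffn_propagate(ffn, "CO2")
    expect_equal(unname(activity_of(st, "r")), f(w2 * f(2 * w1)),
                 tolerance = 1e-12)
  }
})

test_that("non-sensory activities are bounded and monotone in drive", {
  for (seed in 1:6) {
    withr::local_seed(seed)
    x <- random_connectome(density = 0.2)
    sens <- neuron_ids(x, "sensory")
    rpns <- neuron_ids(x, "rpn")
    wa <- input_fractions(x)
    ffn <- suppressMessages(build_ffn(x, wa, sens, rpns))
    org <- x$neurons$sensory_origin[x$neurons$cell_class == "sensory"][1]
    st <- ffn_propagate(ffn, org)
    non_sens <- st$activities[st$activities$layer > 0, ]
    expect_true(all(non_sens$activity >= 0 & non_sens$activity <= 1))

    # raising the activation factor never decreases any activity
    st_hi <- ffn_propagate(ffn, org, ffn_params(activation_factor = 3))
    expect_true(all(st_hi$activities$activity[st_hi$activities$layer > 0] >=
                      non_sens$activity - 1e-12))

    # increasing one incoming weight never decreases downstream activity
    ffn_boost <- ffn
    k <- which.max(ffn_boost$forward_edges$weight < 1)
    ffn_boost$forward_edges$weight[k] <-
      min(1, ffn_boost$forward_edges$weight[k] * 1.5)
    st_boost <- ffn_propagate(ffn_boost, org)
    expect_true(all(st_boost$activities$activity[st_boost$activities$layer > 0]
                    >= non_sens$activity - 1e-12))
  }
})

test_that("joint activation dominates either origin alone (superposition)", {
  withr::local_seed(21)
  x <- random_connectome(density = 0.2)
  sens <- neuron_ids(x, "sensory")
  rpns <- neuron_ids(x, "rpn")
  ffn <- suppressMessages(build_ffn(x, input_fractions(x), sens, rpns))
  orgs <- unique(x$neurons$sensory_origin[x$neurons$cell_class == "sensory"])
  o1 <- orgs[1]; o2 <- orgs[2]
  # joint activation: relabel both origins to one shared label
  x2 <- x
  x2$neurons$sensory_origin[x2$neurons$sensory_origin %in% c(o1, o2)] <- "joint"
  ffn_joint <- suppressMessages(build_ffn(x2, input_fractions(x2), sens, rpns))
  a_joint <- ffn_propagate(ffn_joint, "joint")$activities
  for (o in c(o1, o2)) {
    a_single <- ffn_propagate(ffn, o)$activities
    both <- merge(a_joint[a_joint$layer > 0, c("id", "activity")],
                  a_single[a_single$layer > 0, c("id", "activity")],
                  by = "id")
    expect_true(all(both$activity.x >= both$activity.y - 1e-12))
  }
})

test_that("group means average members, counting absentees as silent", {
  x <- chain_connectome(s_count = 9, other_i = 31, i_count = 5, other_r = 5)
  ffn <- build_ffn(x, input_fractions(x), "s", "r")
  st <- ffn_propagate(ffn, "CO2")
  r_act <- unname(activity_of(st, "r"))
  ga <- mean_group_activity(st, list(CRZ = c("r", "ghost")))
  expect_equal(ga$mean_activity, r_act / 2)
  single <- mean_group_activity(st, list(CRZ = "r"))
  expect_equal(single$mean_activity, r_act)
  expect_error(mean_group_activity(st, list(CRZ = character())),
               "empty group")
})

test_that("factor sweep is monotone and hits both limits", {
  x <- chain_connectome(s_count = 5, other_i = 45, i_count = 5, other_r = 5)
  ffn <- build_ffn(x, input_fractions(x), "s", "r")
  groups <- list(CRZ = "r", INT = "i")
  sw <- ffn_sweep(ffn, "CO2", factors = c(0, 1, 2, 4, 8, 64), groups)
  for (g in names(groups)) {
    m <- sw$mean_activity[sw$group == g]
    expect_true(all(diff(m) >= -1e-12))
  }
  # zero-factor limit: everything silent
  expect_true(all(sw$mean_activity[sw$factor == 0] == 0))
  # factor large enough saturates every sensory-reachable neuron
  expect_equal(sw$mean_activity[sw$factor == 64 & sw$group == "INT"], 1)
})
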