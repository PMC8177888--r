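# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (triple loops, per-edge scans) and never call the
# package functions they are checking.

`%||%` <- function(a, b) if (is.null(a)) b else a

make_neurons <- function(ids, classes, origins = NULL, clusters = NULL) {
  data.frame(id = ids, name = ids, cell_class = classes,
             cluster = if (is.null(clusters)) NA_character_ else clusters,
             sensory_origin = if (is.null(origins)) NA_character_ else origins,
             side = NA_character_, stringsAsFactors = FALSE)
}

make_edges <- function(pre, post, count) {
  data.frame(pre = pre, post = post, count = as.integer(count),
             stringsAsFactors = FALSE)
}

# Small three-layer chain: s -> i (w1 of i's input) -> r (w2 of r's input).
chain_connectome <- function(s_count = 5L, other_i = 45L,
                             i_count = 5L, other_r = 5L) {
  neurons <- rbind(
    make_neurons("s", "sensory", origins = "CO2"),
    make_neurons("bg", "other"),
    make_neurons("i", "interneuron"),
    make_neurons("r", "rpn", clusters = "CRZ"))
  edges <- make_edges(c("s", "bg", "i", "bg"),
                      c("i", "i", "r", "r"),
                      c(s_count, other_i, i_count, other_r))
  suppressMessages(connectome(neurons, edges))
}

# Random mixed-class connectome for oracle-equivalence tests.
random_connectome <- function(n_sens = 8L, n_inter = 14L, n_rpn = 8L,
                              density = 0.15, max_count = 12L) {
  origins <- c("enteric", "pharyngeal", "CO2", "somatosensory")
  ids <- c(sprintf("S%02d", seq_len(n_sens)),
           sprintf("I%02d", seq_len(n_inter)),
           sprintf("R%02d", seq_len(n_rpn)))
  classes <- rep(c("sensory", "interneuron", "rpn"),
                 c(n_sens, n_inter, n_rpn))
  neurons <- make_neurons(
    ids, classes,
    origins = ifelse(classes == "sensory",
                     sample(origins, length(ids), replace = TRUE),
                     NA_character_),
    clusters = ifelse(classes == "rpn",
                      sample(c("CRZ", "DH44", "IPCs"), length(ids),
                             replace = TRUE),
                      NA_character_))
  grid <- expand.grid(pre = ids, post = ids, stringsAsFactors = FALSE)
  grid <- grid[grid$pre != grid$post, ]
  grid <- grid[runif(nrow(grid)) < density, ]
  grid$count <- sample.int(max_count, nrow(grid), replace = TRUE)
  suppressMessages(connectome(neurons, grid))
}

edge_count <- function(x, pre, post) {
  hit <- x$edges$pre == pre & x$edges$post == post
  if (any(hit)) x$edges$count[hit] else 0L
}

# Oracle: upstream partners by exhaustive per-pair scan.
brute_upstream <- function(x, targets, threshold) {
  hits <- character()
  for (n in setdiff(x$neurons$id, targets)) {
    for (t in targets) {
      if (edge_count(x, n, t) >= threshold) hits <- c(hits, n)
    }
  }
  sort(unique(hits))
}

# Oracle: interneuron partition by exhaustive edge scan.
brute_classify <- function(x, interneurons, sensory, threshold) {
  with_s <- character()
  for (i in interneurons) {
    for (s in sensory) {
      if (edge_count(x, s, i) >= threshold) with_s <- c(with_s, i)
    }
  }
  with_s <- sort(unique(with_s))
  list(with_sensory = with_s,
       without_sensory = sort(setdiff(interneurons, with_s)))
}

# Oracle: 1-/2-hop path enumeration by triple loop.
brute_paths <- function(x, sensory, interneurons, rpns,
                        mono = 3L, s2i = 2L, i2r = 3L) {
  origin_of <- setNames(x$neurons$sensory_origin, x$neurons$id)
  rows <- list()
  for (s in sensory) {
    for (r in rpns) {
      c1 <- edge_count(x, s, r)
      if (c1 >= mono) {
        rows[[length(rows) + 1L]] <- data.frame(
          origin = unname(origin_of[s]), sensory_id = s,
          interneuron_id = NA_character_, rpn_id = r,
          hop1_count = c1, hop2_count = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    for (i in interneurons) {
      c1 <- edge_count(x, s, i)
      if (c1 < s2i) next
      for (r in rpns) {
        c2 <- edge_count(x, i, r)
        if (c2 >= i2r) {
          rows[[length(rows) + 1L]] <- data.frame(
            origin = unname(origin_of[s]), sensory_id = s,
            interneuron_id = i, rpn_id = r,
            hop1_count = c1, hop2_count = c2, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(origin = character(), sensory_id = character(),
               interneuron_id = character(), rpn_id = character(),
               hop1_count = integer(), hop2_count = integer(),
               stringsAsFactors = FALSE)
  }
  out[order(out$sensory_id,
            ifelse(is.na(out$interneuron_id), "", out$interneuron_id),
            out$rpn_id, method = "radix"), , drop = FALSE]
}

expect_same_paths <- function(got, want) {
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}

worked_wa <- function() {
  fx <- worked_example_fixture()
  input_fractions(fx$connectome, "declared_total", fx$declared_totals)
}
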