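#' Synthetic connectome generator configuration
#'
#' Describes the statistical structure of the larval sensory-to-
#' neuroendocrine network the analysis assumes: 56 ring gland projection
#' neurons (RPNs) in 10 peptidergic clusters, ~209 upstream interneurons, and
#' sensory neurons grouped by peripheral origin (26 tracheal dendritic
#' CO2-responsive neurons; the other origins are plausibility-level
#' defaults). Synapse counts per connection follow a right-skewed law:
#' 1 + Geometric, truncated at `count_max` (~150, the order of the strongest
#' observed connection, 147 synapses).
#'
#' @param rpn_census named integer vector, RPN cluster -> cell count.
#' @param n_interneurons number of interneurons.
#' @param sensory_census named integer vector, sensory origin -> cell count.
#' @param edge_density probability that an eligible sensory->interneuron or
#'   interneuron->RPN pair is connected. Sensory->RPN pairs connect at a
#'   quarter of this rate and interneuron->interneuron pairs at half of it
#'   (both sparse in the data).
#' @param count_mean mean of the synapse-count law (1 + Geometric with mean
#'   `count_mean`).
#' @param count_max truncation cap for synapse counts.
#' @param planted_motifs list of motifs (see [pathway_motif()]) planted after
#'   background generation.
#' @param seed integer seed; the same seed yields a byte-identical
#'   connectome. Background and motif stages use sub-streams derived from it,
#'   so adding a motif does not perturb background edges.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(rpn_census = c(DMS = 4L, IPCs = 14L, DH44 = 6L,
                                            CRZ = 6L, ITP = 8L, `CA-LP` = 6L,
                                            PTTH = 4L, HugRG = 4L, CAPA = 2L,
                                            EH = 2L),
                             n_interneurons = 209L,
                             sensory_census = c(enteric = 30L,
                                                pharyngeal = 30L,
                                                olfactory = 30L,
                                                somatosensory = 30L,
                                                CO2 = 26L,
                                                TO_VO = 30L),
                             edge_density = 0.02,
                             count_mean = 6,
                             count_max = 150L,
                             planted_motifs = list(),
                             seed = 1L) {
  if (is.null(names(rpn_census)) || any(rpn_census < 1) ||
      any(rpn_census != round(rpn_census))) {
    stop_validation("rpn_census must be a named vector of positive counts")
  }
  if (is.null(names(sensory_census)) || any(sensory_census < 1) ||
      any(sensory_census != round(sensory_census))) {
    stop_validation("sensory_census must be a named vector of positive counts")
  }
  assert_scalar_count(n_interneurons, "n_interneurons")
  if (!is.numeric(edge_density) || edge_density < 0 || edge_density > 1) {
    stop_validation("edge_density must be a probability in [0, 1]")
  }
  if (!is.numeric(count_mean) || count_mean < 1) {
    stop_validation("count_mean must be >= 1")
  }
  assert_scalar_count(count_max, "count_max")
  structure(list(rpn_census = rpn_census,
                 n_interneurons = as.integer(n_interneurons),
                 sensory_census = sensory_census,
                 edge_density = edge_density,
                 count_mean = count_mean,
                 count_max = as.integer(count_max),
                 planted_motifs = planted_motifs,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Define a plantable sensory-to-endocrine pathway motif
#'
#' A motif routes one sensory origin through a small core of interneurons
#' onto one or more RPN clusters with strong synapse counts, emulating e.g.
#' the CO2 pathway through thoracic interneurons to the DH44 and CRZ
#' clusters.
#'
#' @param origin sensory origin supplying the motif.
#' @param n_interneurons number of core interneurons (the motif recruits
#'   existing interneurons).
#' @param targets RPN cluster labels the core projects to (every member of
#'   each cluster receives a strong edge from every core interneuron).
#' @param count_range integer range for planted synapse counts.
#' @param n_sensory_inputs how many origin sensory neurons contact each core
#'   interneuron.
#' @return list of class `pathway_motif`.
#' @export
pathway_motif <- function(origin = "CO2", n_interneurons = 4L,
                          targets = c("DH44", "CRZ"),
                          count_range = c(60L, 150L),
                          n_sensory_inputs = 6L) {
  assert_scalar_count(n_interneurons, "n_interneurons")
  assert_scalar_count(n_sensory_inputs, "n_sensory_inputs")
  if (length(count_range) != 2L || any(count_range < 1) ||
      count_range[1] > count_range[2]) {
    stop_validation("count_range must be an increasing pair of counts >= 1")
  }
  structure(list(origin = origin,
                 n_interneurons = as.integer(n_interneurons),
                 targets = as.character(targets),
                 count_range = as.integer(count_range),
                 n_sensory_inputs = as.integer(n_sensory_inputs)),
            class = "pathway_motif")
}

sample_counts <- function(n, count_mean, count_max) {
  if (n == 0L) return(integer())
  pmin(1L + stats::rgeom(n, prob = 1 / count_mean), count_max)
}

# Bernoulli edge draw over the full pre x post grid, then counts.
draw_block <- function(pre_ids, post_ids, density, count_mean, count_max,
                       no_self = FALSE) {
  if (!length(pre_ids) || !length(post_ids) || density <= 0) {
    return(data.frame(pre = character(), post = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  grid <- expand.grid(pre = pre_ids, post = post_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (no_self) grid <- grid[grid$pre != grid$post, , drop = FALSE]
  keep <- stats::runif(nrow(grid)) < density
  grid <- grid[keep, , drop = FALSE]
  grid$count <- sample_counts(nrow(grid), count_mean, count_max)
  grid
}

#' Generate a synthetic connectome
#'
#' Draws a seeded random connectome with the configured censuses and edge
#' statistics: edges sensory->interneuron and interneuron->RPN at
#' `edge_density`, sparse sensory->RPN and interneuron->interneuron
#' background, synapse counts from the truncated shifted-geometric law, and
#' any configured pathway motifs planted on top (motif planting uses its own
#' derived random sub-stream, so the background is identical with and without
#' motifs). The caller's RNG state is left untouched.
#'
#' @param config generator_config.
#' @return connectome. Neuron ids are `sen_<origin>_<k>`, `int_<k>`,
#'   `rpn_<cluster>_<k>`.
#' @export
simulate_connectome <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  sens <- do.call(rbind, lapply(names(config$sensory_census), function(o) {
    k <- config$sensory_census[[o]]
    data.frame(id = sprintf("sen_%s_%02d", o, seq_len(k)),
               name = sprintf("%s sensory %d", o, seq_len(k)),
               cell_class = "sensory", cluster = NA_character_,
               sensory_origin = o,
               side = rep_len(c("left", "right"), k),
               stringsAsFactors = FALSE)
  }))
  inter <- data.frame(
    id = sprintf("int_%03d", seq_len(config$n_interneurons)),
    name = sprintf("interneuron %d", seq_len(config$n_interneurons)),
    cell_class = "interneuron", cluster = NA_character_,
    sensory_origin = NA_character_,
    side = rep_len(c("left", "right"), config$n_interneurons),
    stringsAsFactors = FALSE)
  rpn <- do.call(rbind, lapply(names(config$rpn_census), function(cl) {
    k <- config$rpn_census[[cl]]
    data.frame(id = sprintf("rpn_%s_%d", cl, seq_len(k)),
               name = sprintf("%s RPN %d", cl, seq_len(k)),
               cell_class = "rpn", cluster = cl,
               sensory_origin = NA_character_,
               side = rep_len(c("left", "right"), k),
               stringsAsFactors = FALSE)
  }))
  neurons <- rbind(sens, inter, rpn)

  d <- config$edge_density
  edges <- rbind(
    draw_block(sens$id, inter$id, d, config$count_mean, config$count_max),
    draw_block(inter$id, rpn$id, d, config$count_mean, config$count_max),
    draw_block(sens$id, rpn$id, d / 4, config$count_mean, config$count_max),
    draw_block(inter$id, inter$id, d / 2, config$count_mean,
               config$count_max, no_self = TRUE)
  )
  out <- suppressMessages(connectome(neurons, edges))
  for (i in seq_along(config$planted_motifs)) {
    out <- plant_pathway(out, config$planted_motifs[[i]],
                         seed = motif_seed(config$seed, i))
  }
  out
}

# Derived sub-stream seed for motif i, kept within 32-bit integer range.
motif_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Plant a strong sensory-to-endocrine pathway motif
#'
#' Adds (or boosts, by count aggregation) edges from `n_sensory_inputs`
#' origin sensory neurons onto each core interneuron, and from each core
#' interneuron onto every member of each target RPN cluster, with synapse
#' counts drawn uniformly from `count_range`. Original neurons are unchanged;
#' the motif recruits the lexicographically first interneurons so repeated
#' planting is stable.
#'
#' @param x connectome.
#' @param motif pathway_motif.
#' @param seed integer seed for the motif's random stream.
#' @return connectome with the motif edges aggregated in, carrying the core
#'   interneuron ids in `attr(, "motif_interneurons")`.
#' @export
plant_pathway <- function(x, motif, seed = 1L) {
  stopifnot(inherits(x, "connectome"), inherits(motif, "pathway_motif"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  sens <- neuron_ids(x, cell_class = "sensory", sensory_origin = motif$origin)
  if (!length(sens)) {
    stop_validation("no sensory neurons of origin '%s'", motif$origin)
  }
  inter <- sort(neuron_ids(x, cell_class = "interneuron"))
  if (length(inter) < motif$n_interneurons) {
    stop_validation("motif needs %d interneurons but connectome has %d",
                    motif$n_interneurons, length(inter))
  }
  core <- inter[seq_len(motif$n_interneurons)]
  missing_cl <- setdiff(motif$targets,
                        unique(stats::na.omit(x$neurons$cluster)))
  if (length(missing_cl)) {
    stop_validation("unknown target cluster(s): %s",
                    paste(missing_cl, collapse = ", "))
  }
  target_ids <- neuron_ids(x, cell_class = "rpn", cluster = motif$targets)

  rcount <- function(n) {
    as.integer(stats::runif(n, motif$count_range[1],
                            motif$count_range[2] + 1))
  }
  in_edges <- do.call(rbind, lapply(core, function(i) {
    src <- sens[sample.int(length(sens),
                           min(motif$n_sensory_inputs, length(sens)))]
    data.frame(pre = src, post = i, count = rcount(length(src)),
               stringsAsFactors = FALSE)
  }))
  out_edges <- expand.grid(pre = core, post = target_ids,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out_edges$count <- rcount(nrow(out_edges))

  planted <- suppressMessages(
    connectome(x$neurons, rbind(x$edges, in_edges, out_edges)))
  attr(planted, "motif_interneurons") <- core
  planted
}

#' Packaged worked-example fixture for the hub score
#'
#' A minimal connectome encoding the printed hub-score example exactly with
#' integer synapse counts and declared input totals of 10000: the Munin-2
#' analog interneuron receives 3233 of its 10000 total input synapses from
#' sensory neurons (fraction 0.3233), and the two-cell CRZ-analog group
#' receives 5652 of its pooled 10000 total input from that interneuron
#' (fraction 0.5652), so the top hub score is 0.3233 * 0.5652 = 0.18272916.
#'
#' @return list with elements `connectome` and `declared_totals` (named
#'   numeric, ready for [input_fractions()] under the `declared_total`
#'   policy).
#' @export
worked_example_fixture <- function() {
  neurons <- data.frame(
    id = c("sen_pharyngeal_01", "sen_pharyngeal_02", "int_munin2",
           "rpn_CRZ_1", "rpn_CRZ_2"),
    name = c("pharyngeal sensory 1", "pharyngeal sensory 2", "Munin 2",
             "CRZ RPN 1", "CRZ RPN 2"),
    cell_class = c("sensory", "sensory", "interneuron", "rpn", "rpn"),
    cluster = c(NA, NA, "Munin2", "CRZ", "CRZ"),
    sensory_origin = c("pharyngeal", "pharyngeal", NA, NA, NA),
    side = c("left", "right", "left", "left", "right"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    pre = c("sen_pharyngeal_01", "sen_pharyngeal_02", "int_munin2",
            "int_munin2"),
    post = c("int_munin2", "int_munin2", "rpn_CRZ_1", "rpn_CRZ_2"),
    count = c(2000L, 1233L, 2826L, 2826L),
    stringsAsFactors = FALSE)
  declared_totals <- c(int_munin2 = 10000, rpn_CRZ_1 = 5000, rpn_CRZ_2 = 5000)
  list(connectome = suppressMessages(connectome(neurons, edges)),
       declared_totals = declared_totals)
}
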