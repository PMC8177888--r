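#' Sensory-to-endocrine hub score
#'
#' The hub score of an interneuron with respect to an RPN output group is the
#' fraction of the interneuron's total synaptic input that comes from sensory
#' neurons, multiplied by the fraction of the group's total synaptic input
#' contributed by that interneuron. It ranks how much endocrine-bound sensory
#' flow is relayed through each interneuron; e.g. an interneuron with 32.33%
#' sensory input supplying 56.52% of the corazonin group's input scores
#' 0.3233 * 0.5652 = 0.18272916.
#'
#' @param frac_sensory_in fraction of the interneuron's total input from
#'   sensory neurons, in \[0, 1\].
#' @param frac_to_rpn fraction of the RPN group's total input from this
#'   interneuron, in \[0, 1\].
#' @return the exact product, full precision retained.
#' @export
hub_score <- function(frac_sensory_in, frac_to_rpn) {
  for (v in list(frac_sensory_in, frac_to_rpn)) {
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v > 1)) {
      stop_validation("hub score fractions must lie in [0, 1]")
    }
  }
  frac_sensory_in * frac_to_rpn
}

#' Hub-score table over interneurons and RPN groups
#'
#' For each interneuron, `frac_sensory_in` is the summed input-fraction
#' weight of its sensory presynaptic partners (under the denominator policy
#' of `wa`). For each RPN group, `frac_to_rpn` is the interneuron's synapse
#' count onto group members divided by the group's pooled total input (the
#' sum of member totals under the same policy); set `per_cell = TRUE` to
#' score against each RPN cell's own total instead of the pooled group total.
#' One record is emitted per (interneuron, group) pair with a nonzero
#' connection.
#'
#' @param x connectome.
#' @param wa weighted_adjacency built from `x`.
#' @param interneurons interneuron ids to score.
#' @param groups named list mapping RPN group label to member ids (e.g.
#'   [rpn_groups()]); non-empty.
#' @param sensory sensory neuron ids.
#' @param per_cell if `TRUE`, emit one record per (interneuron, RPN cell)
#'   with the cell id appended to the group label as `group/cell`.
#' @return data.frame `interneuron`, `rpn_group`, `frac_sensory_in`,
#'   `frac_to_rpn`, `score`, sorted by score descending, ties broken by
#'   (interneuron, rpn_group).
#' @export
hub_table <- function(x, wa, interneurons, groups, sensory,
                      per_cell = FALSE) {
  stopifnot(inherits(x, "connectome"), inherits(wa, "weighted_adjacency"))
  if (!length(groups) || is.null(names(groups))) {
    stop_validation("groups must be a non-empty named list")
  }
  interneurons <- as.character(interneurons)
  sensory <- as.character(sensory)
  w <- wa$weights
  sens_w <- w[w$pre %in% sensory & w$post %in% interneurons, , drop = FALSE]
  fsi <- stats::setNames(rep(0, length(interneurons)), interneurons)
  if (nrow(sens_w)) {
    # Sum integer counts before dividing by the neuron's total: numerically
    # exact when counts and totals are integers, unlike summing per-edge
    # weights.
    s <- tapply(sens_w$count, sens_w$post, sum)
    fsi[names(s)] <- as.numeric(s) / as.numeric(wa$totals[names(s)])
  }
  if (per_cell) {
    groups <- stats::setNames(
      unlist(lapply(names(groups), function(g) {
        stats::setNames(as.list(groups[[g]]),
                        paste(g, groups[[g]], sep = "/"))
      }), recursive = FALSE),
      unlist(lapply(names(groups), function(g) {
        paste(g, groups[[g]], sep = "/")
      })))
  }
  rows <- list()
  for (g in names(groups)) {
    members <- as.character(groups[[g]])
    covered <- intersect(members, names(wa$totals))
    group_total <- sum(wa$totals[covered])
    if (group_total == 0) next
    eg <- w[w$pre %in% interneurons & w$post %in% members, , drop = FALSE]
    if (!nrow(eg)) next
    counts <- tapply(eg$count, eg$pre, sum)
    ftr <- as.numeric(counts) / group_total
    inter <- names(counts)
    rows[[length(rows) + 1L]] <- data.frame(
      interneuron = inter,
      rpn_group = g,
      frac_sensory_in = unname(fsi[inter]),
      frac_to_rpn = ftr,
      score = hub_score(unname(fsi[inter]), ftr),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(interneuron = character(), rpn_group = character(),
               frac_sensory_in = numeric(), frac_to_rpn = numeric(),
               score = numeric(), stringsAsFactors = FALSE)
  }
  ord <- order(-out$score, out$interneuron, out$rpn_group, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

DCV_TISSUES <- c("CC_AO", "CA", "PG")

#' Dense-core-vesicle fusion-site fractions per target tissue
#'
#' Converts counts of membrane-fused dense core vesicles (DCVs, the
#' peptidergic release sites marked in the ring gland) into per-group
#' fractions over the ring gland tissues: corpora cardiaca plus aorta
#' (`CC_AO`), corpus allatum (`CA`) and prothoracic gland (`PG`). Fractions
#' within each RPN group sum to 1; groups with zero total are omitted with a
#' warning.
#'
#' @param records data.frame with columns `rpn_group`, `tissue` (one of
#'   `CC_AO`, `CA`, `PG`) and nonnegative integer `fused_count`. Repeated
#'   (group, tissue) rows are summed; record order never matters.
#' @return data.frame `rpn_group`, `tissue`, `fraction`, sorted by
#'   (rpn_group, tissue).
#' @export
dcv_fractions <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("rpn_group", "tissue", "fused_count") %in% names(records))) {
    stop_validation("records need columns rpn_group, tissue, fused_count")
  }
  bad_tissue <- setdiff(unique(records$tissue), DCV_TISSUES)
  if (length(bad_tissue)) {
    stop_validation("unknown tissue(s): %s (expected %s)",
                    paste(bad_tissue, collapse = ", "),
                    paste(DCV_TISSUES, collapse = ", "))
  }
  cnt <- suppressWarnings(as.numeric(records$fused_count))
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop_validation("fused_count must be nonnegative integers")
  }
  agg <- stats::aggregate(cnt,
                          by = list(rpn_group = as.character(records$rpn_group),
                                    tissue = as.character(records$tissue)),
                          FUN = sum)
  names(agg)[3] <- "fused_count"
  totals <- tapply(agg$fused_count, agg$rpn_group, sum)
  empty <- names(totals)[totals == 0]
  if (length(empty)) {
    warning("omitting group(s) with zero fused DCVs: ",
            paste(empty, collapse = ", "))
    agg <- agg[!(agg$rpn_group %in% empty), , drop = FALSE]
  }
  agg$fraction <- agg$fused_count / as.numeric(totals[agg$rpn_group])
  out <- agg[order_lex(agg$rpn_group, agg$tissue),
             c("rpn_group", "tissue", "fraction")]
  rownames(out) <- NULL
  out
}

#' Read a DCV fusion-site count table
#'
#' @param path CSV with columns `rpn_group,tissue,fused_count`.
#' @return data.frame.
#' @export
read_dcv <- function(path) {
  if (!file.exists(path)) stop_validation("dcv file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}
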