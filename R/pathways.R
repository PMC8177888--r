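#' @title Thresholded connectivity and pathway analysis
#' @description Upstream-partner extraction, interneuron classification by
#'   direct sensory input, sensory profiles, 1-/2-hop path enumeration and
#'   hive-plot edge tables. All synaptic thresholds are inclusive (an edge of
#'   exactly `threshold` synapses passes) and apply per ordered neuron pair,
#'   never pooled over a target group.
#' @name pathway-analysis
NULL

#' Upstream synaptic partners of a target set
#'
#' Returns every neuron outside `targets` that contacts at least one target
#' with `threshold` or more synapses. Thresholding is per (partner, target)
#' pair: counts are not summed across the target group.
#'
#' @param x connectome.
#' @param targets character vector of target neuron ids (non-empty).
#' @param threshold minimum synapse count per pair (default 3, the
#'   reconstruction threshold used for partners of ring gland projection
#'   neurons).
#' @return sorted character vector of partner ids.
#' @export
upstream_partners <- function(x, targets, threshold = 3L) {
  stopifnot(inherits(x, "connectome"))
  assert_scalar_count(threshold, "threshold")
  targets <- as.character(targets)
  if (!length(targets)) stop_validation("target set may not be empty")
  unknown <- setdiff(targets, x$neurons$id)
  if (length(unknown)) {
    stop_validation("unknown target id(s): %s", paste(unknown, collapse = ", "))
  }
  e <- x$edges
  hit <- e$post %in% targets & e$count >= threshold & !(e$pre %in% targets)
  sort(unique(e$pre[hit]))
}

#' Partition interneurons by direct sensory input
#'
#' An interneuron is classed `with_sensory` iff some sensory neuron contacts
#' it with at least `threshold` synapses (default 2, the sensory-to-
#' interneuron threshold).
#'
#' @param x connectome.
#' @param interneurons,sensory disjoint id sets.
#' @param threshold minimum synapse count (inclusive).
#' @return list with sorted character vectors `with_sensory` and
#'   `without_sensory`.
#' @export
classify_interneurons <- function(x, interneurons, sensory, threshold = 2L) {
  stopifnot(inherits(x, "connectome"))
  assert_scalar_count(threshold, "threshold")
  interneurons <- as.character(interneurons)
  sensory <- as.character(sensory)
  if (length(intersect(interneurons, sensory))) {
    stop_validation("interneuron and sensory sets must be disjoint")
  }
  e <- x$edges
  hit <- e$pre %in% sensory & e$post %in% interneurons & e$count >= threshold
  with_s <- sort(intersect(interneurons, unique(e$post[hit])))
  list(with_sensory = with_s,
       without_sensory = sort(setdiff(interneurons, with_s)))
}

#' Sensory profile of a neuron or group
#'
#' Summarises where a subject's sensory input comes from, by peripheral
#' origin. Under basis `of_total_input` each origin's fraction is that
#' origin's synapses onto the subject divided by the subject's total input
#' (so fractions sum to the overall sensory share, <= 1). Under
#' `of_sensory_input` fractions are renormalised over sensory inputs only
#' (ignoring non-sensory inputs, as in pie-chart summaries), summing to 1
#' whenever any sensory input exists. Group subjects pool member input
#' synapses before normalising.
#'
#' @param wa weighted_adjacency (carries counts and per-neuron totals).
#' @param neurons neuron table of the underlying connectome.
#' @param subject a single neuron id, or a character vector of ids treated as
#'   a pooled group.
#' @param basis `"of_total_input"` or `"of_sensory_input"`.
#' @param label optional group label for the output (defaults to the ids
#'   joined by `+`).
#' @return object of class `sensory_profile`: list with `subject`, `basis`,
#'   `fractions` (named numeric by sensory origin, possibly empty) and
#'   `zero_input` flag.
#' @export
sensory_profile <- function(wa, neurons,
                            subject,
                            basis = c("of_total_input", "of_sensory_input"),
                            label = NULL) {
  stopifnot(inherits(wa, "weighted_adjacency"))
  basis <- match.arg(basis)
  neurons <- validate_neurons(neurons)
  subject <- as.character(subject)
  unknown <- setdiff(subject, neurons$id)
  if (length(unknown)) {
    stop_validation("unknown subject id(s): %s", paste(unknown, collapse = ", "))
  }
  label <- label %||% paste(subject, collapse = "+")
  w <- wa$weights[wa$weights$post %in% subject, , drop = FALSE]
  total_in <- sum(wa$totals[intersect(subject, names(wa$totals))])
  if (!nrow(w) || total_in == 0) {
    warning("subject has zero input: ", label)
    return(structure(list(subject = label, basis = basis,
                          fractions = stats::setNames(numeric(), character()),
                          zero_input = TRUE),
                     class = "sensory_profile"))
  }
  origin <- stats::setNames(neurons$sensory_origin, neurons$id)[w$pre]
  sens <- !is.na(origin)
  per_origin <- if (any(sens)) {
    tapply(w$count[sens], origin[sens], sum)
  } else {
    stats::setNames(numeric(), character())
  }
  per_origin <- stats::setNames(as.numeric(per_origin), names(per_origin))
  denom <- switch(basis,
                  of_total_input = total_in,
                  of_sensory_input = sum(per_origin))
  fractions <- if (length(per_origin) && denom > 0) {
    sort(per_origin / denom, decreasing = TRUE)
  } else {
    stats::setNames(numeric(), character())
  }
  structure(list(subject = label, basis = basis, fractions = fractions,
                 zero_input = FALSE),
            class = "sensory_profile")
}

#' @export
print.sensory_profile <- function(x, ...) {
  cat("sensory profile of", x$subject, "(", x$basis, ")\n")
  if (!length(x$fractions)) {
    cat("  no sensory input\n")
  } else {
    for (o in names(x$fractions)) {
      cat(sprintf("  %-15s %.4f\n", o, x$fractions[[o]]))
    }
  }
  invisible(x)
}

#' Enumerate 1- and 2-hop sensory-to-RPN pathways
#'
#' Finds every monosynaptic path sensory -> RPN with synapse count >=
#' `mono_threshold`, and every disynaptic path sensory -> interneuron -> RPN
#' in which the first hop has >= `sens_to_inter_threshold` synapses and the
#' second >= `inter_to_rpn_threshold`. Monosynaptic rows carry `NA` for the
#' interneuron and second hop; they are reported separately from 2-hop paths,
#' never merged.
#'
#' @param x connectome.
#' @param sensory,interneurons,rpns id sets defining the three path layers.
#' @param mono_threshold minimum count for direct sensory->RPN edges
#'   (default 3).
#' @param sens_to_inter_threshold minimum count for the sensory->interneuron
#'   hop (default 2).
#' @param inter_to_rpn_threshold minimum count for the interneuron->RPN hop
#'   (default 3).
#' @return data.frame with columns `origin` (sensory origin of the first
#'   node), `sensory_id`, `interneuron_id` (`NA` for monosynaptic),
#'   `rpn_id`, `hop1_count`, `hop2_count` (`NA` for monosynaptic), sorted
#'   lexicographically by (sensory_id, interneuron_id, rpn_id).
#' @export
enumerate_paths <- function(x, sensory, interneurons, rpns,
                            mono_threshold = 3L,
                            sens_to_inter_threshold = 2L,
                            inter_to_rpn_threshold = 3L) {
  stopifnot(inherits(x, "connectome"))
  assert_scalar_count(mono_threshold, "mono_threshold")
  assert_scalar_count(sens_to_inter_threshold, "sens_to_inter_threshold")
  assert_scalar_count(inter_to_rpn_threshold, "inter_to_rpn_threshold")
  sensory <- as.character(sensory)
  interneurons <- as.character(interneurons)
  rpns <- as.character(rpns)
  origin_of <- stats::setNames(x$neurons$sensory_origin, x$neurons$id)
  e <- x$edges

  empty_paths <- data.frame(origin = character(), sensory_id = character(),
                            interneuron_id = character(),
                            rpn_id = character(), hop1_count = integer(),
                            hop2_count = integer(), stringsAsFactors = FALSE)
  mono <- e[e$pre %in% sensory & e$post %in% rpns &
              e$count >= mono_threshold, , drop = FALSE]
  mono_df <- if (nrow(mono)) {
    data.frame(origin = unname(origin_of[mono$pre]),
               sensory_id = mono$pre,
               interneuron_id = NA_character_,
               rpn_id = mono$post,
               hop1_count = mono$count,
               hop2_count = NA_integer_,
               stringsAsFactors = FALSE)
  } else {
    empty_paths
  }

  hop1 <- e[e$pre %in% sensory & e$post %in% interneurons &
              e$count >= sens_to_inter_threshold, , drop = FALSE]
  hop2 <- e[e$pre %in% interneurons & e$post %in% rpns &
              e$count >= inter_to_rpn_threshold, , drop = FALSE]
  di_df <- empty_paths
  if (nrow(hop1) && nrow(hop2)) {
    joined <- merge(
      data.frame(sensory_id = hop1$pre, interneuron_id = hop1$post,
                 hop1_count = hop1$count, stringsAsFactors = FALSE),
      data.frame(interneuron_id = hop2$pre, rpn_id = hop2$post,
                 hop2_count = hop2$count, stringsAsFactors = FALSE),
      by = "interneuron_id")
    if (nrow(joined)) {
      di_df <- data.frame(origin = unname(origin_of[joined$sensory_id]),
                          sensory_id = joined$sensory_id,
                          interneuron_id = joined$interneuron_id,
                          rpn_id = joined$rpn_id,
                          hop1_count = joined$hop1_count,
                          hop2_count = joined$hop2_count,
                          stringsAsFactors = FALSE)
    }
  }

  paths <- rbind(mono_df, di_df)
  paths <- paths[order_lex(paths$sensory_id,
                           ifelse(is.na(paths$interneuron_id), "",
                                  paths$interneuron_id),
                           paths$rpn_id), , drop = FALSE]
  rownames(paths) <- NULL
  paths
}

#' Hive-plot edge table
#'
#' Edge list for hive-plot style visualisation: edges with fewer than
#' `threshold` synapses are dropped (default 5) and rows are sorted by
#' (pre, post). Equivalent to the edge list of
#' `subnetwork(x, min_count = threshold)`.
#'
#' @param x connectome.
#' @param threshold minimum synapse count (inclusive).
#' @return data.frame `pre`, `post`, `count`.
#' @export
hive_edge_table <- function(x, threshold = 5L) {
  stopifnot(inherits(x, "connectome"))
  assert_scalar_count(threshold, "threshold")
  e <- x$edges[x$edges$count >= threshold, , drop = FALSE]
  e <- e[order_lex(e$pre, e$post), , drop = FALSE]
  rownames(e) <- NULL
  e
}
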