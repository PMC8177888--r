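#' Feed-forward network (FFN) diffusion model parameters
#'
#' The FFN propagates sensory activation through input-fraction synaptic
#' weights in a single forward sweep (no recurrence, no backpropagation).
#' Each non-sensory unit is a rectified linear ramp: it starts responding
#' when a fraction `a` of its weighted input is active and saturates at
#' fraction `b`. Defaults make units respond from 5% and saturate at 50% of
#' active input (`a = 0.05`, `b = 0.5`), chosen to maximise the response
#' range; sensory source neurons emit a fixed activity `activation_factor`
#' (default 2).
#'
#' @param a response onset, as a fraction of active weighted input
#'   (0 <= a < b).
#' @param b saturation point, fraction of active weighted input.
#' @param activation_factor activity emitted by activated sensory neurons
#'   (> 0).
#' @param max_hops path depth of the layered network, 1 or 2.
#' @return object of class `ffn_params`.
#' @export
ffn_params <- function(a = 0.05, b = 0.5, activation_factor = 2,
                       max_hops = 2L) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      is.na(a) || is.na(b) || a < 0 || a >= b) {
    stop_validation("require 0 <= a < b (got a = %s, b = %s)", a, b)
  }
  if (!is.numeric(activation_factor) || length(activation_factor) != 1L ||
      is.na(activation_factor) || activation_factor < 0) {
    stop_validation("activation_factor must be nonnegative (0 is the silent limit)")
  }
  if (!max_hops %in% c(1L, 2L)) {
    stop_validation("max_hops must be 1 or 2")
  }
  structure(list(a = a, b = b,
                 activation_factor = as.numeric(activation_factor),
                 max_hops = as.integer(max_hops)),
            class = "ffn_params")
}

#' Rectified linear-ramp activation function
#'
#' `f(x) = 0` for `x <= a`, `(x - a) / (b - a)` for `a < x < b`, and `1` for
#' `x >= b`, where `x` is the sum of input activities weighted by input
#' fractions. The boundary values `f(a) = 0` and `f(b) = 1` follow from
#' continuity.
#'
#' @param x nonnegative weighted input sum (vectorised).
#' @param params ffn_params.
#' @return activity in \[0, 1\].
#' @export
ffn_activation <- function(x, params = ffn_params()) {
  stopifnot(inherits(params, "ffn_params"))
  if (any(is.na(x)) || any(x < 0)) {
    stop_validation("weighted input x must be nonnegative")
  }
  pmin(pmax((x - params$a) / (params$b - params$a), 0), 1)
}

#' Build the layered feed-forward network
#'
#' Layers the connectome for single-sweep propagation: layer 0 holds the
#' sensory neurons; layer 1 holds every neuron directly postsynaptic to layer
#' 0 (interneurons and directly contacted RPNs); layer 2 holds RPNs reached
#' from layer-1 interneurons. Only forward edges are kept: sensory -> layer 1,
#' and layer-1 interneuron -> RPN. An RPN contacted both monosynaptically and
#' disynaptically sits in layer 1 but retains its inputs from layer-1
#' interneurons, preserving both path lengths. Backward and intra-layer edges
#' (e.g. interneuron -> interneuron) are dropped and reported in
#' `$dropped_edges`.
#'
#' @param x connectome.
#' @param wa weighted_adjacency built from `x` (supplies edge weights).
#' @param sensory,rpns disjoint id sets.
#' @param params ffn_params (`max_hops = 1` keeps only direct
#'   sensory -> target edges).
#' @return object of class `ffn_network`: list with `layers` (list `sensory`,
#'   `hop1`, `hop2`), `forward_edges` (data.frame `pre`, `post`, `weight`),
#'   `origins` (named character: sensory id -> origin), `rpns`,
#'   `dropped_edges`, `params`.
#' @export
build_ffn <- function(x, wa, sensory, rpns, params = ffn_params()) {
  stopifnot(inherits(x, "connectome"), inherits(wa, "weighted_adjacency"),
            inherits(params, "ffn_params"))
  sensory <- as.character(sensory)
  rpns <- as.character(rpns)
  if (length(intersect(sensory, rpns))) {
    stop_validation("sensory and rpn sets must be disjoint")
  }
  w <- wa$weights
  from_sens <- w[w$pre %in% sensory, , drop = FALSE]
  if (!nrow(from_sens)) {
    stop_validation("empty network: no edges leaving the sensory layer")
  }
  hop1 <- sort(setdiff(unique(from_sens$post), sensory))
  hop1_inter <- setdiff(hop1, rpns)
  second <- w[w$pre %in% hop1_inter & w$post %in% rpns, , drop = FALSE]
  if (params$max_hops < 2L) second <- second[0, , drop = FALSE]
  hop2 <- sort(setdiff(unique(second$post), c(hop1, sensory)))

  forward <- rbind(from_sens, second)
  forward <- forward[order_lex(forward$pre, forward$post), c("pre", "post",
                                                             "weight")]
  rownames(forward) <- NULL
  in_model <- unique(c(forward$pre, forward$post))
  dropped <- w[!(paste(w$pre, w$post) %in% paste(forward$pre, forward$post)) &
                 (w$pre %in% in_model | w$post %in% in_model), , drop = FALSE]
  if (nrow(dropped)) {
    message("build_ffn: dropped ", nrow(dropped),
            " non-feed-forward edge(s)")
  }
  origins <- stats::setNames(x$neurons$sensory_origin, x$neurons$id)[sensory]
  structure(list(layers = list(sensory = sort(sensory), hop1 = hop1,
                               hop2 = hop2),
                 forward_edges = forward,
                 origins = origins,
                 rpns = rpns,
                 dropped_edges = dropped[, c("pre", "post", "count")],
                 params = params),
            class = "ffn_network")
}

#' @export
print.ffn_network <- function(x, ...) {
  cat("ffn_network: layers",
      paste(lengths(x$layers), collapse = " / "),
      "(sensory / hop1 / hop2),", nrow(x$forward_edges), "forward edges\n")
  invisible(x)
}

#' Propagate sensory activation through the FFN
#'
#' Sensory neurons of the requested origin emit `activation_factor`; all
#' other sensory neurons emit 0. Propagation is one forward sweep: each
#' layer-1 interneuron receives `x = sum(weight * source activity)` over its
#' sensory inputs and responds with `ffn_activation(x)`; each RPN then sums
#' its retained sensory and layer-1 interneuron inputs the same way. Sensory
#' neurons bypass the activation function (they are sources, not units).
#'
#' @param ffn ffn_network.
#' @param origin sensory origin label to activate (must label at least one
#'   layer-0 neuron).
#' @param params optional ffn_params overriding those stored in `ffn` (e.g.
#'   to sweep the activation factor).
#' @return object of class `activity_state`: list with `activities`
#'   (data.frame `id`, `layer`, `x`, `activity`), `active_origin`, `params`.
#'   Non-sensory activities lie in \[0, 1\]; sensory activities are 0 or
#'   `activation_factor`.
#' @export
ffn_propagate <- function(ffn, origin, params = NULL) {
  stopifnot(inherits(ffn, "ffn_network"))
  params <- params %||% ffn$params
  stopifnot(inherits(params, "ffn_params"))
  known <- sort(unique(stats::na.omit(ffn$origins)))
  if (!origin %in% known) {
    stop_validation("unknown sensory origin '%s' (known: %s)", origin,
                    paste(known, collapse = ", "))
  }
  sens <- ffn$layers$sensory
  act <- stats::setNames(rep(0, length(sens)), sens)
  act[names(ffn$origins)[!is.na(ffn$origins) & ffn$origins == origin]] <-
    params$activation_factor

  fe <- ffn$forward_edges
  weighted_sum <- function(targets, source_act) {
    keep <- fe$post %in% targets & fe$pre %in% names(source_act)
    if (!any(keep)) {
      return(stats::setNames(rep(0, length(targets)), targets))
    }
    s <- tapply(fe$weight[keep] * source_act[fe$pre[keep]], fe$post[keep], sum)
    out <- stats::setNames(rep(0, length(targets)), targets)
    out[names(s)] <- as.numeric(s)
    out
  }

  hop1_inter <- setdiff(ffn$layers$hop1, ffn$rpns)
  hop1_rpn <- intersect(ffn$layers$hop1, ffn$rpns)
  x_inter <- weighted_sum(hop1_inter, act)
  act_inter <- ffn_activation(x_inter, params)
  # RPNs pool their direct sensory drive with layer-1 interneuron activity.
  upstream_act <- c(act, act_inter)
  rpn_nodes <- c(hop1_rpn, ffn$layers$hop2)
  x_rpn <- weighted_sum(rpn_nodes, upstream_act)
  act_rpn <- ffn_activation(x_rpn, params)

  df <- rbind(
    data.frame(id = sens, layer = 0L, x = NA_real_,
               activity = unname(act), stringsAsFactors = FALSE),
    data.frame(id = names(x_inter), layer = 1L, x = unname(x_inter),
               activity = unname(act_inter), stringsAsFactors = FALSE),
    data.frame(id = rpn_nodes,
               layer = ifelse(rpn_nodes %in% ffn$layers$hop1, 1L, 2L),
               x = unname(x_rpn[rpn_nodes]),
               activity = unname(act_rpn[rpn_nodes]),
               stringsAsFactors = FALSE)
  )
  df <- df[order_lex(format(df$layer), df$id), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(activities = df, active_origin = origin, params = params),
            class = "activity_state")
}

#' @export
print.activity_state <- function(x, ...) {
  cat("activity_state: origin =", x$active_origin, ",",
      nrow(x$activities), "neurons, factor =",
      x$params$activation_factor, "\n")
  invisible(x)
}

#' Activity of specific neurons
#'
#' @param state activity_state.
#' @param ids neuron ids; ids absent from the layered network return 0.
#' @return named numeric activities.
#' @export
activity_of <- function(state, ids) {
  stopifnot(inherits(state, "activity_state"))
  a <- stats::setNames(state$activities$activity, state$activities$id)
  out <- stats::setNames(rep(0, length(ids)), ids)
  hit <- intersect(ids, names(a))
  out[hit] <- a[hit]
  out
}

#' Mean activity per neuron group
#'
#' Unweighted mean activity over group members; members absent from the
#' layered network (unreachable from the active sensory layer) count as
#' activity 0.
#'
#' @param state activity_state.
#' @param groups named list mapping group label to member ids; every group
#'   must be non-empty.
#' @return data.frame `group`, `origin`, `mean_activity`, sorted by group.
#' @export
mean_group_activity <- function(state, groups) {
  stopifnot(inherits(state, "activity_state"))
  if (!length(groups) || is.null(names(groups))) {
    stop_validation("groups must be a non-empty named list")
  }
  if (any(lengths(groups) == 0L)) {
    stop_validation("empty group(s): %s",
                    paste(names(groups)[lengths(groups) == 0L], collapse = ", "))
  }
  means <- vapply(groups, function(ids) mean(activity_of(state, ids)),
                  numeric(1))
  out <- data.frame(group = names(groups), origin = state$active_origin,
                    mean_activity = unname(means), stringsAsFactors = FALSE)
  out <- out[order_lex(out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sweep FFN propagation over origins and activation factors
#'
#' Runs one propagation per (origin, factor) combination and tabulates mean
#' group activities.
#'
#' @param ffn ffn_network.
#' @param origins sensory origin labels to activate, one at a time.
#' @param factors positive activation factors to try.
#' @param groups named list of neuron groups (see [mean_group_activity()]).
#' @param params base ffn_params; `activation_factor` is overridden per run.
#' @return data.frame `origin`, `factor`, `group`, `mean_activity`, sorted by
#'   (origin, factor, group).
#' @export
ffn_sweep <- function(ffn, origins, factors, groups, params = NULL) {
  stopifnot(inherits(ffn, "ffn_network"))
  params <- params %||% ffn$params
  if (!length(factors) || any(!is.finite(factors)) || any(factors < 0)) {
    stop_validation("factors must be nonnegative numbers")
  }
  rows <- list()
  for (org in origins) {
    for (f in factors) {
      p <- ffn_params(a = params$a, b = params$b, activation_factor = f,
                      max_hops = params$max_hops)
      ga <- mean_group_activity(ffn_propagate(ffn, org, p), groups)
      rows[[length(rows) + 1L]] <- data.frame(
        origin = org, factor = f, group = ga$group,
        mean_activity = ga$mean_activity, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order_lex(out$origin, format(out$factor, digits = 15),
                       out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
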