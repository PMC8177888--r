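#' @title Connectome data model
#' @description Neuron tables, synapse edge lists and the aggregated
#'   directed connectome. Edge direction is pre -> post (presynaptic neuron
#'   to postsynaptic neuron) everywhere in this package.
#' @name connectome-model
NULL

#' Recognised neuron classes
#'
#' `rpn` denotes ring gland projection neurons (neurosecretory output cells);
#' `endocrine_target` marks non-neuronal target tissue placeholders.
#'
#' @export
NEURON_CLASSES <- c("sensory", "interneuron", "rpn", "endocrine_target",
                    "other")

#' Recognised body sides
#' @export
NEURON_SIDES <- c("left", "right", "unpaired")

neuron_columns <- c("id", "name", "cell_class", "cluster", "sensory_origin",
                    "side")

blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  x
}

#' Validate a neuron annotation table
#'
#' Checks the invariants of the neuron data model: unique ids, known cell
#' classes and sides, and `sensory_origin` present if and only if the neuron
#' is sensory.
#'
#' @param neurons data.frame with columns `id`, `name`, `cell_class`,
#'   `cluster`, `sensory_origin`, `side` (the last three may be `NA`).
#' @return The validated table (invisibly usable), with character columns and
#'   empty strings normalised to `NA`.
#' @export
validate_neurons <- function(neurons) {
  if (!is.data.frame(neurons)) {
    stop_validation("neuron table must be a data.frame")
  }
  missing_cols <- setdiff(neuron_columns, names(neurons))
  if (length(missing_cols)) {
    stop_validation("neuron table lacks column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  neurons <- neurons[neuron_columns]
  for (col in neuron_columns) neurons[[col]] <- blank_to_na(neurons[[col]])
  if (anyNA(neurons$id)) stop_validation("neuron id may not be empty")
  dup <- unique(neurons$id[duplicated(neurons$id)])
  if (length(dup)) {
    stop_validation("duplicate neuron id(s): %s", paste(dup, collapse = ", "))
  }
  bad_class <- unique(neurons$cell_class[
    is.na(neurons$cell_class) | !(neurons$cell_class %in% NEURON_CLASSES)])
  if (length(bad_class)) {
    stop_validation("unknown cell_class value(s): %s (expected one of %s)",
                    paste(bad_class, collapse = ", "),
                    paste(NEURON_CLASSES, collapse = ", "))
  }
  bad_side <- unique(stats::na.omit(
    neurons$side[!(neurons$side %in% NEURON_SIDES) & !is.na(neurons$side)]))
  if (length(bad_side)) {
    stop_validation("unknown side value(s): %s", paste(bad_side, collapse = ", "))
  }
  sens <- neurons$cell_class == "sensory"
  if (any(sens & is.na(neurons$sensory_origin))) {
    stop_validation("missing sensory_origin for sensory neuron(s): %s",
                    paste(neurons$id[sens & is.na(neurons$sensory_origin)],
                          collapse = ", "))
  }
  if (any(!sens & !is.na(neurons$sensory_origin))) {
    stop_validation("sensory_origin set on non-sensory neuron(s): %s",
                    paste(neurons$id[!sens & !is.na(neurons$sensory_origin)],
                          collapse = ", "))
  }
  rownames(neurons) <- NULL
  neurons
}

#' Read a neuron annotation table from CSV
#'
#' Expects a header with columns `id,name,cell_class,cluster,sensory_origin,
#' side`; `cluster`, `sensory_origin` and `side` may be empty. All fields are
#' read as character; ids are opaque strings.
#'
#' @param path path to a UTF-8 comma-separated file.
#' @return validated neuron data.frame.
#' @export
read_neurons <- function(path) {
  if (!file.exists(path)) stop_validation("neuron file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, comment.char = "#")
  validate_neurons(df)
}

#' Read a raw synapse edge list from CSV
#'
#' Expects header columns `pre,post,count`. Rows are *raw* edges: duplicate
#' (pre, post) pairs are permitted here and summed later by [connectome()].
#'
#' @param path path to a comma-separated file.
#' @return data.frame with character `pre`, `post` and integer `count`.
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop_validation("edge file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, comment.char = "#")
  validate_edges(df)
}

#' Validate a raw edge list
#'
#' @param edges data.frame with columns `pre`, `post`, `count`.
#' @return data.frame with integer counts; counts must be positive integers.
#' @export
validate_edges <- function(edges) {
  if (!is.data.frame(edges)) stop_validation("edge table must be a data.frame")
  missing_cols <- setdiff(c("pre", "post", "count"), names(edges))
  if (length(missing_cols)) {
    stop_validation("edge table lacks column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  edges <- edges[c("pre", "post", "count")]
  edges$pre <- blank_to_na(edges$pre)
  edges$post <- blank_to_na(edges$post)
  if (anyNA(edges$pre) || anyNA(edges$post)) {
    stop_validation("edge endpoints may not be empty (row %s)",
                    paste(which(is.na(edges$pre) | is.na(edges$post)),
                          collapse = ", "))
  }
  count_num <- suppressWarnings(as.numeric(edges$count))
  bad <- is.na(count_num) | count_num < 1 | count_num != round(count_num)
  if (any(bad)) {
    stop_validation("synapse count must be a positive integer (row %s)",
                    paste(which(bad), collapse = ", "))
  }
  edges$count <- as.integer(count_num)
  rownames(edges) <- NULL
  edges
}

#' Build an aggregated connectome
#'
#' Aggregates raw synapse edges into a directed multigraph-free connectome:
#' duplicate (pre, post) pairs are summed so that the result holds at most one
#' edge per ordered pair. Every edge endpoint must exist in the neuron table.
#' Autapses (pre == post) are retained but reported via
#' `autapses(x)`.
#'
#' @param neurons neuron table (see [validate_neurons()]).
#' @param edges raw edge list (see [validate_edges()]); may be empty.
#' @return object of class `connectome`: a list with elements `neurons`
#'   (data.frame) and `edges` (aggregated data.frame `pre`, `post`, `count`,
#'   sorted lexicographically by pre then post).
#' @export
connectome <- function(neurons, edges = NULL) {
  neurons <- validate_neurons(neurons)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(pre = character(), post = character(),
                        count = integer(), stringsAsFactors = FALSE)
  } else {
    edges <- validate_edges(edges)
  }
  dangling <- setdiff(unique(c(edges$pre, edges$post)), neurons$id)
  if (length(dangling)) {
    stop_validation("edge endpoint(s) not in neuron table: %s",
                    paste(sort(dangling), collapse = ", "))
  }
  if (nrow(edges)) {
    agg <- stats::aggregate(count ~ pre + post, data = edges, FUN = sum)
    agg$count <- as.integer(agg$count)
    agg <- agg[order_lex(agg$pre, agg$post), , drop = FALSE]
    rownames(agg) <- NULL
    edges <- agg
  }
  obj <- structure(list(neurons = neurons, edges = edges),
                   class = "connectome")
  auta <- autapses(obj)
  if (length(auta)) {
    message("connectome contains autapse(s) on: ", paste(auta, collapse = ", "))
  }
  obj
}

#' Autapses of a connectome
#'
#' @param x connectome.
#' @return character vector of neuron ids with a self edge.
#' @export
autapses <- function(x) {
  stopifnot(inherits(x, "connectome"))
  sort(unique(x$edges$pre[x$edges$pre == x$edges$post]))
}

#' @export
print.connectome <- function(x, ...) {
  cls <- table(factor(x$neurons$cell_class, levels = NEURON_CLASSES))
  cat("connectome:", nrow(x$neurons), "neurons,", nrow(x$edges),
      "aggregated edges\n")
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = " "),
      "\n")
  if (nrow(x$edges)) {
    cat("  synapse counts: min", min(x$edges$count), "max",
        max(x$edges$count), "total", sum(x$edges$count), "\n")
  }
  invisible(x)
}

#' Neuron ids by cell class or cluster
#'
#' Convenience selectors over the neuron table.
#'
#' @param x connectome.
#' @param cell_class optional class filter (one of [NEURON_CLASSES]).
#' @param cluster optional cluster label filter.
#' @param sensory_origin optional sensory origin filter.
#' @return character vector of ids.
#' @export
neuron_ids <- function(x, cell_class = NULL, cluster = NULL,
                       sensory_origin = NULL) {
  stopifnot(inherits(x, "connectome"))
  n <- x$neurons
  keep <- rep(TRUE, nrow(n))
  if (!is.null(cell_class)) keep <- keep & n$cell_class %in% cell_class
  if (!is.null(cluster)) keep <- keep & !is.na(n$cluster) & n$cluster %in% cluster
  if (!is.null(sensory_origin)) {
    keep <- keep & !is.na(n$sensory_origin) & n$sensory_origin %in% sensory_origin
  }
  n$id[keep]
}

#' RPN groups of a connectome
#'
#' Groups ring gland projection neurons by their cluster label (e.g. CRZ,
#' DH44, IPCs).
#'
#' @param x connectome.
#' @return named list mapping cluster label to member neuron ids.
#' @export
rpn_groups <- function(x) {
  stopifnot(inherits(x, "connectome"))
  n <- x$neurons[x$neurons$cell_class == "rpn", , drop = FALSE]
  if (!nrow(n)) return(stats::setNames(list(), character()))
  lab <- ifelse(is.na(n$cluster), "unassigned", n$cluster)
  split(n$id, lab)
}

#' Extract a thresholded subnetwork
#'
#' Removes neurons failing `keep` (with all their edges) and edges whose
#' synapse count falls below `min_count`. With `min_count = 1` and an
#' all-pass predicate this is the identity.
#'
#' @param x connectome.
#' @param keep either a character vector of ids to retain or a predicate
#'   function over the neuron table rows (returning a logical vector).
#' @param min_count minimum synapse count for an edge to survive (inclusive,
#'   >= 1).
#' @return connectome.
#' @export
subnetwork <- function(x, keep = NULL, min_count = 1L) {
  stopifnot(inherits(x, "connectome"))
  assert_scalar_count(min_count, "min_count")
  n <- x$neurons
  if (is.null(keep)) {
    sel <- rep(TRUE, nrow(n))
  } else if (is.function(keep)) {
    sel <- keep(n)
    if (!is.logical(sel) || length(sel) != nrow(n)) {
      stop_validation("keep predicate must return one logical per neuron")
    }
  } else {
    sel <- n$id %in% keep
  }
  n <- n[sel, , drop = FALSE]
  e <- x$edges
  e <- e[e$pre %in% n$id & e$post %in% n$id & e$count >= min_count, ,
         drop = FALSE]
  suppressMessages(connectome(n, e))
}

#' Write a connectome to neurons.csv / edges.csv
#'
#' Files round-trip exactly through [read_connectome()] (ids, counts).
#'
#' @param x connectome.
#' @param neurons_path,edges_path output paths.
#' @return invisibly, the two paths.
#' @export
write_connectome <- function(x, neurons_path, edges_path) {
  stopifnot(inherits(x, "connectome"))
  n <- x$neurons
  for (col in names(n)) n[[col]][is.na(n[[col]])] <- ""
  utils::write.csv(n, neurons_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(x$edges, edges_path, row.names = FALSE, quote = FALSE)
  invisible(c(neurons_path, edges_path))
}

#' Read a connectome from neurons.csv / edges.csv
#'
#' @param neurons_path,edges_path input paths.
#' @return connectome.
#' @export
read_connectome <- function(neurons_path, edges_path) {
  suppressMessages(
    connectome(read_neurons(neurons_path), read_edges(edges_path))
  )
}
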