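#' Input-fraction weight normalisation
#'
#' Converts aggregated synapse counts into synaptic weights expressed as
#' fractions of each postsynaptic neuron's total input, the normalisation the
#' feed-forward network model and the hub score operate on.
#'
#' Two denominator policies are supported. Under `dataset_total` (the
#' default) each neuron's total input is the sum of its incoming synapse
#' counts *within the loaded connectome*, so incoming weights of every
#' non-isolated neuron sum to exactly 1. Under `declared_total` the caller
#' supplies per-neuron totals (e.g. postsynapse counts from the full EM
#' volume, of which the analysed subnetwork sees only a part); weights then
#' sum to at most 1 per neuron.
#'
#' @param x connectome.
#' @param denominator_policy `"dataset_total"` or `"declared_total"`.
#' @param declared_totals named numeric vector mapping post neuron id to its
#'   declared total input synapse count; required under `declared_total`
#'   policy, must cover every neuron with observed input and be >= the
#'   observed input sum.
#' @return object of class `weighted_adjacency`: list with
#'   \describe{
#'     \item{weights}{data.frame `pre`, `post`, `count`, `weight`}
#'     \item{totals}{named numeric, total input per neuron with >= 1 input}
#'     \item{ids}{ordered neuron ids of the underlying connectome}
#'     \item{denominator_policy}{the policy used}
#'     \item{zero_input}{ids of neurons with no incoming synapse (flagged)}
#'   }
#' @export
input_fractions <- function(x,
                            denominator_policy = c("dataset_total",
                                                   "declared_total"),
                            declared_totals = NULL) {
  stopifnot(inherits(x, "connectome"))
  denominator_policy <- match.arg(denominator_policy)
  e <- x$edges
  observed <- if (nrow(e)) {
    tapply(e$count, e$post, sum)
  } else {
    stats::setNames(numeric(), character())
  }
  observed <- stats::setNames(as.numeric(observed), names(observed))
  if (denominator_policy == "declared_total") {
    if (is.null(declared_totals) || is.null(names(declared_totals))) {
      stop_validation("declared_total policy requires named declared_totals")
    }
    uncovered <- setdiff(names(observed), names(declared_totals))
    if (length(uncovered)) {
      stop_validation("declared_totals missing for neuron(s) with input: %s",
                      paste(sort(uncovered), collapse = ", "))
    }
    short <- names(observed)[
      declared_totals[names(observed)] < observed - 1e-9]
    if (length(short)) {
      stop_validation(
        "declared total smaller than observed input sum for: %s",
        paste(sort(short), collapse = ", "))
    }
    totals <- declared_totals[names(observed)]
  } else {
    totals <- observed
  }
  w <- e
  w$weight <- if (nrow(e)) e$count / as.numeric(totals[e$post]) else numeric()
  zero_input <- setdiff(x$neurons$id, names(observed))
  structure(list(weights = w,
                 totals = totals,
                 ids = x$neurons$id,
                 denominator_policy = denominator_policy,
                 zero_input = zero_input),
            class = "weighted_adjacency")
}

#' @export
print.weighted_adjacency <- function(x, ...) {
  cat("weighted_adjacency:", length(x$ids), "neurons,", nrow(x$weights),
      "weighted edges, policy =", x$denominator_policy, "\n")
  if (length(x$zero_input)) {
    cat("  neurons with zero input:", length(x$zero_input), "\n")
  }
  invisible(x)
}

#' Dense weight matrix
#'
#' @param x weighted_adjacency.
#' @param ... unused.
#' @return dense numeric matrix, rows = presynaptic ids, columns =
#'   postsynaptic ids, in the connectome's neuron order. Columns of neurons
#'   with no input are all-zero.
#' @export
as.matrix.weighted_adjacency <- function(x, ...) {
  m <- matrix(0, length(x$ids), length(x$ids),
              dimnames = list(x$ids, x$ids))
  if (nrow(x$weights)) {
    m[cbind(x$weights$pre, x$weights$post)] <- x$weights$weight
  }
  m
}

#' Export a weighted adjacency matrix
#'
#' Writes a dense CSV matrix (neuron ids as first row and first column) and a
#' JSON metadata sidecar recording the denominator policy, per-neuron totals
#' and zero-input neurons.
#'
#' @param x weighted_adjacency.
#' @param matrix_path CSV output path; the sidecar is written next to it with
#'   extension `.json`.
#' @return invisibly, the sidecar path.
#' @export
write_adjacency <- function(x, matrix_path) {
  stopifnot(inherits(x, "weighted_adjacency"))
  m <- as.matrix(x)
  utils::write.csv(as.data.frame(m), matrix_path, row.names = TRUE,
                   quote = FALSE)
  sidecar <- paste0(sub("\\.csv$", "", matrix_path), ".json")
  jsonlite::write_json(
    list(denominator_policy = x$denominator_policy,
         totals = as.list(x$totals),
         zero_input = x$zero_input),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
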