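#' MLC hardware models
#'
#' Describes the leaf geometry of the two supported Varian MLC types.
#' Both banks share the same inplane (y) leaf boundaries; positions are mm
#' at the isocenter plane, centered on the collimator axis.
#'
#' * `millennium120`: 60 leaf pairs — 10 outer leaves of 10 mm, 40 central
#'   leaves of 5 mm, 10 outer leaves of 10 mm per bank (total span 400 mm).
#' * `hdmlc`: 60 leaf pairs — 14 outer leaves of 5 mm, 32 central leaves of
#'   2.5 mm, 14 outer leaves of 5 mm (total span 220 mm).
#'
#' @param name `"millennium120"` or `"hdmlc"`.
#' @return An object of class `mlc_model` with fields `name`,
#'   `leaf_edges` (ordered inplane boundaries, length `n_leaf_pairs + 1`),
#'   `leaf_widths`, `leaf_centers`, and `n_leaf_pairs`.
#' @export
mlc_model <- function(name = c("millennium120", "hdmlc")) {
  name <- match.arg(name)
  widths <- switch(name,
    millennium120 = c(rep(10, 10), rep(5, 40), rep(10, 10)),
    hdmlc = c(rep(5, 14), rep(2.5, 32), rep(5, 14))
  )
  edges <- cumsum(c(0, widths)) - sum(widths) / 2
  structure(
    list(
      name = name,
      leaf_edges = edges,
      leaf_widths = widths,
      leaf_centers = (edges[-1] + edges[-length(edges)]) / 2,
      n_leaf_pairs = length(widths)
    ),
    class = "mlc_model"
  )
}

#' @export
print.mlc_model <- function(x, ...) {
  cat(sprintf("<mlc_model> %s: %d leaf pairs, span %.0f mm (widths %s mm)\n",
              x$name, x$n_leaf_pairs,
              diff(range(x$leaf_edges)),
              paste(unique(x$leaf_widths), collapse = "/")))
  invisible(x)
}

#' Inner (narrow) leaf indices of an MLC model
#'
#' The central narrow leaves (5 mm on the Millennium120, 2.5 mm on the
#' HDMLC) used by the sensitivity experiments.
#' @param mlc an [mlc_model].
#' @return integer vector of leaf indices.
#' @export
inner_leaves <- function(mlc) {
  which(mlc$leaf_widths == min(mlc$leaf_widths))
}
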