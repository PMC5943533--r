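#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Long-format view of a distance matrix
#'
#' @param d A `dist` object.
#' @return Tibble `item1`, `item2`, `distance` (lower triangle).
#' @export
tidy_dist <- function(d) {
  stopifnot(inherits(d, "dist"))
  m <- as.matrix(d)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  tibble::tibble(
    item1 = rownames(m)[idx[, 2]],
    item2 = rownames(m)[idx[, 1]],
    distance = m[idx]
  )
}

#' @rdname tidy.mcp_otu_table
#' @method tidy mcp_otu_table
#' @export
tidy.mcp_otu_table <- function(x, ...) x$counts

#' Tidy and summary methods for pipeline objects
#'
#' `tidy()` returns the per-observation table of the object (long OTU
#' counts, surviving-read length histogram, ordination coordinates,
#' jackknife node support); `glance()` returns a one-row summary.
#'
#' @param x An object produced by the package.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy.mcp_otu_table
NULL

#' @rdname tidy.mcp_otu_table
#' @method glance mcp_otu_table
#' @export
glance.mcp_otu_table <- function(x, ...) {
  tibble::tibble(
    n_otus = nrow(x$representatives),
    n_samples = length(unique(x$counts$sample)),
    n_reads = sum(x$counts$count),
    threshold = x$threshold
  )
}

#' @rdname tidy.mcp_otu_table
#' @method tidy mcp_readset
#' @export
tidy.mcp_readset <- function(x, ...) x$length_histogram

#' @rdname tidy.mcp_otu_table
#' @method glance mcp_readset
#' @export
glance.mcp_readset <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input,
    n_kept = nrow(x$records),
    n_discarded = sum(x$discarded$n),
    discard_fraction = discard_fraction(x)
  )
}

#' @rdname tidy.mcp_otu_table
#' @method tidy mcp_pcoa
#' @export
tidy.mcp_pcoa <- function(x, ...) x$coordinates

#' @rdname tidy.mcp_otu_table
#' @method glance mcp_pcoa
#' @export
glance.mcp_pcoa <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_positive_axes = length(x$proportion_explained),
    prop_axis1 = x$proportion_explained[1],
    prop_axis2 = if (length(x$proportion_explained) >= 2) x$proportion_explained[2] else NA_real_,
    min_eigenvalue = min(x$eigenvalues)
  )
}

#' @rdname tidy.mcp_otu_table
#' @method tidy mcp_jackknife_tree
#' @export
tidy.mcp_jackknife_tree <- function(x, ...) {
  if (is.null(x$support)) {
    tibble::tibble(clade = character(), support = numeric())
  } else {
    x$support
  }
}

#' Bar chart of per-sample length-class composition
#'
#' @param composition Output of [length_class_composition()].
#' @return A ggplot.
#' @export
plot_length_classes <- function(composition) {
  ggplot2::ggplot(
    composition,
    ggplot2::aes(x = .data$sample, y = .data$proportion, fill = .data$class)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "proportion of surviving reads",
      fill = "length (nt)"
    ) +
    ggplot2::theme_minimal()
}

#' Rarefaction curves per sample
#'
#' @param curves Output of [rarefaction()].
#' @return A ggplot.
#' @export
plot_rarefaction <- function(curves) {
  ggplot2::ggplot(
    curves,
    ggplot2::aes(
      x = .data$depth, y = .data$observed_otus,
      colour = .data$sample, group = .data$sample
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "subsampled reads", y = "observed OTUs") +
    ggplot2::theme_minimal()
}

#' @rdname tidy.mcp_otu_table
#' @param object An `mcp_pcoa`.
#' @method autoplot mcp_pcoa
#' @export
autoplot.mcp_pcoa <- function(object, ...) {
  pe <- object$proportion_explained
  lab <- function(i) {
    sprintf("Axis %d (%.1f%%)", i, 100 * pe[i])
  }
  ggplot2::ggplot(
    object$coordinates,
    ggplot2::aes(x = .data$Axis1, y = .data$Axis2, label = .data$sample)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' @keywords internal
#' @useDynLib cyanomcp, .registration = TRUE
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom tibble tibble
#' @importFrom Rcpp evalCpp
NULL
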