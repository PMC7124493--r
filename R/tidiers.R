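#' Tidy the edges of a mixed graph
#'
#' @param x a `mixed_graph`.
#' @param ... unused.
#' @return tibble with one row per edge (tail, head, orientation, status,
#'   confidence, studies) plus recorded deletions flagged in `status`.
#' @export
tidy.mixed_graph <- function(x, ...) {
  e <- tibble(
    tail = x$edges$tail, head = x$edges$head,
    orientation = x$edges$orientation, status = x$edges$status,
    confidence = x$edges$confidence,
    studies = map_chr(x$edges$provenance,
                      function(p) paste(prov_studies(p), collapse = ";")))
  d <- tibble(
    tail = x$deletions$a, head = x$deletions$b,
    orientation = NA_character_, status = "deleted",
    confidence = NA_character_,
    studies = map_chr(x$deletions$provenance,
                      function(p) paste(prov_studies(p), collapse = ";")))
  arrange(bind_rows(e, d), .data$status, .data$tail, .data$head)
}

#' One-row summary of a mixed graph
#'
#' @param x a `mixed_graph`.
#' @param ... unused.
#' @return tibble with node/edge counts by orientation and status, the
#'   stage flag, and acyclicity of the directed part.
#' @export
glance.mixed_graph <- function(x, ...) {
  tibble(
    stage = x$stage,
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_directed = sum(x$edges$orientation == "directed"),
    n_unassigned = sum(x$edges$orientation == "unassigned"),
    n_bidirectional = sum(x$edges$orientation == "bidirectional"),
    n_candidate = sum(x$edges$status == "candidate"),
    n_retained = sum(x$edges$status == "retained"),
    n_deletions = nrow(x$deletions),
    acyclic = is_acyclic(x))
}

#' Tidy a directed edge index
#'
#' @param x an `edge_index`.
#' @param ... unused.
#' @return records tibble with provenance collapsed to a `studies`
#'   column.
#' @export
tidy.edge_index <- function(x, ...) {
  r <- x$records
  arrange(tibble(
    tail = r$tail, head = r$head, bidirectional = r$bidirectional,
    confidence = r$confidence,
    studies = map_chr(r$provenance,
                      function(p) paste(prov_studies(p), collapse = ";")),
    conflict = r$conflict, notes = r$notes), .data$tail, .data$head)
}

#' @rdname tidy.edge_index
#' @export
glance.edge_index <- function(x, ...) {
  tibble(n_records = nrow(x$records),
         n_bidirectional = sum(x$records$bidirectional),
         n_low_confidence = sum(x$records$confidence == "low"),
         n_conflicts = sum(x$records$conflict),
         n_deletions = nrow(x$deletions),
         n_studies = length(prov_studies(unlist(x$records$provenance))))
}

#' Plot a mixed graph
#'
#' A quick diagnostic plot: nodes on a deterministic force-directed
#' layout, solid arrows for directed edges, dashed segments for
#' unassigned candidates, double-headed arrows for bidirectional edges,
#' exposure/outcome nodes emphasised.
#'
#' @param object a `mixed_graph`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mixed_graph <- function(object, ...) {
  g <- object
  ig <- directed_igraph(g, edges = g$edges)
  xy <- withr::with_seed(42, igraph::layout_with_fr(ig))
  lay <- tibble(id = g$nodes$id, x = xy[, 1], y = xy[, 2],
                focal = map_lgl(g$nodes$roles,
                                function(r) any(c("exposure", "outcome") %in% r)))
  e <- g$edges
  seg <- left_join(left_join(
    tibble(tail = e$tail, head = e$head, orientation = e$orientation),
    rename(lay[, 1:3], tail = "id", x0 = "x", y0 = "y"), by = "tail"),
    rename(lay[, 1:3], head = "id", x1 = "x", y1 = "y"), by = "head")
  shrink <- 0.12
  seg$xe <- seg$x0 + (1 - shrink) * (seg$x1 - seg$x0)
  seg$ye <- seg$y0 + (1 - shrink) * (seg$y1 - seg$y0)
  seg$xs <- seg$x0 + shrink * (seg$x1 - seg$x0)
  seg$ys <- seg$y0 + shrink * (seg$y1 - seg$y0)
  p <- ggplot2::ggplot()
  dir_e <- seg[seg$orientation == "directed", ]
  una_e <- seg[seg$orientation == "unassigned", ]
  bi_e <- seg[seg$orientation == "bidirectional", ]
  if (nrow(dir_e) > 0) {
    p <- p + ggplot2::geom_segment(
      data = dir_e,
      ggplot2::aes(x = .data$xs, y = .data$ys, xend = .data$xe, yend = .data$ye),
      arrow = ggplot2::arrow(length = ggplot2::unit(2.5, "mm")))
  }
  if (nrow(una_e) > 0) {
    p <- p + ggplot2::geom_segment(
      data = una_e,
      ggplot2::aes(x = .data$xs, y = .data$ys, xend = .data$xe, yend = .data$ye),
      linetype = "dashed", colour = "grey50")
  }
  if (nrow(bi_e) > 0) {
    p <- p + ggplot2::geom_segment(
      data = bi_e,
      ggplot2::aes(x = .data$xs, y = .data$ys, xend = .data$xe, yend = .data$ye),
      arrow = ggplot2::arrow(length = ggplot2::unit(2.5, "mm"), ends = "both"))
  }
  p +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$focal), size = 3) +
    ggplot2::geom_text(data = lay,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$id),
                       vjust = -1, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::theme_void()
}
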