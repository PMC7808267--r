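#' Plot sequence-level summaries
#'
#' `type = "d"` draws the design diagram: entry, stage-1 treatment nodes,
#' intermediate-evaluation nodes and stage-2 treatment nodes, with distinct
#' markers for treatment assignments and evaluations.  `type = "s"` draws the
#' outcome summary: box plots of the primary outcome by treatment sequence
#' for the gaussian family, or bar charts of the response proportion for the
#' binomial family, optionally with a reference line at the overall mean.
#'
#' @param x a [seqmeans()] object.
#' @param type `"d"` (design diagram) or `"s"` (summary graph).
#' @param title,xlab,ylab plot annotation.
#' @param color fill color for the summary graph.
#' @param reference logical; add a reference line at the overall outcome
#'   mean (summary graph only).
#' @param legend two labels for the diagram's node kinds (evaluation,
#'   treatment).
#' @param ... unused.
#' @return A `ggplot` object.
#' @export
plot.seqmeans <- function(x, type = c("s", "d"), title = NULL,
                          xlab = NULL, ylab = NULL, color = "grey80",
                          reference = TRUE,
                          legend = c("Intermediate evaluation",
                                     "Stage-specific treatment"), ...) {
  type <- match.arg(type)
  if (type == "d") return(design_diagram(x, title = title, legend = legend))
  data <- attr(x, "data")
  family <- attr(x, "family")
  seqlab <- paste0("(", x$A1, ",", x$O2, ",", x$A2, ")")
  key <- paste(x$A1, x$O2, x$A2)
  data$SEQ <- factor(seqlab[match(paste(data$A1, data$O2, data$A2), key)],
                     levels = seqlab)
  p <- if (family == "binomial") {
    ggplot2::ggplot(x, ggplot2::aes(x = factor(seqlab, levels = seqlab),
                                    y = .data$MEAN)) +
      ggplot2::geom_col(fill = color, color = "grey30")
  } else {
    ggplot2::ggplot(data, ggplot2::aes(x = .data$SEQ, y = .data$Y)) +
      ggplot2::geom_boxplot(fill = color)
  }
  if (reference)
    p <- p + ggplot2::geom_hline(yintercept = mean(data$Y),
                                 linetype = "dashed", color = "grey40")
  p + ggplot2::labs(title = title,
                    x = xlab %||% "Treatment sequence (A1,O2,A2)",
                    y = ylab %||% if (family == "binomial")
                      "Response proportion" else "Primary outcome") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# node/edge layout of the two-stage design tree
diagram_layout <- function(design) {
  nodes <- data.frame(x = 0, y = 0, label = "Entry", kind = "evaluation")
  edges <- data.frame(x = numeric(0), y = numeric(0),
                      xend = numeric(0), yend = numeric(0))
  arms <- design$arms
  leaf_y <- 0
  arm_rows <- list()
  # place leaves first: one per sequence, stacked
  tab <- design$sim
  tab$y <- rev(seq_len(nrow(tab)))
  tab$y <- tab$y - mean(tab$y)
  for (a in arms) {
    aa <- as.character(a)
    rows_a <- tab[tab$A1 == a, , drop = FALSE]
    y_arm <- mean(rows_a$y)
    nodes <- rbind(nodes, data.frame(x = 1, y = y_arm,
                                     label = paste0("A1=", a),
                                     kind = "treatment"))
    edges <- rbind(edges, data.frame(x = 0, y = 0, xend = 1, yend = y_arm))
    for (r in design$categories[[aa]]) {
      rows_b <- rows_a[rows_a$O2 == r, , drop = FALSE]
      y_br <- mean(rows_b$y)
      nodes <- rbind(nodes, data.frame(x = 2, y = y_br,
                                       label = paste0("O2=", r),
                                       kind = "evaluation"))
      edges <- rbind(edges, data.frame(x = 1, y = y_arm,
                                       xend = 2, yend = y_br))
      for (i in seq_len(nrow(rows_b))) {
        nodes <- rbind(nodes, data.frame(x = 3, y = rows_b$y[i],
                                         label = paste0("A2=", rows_b$A2[i]),
                                         kind = "treatment"))
        edges <- rbind(edges, data.frame(x = 2, y = y_br,
                                         xend = 3, yend = rows_b$y[i]))
      }
    }
  }
  list(nodes = nodes, edges = edges)
}

design_diagram <- function(x, title = NULL,
                           legend = c("Intermediate evaluation",
                                      "Stage-specific treatment")) {
  design <- if (inherits(x, "smart_design")) x else
    design_from_data(attr(x, "data"))
  lay <- diagram_layout(design)
  lay$nodes$kind <- factor(lay$nodes$kind,
                           levels = c("evaluation", "treatment"),
                           labels = legend)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = lay$edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          color = "grey60") +
    ggplot2::geom_point(data = lay$nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$kind), size = 3) +
    ggplot2::geom_text(data = lay$nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       vjust = -1, size = 3) +
    ggplot2::scale_shape_manual(values = c(18, 19), name = NULL) +
    ggplot2::labs(title = title, x = "Stage", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Forest plot of estimated strategy values
#'
#' Shows each strategy's estimated value with its confidence interval.
#'
#' @param x an [atsmeans()] object.
#' @param title,xlab,ylab annotation.
#' @param reference optional x-position for a vertical reference line.
#' @param ... unused.
#' @return A `ggplot` object.
#' @export
plot.atsmeans <- function(x, title = NULL, xlab = NULL, ylab = NULL,
                          reference = NULL, ...) {
  v <- x$value
  if (is.null(v$lower))
    stop("confidence limits are needed for the forest plot (conf = TRUE)")
  v$code <- factor(x$strategies$code, levels = rev(x$strategies$code))
  p <- ggplot2::ggplot(v, ggplot2::aes(x = .data$value, y = .data$code)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::labs(title = title,
                  x = xlab %||% "Estimated strategy value",
                  y = ylab %||% "Strategy (d0; d00, d01)") +
    ggplot2::theme_minimal()
  if (!is.null(reference))
    p <- p + ggplot2::geom_vline(xintercept = reference,
                                 linetype = "dashed", color = "grey40")
  p
}
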