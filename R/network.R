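#' Pearson correlation matrix for one group's metabolite quantities
#'
#' @param quantities data.frame from [integrate_metabolites()] restricted to
#'   one group, or a plain samples x metabolites matrix; >= 3 samples and
#'   >= 2 metabolites.
#' @param eps SD floor below which a metabolite counts as constant; such
#'   metabolites get `NA` correlations and are recorded in attribute
#'   `"flagged_constant"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(quantities, eps = 1e-12) {
  if (is.data.frame(quantities)) {
    mets <- setdiff(names(quantities), c("sample_id", "group"))
    M <- as.matrix(quantities[, mets, drop = FALSE])
  } else {
    M <- as.matrix(quantities)
  }
  if (nrow(M) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (ncol(M) < 2L) stop("need at least 2 metabolites", call. = FALSE)
  sds <- apply(M, 2, stats::sd)
  flagged <- colnames(M)[sds < eps]
  R <- suppressWarnings(stats::cor(M, method = "pearson"))
  if (length(flagged)) {
    R[flagged, ] <- NA_real_
    R[, flagged] <- NA_real_
  }
  diag(R) <- 1
  attr(R, "flagged_constant") <- flagged
  R
}

#' Build a thresholded correlation network
#'
#' Edges connect metabolite pairs with `|r|` strictly above the threshold
#' (default 0.6, the conventional cut for these networks). Edges carry the
#' coefficient, its sign (`"positive"`/`"negative"`, rendered warm/cool) and
#' a width proportional to `|r|`; nodes carry an optional direction
#' attribute (up/down vs reference) from supplied fold-change directions.
#'
#' @param matrix Symmetric correlation matrix (within 1e-10), e.g. from
#'   [pearson_matrix()]. Metabolites flagged constant (NA rows) get no edges.
#' @param threshold Absolute-correlation threshold, default 0.6.
#' @param direction_attributes Optional named vector (`"up"`/`"down"`) per
#'   metabolite.
#' @param group Optional group name stored on the network.
#' @return List of class `correlation_network`: `nodes` (data.frame `name`,
#'   `direction`), `edges` (data.frame `a`, `b`, `r`, `sign`, `width`),
#'   `group`, `threshold`.
#' @export
build_network <- function(matrix, threshold = 0.6, direction_attributes = NULL,
                          group = NA_character_) {
  M <- as.matrix(matrix)
  if (nrow(M) != ncol(M)) stop("matrix must be square", call. = FALSE)
  finite <- is.finite(M) & is.finite(t(M))
  if (any(abs(M - t(M))[finite] > 1e-10)) {
    stop("matrix must be symmetric within 1e-10", call. = FALSE)
  }
  mets <- colnames(M) %||% paste0("M", seq_len(ncol(M)))
  a <- character(0); b <- character(0); r <- numeric(0)
  for (i in seq_len(ncol(M) - 1L)) {
    for (j in (i + 1L):ncol(M)) {
      rij <- M[i, j]
      if (is.finite(rij) && abs(rij) > threshold) {
        a <- c(a, mets[i]); b <- c(b, mets[j]); r <- c(r, rij)
      }
    }
  }
  dir <- rep(NA_character_, length(mets))
  names(dir) <- mets
  if (!is.null(direction_attributes)) {
    known <- intersect(names(direction_attributes), mets)
    dir[known] <- direction_attributes[known]
  }
  structure(
    list(nodes = data.frame(name = mets, direction = unname(dir),
                            row.names = NULL),
         edges = data.frame(a = a, b = b, r = r,
                            sign = ifelse(r >= 0, "positive", "negative"),
                            width = abs(r), row.names = NULL),
         group = group, threshold = threshold),
    class = "correlation_network"
  )
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("<correlation_network>%s %d nodes, %d edges (|r| > %g)\n",
              if (is.na(x$group)) "" else paste0(" ", x$group),
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Degree centrality summary
#'
#' Degree per node with a descending rank (ties broken alphabetically),
#' making "central vs marginal" network language operational.
#'
#' @param network `correlation_network`.
#' @param top_k Rows to keep in the `top` element of the result attribute.
#' @return data.frame `name`, `degree`, `rank`, sorted by rank.
#' @export
centrality_summary <- function(network, top_k = 5) {
  nodes <- network$nodes$name
  deg <- stats::setNames(rep(0L, length(nodes)), nodes)
  if (nrow(network$edges)) {
    tab <- table(c(network$edges$a, network$edges$b))
    deg[names(tab)] <- as.integer(tab)
  }
  ord <- order(-deg, names(deg))
  out <- data.frame(name = names(deg)[ord], degree = unname(deg[ord]),
                    rank = seq_along(deg), row.names = NULL)
  attr(out, "top") <- utils::head(out, top_k)
  out
}

#' Export a correlation network
#'
#' `write_network_graphml()` writes GraphML via igraph (deterministic bytes
#' for a fixed network); `write_network_edgelist()` writes a TSV of
#' `a, b, r, sign`.
#'
#' @param network `correlation_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edgelist <- function(network, path) {
  utils::write.table(network$edges[, c("a", "b", "r", "sign")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a correlation network to an igraph object
#'
#' @param network `correlation_network`.
#' @return Undirected igraph graph with `r`, `sign`, `width` edge attributes
#'   and `direction` node attribute.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  g
}

#' Plot a correlation network
#'
#' Warm (positive) / cool (negative) edges with width proportional to |r|;
#' node color encodes the up/down direction attribute.
#'
#' @param x `correlation_network`.
#' @param seed Layout seed (deterministic placement).
#' @param ... Unused.
#' @return Invisibly, the igraph object plotted.
#' @export
plot.correlation_network <- function(x, seed = 1, ...) {
  g <- as_igraph(x)
  set.seed(seed)
  lay <- igraph::layout_with_fr(g)
  ecol <- ifelse(igraph::E(g)$sign == "positive", "#D6604D", "#4393C3")
  vcol <- ifelse(is.na(igraph::V(g)$direction), "grey80",
                 ifelse(igraph::V(g)$direction == "up", "#F4A582", "#92C5DE"))
  igraph::plot.igraph(g, layout = lay, edge.color = ecol,
                      edge.width = 1 + 3 * igraph::E(g)$width,
                      vertex.color = vcol, vertex.size = 8,
                      vertex.label.cex = 0.7)
  invisible(g)
}
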