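#' Compute NetExpress scores: network-weighted neighbor expression
#'
#' The NetExpress score of a gene in a given cell line is the sum, over the
#' gene's neighbors in a weighted gene-gene interaction network, of the
#' product of the edge confidence and the neighbor's expression value in that
#' cell line. It summarizes the expression context of a gene in its local
#' network neighborhood and is the cell-specific feature fed to the on-target
#' regression models.
#'
#' Neighbors missing from the expression profile contribute 0 by default
#' (`missing = "zero"`), the common case when the network and expression
#' gene universes differ; `missing = "error"` makes that strict.
#'
#' @param network Edge-list data frame with columns `gene_a`, `gene_b`,
#'   `confidence` (see [read_network()]); treated as undirected, duplicate
#'   edges collapsed to the maximum confidence.
#' @param expression Data frame with columns `gene`, `value`, and optionally
#'   `cell_line`; with several cell lines, scores are computed per cell line.
#' @param genes Genes to score; default all network nodes. Requesting a gene
#'   absent from the network is an error (distinct from an isolated node,
#'   which scores 0).
#' @param missing How to treat neighbors with no expression value.
#' @return A tibble with columns `gene`, `cell_line` (if present), `score`.
#' @examples
#' net <- tibble::tibble(gene_a = "A", gene_b = c("B", "C"),
#'                       confidence = c(0.5, 1))
#' expr <- tibble::tibble(gene = c("B", "C"), value = c(2, 3))
#' netexpress(net, expr)          # A scores 0.5*2 + 1*3 = 4
#' @export
netexpress <- function(network, expression, genes = NULL,
                       missing = c("zero", "error")) {
  missing <- match.arg(missing)
  network <- .validate_network(network)
  nodes <- union(network$gene_a, network$gene_b)
  genes <- genes %||% sort(nodes)
  unknown <- setdiff(genes, nodes)
  if (length(unknown) > 0) {
    abort(sprintf("Gene '%s' is not a node of the network.", unknown[1]))
  }
  if (!all(c("gene", "value") %in% names(expression))) {
    abort("`expression` needs columns `gene` and `value`.")
  }
  if (!all(is.finite(expression$value))) {
    abort("Expression values must be finite.")
  }
  # symmetric half-edges: each undirected edge seen from both endpoints
  half <- tibble(
    gene = c(network$gene_a, network$gene_b),
    neighbor = c(network$gene_b, network$gene_a),
    confidence = rep(network$confidence, 2)
  ) %>% filter(gene %in% genes)

  one_profile <- function(expr_tbl, cl) {
    vals <- setNames(expr_tbl$value, expr_tbl$gene)
    v <- vals[half$neighbor]
    if (missing == "error" && anyNA(v)) {
      abort(sprintf("Neighbor '%s' has no expression value.",
                    half$neighbor[which(is.na(v))[1]]))
    }
    n_missing <- sum(is.na(v))
    if (n_missing > 0) {
      inform(sprintf("NetExpress: %d neighbor lookups had no expression value; contributing 0.",
                     n_missing))
      v[is.na(v)] <- 0
    }
    agg <- rowsum(half$confidence * as.numeric(v), group = half$gene)
    out <- tibble(gene = genes, score = 0)
    hit <- match(rownames(agg), out$gene)
    out$score[hit] <- agg[, 1]
    if (!is.null(cl)) out <- mutate(out, cell_line = cl, .after = "gene")
    out
  }

  if ("cell_line" %in% names(expression)) {
    expression %>%
      group_by(cell_line) %>%
      dplyr::group_map(~ one_profile(.x, .y$cell_line)) %>%
      bind_rows()
  } else {
    one_profile(expression, NULL)
  }
}

#' @rdname netexpress
#' @param gene A single gene identifier.
#' @return `compute_netexpress()` returns the numeric score for one gene.
#' @export
compute_netexpress <- function(gene, network, expression,
                               missing = c("zero", "error")) {
  netexpress(network, expression, genes = gene, missing = missing)$score
}

.validate_network <- function(network) {
  if (!all(c("gene_a", "gene_b", "confidence") %in% names(network))) {
    abort("`network` needs columns `gene_a`, `gene_b`, `confidence`.")
  }
  if (any(!is.finite(network$confidence) | network$confidence <= 0)) {
    abort("Edge confidences must be finite and > 0.")
  }
  if (any(network$gene_a == network$gene_b)) {
    abort("Self-loops are not allowed in the gene network.")
  }
  # undirected: canonical node order, duplicates collapsed to max confidence
  a <- pmin(network$gene_a, network$gene_b)
  b <- pmax(network$gene_a, network$gene_b)
  tibble(gene_a = a, gene_b = b, confidence = network$confidence) %>%
    group_by(gene_a, gene_b) %>%
    summarise(confidence = max(confidence), .groups = "drop")
}
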