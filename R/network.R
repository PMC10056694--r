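# Thresholded correlation networks: top-fraction edge selection, two-group
# merging, degrees, and Cytoscape-compatible export/import.

#' Build a thresholded correlation network
#'
#' Retains the `ceiling(topFraction * nEligible)` strongest correlations as
#' weighted edges. Eligible pairs are the finite entries of the matrix (all
#' row-column pairs for a bipartite matrix, the upper triangle for a square
#' symmetric one); `positiveOnly` drops negative correlations before
#' ranking. "Strongest" means largest signed value (model-based
#' correlations are non-negative by construction); set `absolute = TRUE` to
#' rank by magnitude for signed methods. All values tied with the cutoff are
#' included, so the realised edge count can exceed the ceiling rule by ties.
#'
#' @param corr a [CorrMatrix-class] or numeric matrix with dimnames.
#' @param topFraction fraction of eligible pairs to keep, in (0, 1].
#' @param positiveOnly drop negative correlations before ranking.
#' @param absolute rank by absolute value.
#' @param group optional group tag recorded on every edge ("groupA" or
#'   "groupB").
#' @param rowLayer,colLayer node layer labels (e.g. "species",
#'   "metabolite") recorded in the node table.
#' @return an [EdgeList-class].
#' @export
buildNetwork <- function(corr, topFraction = 0.30, positiveOnly = FALSE,
                         absolute = FALSE, group = NA_character_,
                         rowLayer = "feature", colLayer = rowLayer) {
  stopifnot(topFraction > 0, topFraction <= 1)
  method <- if (methods::is(corr, "CorrMatrix")) corr@method else "matrix"
  m <- if (methods::is(corr, "CorrMatrix")) corr@values else as.matrix(corr)
  if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  square <- nrow(m) == ncol(m) && identical(rownames(m), colnames(m))
  if (square) {
    idx <- which(upper.tri(m), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(
      row = seq_len(nrow(m)),
      col = seq_len(ncol(m))
    ))
  }
  w <- m[idx]
  keep <- is.finite(w)
  if (positiveOnly) keep <- keep & w >= 0
  idx <- idx[keep, , drop = FALSE]
  w <- w[keep]
  nodeTable <- .networkNodes(m, square, rowLayer, colLayer)
  if (length(w) == 0) {
    return(.newEdgeList(.emptyEdges(), nodeTable))
  }
  score <- if (absolute) abs(w) else w
  nKeep <- ceiling(topFraction * length(w))
  cutoff <- sort(score, decreasing = TRUE)[nKeep]
  sel <- score >= cutoff # ties at the cutoff are all included
  edges <- data.frame(
    source = rownames(m)[idx[sel, 1L]],
    target = colnames(m)[idx[sel, 2L]],
    weight = w[sel], method = method, group = group,
    stringsAsFactors = FALSE
  )
  edges <- edges[order(-edges$weight, edges$source, edges$target), ]
  rownames(edges) <- NULL
  .newEdgeList(edges, nodeTable)
}

.emptyEdges <- function() {
  data.frame(
    source = character(0), target = character(0), weight = numeric(0),
    method = character(0), group = character(0), stringsAsFactors = FALSE
  )
}

.networkNodes <- function(m, square, rowLayer, colLayer) {
  if (square) {
    data.frame(
      id = rownames(m), layer = rowLayer,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      id = c(rownames(m), colnames(m)),
      layer = c(
        rep(rowLayer, nrow(m)),
        rep(colLayer, ncol(m))
      ),
      stringsAsFactors = FALSE
    )
  }
}

.newEdgeList <- function(edges, nodes) {
  methods::new("EdgeList", edgeTable = edges, nodeTable = nodes)
}

#' @describeIn buildNetwork the edge table
#' @param object an [EdgeList-class]
#' @export
setMethod("edges", "EdgeList", function(object) object@edgeTable)

#' @describeIn buildNetwork the node table
#' @export
setMethod("nodes", "EdgeList", function(object) object@nodeTable)

setMethod("show", "EdgeList", function(object) {
  cat(sprintf(
    "EdgeList: %d edges over %d nodes\n", nrow(object@edgeTable),
    nrow(object@nodeTable)
  ))
  if (nrow(object@edgeTable)) {
    print(table(group = object@edgeTable$group, useNA = "ifany"))
  }
})

.edgeKey <- function(e) {
  paste(pmin(e$source, e$target), pmax(e$source, e$target), sep = "\r")
}

#' Merge the networks of two sample groups
#'
#' Union of the two edge sets over a shared node universe; an edge present
#' in both inputs is tagged "both" (its weight is the mean of the two
#' group weights, kept individually in `weightA`/`weightB`), otherwise it
#' keeps its group of origin ("groupA" or "groupB").
#'
#' @param netA,netB [EdgeList-class] objects (e.g. healthy and diseased
#'   group networks built with the same per-group top fraction).
#' @return an [EdgeList-class] with group tags and per-group weights.
#' @export
mergeGroupNetworks <- function(netA, netB) {
  eA <- netA@edgeTable
  eB <- netB@edgeTable
  kA <- .edgeKey(eA)
  kB <- .edgeKey(eB)
  shared <- intersect(kA, kB)
  onlyA <- eA[!(kA %in% shared), , drop = FALSE]
  onlyB <- eB[!(kB %in% shared), , drop = FALSE]
  both <- eA[match(shared, kA), , drop = FALSE]
  if (nrow(onlyA)) onlyA$group <- "groupA"
  if (nrow(onlyB)) onlyB$group <- "groupB"
  onlyA[["weightA"]] <- onlyA$weight
  onlyA[["weightB"]] <- rep(NA_real_, nrow(onlyA))
  onlyB[["weightA"]] <- rep(NA_real_, nrow(onlyB))
  onlyB[["weightB"]] <- onlyB$weight
  both[["weightA"]] <- both$weight
  both[["weightB"]] <- eB$weight[match(shared, kB)]
  if (nrow(both)) {
    both$group <- "both"
    both$weight <- (both$weightA + both$weightB) / 2
  }
  edges <- rbind(both, onlyA, onlyB)
  rownames(edges) <- NULL
  nodes <- unique(rbind(netA@nodeTable, netB@nodeTable))
  rownames(nodes) <- NULL
  .newEdgeList(edges, nodes)
}

#' Node degree table of a network
#'
#' @param net an [EdgeList-class].
#' @return data.frame with columns `node`, `degree` and, when group tags are
#'   present, `degreeA` / `degreeB` (edges tagged "both" count in both).
#' @export
nodeDegrees <- function(net) {
  e <- net@edgeTable
  if (nrow(e) == 0) {
    return(data.frame(
      node = character(0), degree = integer(0),
      degreeA = integer(0), degreeB = integer(0)
    ))
  }
  ends <- c(e$source, e$target)
  grp <- rep(e$group, 2L)
  nodesAll <- sort(unique(ends))
  deg <- as.integer(table(factor(ends, levels = nodesAll)))
  inA <- grp %in% c("groupA", "both")
  inB <- grp %in% c("groupB", "both")
  degA <- as.integer(table(factor(ends[inA], levels = nodesAll)))
  degB <- as.integer(table(factor(ends[inB], levels = nodesAll)))
  data.frame(node = nodesAll, degree = deg, degreeA = degA, degreeB = degB)
}

#' Export a network to SIF, GraphML or edge-TSV
#'
#' `sif` writes Cytoscape simple-interaction lines
#' (`source<TAB>cc<TAB>target`) plus two sidecar TSVs, `<path>.nodes.tsv`
#' (node attributes) and `<path>.edges.tsv` (edge attributes, so the export
#' stays lossless). `graphml` goes through igraph with weight, group,
#' method and node-layer attributes. `edge_tsv` is a single TSV with node
#' attributes in `<path>.nodes.tsv`.
#'
#' @param net an [EdgeList-class].
#' @param format "sif", "graphml" or "edge_tsv".
#' @param path output file path.
#' @return invisibly, the main output path.
#' @export
exportNetwork <- function(net, format = c("edge_tsv", "sif", "graphml"),
                          path) {
  format <- match.arg(format)
  e <- net@edgeTable
  nd <- net@nodeTable
  tryCatch(
    switch(format,
      sif = {
        writeLines(paste(e$source, "cc", e$target, sep = "\t"), path)
        write.table(e, paste0(path, ".edges.tsv"),
          sep = "\t",
          quote = FALSE, row.names = FALSE
        )
        write.table(nd, paste0(path, ".nodes.tsv"),
          sep = "\t",
          quote = FALSE, row.names = FALSE
        )
      },
      graphml = {
        e2 <- e
        e2$group[is.na(e2$group)] <- "" # graphml has no NA
        g <- igraph::graph_from_data_frame(
          d = e2, directed = FALSE,
          vertices = nd
        )
        igraph::write_graph(g, path, format = "graphml")
      },
      edge_tsv = {
        write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(nd, paste0(path, ".nodes.tsv"),
          sep = "\t",
          quote = FALSE, row.names = FALSE
        )
      }
    ),
    error = function(err) {
      stop("export to ", path, " failed: ", conditionMessage(err),
        call. = FALSE
      )
    }
  )
  invisible(path)
}

#' Import a network written by [exportNetwork()]
#'
#' @param path file path given to the exporter.
#' @param format the format it was written in.
#' @return an [EdgeList-class].
#' @export
importNetwork <- function(path, format = c("edge_tsv", "sif", "graphml")) {
  format <- match.arg(format)
  readTsv <- function(p) {
    read.delim(p, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    e <- igraph::as_data_frame(g, what = "edges")
    v <- igraph::as_data_frame(g, what = "vertices")
    # the original identifiers are the vertex names; reading graphml adds an
    # "id" attribute holding igraph's internal XML node ids, which we drop
    v$id <- NULL
    grp <- e$group
    grp[grp == ""] <- NA_character_
    edges <- data.frame(
      source = e$from, target = e$to, weight = e$weight,
      method = e$method, group = grp, stringsAsFactors = FALSE
    )
    extra <- setdiff(names(e), c("from", "to", "weight", "method", "group"))
    for (col in extra) edges[[col]] <- e[[col]]
    nodes <- data.frame(id = v$name, stringsAsFactors = FALSE)
    for (col in setdiff(names(v), "name")) nodes[[col]] <- v[[col]]
    return(.newEdgeList(edges, nodes))
  }
  edgePath <- if (format == "sif") paste0(path, ".edges.tsv") else path
  edges <- readTsv(edgePath)
  if ("group" %in% names(edges)) {
    edges$group <- as.character(edges$group)
  } else {
    edges$group <- NA_character_
  }
  nodes <- readTsv(paste0(path, ".nodes.tsv"))
  .newEdgeList(edges, nodes)
}
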