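new_mi_network <- function(nodes, edges, mode, metadata = list()) {
  structure(list(nodes = nodes, edges = edges, mode = mode,
                 metadata = metadata),
            class = "mi_network")
}

edge_type_of <- function(roles, src, dst) {
  paste(roles[src], roles[dst], sep = "-")
}

#' Reconstruct a network from a thresholded mutual information matrix
#'
#' Retains exactly the MIM entries whose MI strictly exceeds the threshold
#' \eqn{I_0} as edges weighted by their MI; entries at or below the threshold
#' are considered statistically insignificant and discarded. All variables
#' stay in the node list; nodes left without any edge get provenance
#' `"none"`. In full mode each unordered pair is considered once and edges
#' are typed `input-input`, `input-output` or `output-output` (output-output
#' edges are computed and flagged but excluded from default edge rankings,
#' which are input-centric).
#'
#' @param mim an `mi_matrix` from [compute_mim()].
#' @param threshold positive MI threshold \eqn{I_0}, e.g. from
#'   [threshold_for_pvalue()].
#' @param roles optional named role vector for the variables; inferred from
#'   the MIM layout in bipartite mode (rows are inputs, columns outputs).
#'   Required for full mode if role typing of edges is wanted; defaults to
#'   `"input"` for all.
#' @param dataset_label provenance label attached to nodes and edges.
#' @return An object of class `mi_network`: list with `nodes` (data.frame
#'   `name`, `role`, `provenance`), `edges` (data.frame `source`, `target`,
#'   `weight` in nats, `edge_type`, `provenance`), `mode` and `metadata`
#'   (bandwidth, threshold, label).
#' @export
reconstruct <- function(mim, threshold, roles = NULL,
                        dataset_label = mim$dataset_label) {
  stopifnot(inherits(mim, "mi_matrix"))
  check_positive_scalar(threshold, "threshold")
  v <- mim$values
  rn <- rownames(v); cn <- colnames(v)
  if (mim$mode == "bipartite") {
    if (is.null(roles))
      roles <- stats::setNames(c(rep("input", length(rn)),
                                 rep("output", length(cn))), c(rn, cn))
    node_names <- c(rn, cn)
    idx <- which(!is.na(v) & pmax(v, 0) > threshold, arr.ind = TRUE)
    edges <- data.frame(source = rn[idx[, 1]], target = cn[idx[, 2]],
                        weight = v[idx], stringsAsFactors = FALSE)
  } else {
    node_names <- rn
    if (is.null(roles)) roles <- stats::setNames(rep("input", length(rn)), rn)
    ut <- upper.tri(v)
    idx <- which(ut & !is.na(v) & pmax(v, 0) > threshold, arr.ind = TRUE)
    edges <- data.frame(source = rn[idx[, 1]], target = cn[idx[, 2]],
                        weight = v[idx], stringsAsFactors = FALSE)
  }
  roles <- roles[node_names]
  if (anyNA(roles)) stop("roles missing for some MIM variables")
  if (nrow(edges)) {
    edges$edge_type <- edge_type_of(roles, edges$source, edges$target)
    # orient role-mixed edges input -> output for readability
    flip <- edges$edge_type == "output-input"
    if (any(flip)) {
      tmp <- edges$source[flip]
      edges$source[flip] <- edges$target[flip]
      edges$target[flip] <- tmp
      edges$edge_type[flip] <- "input-output"
    }
    edges$provenance <- dataset_label
    edges <- edges[order(-edges$weight, edges$source, edges$target), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), edge_type = character(),
                        provenance = character(), stringsAsFactors = FALSE)
  }
  connected <- unique(c(edges$source, edges$target))
  nodes <- data.frame(name = node_names, role = unname(roles),
                      provenance = ifelse(node_names %in% connected,
                                          dataset_label, "none"),
                      stringsAsFactors = FALSE)
  new_mi_network(nodes, edges, mim$mode,
                 list(h = mim$h, threshold = threshold,
                      n_observations = mim$n_observations,
                      dataset_label = dataset_label))
}

#' @export
print.mi_network <- function(x, ...) {
  cat(sprintf("mi_network (%s): %d nodes, %d edges", x$mode,
              nrow(x$nodes), nrow(x$edges)))
  if (!is.null(x$metadata$threshold))
    cat(sprintf(" (I0 = %.4f)", x$metadata$threshold))
  cat("\n")
  oo <- sum(x$edges$edge_type == "output-output")
  if (oo) cat(sprintf("  (%d output-output edges flagged)\n", oo))
  if (nrow(x$edges)) print(head(rank_edges(x), 10))
  invisible(x)
}

#' Combine two dataset-specific networks into one
#'
#' Takes the union of the edge sets of two networks of the same mode (e.g.
#' the networks reconstructed separately from Toll and non-Toll stimulation
#' data) and tags every node and edge with its provenance: the label of the
#' dataset it came from, or `"both"` for edges found in both networks and for
#' nodes carrying edges in both. An edge present in both networks keeps both
#' MI weights (columns `weight_<labelA>` and `weight_<labelB>`); the `weight`
#' column used for ranking holds the larger of the available weights.
#'
#' @param netA,netB `mi_network` objects of the same mode with consistent
#'   node roles.
#' @param labels length-2 character, the dataset labels (defaults taken from
#'   the networks' own metadata).
#' @return A combined `mi_network`; `metadata` stores both datasets'
#'   bandwidths and thresholds.
#' @export
combine_networks <- function(netA, netB, labels = NULL) {
  stopifnot(inherits(netA, "mi_network"), inherits(netB, "mi_network"))
  if (!identical(netA$mode, netB$mode)) stop("networks have different modes")
  if (is.null(labels))
    labels <- c(netA$metadata$dataset_label, netB$metadata$dataset_label)
  if (any(!nzchar(labels)) || labels[1] == labels[2])
    labels <- c("datasetA", "datasetB")
  shared <- intersect(netA$nodes$name, netB$nodes$name)
  ra <- stats::setNames(netA$nodes$role, netA$nodes$name)
  rb <- stats::setNames(netB$nodes$role, netB$nodes$name)
  bad <- shared[ra[shared] != rb[shared]]
  if (length(bad))
    stop("conflicting roles for node(s): ", paste(bad, collapse = ", "))

  ekey <- function(e, mode) {
    if (!nrow(e)) return(character())
    if (mode == "full") {
      a <- pmin(e$source, e$target); b <- pmax(e$source, e$target)
      paste(a, b, sep = "\r")
    } else paste(e$source, e$target, sep = "\r")
  }
  ka <- ekey(netA$edges, netA$mode); kb <- ekey(netB$edges, netB$mode)
  keys <- union(ka, kb)
  ia <- match(keys, ka); ib <- match(keys, kb)
  src <- ifelse(!is.na(ia), netA$edges$source[ia], netB$edges$source[ib])
  dst <- ifelse(!is.na(ia), netA$edges$target[ia], netB$edges$target[ib])
  et  <- ifelse(!is.na(ia), netA$edges$edge_type[ia], netB$edges$edge_type[ib])
  wa <- ifelse(!is.na(ia), netA$edges$weight[ia], NA_real_)
  wb <- ifelse(!is.na(ib), netB$edges$weight[ib], NA_real_)
  prov <- ifelse(!is.na(ia) & !is.na(ib), "both",
                 ifelse(!is.na(ia), labels[1], labels[2]))
  edges <- data.frame(source = src, target = dst,
                      weight = pmax(wa, wb, na.rm = TRUE),
                      edge_type = et, provenance = prov,
                      stringsAsFactors = FALSE)
  edges[[paste0("weight_", labels[1])]] <- wa
  edges[[paste0("weight_", labels[2])]] <- wb
  if (nrow(edges)) {
    edges <- edges[order(-edges$weight, edges$source, edges$target), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  node_names <- union(netA$nodes$name, netB$nodes$name)
  roles <- c(ra, rb[setdiff(names(rb), names(ra))])[node_names]
  inA <- node_names %in% c(netA$edges$source, netA$edges$target)
  inB <- node_names %in% c(netB$edges$source, netB$edges$target)
  nodes <- data.frame(name = node_names, role = unname(roles),
                      provenance = ifelse(inA & inB, "both",
                                   ifelse(inA, labels[1],
                                   ifelse(inB, labels[2], "none"))),
                      stringsAsFactors = FALSE)
  new_mi_network(nodes, edges, netA$mode,
                 list(labels = labels,
                      datasetA = netA$metadata, datasetB = netB$metadata))
}

#' Node-by-node network reconstruction
#'
#' Rebuilds the network one output at a time: for a chosen output variable
#' the MIM is restricted to that single output column, the permutation null
#' and the large-deviation threshold are recalibrated on that restriction,
#' and the output's star network is reconstructed. With `output_name = NULL`
#' every output is processed and the per-output stars are unioned, which
#' serves as a robustness check of the jointly calibrated network: the two
#' differ only for edges whose MI lies within calibration noise of the
#' threshold.
#'
#' @param data a [sample_matrix()].
#' @param output_name one output variable, or `NULL` for the union over all
#'   outputs.
#' @param h bandwidth (number or `bandwidth` object); `NULL` selects it via
#'   [select_bandwidth()].
#' @param p_value tail probability for the threshold (default 0.005).
#' @param n_permutations permutation rounds per output.
#' @param seed integer master seed.
#' @return An `mi_network` (bipartite); for the union, `metadata$per_output`
#'   stores each output's threshold.
#' @export
node_by_node <- function(data, output_name = NULL, h = NULL, p_value = 0.005,
                         n_permutations = 100L, seed = 1L) {
  stopifnot(inherits(data, "sample_matrix"))
  outs <- output_names(data)
  if (!length(outs)) stop("data has no output variables")
  if (!is.null(output_name)) {
    if (!output_name %in% outs) stop("unknown output variable: ", output_name)
    outs <- output_name
  }
  if (is.null(h))
    h <- select_bandwidth(data, seed = stage_seed(seed, "bandwidth"))
  if (inherits(h, "bandwidth")) h <- h$h
  nets <- vector("list", length(outs)); names(nets) <- outs
  thresholds <- stats::setNames(numeric(length(outs)), outs)
  for (k in seq_along(outs)) {
    keep <- c(input_names(data), outs[k])
    sub <- sample_matrix(data$values[, keep, drop = FALSE],
                         data$roles[keep], data$dataset_label)
    mim <- compute_mim(sub, "bipartite", h)
    cal <- calibrate_threshold(sub, "bipartite", h, p_value, n_permutations,
                               seed = stage_seed(seed, "null") + k)
    thresholds[k] <- cal$threshold
    nets[[k]] <- reconstruct(mim, cal$threshold)
  }
  if (length(nets) == 1L) {
    net <- nets[[1]]
    net$metadata$p_value <- p_value
    return(net)
  }
  edges <- do.call(rbind, lapply(nets, function(n) n$edges))
  rownames(edges) <- NULL
  if (nrow(edges))
    edges <- edges[order(-edges$weight, edges$source, edges$target), ,
                   drop = FALSE]
  node_names <- c(input_names(data), output_names(data))
  connected <- unique(c(edges$source, edges$target))
  lab <- data$dataset_label
  nodes <- data.frame(name = node_names,
                      role = unname(data$roles[node_names]),
                      provenance = ifelse(node_names %in% connected, lab,
                                          "none"),
                      stringsAsFactors = FALSE)
  new_mi_network(nodes, edges, "bipartite",
                 list(h = h, p_value = p_value, per_output = thresholds,
                      dataset_label = lab, node_by_node = TRUE))
}

#' Rank network edges by mutual information
#'
#' Sorts edges by descending MI weight, breaking ties lexicographically by
#' (source, target) so the ordering is stable across runs. The MI weight is
#' the measure of regulatory impact: the top edge is the strongest
#' statistical dependency in the network.
#'
#' @param net an `mi_network`.
#' @param include_output_output keep flagged output-output edges (default
#'   `FALSE`: rankings are input-centric).
#' @return The edge data.frame in rank order.
#' @export
rank_edges <- function(net, include_output_output = FALSE) {
  stopifnot(inherits(net, "mi_network"))
  e <- net$edges
  if (!nrow(e)) stop("network has no edges")
  if (!include_output_output) e <- e[e$edge_type != "output-output", , drop = FALSE]
  e <- e[order(-e$weight, e$source, e$target), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Export / import networks
#'
#' `write_edge_list()` writes a tab-separated edge list (`source`, `target`,
#' `mi_nats`) with `#` header lines recording mode and threshold;
#' `read_edge_list()` reads it back. `write_graphml()` exports the network
#' with node attributes `role`/`provenance` and edge attributes
#' `weight`/`provenance` for use in graph tools (e.g. Cytoscape).
#'
#' @param net an `mi_network`.
#' @param path file path.
#' @return `path` invisibly (writers); an `mi_network` (reader).
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "mi_network"))
  con <- file(path, "w"); on.exit(close(con))
  thr <- net$metadata$threshold
  writeLines(sprintf("# mode=%s threshold=%s", net$mode,
                     if (is.null(thr)) "NA" else format(thr, digits = 15)),
             con)
  writeLines("source\ttarget\tmi_nats", con)
  e <- net$edges
  if (nrow(e))
    writeLines(paste(e$source, e$target,
                     format(e$weight, digits = 15, trim = TRUE), sep = "\t"),
               con)
  invisible(path)
}

#' @rdname write_edge_list
#' @param roles optional named role vector for the nodes of the read network
#'   (default: all `"input"` unless a node only appears as a target, then
#'   `"output"`).
#' @export
read_edge_list <- function(path, roles = NULL) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!startsWith(hdr, "#")) stop("missing edge-list header line")
  kv <- strsplit(sub("^#\\s*", "", hdr), "\\s+")[[1]]
  meta <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  mode <- meta[["mode"]]
  thr <- suppressWarnings(as.numeric(meta[["threshold"]]))
  body <- utils::read.delim(text = paste(lines[-1], collapse = "\n"),
                            check.names = FALSE,
                            colClasses = c("character", "character", "numeric"))
  node_names <- unique(c(body$source, body$target))
  if (is.null(roles)) {
    only_target <- setdiff(body$target, body$source)
    roles <- stats::setNames(ifelse(node_names %in% only_target, "output",
                                    "input"), node_names)
  }
  edges <- data.frame(source = body$source, target = body$target,
                      weight = body$mi_nats,
                      stringsAsFactors = FALSE)
  if (nrow(edges)) {
    edges$edge_type <- edge_type_of(roles, edges$source, edges$target)
    edges$provenance <- ""
  } else {
    edges$edge_type <- character(); edges$provenance <- character()
  }
  nodes <- data.frame(name = node_names, role = unname(roles[node_names]),
                      provenance = "", stringsAsFactors = FALSE)
  new_mi_network(nodes, edges, mode,
                 list(threshold = if (is.finite(thr)) thr else NULL))
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "mi_network"))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, nrow(net$nodes), name = net$nodes$name,
                            role = net$nodes$role,
                            provenance = net$nodes$provenance)
  if (nrow(net$edges)) {
    idx <- rbind(match(net$edges$source, net$nodes$name),
                 match(net$edges$target, net$nodes$name))
    g <- igraph::add_edges(g, as.vector(idx),
                           weight = net$edges$weight,
                           edge_type = net$edges$edge_type,
                           provenance = net$edges$provenance)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
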