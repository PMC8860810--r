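#' Inverse-weight distance graph of a network
#'
#' Converts the edge-weight matrix to the distance representation used by
#' shortest-pathways analysis: `D_ij = 1 / |W_ij|` where `|W_ij| > 1e-8`, and
#' no edge (infinite distance) otherwise. The absolute value is taken because
#' negative partial correlations still transmit association; stronger edges
#' are shorter.
#'
#' @param net a `pcor_network`, or a plain symmetric weight matrix with
#'   dimnames.
#' @param unweighted if TRUE every present edge gets distance 1, so path
#'   length is the hop count.
#' @return Object of class `distance_graph`: list with `D` (p x p, `Inf` for
#'   absent edges, `NA` diagonal), `W` (signed weights), `node_names`,
#'   `unweighted`.
#' @export
to_distance_graph <- function(net, unweighted = FALSE) {
  W <- if (inherits(net, "pcor_network")) net$W else as.matrix(net)
  nm <- colnames(W)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(W)))
  present <- abs(W) > 1e-8
  D <- matrix(Inf, nrow(W), ncol(W), dimnames = list(nm, nm))
  D[present] <- if (unweighted) 1 else 1 / abs(W[present])
  diag(D) <- NA_real_
  structure(list(D = D, W = W, node_names = nm, unweighted = unweighted),
            class = "distance_graph")
}

#' Single-source shortest distances with full predecessor sets
#'
#' Dijkstra's algorithm on the undirected positive-distance graph. For every
#' node the complete set of predecessors on co-optimal shortest paths is
#' retained, so all equally short routes are recoverable, not just one.
#' Unreachable nodes get infinite distance and an empty predecessor set.
#'
#' @param D a [to_distance_graph()] result, or a symmetric distance matrix
#'   (`Inf` = absent edge).
#' @param source node name or index.
#' @return List with `dist` (named numeric), `pred` (named list of integer
#'   predecessor vectors), `source`.
#' @export
dijkstra <- function(D, source) {
  if (inherits(D, "distance_graph")) D <- D$D
  p <- ncol(D)
  nm <- colnames(D)
  if (is.character(source)) {
    s <- match(source, nm)
    if (is.na(s)) {
      stop("unknown node '", source, "'; valid nodes: ",
           paste(nm, collapse = ", "))
    }
  } else {
    s <- as.integer(source)
    if (s < 1 || s > p) stop("source index out of range")
  }
  dist <- rep(Inf, p)
  dist[s] <- 0
  pred <- vector("list", p)
  visited <- rep(FALSE, p)
  for (step in seq_len(p)) {
    cand <- which(!visited & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    visited[u] <- TRUE
    for (v in which(is.finite(D[u, ]))) {
      if (visited[v]) next
      alt <- dist[u] + D[u, v]
      if (alt < dist[v] - 1e-12) {
        dist[v] <- alt
        pred[[v]] <- u
      } else if (abs(alt - dist[v]) <= 1e-12) {
        pred[[v]] <- sort(unique(c(pred[[v]], u)))
      }
    }
  }
  names(dist) <- nm
  names(pred) <- nm
  list(dist = dist, pred = pred, source = nm[s])
}

# enumerate all co-optimal node sequences source -> target from predecessor
# sets; returns a list of integer vectors, deterministically ordered
collect_paths <- function(pred, s, t) {
  if (t == s) return(list(s))
  if (is.null(pred[[t]])) return(list())
  out <- list()
  for (u in pred[[t]]) {
    for (head in collect_paths(pred, s, u)) {
      out[[length(out) + 1L]] <- c(head, t)
    }
  }
  # deterministic order by the node-index sequence
  key <- vapply(out, function(v) paste(sprintf("%04d", v), collapse = "."), "")
  out[order(key)]
}

#' Shortest pathways between maltreatment and symptom nodes
#'
#' For every (source, target) pair, finds all co-optimal shortest routes on
#' the inverse-weight distance graph, with the signed edge weights along each
#' route. Defaults trace each of the five CTQ maltreatment nodes to the two
#' ED-specific symptoms (body dissatisfaction and bulimia). Unreachable pairs
#' are flagged, not errors. The union of all route edges — the
#' "shortest-pathway network" — is returned alongside the per-pair results.
#'
#' @param net a `pcor_network` (or weight matrix with dimnames).
#' @param sources,targets node-name vectors; disjoint. Defaults: the CM nodes
#'   present in the network, and `body_dissatisfaction` + `bulimia`.
#' @param unweighted passed to [to_distance_graph()].
#' @return Object of class `pathway_set`: list of per-pair results (each with
#'   `source`, `target`, `distance`, `hops`, `paths` — a list of node-name
#'   vectors — `edges` — per path, a data.frame of constituent edges with
#'   signed weights — and `reachable`), plus `union_edges` (data.frame of
#'   edges on any shortest pathway) and `node_names`.
#' @export
#' @examples
#' spec <- planted_topology_spec("BN", n_subjects = 2000, seed = 5)
#' net <- estimate_network(generate_dataset(spec))
#' pw <- shortest_pathways(net)
#' pw
shortest_pathways <- function(net, sources = NULL, targets = NULL,
                              unweighted = FALSE) {
  dg <- to_distance_graph(net, unweighted = unweighted)
  nm <- dg$node_names
  if (is.null(sources)) {
    sources <- if (inherits(net, "pcor_network") && !is.null(net$variable_role)) {
      nm[net$variable_role[nm] == "CM"]
    } else intersect(cm_nodes(), nm)
  }
  if (is.null(targets)) targets <- intersect(ed_specific_nodes(), nm)
  if (!length(sources) || !length(targets)) {
    stop("`sources` and `targets` must be nonempty")
  }
  bad <- setdiff(c(sources, targets), nm)
  if (length(bad)) {
    stop("unknown node(s): ", paste(bad, collapse = ", "),
         "; valid nodes: ", paste(nm, collapse = ", "))
  }
  if (length(intersect(sources, targets))) {
    stop("`sources` and `targets` must be disjoint")
  }

  results <- list()
  union_key <- character()
  for (src in sources) {
    sp <- dijkstra(dg, src)
    s <- match(src, nm)
    for (tgt in targets) {
      t <- match(tgt, nm)
      if (!is.finite(sp$dist[t])) {
        results[[paste(src, tgt, sep = "->")]] <- list(
          source = src, target = tgt, distance = Inf, hops = NA_integer_,
          paths = list(), edges = list(), reachable = FALSE)
        next
      }
      idx_paths <- collect_paths(sp$pred, s, t)
      paths <- lapply(idx_paths, function(v) nm[v])
      edges <- lapply(idx_paths, function(v) {
        i <- v[-length(v)]; j <- v[-1]
        data.frame(from = nm[i], to = nm[j],
                   weight = dg$W[cbind(i, j)],
                   distance = dg$D[cbind(i, j)],
                   stringsAsFactors = FALSE)
      })
      for (e in edges) {
        union_key <- c(union_key, paste(pmin(e$from, e$to), pmax(e$from, e$to),
                                        sep = "|"))
      }
      results[[paste(src, tgt, sep = "->")]] <- list(
        source = src, target = tgt, distance = unname(sp$dist[t]),
        hops = length(idx_paths[[1]]) - 1L, paths = paths, edges = edges,
        reachable = TRUE)
    }
  }
  union_key <- unique(union_key)
  union_edges <- if (length(union_key)) {
    parts <- strsplit(union_key, "|", fixed = TRUE)
    data.frame(
      from = vapply(parts, `[`, "", 1), to = vapply(parts, `[`, "", 2),
      weight = mapply(function(a, b) dg$W[a, b],
                      vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2)),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(from = character(), to = character(), weight = numeric())
  }
  structure(list(pairs = results, union_edges = union_edges, node_names = nm,
                 sources = sources, targets = targets,
                 unweighted = unweighted),
            class = "pathway_set")
}

#' @export
print.pathway_set <- function(x, ...) {
  cat(sprintf("Shortest pathways: %d source(s) x %d target(s)%s\n",
              length(x$sources), length(x$targets),
              if (x$unweighted) " (unweighted hops)" else " (distance = 1/|w|)"))
  for (r in x$pairs) {
    if (!r$reachable) {
      cat(sprintf("  %s -> %s: unreachable\n", r$source, r$target))
    } else {
      cat(sprintf("  %s -> %s: distance %.2f, %d hop(s), %d route(s)\n",
                  r$source, r$target, r$distance, r$hops, length(r$paths)))
      for (pth in r$paths) cat("    ", paste(pth, collapse = " - "), "\n")
    }
  }
  invisible(x)
}

#' Does a shortest route traverse the given nodes?
#'
#' Convenience predicate over a [shortest_pathways()] result: TRUE when every
#' co-optimal route for the pair passes through all of `via` (in any
#' position).
#'
#' @param pw a `pathway_set`.
#' @param source,target node names.
#' @param via character vector of intermediate node names.
#' @return Logical; NA if the pair is unreachable.
#' @export
path_traverses <- function(pw, source, target, via) {
  r <- pw$pairs[[paste(source, target, sep = "->")]]
  if (is.null(r)) stop("pair not present in the pathway set")
  if (!r$reachable) return(NA)
  all(vapply(r$paths, function(pth) all(via %in% pth), logical(1)))
}

#' Export a network with shortest-pathway membership to GraphML
#'
#' Writes the full weighted network with a boolean edge attribute
#' `on_shortest_path` marking edges on any shortest pathway of interest (the
#' continuous-vs-dotted distinction of shortest-pathway figures).
#'
#' @param net a `pcor_network`.
#' @param pw a [shortest_pathways()] result for that network.
#' @param file output path.
#' @return The file path, invisibly.
#' @export
write_pathways_graphml <- function(net, pw, file) {
  g <- as_igraph(net)
  el <- igraph::as_edgelist(g)
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
  on_path <- key %in% paste(pmin(pw$union_edges$from, pw$union_edges$to),
                            pmax(pw$union_edges$from, pw$union_edges$to),
                            sep = "|")
  igraph::E(g)$on_shortest_path <- on_path
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}
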