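#' Build a transition-count network from a state series
#'
#' Counts ordered frame pairs (t, t+lag) with S(t) = i and S(t+lag) = j,
#' within trajectory segments only (no pairs across independent runs). The
#' diagonal self-transition count of a state is its population: states that
#' keep transitioning into themselves are conformationally stable.
#'
#' @param series a `state_series` from [project_trajectory()], or a plain
#'   integer vector of state ids (then `segments` applies).
#' @param segments optional two-column (start, end) matrix; defaults to the
#'   series' own segments, or one segment for a plain vector.
#' @param lag transition lag in frames (default 1).
#' @return An object of class `transition_network`: list with `counts`
#'   (dense S x S matrix), `populations` (diagonal), `states` (data frame of
#'   per-state binned key and raw descriptor means, when available),
#'   `lag`, `n_frames`, and empty slots for `communities` and `summary`.
#' @export
build_transition_matrix <- function(series, segments = NULL, lag = 1L) {
  if (inherits(series, "state_series")) {
    s <- series$states
    if (is.null(segments)) segments <- series$segments
    states_df <- series$key
    raw <- series$raw
  } else {
    s <- as.integer(series)
    if (anyNA(s) || any(s < 1)) stop("state ids must be positive integers")
    states_df <- data.frame(state = sort(unique(s)))
    raw <- NULL
  }
  if (is.null(segments)) segments <- matrix(c(1L, length(s)), 1)
  segments <- matrix(as.integer(segments), ncol = 2)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1 frame")
  if (any(segments[, 2] - segments[, 1] + 1L <= lag))
    stop("every segment must be longer than the lag (", lag, " frames)")
  ns <- max(s)
  counts <- matrix(0, ns, ns)
  for (k in seq_len(nrow(segments))) {
    a <- segments[k, 1]; b <- segments[k, 2]
    from <- s[a:(b - lag)]
    to <- s[(a + lag):b]
    tab <- table(factor(from, levels = 1:ns), factor(to, levels = 1:ns))
    counts <- counts + unclass(tab)
  }
  dimnames(counts) <- NULL
  if (!is.null(raw)) {
    agg <- stats::aggregate(raw[, c("Nalpha", "Nbeta", "dNC")],
                            by = list(state = s), FUN = mean)
    states_df <- merge(states_df, agg, by = "state", sort = TRUE)
  }
  structure(list(counts = counts, populations = diag(counts),
                 states = states_df, lag = lag, n_frames = length(s),
                 segments = segments, state_of_frame = s,
                 communities = NULL, summary = NULL),
            class = "transition_network")
}

#' @export
print.transition_network <- function(x, ...) {
  cat("Transition network: ", nrow(x$counts), " states, ",
      sum(x$counts) - sum(diag(x$counts)), " inter-state transitions, lag ",
      x$lag, "\n", sep = "")
  if (!is.null(x$communities))
    cat("  communities: ", length(unique(x$communities)), "\n", sep = "")
  invisible(x)
}

## Symmetrized off-diagonal weight matrix used for modularity.
symmetrized_weights <- function(counts) {
  w <- counts + t(counts)
  diag(w) <- 0
  w
}

## Newman modularity of a partition (membership vector) on a symmetric
## weight matrix with zero diagonal, with a resolution parameter.
modularity_matrix <- function(w, resolution = 1) {
  m2 <- sum(w)                      # 2m
  if (m2 == 0) return(matrix(0, nrow(w), ncol(w)))
  k <- rowSums(w)
  w / m2 - resolution * outer(k, k) / m2^2
}

modularity_value <- function(w, membership, resolution = 1) {
  if (sum(w) == 0) return(0)
  B <- modularity_matrix(w, resolution)
  sum(B[outer(membership, membership, "==")])
}

## Exhaustive modularity maximization by iterating restricted-growth
## strings (all set partitions). Feasible for n <= 10 (Bell(10) = 115975).
exact_modularity_partition <- function(w, resolution = 1) {
  n <- nrow(w)
  B <- modularity_matrix(w, resolution)
  qval <- function(a) sum(B[outer(a, a, "==")])
  best <- rep(1L, n); bestq <- qval(best)
  a <- rep(1L, n)           # restricted growth string, 1-based
  repeat {
    ## advance to next RGS
    i <- n
    while (i > 1L) {
      if (a[i] <= max(a[1:(i - 1)])) break
      i <- i - 1L
    }
    if (i == 1L) break
    a[i] <- a[i] + 1L
    if (i < n) a[(i + 1L):n] <- 1L
    q <- qval(a)
    if (q > bestq + 1e-12) { bestq <- q; best <- a }
  }
  list(membership = best, modularity = bestq)
}

#' Detect communities by modularity maximization
#'
#' Partitions the states of a transition network into communities by
#' maximizing Newman modularity on the symmetrized transition graph
#' (weight(i,j) = count(i,j) + count(j,i), self-loops excluded). Networks
#' with at most `exact_max_n` states are solved by exhaustive search over
#' all partitions, which provably attains the optimum; larger networks use
#' the Louvain algorithm (igraph) with a fixed seed for reproducibility.
#'
#' @param net a `transition_network`.
#' @param resolution modularity resolution parameter (1 = classic).
#' @param seed RNG seed for the Louvain passes.
#' @param exact_max_n largest state count solved exhaustively (default 10).
#' @return `net` with `communities` filled: integer labels 1..K, renumbered
#'   in order of first appearance over ascending state id.
#' @export
detect_communities <- function(net, resolution = 1, seed = 1L,
                               exact_max_n = 10L) {
  stopifnot(inherits(net, "transition_network"))
  n <- nrow(net$counts)
  if (n == 0) stop("empty network")
  w <- symmetrized_weights(net$counts)
  if (n == 1 || sum(w) == 0) {
    memb <- if (sum(w) == 0) seq_len(n) else rep(1L, n)
    if (n == 1) memb <- 1L
  } else if (n <= exact_max_n) {
    memb <- exact_modularity_partition(w, resolution)$membership
  } else {
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    memb <- as.integer(igraph::membership(cl))
  }
  memb <- match(memb, unique(memb))   # stable renumbering by state id
  net$communities <- memb
  net$modularity <- modularity_value(w, memb, resolution)
  net
}

#' Per-community average descriptors and population fractions
#'
#' Averages the raw (unbinned) descriptor values over all frames whose
#' state belongs to each community, and reports each community's population
#' fraction (frames in community / total frames). Fractions sum to 1.
#'
#' @param net a `transition_network` with communities assigned.
#' @param series the `state_series` the network was built from.
#' @return A data frame: community, n_states, n_frames, fraction, Nalpha,
#'   Nbeta, dNC (population-weighted means). Also stored in `net$summary`
#'   when assigned back.
#' @export
summarize_communities <- function(net, series) {
  if (is.null(net$communities)) stop("run detect_communities() first")
  s <- if (inherits(series, "state_series")) series$states else net$state_of_frame
  raw <- if (inherits(series, "state_series")) series$raw else NULL
  comm_of_frame <- net$communities[s]
  out <- data.frame(community = sort(unique(net$communities)))
  out$n_states <- as.integer(table(net$communities)[as.character(out$community)])
  tf <- table(factor(comm_of_frame, levels = out$community))
  out$n_frames <- as.integer(tf)
  out$fraction <- out$n_frames / length(s)
  if (!is.null(raw)) {
    for (v in c("Nalpha", "Nbeta", "dNC")) {
      out[[v]] <- as.numeric(tapply(raw[[v]], factor(comm_of_frame,
                                                     levels = out$community),
                                    mean))
    }
  }
  out
}

#' Linear node-size scale for network display
#'
#' Maps state populations to display sizes on a linear scale from 1 (least
#' populated) to 10 (most populated). When all populations are equal the
#' midpoint 5.5 is used for every node.
#'
#' @param populations numeric vector of node populations (>= 1 node).
#' @return Numeric vector of sizes in \[1, 10\].
#' @export
scale_node_sizes <- function(populations) {
  stopifnot(length(populations) >= 1)
  pmin <- min(populations); pmax <- max(populations)
  if (pmax == pmin) return(rep(5.5, length(populations)))
  1 + 9 * (populations - pmin) / (pmax - pmin)
}

network_igraph <- function(net) {
  n <- nrow(net$counts)
  idx <- which(net$counts > 0, arr.ind = TRUE)
  edges <- data.frame(from = idx[, 1], to = idx[, 2],
                      count = net$counts[idx])
  vert <- data.frame(name = as.character(seq_len(n)),
                     population = net$populations,
                     size = scale_node_sizes(net$populations))
  sdf <- net$states
  for (v in intersect(c("Nalpha", "Nbeta", "dNC", "dNC_bin"), names(sdf)))
    vert[[v]] <- sdf[[v]][match(seq_len(n), sdf$state)]
  if (!is.null(net$communities)) {
    vert$community <- net$communities
    summ <- net$summary
    if (is.null(summ) && !is.null(net$state_of_frame) && "Nalpha" %in% names(sdf))
      summ <- NULL
    if (!is.null(summ)) {
      m <- match(net$communities, summ$community)
      vert$comm_Nalpha <- summ$Nalpha[m]
      vert$comm_Nbeta <- summ$Nbeta[m]
      vert$comm_dNC <- summ$dNC[m]
    }
  }
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vert)
}

#' Export a transition network for Gephi or other graph tools
#'
#' Writes GEXF 1.3 (Gephi's native exchange format), GraphML, or a plain
#' CSV edge list. Node attributes carried: per-state descriptor values,
#' population (self-transition count), display size on the 1-10 linear
#' scale, and community label plus community-average descriptors when
#' available. The edge attribute is the directed transition count.
#'
#' @param net a `transition_network` (optionally with communities and a
#'   `summary` attached via `net$summary <- summarize_communities(...)`).
#' @param path output file.
#' @param format `"gexf"`, `"graphml"` or `"csv_edgelist"` (guessed from
#'   the extension when omitted).
#' @export
export_network <- function(net, path,
                           format = c("gexf", "graphml", "csv_edgelist")) {
  if (missing(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     gexf = "gexf", graphml = "graphml", "csv_edgelist")
  }
  format <- match.arg(format)
  g <- network_igraph(net)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "csv_edgelist") {
    idx <- which(net$counts > 0, arr.ind = TRUE)
    utils::write.csv(data.frame(source = idx[, 1], target = idx[, 2],
                                count = net$counts[idx]),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    write_gexf(g, path)
  }
  invisible(path)
}

## Minimal GEXF 1.3 writer (static directed weighted graph with typed node
## attributes). Gephi reads this directly.
write_gexf <- function(g, path) {
  va <- setdiff(igraph::vertex_attr_names(g), "name")
  vclass <- vapply(va, function(a)
    if (is.numeric(igraph::vertex_attr(g, a))) "double" else "string", "")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  xml_esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://gexf.net/1.3" version="1.3">')
  w('  <graph defaultedgetype="directed" mode="static">')
  w('    <attributes class="node">')
  for (i in seq_along(va))
    w(sprintf('      <attribute id="%d" title="%s" type="%s"/>',
              i - 1L, va[i], vclass[i]))
  w('    </attributes>')
  w('    <nodes>')
  ids <- igraph::V(g)$name
  for (v in seq_along(ids)) {
    w(sprintf('      <node id="%s" label="%s">', xml_esc(ids[v]),
              xml_esc(ids[v])))
    w('        <attvalues>')
    for (i in seq_along(va)) {
      val <- igraph::vertex_attr(g, va[i])[v]
      val <- if (is.numeric(val)) sprintf("%.17g", val) else xml_esc(val)
      w(sprintf('          <attvalue for="%d" value="%s"/>', i - 1L, val))
    }
    w('        </attvalues>')
    w('      </node>')
  }
  w('    </nodes>')
  w('    <edges>')
  el <- igraph::as_edgelist(g)
  cnt <- igraph::E(g)$count
  for (e in seq_len(nrow(el)))
    w(sprintf('      <edge id="%d" source="%s" target="%s" weight="%.17g"/>',
              e - 1L, xml_esc(el[e, 1]), xml_esc(el[e, 2]), cnt[e]))
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
}
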