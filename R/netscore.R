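# Functional-subnetwork extraction and affinity-weighted perturbation
# scoring (S_net) on a protein-protein interaction network.

#' Extract functional subnetworks from an interactome
#'
#' A functional subnetwork is a connected fraction of the interactome in
#' which all proteins share one functional annotation. For each term the
#' induced subgraph of its annotated nodes is taken and, when it is
#' disconnected, the largest connected component is kept (or every
#' component with `all_components = TRUE`). Terms with no node in the graph
#' are dropped.
#'
#' @param graph An undirected [igraph::graph] with named vertices.
#' @param term2nodes Named list: term id -> character vector of node names.
#' @param all_components Score every connected component instead of only
#'   the largest (components of one term are suffixed `#1`, `#2`, ...).
#' @return List of `functional_subnetwork` objects (`term`, `nodes`,
#'   `size`).
#' @export
extract_subnetworks <- function(graph, term2nodes, all_components = FALSE) {
  vn <- igraph::V(graph)$name
  out <- list()
  for (term in names(term2nodes)) {
    nodes <- intersect(term2nodes[[term]], vn)
    if (length(nodes) == 0L) next
    sub <- igraph::induced_subgraph(graph, nodes)
    comp <- igraph::components(sub)
    split_nodes <- split(igraph::V(sub)$name, comp$membership)
    if (all_components && comp$no > 1) {
      for (i in seq_along(split_nodes)) {
        nd <- split_nodes[[i]]
        out[[length(out) + 1L]] <- structure(
          list(term = paste0(term, "#", i), nodes = nd, size = length(nd)),
          class = "functional_subnetwork")
      }
    } else {
      nd <- split_nodes[[which.max(lengths(split_nodes))]]
      out[[length(out) + 1L]] <- structure(
        list(term = term, nodes = nd, size = length(nd)),
        class = "functional_subnetwork")
    }
  }
  out
}

#' Perturbation score of one functional subnetwork
#'
#' Scores the impact of a drug's weighted target set `T` on a subnetwork
#' with node set `V_f`:
#' \deqn{S_{net} = \Big(\sum_{t \in T \cap V_f} a_t +
#'   \sum_{t \in T \setminus V_f} a_t \, e(t, V_f)/\deg(t)\Big) / |V_f|}
#' where `a_t` is the drug's affinity for target `t` (in (0, 1]),
#' `e(t, V_f)` the number of edges from a peripheral target into the
#' subnetwork, and `deg(t)` its total degree. Direct members contribute
#' their full affinity; peripheral targets contribute in proportion to the
#' fraction of their interactions that point into the subnetwork; targets
#' of degree 0 contribute nothing peripherally.
#'
#' @param subnet A `functional_subnetwork` (or list with `term` and
#'   `nodes`).
#' @param affinities Named numeric vector of target affinities in (0, 1].
#' @param graph The interactome ([igraph::graph], named vertices).
#' @return A `subnetwork_score`: list with `term`, `n_nodes`, `n_targets`
#'   (targets touching the subnetwork directly or peripherally), `s_net`.
#' @export
s_net <- function(subnet, affinities, graph) {
  nodes <- subnet$nodes
  vn <- igraph::V(graph)$name
  targets <- names(affinities)
  direct <- intersect(targets, nodes)
  periph <- setdiff(intersect(targets, vn), nodes)
  score <- sum(affinities[direct])
  n_touch <- length(direct)
  for (t in periph) {
    dg <- igraph::degree(graph, t)
    if (dg == 0) next
    e_in <- sum(igraph::neighbors(graph, t)$name %in% nodes)
    if (e_in > 0) {
      score <- score + affinities[[t]] * e_in / dg
      n_touch <- n_touch + 1L
    }
  }
  structure(
    list(term = subnet$term, n_nodes = length(nodes),
         n_targets = n_touch, s_net = unname(score) / length(nodes)),
    class = "subnetwork_score"
  )
}

#' Rank functional subnetworks by perturbation score
#'
#' @param subnets List of `functional_subnetwork`s from
#'   [extract_subnetworks()].
#' @param affinities Named numeric vector of target affinities.
#' @param graph The interactome.
#' @return Data frame (`term`, `n_nodes`, `n_targets`, `s_net`) sorted by
#'   `s_net` descending, ties broken by term id.
#' @export
rank_perturbed <- function(subnets, affinities, graph) {
  stopifnot(length(subnets) >= 1)
  rows <- lapply(subnets, function(sn) {
    sc <- s_net(sn, affinities, graph)
    data.frame(term = sc$term, n_nodes = sc$n_nodes,
               n_targets = sc$n_targets, s_net = sc$s_net,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$s_net, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Interactions between drug targets and differential proteins
#'
#' All network edges with one endpoint in the target set and the other in
#' the differentially expressed set. Membership of a protein in both sets
#' does not by itself create a pair; a `(x, x)` pair is reported only for an
#' actual self-edge.
#'
#' @param targets Character vector of target accessions.
#' @param de_proteins Character vector of differentially expressed
#'   accessions.
#' @param graph The interactome ([igraph::graph], named vertices).
#' @return Data frame (`target`, `de_protein`), deduplicated and sorted.
#' @export
interaction_overlap <- function(targets, de_proteins, graph) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  pairs <- list()
  add <- function(t, d) pairs[[length(pairs) + 1L]] <<- c(t, d)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    if (a %in% targets && b %in% de_proteins) add(a, b)
    if (a != b && b %in% targets && a %in% de_proteins) add(b, a)
  }
  if (length(pairs) == 0L) {
    return(data.frame(target = character(), de_protein = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(data.frame(target = vapply(pairs, `[`, "", 1),
                           de_protein = vapply(pairs, `[`, "", 2),
                           stringsAsFactors = FALSE))
  out <- out[order(out$target, out$de_protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}
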