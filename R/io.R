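# Network and field serialization: GraphML (via igraph) plus flat CSV
# tables for interoperability; fields as plain CSV matrices.

#' Save a vessel network
#'
#' Writes GraphML (nodes: x, y, role, pressure; edges: radius, length,
#' class, flow, hematocrit, shear) and/or flat CSV node and segment tables.
#'
#' @param net A \code{vessel_network}.
#' @param graphml,nodes_csv,segments_csv Output paths (NULL to skip).
#' @return Invisibly, the network.
#' @export
save_network <- function(net, graphml = NULL, nodes_csv = NULL,
                         segments_csv = NULL) {
  nd <- network_nodes(net); sg <- network_segments(net)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = sg$node1, to = sg$node2, radius = sg$radius,
                     length = sg$length, class = sg$class, flow = sg$flow,
                     hematocrit = sg$hematocrit, shear = sg$shear,
                     upnode = sg$node1),   # records the flow sign convention
      directed = FALSE,
      vertices = data.frame(name = nd$id, x = nd$x, y = nd$y,
                            role = nd$role, pressure = nd$pressure))
    igraph::write_graph(g, graphml, format = "graphml")
  }
  if (!is.null(nodes_csv)) utils::write.csv(nd, nodes_csv, row.names = FALSE)
  if (!is.null(segments_csv))
    utils::write.csv(sg, segments_csv, row.names = FALSE)
  invisible(net)
}

#' Load a vessel network from GraphML
#'
#' Reads a network written by [save_network()]; inlet/outlet roles and all
#' segment attributes are restored. Lattice indexing is not retained (the
#' loaded network supports flow solves and particle injections, not
#' further angiogenic growth).
#'
#' @param graphml Path to a GraphML file.
#' @return A \code{vessel_network}.
#' @export
load_network <- function(graphml) {
  g <- igraph::read_graph(graphml, format = "graphml")
  vd <- igraph::as_data_frame(g, "vertices")
  ed <- igraph::as_data_frame(g, "edges")
  net <- new_network(NULL, cap_nodes = nrow(vd), cap_segs = nrow(ed))
  role_code <- c(interior = 0L, inlet = 1L, outlet = 2L)
  ids <- integer(nrow(vd))
  for (k in seq_len(nrow(vd)))
    ids[k] <- add_node(net, vd$x[k], vd$y[k], role = role_code[[vd$role[k]]])
  names(ids) <- vd$name
  for (k in seq_len(nrow(ed))) {
    id <- add_segment(net, ids[[ed$from[k]]], ids[[ed$to[k]]],
                      ed$radius[k], ed$length[k],
                      if (ed$class[k] == "pre") SEG_PRE else SEG_NEO)
    # igraph may normalize the endpoint order of undirected edges; restore
    # the signed-flow convention from the recorded upstream endpoint
    flip <- ids[[as.character(ed$upnode[k])]] != ids[[ed$from[k]]]
    net$sg_Q[id] <- if (flip) -ed$flow[k] else ed$flow[k]
    net$sg_H[id] <- ed$hematocrit[k]
    net$sg_S[id] <- ed$shear[k]
  }
  net$nd_p[seq_len(net$nn)] <- vd$pressure
  segs <- alive_segs(net)
  net$sg_mu[segs] <- apparent_viscosity(net$sg_R[segs], net$sg_H[segs])
  qmax <- max(abs(net$sg_Q[segs]))
  if (qmax > 0) net$sg_perfused[segs] <- abs(net$sg_Q[segs]) > 1e-8 * qmax
  net
}

#' Write a field matrix as CSV
#'
#' @param field An \code{nx} x \code{ny} matrix.
#' @param path Output path.
#' @export
write_field_csv <- function(field, path) {
  utils::write.table(field, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}

#' Export the per-day metrics table and per-segment day-24 table of a run
#'
#' @param sim A \code{nanovasc_sim}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_run <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "timeseries.csv")
  utils::write.csv(sim$history, paths[1], row.names = FALSE)
  for (d in names(sim$snapshots)) {
    sn <- sim$snapshots[[d]]
    p <- file.path(dir, sprintf("network_day%s.csv", d))
    utils::write.csv(network_segments(sn$net), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Hop distance of each perfused segment from the injection nodes
#'
#' Breadth-first distance along flow directions from the inlet nodes to
#' each perfused segment's upstream node; used to stratify accumulation
#' into upstream and downstream tumor vasculature.
#'
#' @param net A flow-solved \code{vessel_network}.
#' @return Named numeric vector over perfused live segment ids (Inf for
#'   segments not reachable from the inlets).
#' @export
flow_path_depth <- function(net) {
  segs <- alive_segs(net)
  w <- segs[net$sg_perfused[segs]]
  Q <- net$sg_Q[w]
  up <- ifelse(Q >= 0, net$sg_n1[w], net$sg_n2[w])
  dn <- ifelse(Q >= 0, net$sg_n2[w], net$sg_n1[w])
  g <- igraph::graph_from_edgelist(cbind(up, dn), directed = TRUE)
  if (igraph::vcount(g) < net$nn)
    g <- igraph::add_vertices(g, net$nn - igraph::vcount(g))
  d <- suppressWarnings(
    igraph::distances(g, v = inlet_nodes(net), mode = "out"))
  depth <- apply(d, 2, min)[up]
  names(depth) <- w
  depth
}
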