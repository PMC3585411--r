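# Vessel network container. Backed by an environment with preallocated
# column vectors so that the angiogenic random walk can append nodes and
# segments in O(1); lattice-resident nodes are indexed by a dense key table
# and edges by a hash for constant-time existence checks.

SEG_PRE <- 1L
SEG_NEO <- 2L

new_network <- function(lattice = NULL, cap_nodes = 256L, cap_segs = 256L) {
  net <- new.env(parent = emptyenv())
  net$nn <- 0L
  net$nd_ix <- integer(cap_nodes); net$nd_iy <- integer(cap_nodes)
  net$nd_x <- numeric(cap_nodes); net$nd_y <- numeric(cap_nodes)
  net$nd_role <- integer(cap_nodes)   # 0 interior, 1 inlet, 2 outlet
  net$nd_p <- numeric(cap_nodes)
  net$ns <- 0L
  for (f in c("sg_R", "sg_L", "sg_Q", "sg_H", "sg_mu", "sg_tau", "sg_S"))
    assign(f, numeric(cap_segs), envir = net)
  net$sg_n1 <- integer(cap_segs); net$sg_n2 <- integer(cap_segs)
  net$sg_class <- integer(cap_segs)
  net$sg_alive <- logical(cap_segs)
  net$sg_perfused <- logical(cap_segs)
  net$lattice <- lattice
  if (!is.null(lattice))
    net$node_key <- integer(lattice$nkx * lattice$nky)
  net$edges <- new.env(parent = emptyenv(), hash = TRUE)
  class(net) <- "vessel_network"
  net
}

grow_vec <- function(v, n) { length(v) <- max(n, 2L * length(v)); v }

ensure_node_cap <- function(net, extra) {
  need <- net$nn + extra
  if (need <= length(net$nd_x)) return(invisible())
  for (f in c("nd_ix", "nd_iy", "nd_x", "nd_y", "nd_role", "nd_p")) {
    v <- grow_vec(get(f, envir = net), need)
    v[is.na(v) & seq_along(v) > net$nn] <- if (is.integer(v)) 0L else 0
    assign(f, v, envir = net)
  }
  invisible()
}

ensure_seg_cap <- function(net, extra) {
  need <- net$ns + extra
  if (need <= length(net$sg_R)) return(invisible())
  for (f in c("sg_n1", "sg_n2", "sg_class", "sg_R", "sg_L", "sg_Q", "sg_H",
              "sg_mu", "sg_tau", "sg_S", "sg_alive", "sg_perfused")) {
    v <- grow_vec(get(f, envir = net), need)
    v[is.na(v) & seq_along(v) > net$ns] <-
      if (is.integer(v)) 0L else if (is.logical(v)) FALSE else 0
    assign(f, v, envir = net)
  }
  invisible()
}

lattice_key <- function(net, ix, iy) ix + net$lattice$nkx * iy + 1L

#' @rdname network_nodes
#' @param ix,iy Lattice indices (0-based).
#' @export
node_at <- function(net, ix, iy) {
  k <- lattice_key(net, ix, iy)
  net$node_key[k]
}

add_node <- function(net, x, y, ix = NA_integer_, iy = NA_integer_,
                     role = 0L) {
  if (!is.na(ix) && !is.null(net$lattice)) {
    id <- node_at(net, ix, iy)
    if (id > 0L) return(id)
  }
  ensure_node_cap(net, 1L)
  id <- net$nn + 1L
  net$nn <- id
  net$nd_ix[id] <- ix; net$nd_iy[id] <- iy
  net$nd_x[id] <- x; net$nd_y[id] <- y
  net$nd_role[id] <- role; net$nd_p[id] <- 0
  if (!is.na(ix) && !is.null(net$lattice))
    net$node_key[lattice_key(net, ix, iy)] <- id
  id
}

edge_key <- function(i, j) {
  if (i < j) paste0(i, ":", j) else paste0(j, ":", i)
}

seg_between <- function(net, i, j) {
  k <- edge_key(i, j)
  if (exists(k, envir = net$edges, inherits = FALSE))
    get(k, envir = net$edges) else 0L
}

add_segment <- function(net, i, j, radius, length, class = SEG_NEO) {
  id <- seg_between(net, i, j)
  if (id > 0L && net$sg_alive[id]) return(id)
  ensure_seg_cap(net, 1L)
  id <- net$ns + 1L
  net$ns <- id
  net$sg_n1[id] <- i; net$sg_n2[id] <- j
  net$sg_R[id] <- radius; net$sg_L[id] <- length
  net$sg_class[id] <- class
  net$sg_Q[id] <- 0; net$sg_H[id] <- 0; net$sg_mu[id] <- 0
  net$sg_tau[id] <- 0; net$sg_S[id] <- 0
  net$sg_alive[id] <- TRUE; net$sg_perfused[id] <- FALSE
  assign(edge_key(i, j), id, envir = net$edges)
  id
}

remove_segments <- function(net, ids) {
  ids <- ids[net$sg_alive[ids]]
  if (!length(ids)) return(invisible())
  net$sg_alive[ids] <- FALSE
  for (id in ids)
    rm(list = edge_key(net$sg_n1[id], net$sg_n2[id]), envir = net$edges)
  invisible()
}

alive_segs <- function(net) which(net$sg_alive[seq_len(net$ns)])

#' Node and segment tables of a vessel network
#'
#' @param net A \code{vessel_network}.
#' @return \code{network_nodes}: data frame with position, lattice indices,
#'   role (\code{"interior"}, \code{"inlet"}, \code{"outlet"}) and pressure.
#'   \code{network_segments}: one row per live segment with endpoints,
#'   radius and length (um), class (\code{"pre"}/\code{"neo"}), flow
#'   (m^3/s, signed node1 to node2), hematocrit, apparent viscosity (Pa s),
#'   wall shear stress (Pa), shear rate (1/s), and perfusion flag.
#' @export
network_nodes <- function(net) {
  n <- net$nn
  data.frame(id = seq_len(n), x = net$nd_x[seq_len(n)],
             y = net$nd_y[seq_len(n)], ix = net$nd_ix[seq_len(n)],
             iy = net$nd_iy[seq_len(n)],
             role = c("interior", "inlet", "outlet")[net$nd_role[seq_len(n)] + 1L],
             pressure = net$nd_p[seq_len(n)])
}

#' @rdname network_nodes
#' @export
network_segments <- function(net) {
  a <- alive_segs(net)
  data.frame(id = a, node1 = net$sg_n1[a], node2 = net$sg_n2[a],
             radius = net$sg_R[a], length = net$sg_L[a],
             class = c("pre", "neo")[net$sg_class[a]],
             flow = net$sg_Q[a], hematocrit = net$sg_H[a],
             viscosity = net$sg_mu[a], wall_stress = net$sg_tau[a],
             shear = net$sg_S[a], perfused = net$sg_perfused[a])
}

#' @export
print.vessel_network <- function(x, ...) {
  a <- alive_segs(x)
  cat(sprintf("<vessel_network> %d nodes, %d segments (%d pre, %d neo)\n",
              x$nn, length(a), sum(x$sg_class[a] == SEG_PRE),
              sum(x$sg_class[a] == SEG_NEO)))
  invisible(x)
}

copy_network <- function(net) {
  out <- new.env(parent = emptyenv())
  for (f in ls(net, all.names = TRUE)) {
    v <- get(f, envir = net)
    if (is.environment(v)) {
      e <- new.env(parent = emptyenv(), hash = TRUE)
      for (k in ls(v, all.names = TRUE)) assign(k, get(k, envir = v), envir = e)
      assign(f, e, envir = out)
    } else assign(f, v, envir = out)
  }
  class(out) <- class(net)
  out
}

#' Build the regular pre-existing vessel grid
#'
#' Lays out straight vessels every \code{vessel_spacing} um along both
#' dimensions (boundary lines included), subdivided into lattice-edge
#' segments of length \code{grid_spacing}, every radius equal to
#' \code{initial_vessel_radius}. Nodes on the left domain edge are inlets,
#' nodes on the right edge outlets.
#'
#' @param config A [simulation_config()].
#' @return A \code{vessel_network}.
#' @export
build_preexisting_grid <- function(config) {
  h <- config$grid_spacing
  nk <- as.integer(round(config$domain_size / h)) + 1L
  m <- as.integer(round(config$vessel_spacing / h))
  lattice <- list(nkx = nk, nky = nk, h = h)
  lines <- seq.int(0L, nk - 1L, by = m)
  n_lines <- length(lines)
  net <- new_network(lattice,
                     cap_nodes = 4L * n_lines * nk,
                     cap_segs = 8L * n_lines * nk)
  role_of <- function(ix) if (ix == 0L) 1L else if (ix == nk - 1L) 2L else 0L
  nid <- function(ix, iy) {
    id <- node_at(net, ix, iy)
    if (id > 0L) return(id)
    add_node(net, ix * h, iy * h, ix, iy, role_of(ix))
  }
  r0 <- config$initial_vessel_radius
  for (iy in lines)   # horizontal lines
    for (ix in 0:(nk - 2L))
      add_segment(net, nid(ix, iy), nid(ix + 1L, iy), r0, h, SEG_PRE)
  for (ix in lines)   # vertical lines
    for (iy in 0:(nk - 2L))
      add_segment(net, nid(ix, iy), nid(ix, iy + 1L), r0, h, SEG_PRE)
  net
}

#' Small analytic vessel-network fixtures
#'
#' Prescribed topologies used to exercise the flow, hematocrit and particle
#' transport operators against closed-form solutions.
#'
#' @param topology One of \code{"single"} (one segment), \code{"series"}
#'   (a chain), \code{"Y"} (one inlet bifurcating into two outlet
#'   branches) or \code{"loop"} (a symmetric diamond).
#' @param radius Segment radius in um, recycled; for \code{"loop"} a length
#'   4 vector assigns (upper-in, upper-out, lower-in, lower-out).
#' @param length Segment length in um.
#' @param n_segments Chain length for \code{"series"}.
#' @return A \code{vessel_network} with inlet and outlet roles assigned.
#' @export
make_fixture_network <- function(topology = c("single", "series", "Y", "loop"),
                                 radius = 6, length = 100, n_segments = 4) {
  topology <- match.arg(topology)
  net <- new_network(NULL)
  L <- length
  switch(topology,
    single = {
      a <- add_node(net, 0, 0, role = 1L)
      b <- add_node(net, L, 0, role = 2L)
      add_segment(net, a, b, radius[1], L, SEG_PRE)
    },
    series = {
      r <- rep_len(radius, n_segments)
      prev <- add_node(net, 0, 0, role = 1L)
      for (k in seq_len(n_segments)) {
        nxt <- add_node(net, k * L, 0,
                        role = if (k == n_segments) 2L else 0L)
        add_segment(net, prev, nxt, r[k], L, SEG_PRE)
        prev <- nxt
      }
    },
    Y = {
      r <- rep_len(radius, 3L)
      a <- add_node(net, 0, 0, role = 1L)
      j <- add_node(net, L, 0)
      b <- add_node(net, 2 * L, L / 2, role = 2L)
      c_ <- add_node(net, 2 * L, -L / 2, role = 2L)
      add_segment(net, a, j, r[1], L, SEG_PRE)
      add_segment(net, j, b, r[2], L, SEG_PRE)
      add_segment(net, j, c_, r[3], L, SEG_PRE)
    },
    loop = {
      r <- rep_len(radius, 4L)
      a <- add_node(net, 0, 0, role = 1L)
      u <- add_node(net, L, L / 2)
      d <- add_node(net, L, -L / 2)
      b <- add_node(net, 2 * L, 0, role = 2L)
      add_segment(net, a, u, r[1], L, SEG_PRE)
      add_segment(net, u, b, r[2], L, SEG_PRE)
      add_segment(net, a, d, r[3], L, SEG_PRE)
      add_segment(net, d, b, r[4], L, SEG_PRE)
    })
  net
}

seg_midpoints <- function(net, segs = alive_segs(net)) {
  cbind(x = (net$nd_x[net$sg_n1[segs]] + net$nd_x[net$sg_n2[segs]]) / 2,
        y = (net$nd_y[net$sg_n1[segs]] + net$nd_y[net$sg_n2[segs]]) / 2)
}

seg_cells <- function(net, grid, segs = alive_segs(net)) {
  mid <- seg_midpoints(net, segs)
  cx <- pmin(pmax(floor(mid[, "x"] / grid$dx), 0), grid$nx - 1)
  cy <- pmin(pmax(floor(mid[, "y"] / grid$dx), 0), grid$ny - 1)
  cbind(cx = as.integer(cx), cy = as.integer(cy))
}

#' Vessel indicator field
#'
#' Binary cell-centered field equal to 1 on grid cells crossed by a vessel
#' segment (a segment is assigned the cell containing its midpoint; lattice
#' segments lying on the outermost grid lines map to the adjacent interior
#' cell row/column).
#'
#' @param net A \code{vessel_network}.
#' @param grid A [grid2d()].
#' @param segs Segment ids to rasterize (default all live segments).
#' @return An \code{nx} x \code{ny} 0/1 matrix.
#' @export
rasterize_vessels <- function(net, grid, segs = alive_segs(net)) {
  ind <- matrix(0, grid$nx, grid$ny)
  if (length(segs)) {
    sc <- seg_cells(net, grid, segs)
    ind[cbind(sc[, "cx"] + 1L, sc[, "cy"] + 1L)] <- 1
  }
  ind
}

as_igraph <- function(net, segs = alive_segs(net)) {
  igraph::graph_from_edgelist(
    cbind(net$sg_n1[segs], net$sg_n2[segs]), directed = FALSE) |>
    (\(g) if (igraph::vcount(g) < net$nn)
       igraph::add_vertices(g, net$nn - igraph::vcount(g)) else g)()
}

inlet_nodes <- function(net) which(net$nd_role[seq_len(net$nn)] == 1L)
outlet_nodes <- function(net) which(net$nd_role[seq_len(net$nn)] == 2L)
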