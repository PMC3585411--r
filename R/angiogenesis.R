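# Stochastic lattice angiogenesis: sprout tips initiate on perfused vessels
# where TAF is high, perform a chemotactically and haptotactically biased
# random walk on the lattice (laying down neovessel segments as they go),
# branch, and fuse with vessels they run into (anastomosis). The continuum
# endothelial-density equation is represented only through this discretized
# stochastic tip form.

#' Create an empty sprout tip population
#'
#' @return Environment of class \code{sprout_tips} holding the per-tip
#'   state (current node, previous node, age, trail) and per-node sprout
#'   cooldown bookkeeping.
#' @export
new_tips <- function() {
  tips <- new.env(parent = emptyenv())
  tips$nt <- 0L
  tips$node <- integer(64); tips$prev <- integer(64)
  tips$age <- integer(64); tips$alive <- logical(64)
  tips$trail <- vector("list", 64)
  tips$last_sprout <- numeric(0)   # per network node, step of last sprout
  class(tips) <- "sprout_tips"
  tips
}

tips_add <- function(tips, node) {
  if (tips$nt >= length(tips$node)) {
    n2 <- 2L * length(tips$node)
    length(tips$node) <- n2; length(tips$prev) <- n2
    length(tips$age) <- n2; length(tips$alive) <- n2
    length(tips$trail) <- n2
  }
  k <- tips$nt + 1L; tips$nt <- k
  tips$node[k] <- node; tips$prev[k] <- 0L
  tips$age[k] <- 0L; tips$alive[k] <- TRUE
  tips$trail[[k]] <- node
  k
}

active_tips <- function(tips) which(tips$alive[seq_len(tips$nt)])

# Cell field -> lattice corner field (mean of the adjacent cells, edges
# clamped); tips live on lattice corners.
corner_field <- function(M) {
  nx <- nrow(M); ny <- ncol(M)
  i0 <- c(1L, seq_len(nx)); i1 <- c(seq_len(nx), nx)
  j0 <- c(1L, seq_len(ny)); j1 <- c(seq_len(ny), ny)
  (M[i0, j0] + M[i1, j0] + M[i0, j1] + M[i1, j1]) / 4
}

#' Initiate sprout tips on the perfused vasculature
#'
#' Creates new tips at lattice nodes of perfused vessel segments where the
#' TAF level exceeds \code{taf_threshold}: each eligible node sprouts with
#' probability \code{initiation_prob} (at most one tip per node per step),
#' then enters a cooldown.
#'
#' @param net A \code{vessel_network}.
#' @param tips A \code{sprout_tips} population (updated in place).
#' @param taf_corner TAF sampled at lattice corners ([corner_field()]).
#' @param ang [angiogenesis_params()].
#' @param day Current simulation day (for the cooldown).
#' @param rng RNG handle from [make_rng()].
#' @return Number of sprouts created.
#' @export
initiate_sprouts <- function(net, tips, taf_corner, ang, day, rng) {
  segs <- alive_segs(net)
  perf <- segs[net$sg_perfused[segs]]
  if (!length(perf)) return(0L)
  cand <- unique(c(net$sg_n1[perf], net$sg_n2[perf]))
  cand <- cand[!is.na(net$nd_ix[cand])]
  if (length(tips$last_sprout) < net$nn)
    tips$last_sprout <- c(tips$last_sprout,
                          rep(-Inf, net$nn - length(tips$last_sprout)))
  tval <- taf_corner[cbind(net$nd_ix[cand] + 1L, net$nd_iy[cand] + 1L)]
  cand <- cand[tval > ang$taf_threshold &
                 (day - tips$last_sprout[cand]) >= ang$sprout_cooldown]
  if (!length(cand)) return(0L)
  picked <- rng_eval(rng, "angiogenesis", function()
    cand[stats::runif(length(cand)) < ang$initiation_prob])
  n_room <- max(0L, ang$max_tips - length(active_tips(tips)))
  if (length(picked) > n_room) picked <- picked[seq_len(n_room)]
  for (nd in picked) tips_add(tips, nd)
  tips$last_sprout[picked] <- day
  length(picked)
}

# One biased-random-walk migration step for every active tip; neovessel
# segments are laid along traversed edges; entering an existing vessel node
# fuses (anastomosis) and terminates the tip (and any tip already there).
migrate_tips <- function(net, tips, taf_corner, ecm_corner, ang, rng, r0) {
  act <- active_tips(tips)
  if (!length(act)) return(invisible(0L))
  nkx <- net$lattice$nkx; nky <- net$lattice$nky; h <- net$lattice$h
  dirs <- cbind(c(1L, -1L, 0L, 0L), c(0L, 0L, 1L, -1L))
  n_anast <- 0L
  rng_eval(rng, "angiogenesis", function() {
    for (t in act) {
      if (!tips$alive[t]) next   # may have been fused into this step
      cur <- tips$node[t]
      ix <- net$nd_ix[cur]; iy <- net$nd_iy[cur]
      Th <- taf_corner[ix + 1L, iy + 1L]
      Eh <- ecm_corner[ix + 1L, iy + 1L]
      chi <- ang$chi0 / (1 + ang$c_t * Th)
      w <- numeric(4)
      for (d in 1:4) {
        jx <- ix + dirs[d, 1]; jy <- iy + dirs[d, 2]
        if (jx < 0L || jy < 0L || jx > nkx - 1L || jy > nky - 1L) next
        nb <- node_at(net, jx, jy)
        if (nb > 0L && nb == tips$prev[t]) next   # no immediate backtrack
        w[d] <- max(0, ang$d_motility +
                      chi * (taf_corner[jx + 1L, jy + 1L] - Th) +
                      ang$rho * (ecm_corner[jx + 1L, jy + 1L] - Eh))
      }
      s <- sum(w)
      tips$age[t] <- tips$age[t] + 1L
      if (s <= 0) next                          # stalled
      d <- findInterval(stats::runif(1) * s, cumsum(w)) + 1L
      jx <- ix + dirs[d, 1]; jy <- iy + dirs[d, 2]
      nb <- node_at(net, jx, jy)
      if (nb > 0L) {                            # running into the network
        if (!ang$anastomosis) next
        if (seg_between(net, cur, nb) == 0L)
          add_segment(net, cur, nb, r0, h, SEG_NEO)
        tips$alive[t] <- FALSE
        others <- active_tips(tips)
        tips$alive[others[tips$node[others] == nb]] <- FALSE
        n_anast <<- n_anast + 1L
      } else {
        nb <- add_node(net, jx * h, jy * h, jx, jy, 0L)
        add_segment(net, cur, nb, r0, h, SEG_NEO)
        tips$prev[t] <- cur
        tips$node[t] <- nb
        tips$trail[[t]] <- c(tips$trail[[t]], nb)
      }
      if (tips$age[t] > ang$tip_max_age) tips$alive[t] <- FALSE
    }
    invisible(NULL)
  })
  invisible(n_anast)
}

#' Branch eligible sprout tips
#'
#' Each active tip of age at least \code{branch_min_age} sitting in
#' sufficient TAF branches into two with probability \code{branch_prob};
#' both children inherit the parent position. (Anastomosis itself happens
#' during migration, when a tip steps onto an existing vessel node.)
#'
#' @inheritParams initiate_sprouts
#' @return Number of branching events.
#' @export
branch_and_anastomose <- function(tips, net, taf_corner, ang, rng) {
  act <- active_tips(tips)
  if (!length(act)) return(0L)
  elig <- act[tips$age[act] >= ang$branch_min_age]
  if (length(elig)) {
    tv <- taf_corner[cbind(net$nd_ix[tips$node[elig]] + 1L,
                           net$nd_iy[tips$node[elig]] + 1L)]
    elig <- elig[tv > ang$taf_threshold]
  }
  if (!length(elig)) return(0L)
  room <- max(0L, ang$max_tips - length(act))
  branched <- rng_eval(rng, "angiogenesis", function()
    elig[stats::runif(length(elig)) < ang$branch_prob])
  if (length(branched) > room) branched <- branched[seq_len(room)]
  for (t in branched) {
    k <- tips_add(tips, tips$node[t])
    tips$age[k] <- tips$age[t]   # child is as mature as the parent
  }
  length(branched)
}

#' Prune collapsed segments and flag the perfused subnetwork
#'
#' Dead-end (zero-flow) chains are already excluded from flow statistics by
#' the perfusion flag and are retained as growing sprouts; this removes
#' segments whose radius has collapsed below \code{prune_radius} under
#' adaptation, unless removal would disconnect the inlets from the outlets
#' (checked, and rolled back if so).
#'
#' @param net A flow-solved \code{vessel_network}.
#' @param adaptation [adaptation_params()].
#' @return Number of segments removed.
#' @export
prune_nonperfused <- function(net, adaptation) {
  segs <- alive_segs(net)
  doomed <- segs[net$sg_R[segs] <= adaptation$prune_radius]
  if (!length(doomed)) return(0L)
  keep <- setdiff(segs, doomed)
  g <- as_igraph(net, keep)
  memb <- igraph::components(g)$membership
  if (!length(intersect(memb[inlet_nodes(net)], memb[outlet_nodes(net)])))
    return(0L)   # would disconnect; keep everything this step
  remove_segments(net, doomed)
  length(doomed)
}
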