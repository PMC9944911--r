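#' Poiseuille segment resistance
#'
#' Resistance in model units, `length / diameter^4`. The constant prefactor
#' (8 mu / pi) is irrelevant because only flow ratios at bifurcations enter
#' the embolus routing model.
#'
#' @param diameter,length Positive values in mm.
#' @return Resistance in model units.
#' @export
segment_resistance <- function(diameter, length) {
  if (any(diameter <= 0)) stopf("diameter must be positive")
  if (any(length <= 0)) stopf("length must be positive")
  length / diameter^4
}

#' Solve steady relative flows in a (possibly occluded) tree
#'
#' Two linear-time passes under Poiseuille assumptions with a single inlet
#' and equal pressures at all terminals: a post-order pass computes
#' equivalent subtree resistances (occluded subtrees have infinite
#' resistance), then a pre-order pass splits each parent's flow over its
#' children in proportion to inverse equivalent resistance. The root carries
#' `input_flow` unless it is itself occluded, in which case all flows are
#' zero. An occluded segment and everything distal to it carries zero flow.
#'
#' @param tree A `vascular_tree`.
#' @param occlusions Integer ids of occluded segments (may be empty).
#' @param input_flow Total inflow in arbitrary relative units.
#' @return An object of class `flow_state` with per-segment `flow`,
#'   `resistance` and equivalent subtree resistance `R_eq`.
#' @export
solve_flows <- function(tree, occlusions = integer(0), input_flow = 1) {
  stopifnot(inherits(tree, "vascular_tree"))
  seg <- tree$seg
  idx <- tree$index
  n <- nrow(seg)
  R <- segment_resistance(seg$diameter, seg$length)
  occ <- logical(n); occ[occlusions] <- TRUE

  depth <- idx$depth
  c1 <- idx$child1; c2 <- idx$child2; nch <- idx$n_children
  levels <- split(seq_len(n), depth)
  nlev <- length(levels)

  # post-order: equivalent resistance of the subtree rooted at each segment
  Req <- R
  for (li in rev(seq_len(nlev))) {
    v <- levels[[li]]
    two <- v[nch[v] == 2L]
    if (length(two)) {
      g <- 1 / Req[c1[two]] + 1 / Req[c2[two]]
      Req[two] <- R[two] + ifelse(g > 0, 1 / g, Inf)
    }
    one <- v[nch[v] == 1L]
    if (length(one)) Req[one] <- R[one] + Req[c1[one]]
    Req[v[occ[v]]] <- Inf
  }

  # pre-order: split flow by inverse equivalent resistance
  flow <- numeric(n)
  flow[tree$root] <- if (is.finite(Req[tree$root])) input_flow else 0
  for (li in seq_len(nlev)) {
    v <- levels[[li]]
    two <- v[nch[v] == 2L & flow[v] > 0]
    if (length(two)) {
      ga <- ifelse(is.finite(Req[c1[two]]), 1 / Req[c1[two]], 0)
      gb <- ifelse(is.finite(Req[c2[two]]), 1 / Req[c2[two]], 0)
      gt <- ga + gb
      share <- ifelse(gt > 0, ga / gt, 0)
      flow[c1[two]] <- flow[two] * share
      flow[c2[two]] <- flow[two] * ifelse(gt > 0, gb / gt, 0)
    }
    one <- v[nch[v] == 1L & flow[v] > 0]
    if (length(one)) flow[c1[one]] <- ifelse(is.finite(Req[c1[one]]), flow[one], 0)
  }

  structure(list(flow = flow, resistance = R, R_eq = Req,
                 occluded = which(occ), input_flow = input_flow),
            class = "flow_state")
}

#' Terminal flows of a flow state
#'
#' @param tree The tree the flows were solved on.
#' @param flows A [solve_flows()] result.
#' @return Flows of the terminal segments, in Euler-tour (tin) order.
#' @export
terminal_flows <- function(tree, flows) {
  flows$flow[tree$index$terminals]
}
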