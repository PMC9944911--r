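#' Transport model configuration
#'
#' Parameters of the stochastic embolus transport model.
#'
#' @param sigma Routing sharpness (>= 1). `sigma = 1` routes emboli in
#'   proportion to flow; larger values bias them towards the higher-flow
#'   branch (sigmoid, approaching a step function).
#' @param Delta Embolus diameter reduction rate in mm per 24 h while lodged
#'   (0 = permanent occlusion).
#' @param tau Ischaemia threshold in hours: a terminal without flow for a
#'   continuous period of `tau` produces a lesion.
#' @param max_time Maximum simulated time in hours.
#' @param seed Optional default RNG seed for [simulate_stroke()].
#' @return A list of class `transport_config`.
#' @export
transport_config <- function(sigma = 1, Delta = 0.533, tau = 4,
                             max_time = 24, seed = NULL) {
  if (sigma < 1) stopf("sigma must be >= 1")
  if (Delta < 0) stopf("Delta must be >= 0")
  if (tau <= 0) stopf("tau must be positive")
  if (max_time <= 0) stopf("max_time must be positive")
  structure(list(sigma = sigma, Delta = Delta, tau = tau,
                 max_time = max_time, seed = seed),
            class = "transport_config")
}

#' Probability that an embolus enters branch A
#'
#' Sigmoid routing rule
#' `p_A = (tanh(sigma * atanh(2 f_A / (f_A + f_B) - 1)) + 1) / 2`,
#' which reduces exactly to the flow fraction `f_A / (f_A + f_B)` at
#' `sigma = 1` and approaches a step function for large `sigma`. The
#' `atanh` limits are handled so that a zero-flow branch receives
#' probability 0.
#'
#' @param f_A,f_B Non-negative relative flows in the two branches
#'   (vectorised; both zero is an error).
#' @param sigma Routing sharpness (> 0).
#' @return `p_A` in `[0, 1]`, with `p_A + p_B = 1`.
#' @export
branch_probability <- function(f_A, f_B, sigma = 1) {
  if (any(f_A < 0) || any(f_B < 0)) stopf("flows must be non-negative")
  if (any(f_A + f_B <= 0)) stopf("both branch flows are zero")
  if (sigma <= 0) stopf("sigma must be positive")
  x <- 2 * f_A / (f_A + f_B) - 1
  p <- ifelse(x <= -1, 0, ifelse(x >= 1, 1, (tanh(sigma * atanh(x)) + 1) / 2))
  pmin(pmax(p, 0), 1)
}

#' Routing decision of an embolus at one bifurcation
#'
#' Applies the lodging rules: if the embolus is wider than both daughter
#' vessels it obstructs the parent; if it is wider than exactly one, it
#' travels down the larger branch deterministically; otherwise it chooses a
#' branch by Monte Carlo with [branch_probability()].
#'
#' @param embolus_diameter Embolus diameter (mm); must fit the parent.
#' @param child_diameters,child_flows Length-2 vectors for branches A and B.
#' @param sigma Routing sharpness.
#' @return A list with `action` (`"branch"` or `"lodge"`) and, for
#'   branches, `child` (1 or 2).
#' @export
choose_branch <- function(embolus_diameter, child_diameters, child_flows,
                          sigma = 1) {
  stopifnot(length(child_diameters) == 2, length(child_flows) == 2)
  d <- embolus_diameter
  wider <- d > child_diameters
  if (all(wider)) return(list(action = "lodge", child = NA_integer_))
  if (any(wider)) return(list(action = "branch",
                              child = which.max(child_diameters)))
  p_A <- branch_probability(child_flows[1], child_flows[2], sigma)
  list(action = "branch", child = if (runif(1) <= p_A) 1L else 2L)
}

#' Time for a lodged embolus to shrink enough to pass
#'
#' The passing threshold is the larger daughter diameter at the blocked
#' bifurcation; with linear dissolution at rate `Delta` (mm per 24 h) the
#' embolus can pass after `(d - threshold) / Delta` days. `Delta = 0` gives
#' a permanent occlusion (infinite time).
#'
#' @param embolus_diameter Lodged embolus diameter (mm).
#' @param threshold Passing threshold (mm): the larger daughter diameter, or
#'   0 for full dissolution.
#' @param Delta Dissolution rate in mm per 24 h.
#' @return A list with `time` (hours) and `threshold` (mm).
#' @export
remobilization_time <- function(embolus_diameter, threshold, Delta) {
  if (embolus_diameter < threshold) stopf("embolus already below threshold")
  time <- if (Delta > 0) (embolus_diameter - threshold) / Delta * 24 else
    if (embolus_diameter > threshold) Inf else 0
  list(time = time, threshold = threshold)
}

#' Simulate a single embolic stroke
#'
#' Event loop of one stroke: the embolus is released at the tree input and
#' transits bifurcations instantaneously under the routing rules of
#' [choose_branch()]. On lodging, the blocked vessel occludes and every
#' terminal distal to it loses flow (the exact consequence of the
#' series-parallel flow model with a fixed input flow); a remobilization is
#' scheduled at which the embolus has shrunk to the larger daughter diameter
#' and resumes its walk from the lodge site. Terminals are monitored for
#' continuous zero-flow intervals; those starved for at least `config$tau`
#' hours are lesioned ([lesioned_terminals()]). The simulation ends when the
#' embolus exits through a terminal at least as wide as itself, or at
#' `config$max_time`. Deterministic given `seed`.
#'
#' @param tree A `vascular_tree`.
#' @param embolus_diameter Embolus diameter in mm.
#' @param config A [transport_config()].
#' @param phantom Optional [build_phantom()] result for lesion volumes.
#' @param perfusion Optional precomputed [perfusion_map()] (built from
#'   `phantom` if missing; pass explicitly in cohort loops).
#' @param flows Optional precomputed baseline [solve_flows()] result.
#' @param seed RNG seed for the Monte Carlo branch choices.
#' @param keep_trajectory Record every entered segment (set `FALSE` in
#'   large cohorts).
#' @param clock_method `"range"` (fast, contiguous Euler-tour updates) or
#'   `"general"` (vectorised [record_flow_interval()] over all terminals);
#'   both give identical outcomes.
#' @return An object of class `stroke_outcome`: lesioned terminals, infarct
#'   volume (% of brain volume), per-territory breakdown, final embolus
#'   status and the trajectory log.
#' @export
simulate_stroke <- function(tree, embolus_diameter,
                            config = transport_config(),
                            phantom = NULL, perfusion = NULL, flows = NULL,
                            seed = config$seed, keep_trajectory = TRUE,
                            clock_method = c("range", "general")) {
  stopifnot(inherits(tree, "vascular_tree"))
  if (embolus_diameter < 0) stopf("embolus diameter must be non-negative")
  clock_method <- match.arg(clock_method)
  if (is.null(perfusion) && !is.null(phantom))
    perfusion <- perfusion_map(tree, phantom)
  if (is.null(flows)) flows <- solve_flows(tree)

  idx <- tree$index
  diam <- tree$seg$diameter
  c1 <- idx$child1; c2 <- idx$child2; nch <- idx$n_children
  f <- flows$flow
  term_tin <- idx$term_tin
  n_term <- length(idx$terminals)
  sigma <- config$sigma; Delta <- config$Delta
  tau <- config$tau; t_max <- config$max_time

  traj_t <- numeric(0); traj_e <- character(0); traj_s <- integer(0); traj_d <- numeric(0)
  note <- function(time, event, segment, d) {
    traj_t[length(traj_t) + 1] <<- time
    traj_e[length(traj_e) + 1] <<- event
    traj_s[length(traj_s) + 1] <<- segment
    traj_d[length(traj_d) + 1] <<- d
  }

  clocks <- leaf_clocks(tree)
  cur_start <- rep(NA_real_, n_term)
  longest <- numeric(n_term)
  open_range <- NULL  # c(lo, hi) of currently starved terminal positions

  distal_range <- function(s)
    c(findInterval(idx$tin[s] - 1L, term_tin) + 1L,
      findInterval(idx$tout[s], term_tin))

  res <- with_seed(seed, {
    t <- 0; d <- embolus_diameter; status <- "moving"
    s <- tree$root
    note(0, "release", s, d)
    lodge_site <- NA_integer_
    lodged <- d > diam[s]

    repeat {
      if (!lodged) {
        # instantaneous walk from s
        repeat {
          k <- nch[s]
          if (k == 0L) { status <- "exited"; note(t, "exit", s, d); break }
          if (k == 1L) {
            ch <- c1[s]
            if (d <= diam[ch]) {
              s <- ch
              if (keep_trajectory) note(t, "enter-segment", s, d)
            } else { lodged <- TRUE; break }
          } else {
            a <- c1[s]; b <- c2[s]
            da <- diam[a]; db <- diam[b]
            if (d > da && d > db) { lodged <- TRUE; break }
            s <- if (d > da) b
                 else if (d > db) a
                 else if (runif(1) <= branch_probability(f[a], f[b], sigma)) a else b
            if (keep_trajectory) note(t, "enter-segment", s, d)
          }
        }
        if (status == "exited") break
      }

      # embolus lodged in (obstructs) segment s
      lodge_site <- s
      note(t, "lodge", s, d)
      thr <- if (nch[s] == 0L) 0 else if (nch[s] == 1L) diam[c1[s]] else
        max(diam[c1[s]], diam[c2[s]])
      t_free <- t + remobilization_time(d, thr, Delta)$time
      r <- distal_range(s)
      if (clock_method == "range") {
        # nested chain: previous open range shrinks to r; shed terminals close
        if (!is.null(open_range)) {
          shed <- setdiff(open_range[1]:open_range[2], r[1]:r[2])
          if (length(shed)) {
            longest[shed] <- pmax(longest[shed], t - cur_start[shed])
            cur_start[shed] <- NA_real_
          }
        }
        sel <- r[1]:r[2]
        sel <- sel[is.na(cur_start[sel])]
        cur_start[sel] <- t
        open_range <- r
      } else {
        lf <- f[idx$terminals]
        if (r[1] <= r[2]) lf[r[1]:r[2]] <- 0
        clocks <- record_flow_interval(clocks, t, min(t_free, t_max), lf)
      }

      if (t_free > t_max) { t <- t_max; status <- "lodged"; break }
      t <- t_free
      d <- thr
      note(t, "remobilize", s, d)
      if (d <= 0) { status <- "dissolved"; note(t, "dissolve", s, d); break }
      # deterministically enters the larger (= threshold) daughter
      s <- if (nch[s] == 1L) c1[s] else
        if (diam[c1[s]] >= diam[c2[s]]) c1[s] else c2[s]
      if (keep_trajectory) note(t, "enter-segment", s, d)
      lodged <- FALSE
    }

    if (clock_method == "range") {
      if (!is.null(open_range)) {
        sel <- open_range[1]:open_range[2]
        sel <- sel[!is.na(cur_start[sel])]
        longest[sel] <- pmax(longest[sel], t - cur_start[sel])
        cur_start[sel] <- NA_real_
      }
      clocks$longest <- longest
      clocks$t_last <- t
    } else if (status %in% c("exited", "dissolved") && t < t_max) {
      # restored flow closes all open zero-flow intervals at t
      clocks <- record_flow_interval(clocks, t, t, f[idx$terminals])
    }
    list(status = status, t_end = t, lodge_site = lodge_site, d_final = d)
  })

  les <- lesioned_terminals(clocks, tau)
  out <- list(embolus_diameter = embolus_diameter, seed = seed,
              status = res$status, t_end = res$t_end,
              lodge_site = res$lodge_site,
              lodge_territory = if (is.na(res$lodge_site)) NA_character_ else
                tree$seg$territory[res$lodge_site] %||% NA_character_,
              lesioned = les,
              infarct_pct = NA_real_, territory_pct = NULL,
              trajectory = data.frame(time = traj_t, event = traj_e,
                                      segment = traj_s, diameter = traj_d))
  if (!is.null(perfusion)) {
    vol <- lesion_volumes(les, perfusion)
    out$infarct_pct <- vol$infarct_pct
    out$territory_pct <- vol$territory_pct
  }
  structure(out, class = "stroke_outcome")
}

#' @export
print.stroke_outcome <- function(x, ...) {
  cat("stroke_outcome: embolus", x$embolus_diameter, "mm ->", x$status,
      "at t =", format(x$t_end, digits = 3), "h\n")
  cat("  lesioned terminals:", length(x$lesioned),
      if (!is.na(x$infarct_pct))
        paste0("; infarct ", format(x$infarct_pct, digits = 3),
               "% of brain volume"), "\n")
  invisible(x)
}

#' Export a trajectory log as CSV
#'
#' @param outcome A [simulate_stroke()] result.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(outcome, path) {
  write.csv(outcome$trajectory, path, row.names = FALSE)
  invisible(path)
}
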