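# Resting coronary flow from LV mass, allocation over the tree by the
# flow--diameter scaling law, and the stenosis-dependent hyperemic
# multiplier. Flow is represented per branch as a piecewise-constant profile
# between side-branch attachment points, so conservation at every junction
# is exact by construction.

#' Patient context: physiology and fluid properties
#'
#' @param lvm Left-ventricular mass, g (> 0). Total resting coronary flow is
#'   `q0 * lvm` mL/min.
#' @param sbp,dbp Systolic and diastolic cuff pressure, mmHg (`sbp > dbp > 0`).
#' @param hct Optional hematocrit, fraction. When `use_hct_viscosity = TRUE`
#'   the viscosity becomes `1.2e-3 * exp(2 * hct)` Pa s; off by default.
#' @param q0 Resting myocardial perfusion per gram, mL/min/g (default 0.8).
#' @param mu Blood dynamic viscosity, Pa s (default 3.5e-3).
#' @param rho Blood density, kg/m^3 (default 1060).
#' @param k_max,ds_lo,ds_hi,k_floor Hyperemic multiplier parameters, see
#'   [hyperemic_multiplier()].
#' @param territory_fraction Share of total resting coronary flow subtended
#'   by the modeled (sub)tree, fraction in (0, 1]. A single-vessel model is a
#'   subtree of the full coronary circulation and should not receive the
#'   entire LV flow; 1 means the tree is the whole circulation of interest.
#' @param use_hct_viscosity Logical, apply the hematocrit viscosity relation.
#' @return An object of class `patient_context`.
#' @export
patient_context <- function(lvm = 115, sbp = 134, dbp = 77, hct = NULL,
                            q0 = 0.8, mu = 3.5e-3, rho = 1060,
                            k_max = 4, ds_lo = 0.3, ds_hi = 0.9, k_floor = 1,
                            territory_fraction = 1,
                            use_hct_viscosity = FALSE) {
  stopifnot(lvm > 0, sbp > dbp, dbp > 0, q0 > 0, mu > 0, rho > 0,
            k_max >= k_floor, k_floor >= 1, ds_lo >= 0, ds_lo < ds_hi,
            ds_hi <= 1, territory_fraction > 0, territory_fraction <= 1)
  if (use_hct_viscosity) {
    if (is.null(hct)) stop("use_hct_viscosity requires hct")
    stopifnot(hct > 0, hct < 1)
    mu <- 1.2e-3 * exp(2 * hct)
  }
  structure(list(lvm = lvm, sbp = sbp, dbp = dbp, hct = hct, q0 = q0,
                 mu = mu, rho = rho,
                 hyperemia = list(k_max = k_max, ds_lo = ds_lo,
                                  ds_hi = ds_hi, k_floor = k_floor),
                 territory_fraction = territory_fraction),
            class = "patient_context")
}

#' Total resting coronary flow
#'
#' Linear in LV mass: `q0 * lvm` mL/min, returned in mL/s.
#'
#' @param ctx A [patient_context()].
#' @return Flow, mL/s.
#' @export
total_resting_flow <- function(ctx) {
  stopifnot(inherits(ctx, "patient_context"))
  ctx$q0 * ctx$lvm / 60
}

#' Hyperemic flow multiplier k(DS)
#'
#' Piecewise-linear in diameter stenosis: `k = k_max` up to `ds_lo`, falling
#' linearly to `k_floor` at `ds_hi`, constant beyond. Reflects adenosine
#' hyperemia (~4x resting flow in an unobstructed bed) attenuated by the
#' stenosis itself.
#'
#' @param ds Diameter stenosis, fraction in [0, 1] (vectorized).
#' @param k_max,ds_lo,ds_hi,k_floor Multiplier parameters.
#' @return Multiplier k (dimensionless).
#' @export
hyperemic_multiplier <- function(ds, k_max = 4, ds_lo = 0.3, ds_hi = 0.9,
                                 k_floor = 1) {
  if (any(ds < 0 | ds > 1)) stop("ds must lie in [0, 1]")
  k <- k_max - (k_max - k_floor) * (ds - ds_lo) / (ds_hi - ds_lo)
  pmin(k_max, pmax(k_floor, k))
}

# 75th percentile of equivalent diameters over a 5 mm window distal of
# s_from: the branch's "reference healthy diameter" at that takeoff, robust
# to a local stenosis sitting at the window.
reference_diameter <- function(b, s_from, window = 5) {
  sel <- b$s >= s_from - 1e-9 & b$s <= s_from + window + 1e-9
  if (!any(sel)) sel <- which.min(abs(b$s - s_from))
  d <- 2 * area_to_radius(b$area[sel])
  stats::quantile(d, 0.75, names = FALSE)
}

#' Allocate resting flow over the tree by the scaling law
#'
#' The inflow `q_total` enters the root. At each junction the incoming flow
#' splits among the daughters (the attached branch plus the parent's distal
#' continuation) in proportion to their reference healthy diameters raised
#' to `exponent` (default 7/3, the flow--diameter scaling law; 3 gives
#' Murray's law). The reference diameter is the 75th percentile of
#' equivalent diameters over the daughter's proximal 5 mm, so a stenosis at
#' a daughter ostium does not starve its own subtree. A branch whose
#' children attach at its distal tip has no continuation outlet there.
#' Conservation at every junction is exact by construction.
#'
#' @param tree A `coronary_tree` without occluded branches on supplied paths.
#' @param q_total Inflow at the root, mL/s (>= 0).
#' @param exponent Scaling-law exponent (default 7/3).
#' @param window Reference-diameter window, mm.
#' @return An object of class `flow_assignment`: per branch, piecewise
#'   segments `(s0, s1, q)` in mL/s plus the terminal outlet flow; plus the
#'   children grouping used (reused by [hyperemic_flows()]).
#' @export
allocate_branch_flows <- function(tree, q_total, exponent = 7 / 3,
                                  window = 5) {
  stopifnot(q_total >= 0)
  branches_out <- list()
  walk <- function(id, q_in) {
    b <- tree$branches[[id]]
    if (b$occluded || any(b$area <= 0))
      stop("branch '", id, "' is occluded; flow allocation is undefined")
    kids <- children_of(tree, id)
    s_end <- branch_range(b)[2]
    # group children by (numerically) identical attachment points
    att <- vapply(kids, `[[`, 0, "attach_s")
    groups <- if (length(att)) split(names(kids), round(att, 9)) else list()
    gpos <- as.numeric(names(groups))
    segs <- list(); q_cur <- q_in; s_cur <- branch_range(b)[1]
    for (gi in seq_along(groups)) {
      s_a <- gpos[gi]
      segs[[length(segs) + 1L]] <- c(s_cur, s_a, q_cur)
      kid_ids <- groups[[gi]]
      w_kids <- vapply(kid_ids, function(kid)
        reference_diameter(tree$branches[[kid]],
                           branch_range(tree$branches[[kid]])[1],
                           window)^exponent, 0)
      at_tip <- s_a >= s_end - 1e-9
      w_cont <- if (at_tip) 0 else reference_diameter(b, s_a, window)^exponent
      tot <- sum(w_kids) + w_cont
      for (j in seq_along(kid_ids))
        walk(kid_ids[j], q_cur * w_kids[j] / tot)
      q_cur <- q_cur * w_cont / tot
      s_cur <- s_a
    }
    segs[[length(segs) + 1L]] <- c(s_cur, s_end, q_cur)
    segm <- do.call(rbind, segs)
    branches_out[[id]] <<- list(
      seg = data.frame(s0 = segm[, 1], s1 = segm[, 2], q = segm[, 3]),
      outlet = q_cur,
      child_groups = lapply(seq_along(groups), function(gi)
        list(s = gpos[gi], ids = groups[[gi]])))
  }
  walk(tree$root_id, q_total)
  structure(list(branches = branches_out, q_total = q_total,
                 exponent = exponent, state = "rest"),
            class = "flow_assignment")
}

#' Flow at a location
#'
#' @param assign A `flow_assignment`.
#' @param branch_id,s Location on the tree.
#' @return Flow, mL/s, of the piecewise segment containing `s`.
#' @export
flow_at <- function(assign, branch_id, s) {
  fb <- assign$branches[[branch_id]]
  if (is.null(fb)) stop("unknown branch id '", branch_id, "'")
  seg <- fb$seg
  i <- which(s >= seg$s0 - 1e-9 & s <= seg$s1 + 1e-9)
  if (!length(i)) stop("s=", s, " outside branch '", branch_id, "'")
  # at a junction point take the distal segment, but skip zero-length
  # bookkeeping segments (e.g. the continuation stub of a tip bifurcation)
  real <- i[seg$s1[i] > seg$s0[i] + 1e-12]
  if (length(real)) seg$q[real[length(real)]] else seg$q[i[length(i)]]
}

# sum of (hyperemic) outlet flows over the subtree rooted at id
subtree_outlet_sum <- function(assign, tree, id, outlets) {
  fb <- assign$branches[[id]]
  total <- outlets[[id]]
  for (g in fb$child_groups) for (kid in g$ids)
    total <- total + subtree_outlet_sum(assign, tree, kid, outlets)
  total
}

#' Hyperemic flows
#'
#' For each terminal outlet, the multiplier k is evaluated at the maximum
#' diameter stenosis over the lesions intersecting its supply path (ostium
#' to outlet); the outlet's hyperemic flow is k times its resting flow, and
#' internal branch flows are recomputed by summation so junction
#' conservation holds exactly.
#'
#' @param assign Resting `flow_assignment` from [allocate_branch_flows()].
#' @param tree The `coronary_tree` it was computed on.
#' @param lesions List of [lesion()] objects on the tree.
#' @param ctx A [patient_context()] carrying the multiplier parameters.
#' @return A hyperemic `flow_assignment` with per-lesion flows in field
#'   `q_lesion` (mL/s, named by lesion index).
#' @export
hyperemic_flows <- function(assign, tree, lesions, ctx) {
  hp <- ctx$hyperemia
  ids <- names(assign$branches)
  # max lesion ds intersecting the supply path of each branch tip
  outlet_hyper <- list()
  for (id in ids) {
    fb <- assign$branches[[id]]
    if (fb$outlet <= 0) { outlet_hyper[[id]] <- 0; next }
    tip <- branch_range(tree$branches[[id]])[2]
    pth <- path_to(tree, tree_location(id, tip))
    mx <- 0
    for (l in lesions) {
      onp <- pth[pth$branch_id == l$branch_id, ]
      for (r in seq_len(nrow(onp)))
        if (l$s_prox < onp$s_end[r] + 1e-9 && l$s_dist > onp$s_start[r] - 1e-9)
          mx <- max(mx, l$ds)
    }
    k <- hyperemic_multiplier(mx, hp$k_max, hp$ds_lo, hp$ds_hi, hp$k_floor)
    outlet_hyper[[id]] <- k * fb$outlet
  }
  out <- assign
  for (id in ids) out$branches[[id]]$outlet <- outlet_hyper[[id]]
  # recompute piecewise flows: flow in a segment is the branch's own outlet
  # plus the subtree outlets of every child group attached distal to it
  for (id in ids) {
    fb <- out$branches[[id]]
    gsums <- vapply(fb$child_groups, function(g)
      sum(vapply(g$ids, function(kid)
        subtree_outlet_sum(out, tree, kid, outlet_hyper), 0)), 0)
    nseg <- nrow(fb$seg)
    q <- numeric(nseg)
    for (j in seq_len(nseg)) {
      distal_groups <- if (length(gsums)) gsums[seq_along(gsums) >= j] else numeric(0)
      q[j] <- outlet_hyper[[id]] + sum(distal_groups)
    }
    out$branches[[id]]$seg$q <- q
  }
  out$state <- "hyper"
  q_lesion <- vapply(lesions, function(l)
    flow_at(out, l$branch_id, (l$s_throat_start + l$s_throat_end) / 2), 0)
  out$q_lesion <- q_lesion
  out
}

#' Junction conservation residuals
#'
#' For every junction, `|q_parent_before - (sum of child inflows +
#' q_parent_after)|` relative to the inflow. Used by the test suite; should
#' be at machine precision.
#'
#' @param assign A `flow_assignment`.
#' @return Numeric vector of relative residuals (possibly empty).
#' @export
junction_residuals <- function(assign) {
  res <- numeric(0)
  for (id in names(assign$branches)) {
    fb <- assign$branches[[id]]
    for (gi in seq_along(fb$child_groups)) {
      q_before <- fb$seg$q[gi]
      q_after <- fb$seg$q[gi + 1L]
      q_kids <- sum(vapply(fb$child_groups[[gi]]$ids, function(kid)
        assign$branches[[kid]]$seg$q[1], 0))
      denom <- max(q_before, .Machine$double.eps)
      res <- c(res, abs(q_before - (q_after + q_kids)) / denom)
    }
  }
  res
}

#' Flow report table
#'
#' @param assign A `flow_assignment`.
#' @return data.frame with `branch_id`, `s0_mm`, `s1_mm`, `q_ml_s`.
#' @export
flow_table <- function(assign) {
  do.call(rbind, lapply(names(assign$branches), function(id) {
    seg <- assign$branches[[id]]$seg
    data.frame(branch_id = id, s0_mm = seg$s0, s1_mm = seg$s1,
               q_ml_s = seg$q, stringsAsFactors = FALSE)
  }))
}
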