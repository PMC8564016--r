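# Generators for idealized stenosed vessels, bifurcating trees and virtual
# cohorts. These define the study conditions every downstream stage is tested
# on: single vessels realize the three-segment lesion geometry (contracting
# taper, flat throat, expanding taper) with half-cosine radius tapers, and
# cohort parameter distributions are truncated normals centered on the
# anatomy of FFR-interrogated clinical vessels.

#' Stenosis specification
#'
#' Describes one target lesion on an otherwise healthy vessel.
#'
#' @param ds_true Target diameter stenosis, fraction in [0, 1).
#' @param L Total lesion length, mm.
#' @param L_ps,L_sd Proximal (contracting) and distal (expanding) taper
#'   lengths, mm; `L_ps + L_sd <= L` (the remainder is the flat throat).
#' @param center_s Lesion center position along the vessel, mm.
#' @param reference_radius Healthy lumen radius, mm.
#' @return An object of class `stenosis_spec`.
#' @export
stenosis_spec <- function(ds_true, L = 10.8, L_ps = 3.7, L_sd = 3.5,
                          center_s = 15, reference_radius = 1.5) {
  stopifnot(ds_true >= 0, ds_true < 1, L > 0, L_ps >= 0, L_sd >= 0,
            reference_radius > 0, center_s > 0)
  if (L_ps + L_sd > L + 1e-9)
    stop("taper lengths L_ps + L_sd exceed total lesion length L")
  structure(list(ds_true = ds_true, L = L, L_ps = L_ps, L_sd = L_sd,
                 center_s = center_s, reference_radius = reference_radius),
            class = "stenosis_spec")
}

#' Straight-tube test fixture
#'
#' Single-branch tree of constant lumen area `pi * radius^2`.
#'
#' @param length Tube length, mm.
#' @param radius Lumen radius, mm.
#' @param step Grid spacing, mm.
#' @param id Branch id.
#' @return A `coronary_tree` with one branch.
#' @export
make_straight_tube <- function(length, radius, step = 0.5, id = "root") {
  stopifnot(length > 0, radius > 0, step > 0)
  n <- max(1L, as.integer(ceiling(length / step)))
  s <- seq(0, length, length.out = n + 1L)
  coronary_tree(list(branch(id, s, rep(pi * radius^2, length(s)))),
                root_id = id,
                meta = list(generator = "straight-tube"))
}

# Radius profile of the three-segment lesion, evaluated at arc lengths s (mm).
# Half-cosine (C^1) tapers, flat throat; healthy radius outside the lesion.
stenosis_radius <- function(s, spec) {
  r_ref <- spec$reference_radius
  r_th <- r_ref * (1 - spec$ds_true)
  s0 <- spec$center_s - spec$L / 2          # lesion proximal end
  s1 <- s0 + spec$L_ps                      # throat start
  s2 <- spec$center_s + spec$L / 2 - spec$L_sd  # throat end
  s3 <- spec$center_s + spec$L / 2          # lesion distal end
  r <- rep(r_ref, length(s))
  in_ps <- s >= s0 & s < s1
  if (spec$L_ps > 0)
    r[in_ps] <- r_ref - (r_ref - r_th) * (1 - cos(pi * (s[in_ps] - s0) / spec$L_ps)) / 2
  r[s >= s1 & s <= s2] <- r_th
  in_sd <- s > s2 & s <= s3
  if (spec$L_sd > 0)
    r[in_sd] <- r_th + (r_ref - r_th) * (1 - cos(pi * (s[in_sd] - s2) / spec$L_sd)) / 2
  r
}

# Arc length offsets (from the lesion proximal end) at which the
# instantaneous diameter stenosis of the half-cosine profile crosses a given
# level; closed form, used as the analytical oracle for detected extents.
stenosis_shoulder_extent <- function(spec, ds_level) {
  if (spec$ds_true <= ds_level) return(c(NA_real_, NA_real_))
  # (1 - cos(pi u))/2 = ds_level/ds_true  =>  u
  u <- acos(1 - 2 * ds_level / spec$ds_true) / pi
  s0 <- spec$center_s - spec$L / 2
  s3 <- spec$center_s + spec$L / 2
  c(s0 + u * spec$L_ps, s3 - u * spec$L_sd)
}

#' Generate a stenosed vessel
#'
#' Single-branch tree realizing the three-segment lesion geometry: a
#' proximal contracting taper of length `L_ps`, a flat maximally stenosed
#' throat of length `L - L_ps - L_sd`, and a distal expanding taper of length
#' `L_sd`. Tapers are half-cosine in radius (smooth), so lesion detection and
#' angle estimation are exercised on non-trivial profiles. The minimal area
#' satisfies `sqrt(A_s / A_ref) = 1 - ds_true` exactly at throat grid points.
#'
#' @param spec A [stenosis_spec()].
#' @param step Grid spacing, mm.
#' @param vessel_length Total vessel length, mm; defaults to `2 * center_s`.
#' @param id Branch id.
#' @return A `coronary_tree` with one branch.
#' @export
make_stenosed_vessel <- function(spec, step = 0.25, vessel_length = NULL,
                                 id = "root") {
  stopifnot(inherits(spec, "stenosis_spec"), step > 0)
  if (is.null(vessel_length)) vessel_length <- 2 * spec$center_s
  if (spec$center_s - spec$L / 2 < 0 ||
      spec$center_s + spec$L / 2 > vessel_length)
    stop("lesion extends beyond the vessel [0, ", vessel_length, "] mm")
  n <- max(1L, as.integer(ceiling(vessel_length / step)))
  s <- seq(0, vessel_length, length.out = n + 1L)
  # include the exact segment breakpoints so throat depth is realized exactly
  brk <- c(spec$center_s - spec$L / 2,
           spec$center_s - spec$L / 2 + spec$L_ps,
           spec$center_s + spec$L / 2 - spec$L_sd,
           spec$center_s + spec$L / 2)
  brk <- brk[brk > 0 & brk < vessel_length]
  s <- sort(unique(c(s, brk)))
  r <- stenosis_radius(s, spec)
  coronary_tree(list(branch(id, s, pi * r^2)), root_id = id,
                meta = list(generator = "stenosed-vessel",
                            ds_true = spec$ds_true))
}

#' Add a stenosis to an existing branch of a tree
#'
#' Multiplies the branch radius profile by the half-cosine lesion shape.
#'
#' @param tree A `coronary_tree`.
#' @param branch_id Branch to modify.
#' @param ds_true,L,L_ps,L_sd,center_s As in [stenosis_spec()]; `center_s` is
#'   on the target branch's arc length.
#' @return The modified tree.
#' @export
add_stenosis <- function(tree, branch_id, ds_true, L = 8, L_ps = 3,
                         L_sd = 3, center_s) {
  b <- tree$branches[[branch_id]]
  if (is.null(b)) stop("unknown branch id '", branch_id, "'")
  spec <- stenosis_spec(ds_true, L = L, L_ps = L_ps, L_sd = L_sd,
                        center_s = center_s, reference_radius = 1)
  shape <- stenosis_radius(b$s, spec)   # multiplicative radius factor
  tree$branches[[branch_id]]$area <- b$area * shape^2
  validate_tree(tree)
  tree
}

#' Generate a bifurcating tree
#'
#' Binary tree of `generations` levels; each child's radius is the parent's
#' radius times the corresponding entry of `child_ratios`, and children
#' attach at the parent's distal end. Branch length scales with radius
#' (`length_factor * radius`).
#'
#' @param generations Number of levels (>= 1); 1 gives a single branch.
#' @param root_radius Root lumen radius, mm.
#' @param child_ratios Length-2 numeric, radius ratios of the two daughters.
#' @param step Grid spacing, mm.
#' @param length_factor Branch length per unit radius (default 15).
#' @return A `coronary_tree`.
#' @export
make_bifurcating_tree <- function(generations, root_radius = 2,
                                  child_ratios = c(0.8, 0.7), step = 0.5,
                                  length_factor = 15) {
  stopifnot(generations >= 1, root_radius > 0, length(child_ratios) == 2,
            all(child_ratios > 0), all(child_ratios <= 1))
  brs <- list()
  grow <- function(id, parent_id, attach_s, radius, gen) {
    len <- length_factor * radius
    n <- max(1L, as.integer(ceiling(len / step)))
    s <- seq(0, len, length.out = n + 1L)
    brs[[id]] <<- branch(id, s, rep(pi * radius^2, length(s)),
                         parent_id = parent_id, attach_s = attach_s)
    if (gen < generations) {
      grow(paste0(id, "L"), id, len, radius * child_ratios[1], gen + 1L)
      grow(paste0(id, "R"), id, len, radius * child_ratios[2], gen + 1L)
    }
  }
  grow("root", NULL, NULL, root_radius, 1L)
  coronary_tree(unname(brs), root_id = "root",
                meta = list(generator = "bifurcating-tree"))
}

# ---- virtual cohorts --------------------------------------------------------

# truncated-normal draw by rejection (bounds assumed to carry decent mass)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

ptruncnorm <- function(q, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd); phi <- stats::pnorm(upper, mean, sd)
  pmin(1, pmax(0, (stats::pnorm(q, mean, sd) - plo) / (phi - plo)))
}

#' Virtual cohort specification
#'
#' Parameter distributions are truncated normals matched to the anatomy of
#' FFR-interrogated clinical vessels (reference lumen area 6.8 +/- 3.7 mm^2
#' truncated to [3, 15] mm^2, lesion length 10.8 +/- 6.7 mm on [3, 25] mm,
#' taper lengths 3.7 +/- 3.2 mm), and to adult physiology (LV mass
#' 115 +/- 31 g on [60, 200] g; cuff pressures 134/77 mmHg). The lower area
#' bound corresponds to a ~2 mm diameter vessel, the smallest caliber at
#' which pressure-wire interrogation is performed. Diameter stenosis is drawn
#' uniform on `ds_pos_range` with probability `prevalence`, else on
#' `ds_neg_range`, so the expected fraction with `ds_true >= 0.5` equals
#' `prevalence`.
#'
#' @param n Number of virtual vessels (>= 1).
#' @param prevalence Fraction with `ds_true >= 0.5`, in [0, 1].
#' @param seed RNG seed; per-vessel substreams are derived by counter so `n`
#'   can change without reshuffling earlier vessels.
#' @param ds_pos_range,ds_neg_range Uniform ranges for diseased (>= 0.5) and
#'   non-diseased draws of `ds_true`.
#' @param area_ref Mean/sd/bounds of healthy reference area, mm^2.
#' @param lesion_len,taper_len Mean/sd/bounds of `L` and of `L_ps`, `L_sd`, mm.
#' @param lvm,sbp,dbp Mean/sd/bounds of LV mass (g) and cuff pressures (mmHg).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, prevalence = 0.43, seed = 1L,
                        ds_pos_range = c(0.5, 0.85),
                        ds_neg_range = c(0.1, 0.5),
                        area_ref = c(mean = 6.8, sd = 3.66, lo = 3, hi = 15),
                        lesion_len = c(mean = 10.77, sd = 6.74, lo = 3, hi = 25),
                        taper_len = c(mean = 3.6, sd = 3.0, lo = 0.5, hi = 8),
                        lvm = c(mean = 115, sd = 31, lo = 60, hi = 200),
                        sbp = c(mean = 134, sd = 17, lo = 100, hi = 190),
                        dbp = c(mean = 77, sd = 11, lo = 50, hi = 110)) {
  stopifnot(n >= 1, prevalence >= 0, prevalence <= 1)
  structure(list(n = as.integer(n), prevalence = prevalence,
                 seed = as.integer(seed),
                 ds_pos_range = ds_pos_range, ds_neg_range = ds_neg_range,
                 area_ref = area_ref, lesion_len = lesion_len,
                 taper_len = taper_len, lvm = lvm, sbp = sbp, dbp = dbp),
            class = "cohort_spec")
}

#' Generate a virtual cohort of stenosed vessels
#'
#' Deterministic given the spec's seed. Each entry couples a single-vessel
#' tree with a patient context whose `territory_fraction` scales the vessel's
#' share of total resting flow with its caliber (see [patient_context()]).
#'
#' @param spec A [cohort_spec()].
#' @param step Grid spacing for generated vessels, mm.
#' @return A list of entries, each a list with elements `vessel_id`, `tree`,
#'   `ctx` ([patient_context()]), `spec` ([stenosis_spec()]), `ds_true`.
#' @export
make_virtual_cohort <- function(spec, step = 0.25) {
  stopifnot(inherits(spec, "cohort_spec"))
  lapply(seq_len(spec$n), function(i) {
    # counter-derived substream: vessel i is reproducible independent of n
    set.seed((spec$seed %% 1009L) * 1000003L %% 2147483647L + i)
    diseased <- stats::runif(1) < spec$prevalence
    rng <- if (diseased) spec$ds_pos_range else spec$ds_neg_range
    ds <- stats::runif(1, rng[1], rng[2])
    a_ref <- rtruncnorm(1, spec$area_ref["mean"], spec$area_ref["sd"],
                        spec$area_ref["lo"], spec$area_ref["hi"])
    L <- rtruncnorm(1, spec$lesion_len["mean"], spec$lesion_len["sd"],
                    spec$lesion_len["lo"], spec$lesion_len["hi"])
    lps <- rtruncnorm(1, spec$taper_len["mean"], spec$taper_len["sd"],
                      spec$taper_len["lo"], min(spec$taper_len["hi"], 0.45 * L))
    lsd <- rtruncnorm(1, spec$taper_len["mean"], spec$taper_len["sd"],
                      spec$taper_len["lo"], min(spec$taper_len["hi"], 0.45 * L))
    center <- stats::runif(1, max(L / 2 + 3, 12), max(L / 2 + 8, 20))
    sspec <- stenosis_spec(ds_true = ds, L = L, L_ps = lps, L_sd = lsd,
                           center_s = center,
                           reference_radius = area_to_radius(a_ref))
    tree <- if (ds > 0) make_stenosed_vessel(sspec, step = step)
            else make_straight_tube(2 * center, area_to_radius(a_ref),
                                    step = step)
    lvm <- rtruncnorm(1, spec$lvm["mean"], spec$lvm["sd"],
                      spec$lvm["lo"], spec$lvm["hi"])
    sbp <- rtruncnorm(1, spec$sbp["mean"], spec$sbp["sd"],
                      spec$sbp["lo"], spec$sbp["hi"])
    dbp <- rtruncnorm(1, spec$dbp["mean"], spec$dbp["sd"],
                      spec$dbp["lo"], min(spec$dbp["hi"], sbp - 20))
    ctx <- patient_context(lvm = lvm, sbp = sbp, dbp = dbp,
                           territory_fraction = territory_fraction(a_ref))
    list(vessel_id = sprintf("v%04d", i), tree = tree, ctx = ctx,
         spec = sspec, ds_true = ds)
  })
}

# Caliber-scaled share of total resting coronary flow subtended by a vessel
# whose healthy reference area is a_ref (mm^2): the flow--diameter scaling
# law applied against a nominal 6.8 mm^2 proximal vessel carrying half of
# total LV flow. Capped below 1.
territory_fraction <- function(a_ref, exponent = 7 / 3) {
  min(0.9, 0.5 * (a_ref / 6.8)^(exponent / 2))
}
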