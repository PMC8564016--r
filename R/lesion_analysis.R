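# Lesion detection on lumen-area profiles and anatomical parameterization:
# A_p, A_s, A_d (areas at the proximal end, throat, distal end), L, L_ps,
# L_sd (total, contracting and expanding lengths), flow entrance/exit angles
# alpha and beta, and diameter stenosis against a disease-free reference
# profile.

#' Moving-median smoothing of an area profile
#'
#' Median over a sliding arc-length window; endpoints are handled by window
#' truncation and `window = 0` is the identity. Median (not mean) smoothing
#' removes isolated segmentation spikes without rounding lesion shoulders.
#'
#' @param b A [branch()].
#' @param window Window width, mm (>= 0).
#' @return The smoothed branch.
#' @export
smooth_area_profile <- function(b, window) {
  stopifnot(window >= 0)
  if (window == 0) return(b)
  half <- window / 2
  a <- vapply(seq_along(b$s), function(i)
    stats::median(b$area[abs(b$s - b$s[i]) <= half]), 0)
  b$area <- a
  validate_branch(b)
  b
}

#' Disease-free reference area profile
#'
#' Piecewise-linear interpolation between "healthy anchor" points: local
#' maxima of the (smoothed) area profile whose area reaches the 60th
#' percentile of the branch's areas, plus both endpoints. Between anchors
#' spanning a lesion the interpolant rides over the narrowing, providing the
#' denominator for instantaneous diameter stenosis.
#'
#' @param b A smoothed [branch()].
#' @return An object of class `reference_profile`: list with `s`, `area_ref`
#'   (mm, mm^2) on the branch grid.
#' @export
reference_area <- function(b) {
  n <- length(b$s)
  if (n < 2L) stop("branch '", b$id, "' too short for a reference profile")
  a <- b$area
  q60 <- stats::quantile(a, 0.6, names = FALSE)
  is_max <- rep(FALSE, n)
  if (n >= 3L)
    is_max[2:(n - 1L)] <- a[2:(n - 1L)] >= a[1:(n - 2L)] &
                          a[2:(n - 1L)] >= a[3:n]
  anchors <- sort(unique(c(1L, n, which(is_max & a >= q60))))
  ref <- stats::approx(b$s[anchors], a[anchors], xout = b$s)$y
  structure(list(s = b$s, area_ref = pmax(ref, .Machine$double.eps)),
            class = "reference_profile")
}

# instantaneous diameter stenosis on the branch grid
instantaneous_ds <- function(b, ref) {
  1 - sqrt(pmin(b$area / ref$area_ref, 1))
}

#' Detect lesions on an area profile
#'
#' Finds maximal contiguous intervals where the instantaneous diameter
#' stenosis `1 - sqrt(A(s)/A_ref(s))` reaches `ds_min`, then extends each
#' outward to the nearest points where it falls below `ds_min / 2` (the
#' lesion shoulders). Overlapping extended intervals are merged; results are
#' ordered proximal to distal.
#'
#' @param b A (smoothed) [branch()].
#' @param ref A [reference_area()] profile on the same grid.
#' @param ds_min Detection threshold, fraction in (0, 1); the default 0.25
#'   is the floor of the "mild" anatomical severity grade.
#' @return data.frame with columns `s_prox`, `s_dist` (mm); zero rows when
#'   no lesion is present.
#' @export
detect_lesions <- function(b, ref, ds_min = 0.25) {
  stopifnot(ds_min > 0, ds_min < 1)
  ds <- instantaneous_ds(b, ref)
  core <- ds >= ds_min
  if (!any(core))
    return(data.frame(s_prox = numeric(0), s_dist = numeric(0)))
  n <- length(ds)
  r <- rle(core)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])
  shoulder <- ds < ds_min / 2
  out <- t(apply(iv, 1, function(e) {
    i0 <- e[1]
    while (i0 > 1L && !shoulder[i0 - 1L]) i0 <- i0 - 1L
    if (i0 > 1L) i0 <- i0 - 1L           # include the crossing point
    i1 <- e[2]
    while (i1 < n && !shoulder[i1 + 1L]) i1 <- i1 + 1L
    if (i1 < n) i1 <- i1 + 1L
    c(i0, i1)
  }))
  # merge overlapping extended intervals
  out <- out[order(out[, 1]), , drop = FALSE]
  merged <- list(out[1, ])
  if (nrow(out) > 1L) for (k in 2:nrow(out)) {
    last <- merged[[length(merged)]]
    if (out[k, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], out[k, 2]))
    } else merged[[length(merged) + 1L]] <- out[k, ]
  }
  data.frame(s_prox = b$s[vapply(merged, `[`, 0, 1)],
             s_dist = b$s[vapply(merged, `[`, 0, 2)])
}

#' Parameterize a detected lesion
#'
#' Measures the anatomical inputs of the analytical pressure-drop model on a
#' lesion extent: areas at the proximal end (`A_p`), throat (`A_s`, the
#' minimum) and distal end (`A_d`); the throat as the maximal contiguous
#' region with `A <= 1.05 * A_s` (a pointwise minimum would make the throat
#' length vanish on smooth profiles); segment lengths `L`, `L_ps`, `L_sd`;
#' flow entrance and exit angles from equivalent circular radii,
#' `alpha = atan((r_p - r_s)/L_ps)` and `beta = atan((r_d - r_s)/L_sd)` in
#' degrees (90 if the corresponding taper length is zero); and diameter
#' stenosis `ds = 1 - sqrt(A_s / A_ref)` at the throat.
#'
#' @param b A (smoothed) [branch()].
#' @param ref A [reference_area()] profile.
#' @param extent Length-2 numeric `c(s_prox, s_dist)` from [detect_lesions()].
#' @param throat_tol Throat area tolerance relative to `A_s` (default 1.05).
#' @return An object of class `lesion`.
#' @export
parameterize_lesion <- function(b, ref, extent, throat_tol = 1.05) {
  idx <- which(b$s >= extent[1] - 1e-9 & b$s <= extent[2] + 1e-9)
  if (length(idx) < 3L)
    stop("lesion extent covers fewer than 3 grid points")
  s <- b$s[idx]; a <- b$area[idx]
  imin <- which.min(a)
  A_s <- a[imin]
  in_throat <- a <= throat_tol * A_s
  # maximal contiguous throat run containing the minimum
  t0 <- imin; while (t0 > 1L && in_throat[t0 - 1L]) t0 <- t0 - 1L
  t1 <- imin; while (t1 < length(a) && in_throat[t1 + 1L]) t1 <- t1 + 1L
  s_prox <- s[1]; s_dist <- s[length(s)]
  s_ts <- s[t0]; s_te <- s[t1]
  A_p <- a[1]; A_d <- a[length(a)]
  L <- s_dist - s_prox
  L_ps <- s_ts - s_prox
  L_sd <- s_dist - s_te
  r_p <- area_to_radius(A_p); r_s <- area_to_radius(A_s)
  r_d <- area_to_radius(A_d)
  alpha <- if (L_ps <= 0) 90 else atan((r_p - r_s) / L_ps) * 180 / pi
  beta <- if (L_sd <= 0) 90 else atan((r_d - r_s) / L_sd) * 180 / pi
  ref_at_min <- stats::approx(ref$s, ref$area_ref, xout = s[imin])$y
  ds <- 1 - sqrt(min(A_s / ref_at_min, 1))
  lesion(branch_id = b$id, s_prox = s_prox, s_dist = s_dist,
         s_throat_start = s_ts, s_throat_end = s_te,
         A_p = A_p, A_s = A_s, A_d = A_d,
         L = L, L_ps = L_ps, L_sd = L_sd,
         alpha = alpha, beta = beta, ds = ds)
}

#' Construct a lesion record
#'
#' Normally produced by [parameterize_lesion()]; the constructor validates
#' the geometric invariants (ordering of extents, `A_s <= min(A_p, A_d)`,
#' consistent lengths, angles in [0, 90]).
#'
#' @param branch_id Branch identifier.
#' @param s_prox,s_dist Lesion extent, mm.
#' @param s_throat_start,s_throat_end Throat extent, mm.
#' @param A_p,A_s,A_d Areas, mm^2.
#' @param L,L_ps,L_sd Lengths, mm.
#' @param alpha,beta Flow entrance/exit angles, degrees.
#' @param ds Diameter stenosis, fraction.
#' @return An object of class `lesion`.
#' @export
lesion <- function(branch_id, s_prox, s_dist, s_throat_start, s_throat_end,
                   A_p, A_s, A_d, L, L_ps, L_sd, alpha, beta, ds) {
  if (!(s_prox < s_throat_start || abs(s_prox - s_throat_start) < 1e-12) ||
      s_throat_start > s_throat_end + 1e-12 ||
      !(s_throat_end < s_dist || abs(s_throat_end - s_dist) < 1e-12))
    stop("lesion on '", branch_id, "': throat extent not ordered within lesion")
  if (A_s > min(A_p, A_d) + 1e-12)
    stop("lesion on '", branch_id, "': throat area exceeds an endpoint area")
  if (abs((s_dist - s_prox) - L) > 1e-9 ||
      abs((s_throat_start - s_prox) - L_ps) > 1e-9 ||
      abs((s_dist - s_throat_end) - L_sd) > 1e-9)
    stop("lesion on '", branch_id, "': inconsistent segment lengths")
  if (alpha < 0 || alpha > 90 || beta < 0 || beta > 90)
    stop("lesion on '", branch_id, "': angles must lie in [0, 90] degrees")
  if (ds < 0 || ds >= 1)
    stop("lesion on '", branch_id, "': ds must lie in [0, 1)")
  structure(list(branch_id = branch_id, s_prox = s_prox, s_dist = s_dist,
                 s_throat_start = s_throat_start, s_throat_end = s_throat_end,
                 A_p = A_p, A_s = A_s, A_d = A_d, L = L, L_ps = L_ps,
                 L_sd = L_sd, alpha = alpha, beta = beta, ds = ds),
            class = "lesion")
}

#' Grade anatomical stenosis severity
#'
#' Standard CT severity grades by diameter stenosis: normal (0, no plaque),
#' minimal (< 0.25), mild (0.25--0.49), moderate (0.50--0.69), severe
#' (0.70--0.99), occluded (1.0).
#'
#' @param ds Diameter stenosis, fraction in [0, 1] (vectorized).
#' @return Character vector of grades.
#' @export
grade_stenosis <- function(ds) {
  if (any(ds < 0 | ds > 1)) stop("ds must lie in [0, 1]")
  out <- character(length(ds))
  out[ds == 0] <- "normal"
  out[ds > 0 & ds < 0.25] <- "minimal"
  out[ds >= 0.25 & ds < 0.5] <- "mild"
  out[ds >= 0.5 & ds < 0.7] <- "moderate"
  out[ds >= 0.7 & ds < 1] <- "severe"
  out[ds == 1] <- "occluded"
  out
}

#' Select the dominant lesion of a vessel
#'
#' For vessels with multiple lesions, the lesion contributing the largest
#' pressure drop is selected; ties break to the proximal-most lesion.
#'
#' @param lesions Non-empty list of [lesion()] objects.
#' @param drops Numeric vector of pressure drops (mmHg), same length.
#' @return The selected `lesion`.
#' @export
dominant_lesion <- function(lesions, drops) {
  if (length(lesions) == 0L) stop("empty lesion list")
  if (length(lesions) != length(drops))
    stop("lesions and drops must have equal length")
  prox <- vapply(lesions, `[[`, 0, "s_prox")
  lesions[[order(-drops, prox)[1]]]
}

#' Detect and parameterize all lesions of a tree
#'
#' Convenience wrapper: smooths each branch, builds its reference profile,
#' detects lesions and parameterizes them.
#'
#' @param tree A `coronary_tree` (ideally already resampled).
#' @param ds_min Detection threshold (see [detect_lesions()]).
#' @param window Smoothing window, mm.
#' @return List of [lesion()] objects (possibly empty), proximal-first per
#'   branch.
#' @export
find_lesions <- function(tree, ds_min = 0.25, window = 1) {
  out <- list()
  for (b in tree$branches) {
    if (b$occluded) next
    sb <- smooth_area_profile(b, window)
    ref <- reference_area(sb)
    ext <- detect_lesions(sb, ref, ds_min)
    for (k in seq_len(nrow(ext)))
      out[[length(out) + 1L]] <-
        parameterize_lesion(sb, ref, c(ext$s_prox[k], ext$s_dist[k]))
  }
  out
}

#' Lesion table
#'
#' @param lesions List of [lesion()] objects.
#' @param path Optional CSV output path.
#' @return data.frame with one row per lesion, column names mirroring the
#'   anatomical symbols (`A_p_mm2`, `L_ps_mm`, `alpha_deg`, ...).
#' @export
lesion_table <- function(lesions, path = NULL) {
  df <- do.call(rbind, lapply(lesions, function(l)
    data.frame(branch_id = l$branch_id, s_prox_mm = l$s_prox,
               s_dist_mm = l$s_dist, A_p_mm2 = l$A_p, A_s_mm2 = l$A_s,
               A_d_mm2 = l$A_d, L_mm = l$L, L_ps_mm = l$L_ps,
               L_sd_mm = l$L_sd, alpha_deg = l$alpha, beta_deg = l$beta,
               ds = l$ds, stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame()
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
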