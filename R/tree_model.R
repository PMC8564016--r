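# Coronary tree domain types, CTREE-JSON I/O, resampling, topology queries.
#
# A branch is an arc-length-parameterized lumen-area profile; a tree is a set
# of branches connected parent->child at attachment arc lengths, rooted at the
# ostium. Arc length is 0-based at each branch origin and measured in mm;
# areas are mm^2 (area, not diameter, is the stored primitive -- equivalent
# radius is derived where needed).

#' Construct a coronary branch
#'
#' @param id Branch identifier (character scalar).
#' @param s Arc length from the branch origin, mm; strictly increasing,
#'   non-negative, length >= 2.
#' @param area Lumen cross-sectional area at each `s`, mm^2; must be positive
#'   unless the branch is flagged `occluded`.
#' @param parent_id Identifier of the parent branch, or `NULL` for the root.
#' @param attach_s Arc length on the parent where this branch originates, mm.
#' @param xyz Optional n x 3 matrix of centerline coordinates, mm.
#' @param occluded Logical; `TRUE` marks a totally occluded branch (area may
#'   be zero there). Flow and pressure operations refuse occluded branches.
#' @return An object of class `ffram_branch`.
#' @export
branch <- function(id, s, area, parent_id = NULL, attach_s = NULL,
                   xyz = NULL, occluded = FALSE) {
  stopifnot(is.character(id), length(id) == 1L)
  s <- as.numeric(s); area <- as.numeric(area)
  if (!is.null(xyz)) {
    xyz <- as.matrix(xyz)
    stopifnot(ncol(xyz) == 3L, nrow(xyz) == length(s))
  }
  b <- structure(list(id = id, parent_id = parent_id,
                      attach_s = if (is.null(attach_s)) NULL else as.numeric(attach_s),
                      s = s, area = area, xyz = xyz,
                      occluded = isTRUE(occluded)),
                 class = "ffram_branch")
  validate_branch(b)
  b
}

validate_branch <- function(b) {
  if (length(b$s) < 2L)
    stop("branch '", b$id, "': needs at least 2 centerline points")
  if (any(!is.finite(b$s)) || any(b$s < 0))
    stop("branch '", b$id, "': arc length must be finite and >= 0")
  if (any(diff(b$s) <= 0))
    stop("branch '", b$id, "': arc length must be strictly increasing")
  if (any(!is.finite(b$area)))
    stop("branch '", b$id, "': non-finite lumen area")
  if (!b$occluded && any(b$area <= 0))
    stop("branch '", b$id, "': non-positive lumen area on a branch not flagged occluded")
  if (b$occluded && any(b$area < 0))
    stop("branch '", b$id, "': negative lumen area")
  invisible(b)
}

branch_length <- function(b) b$s[length(b$s)] - b$s[1]
branch_range <- function(b) range(b$s)

#' Construct a coronary tree
#'
#' @param branches List of [branch()] objects.
#' @param root_id Identifier of the ostium (root) branch.
#' @param meta Free-form provenance list.
#' @return An object of class `coronary_tree`, validated.
#' @export
coronary_tree <- function(branches, root_id, meta = list()) {
  names(branches) <- vapply(branches, `[[`, "", "id")
  tr <- structure(list(branches = branches, root_id = root_id, meta = meta),
                  class = "coronary_tree")
  validate_tree(tr)
  tr
}

#' Validate a coronary tree
#'
#' Checks every branch invariant plus: exactly one root, every non-root
#' `parent_id` resolves, attachment arc lengths lie within the parent's range,
#' no cycles, and the tree is connected.
#'
#' @param tree A `coronary_tree`.
#' @return The tree, invisibly; errors name the offending branch and rule.
#' @export
validate_tree <- function(tree) {
  brs <- tree$branches
  if (length(brs) == 0L) stop("tree has no branches")
  ids <- names(brs)
  if (anyDuplicated(ids)) stop("duplicate branch ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (b in brs) validate_branch(b)
  roots <- ids[vapply(brs, function(b) is.null(b$parent_id), TRUE)]
  if (length(roots) != 1L)
    stop("tree must have exactly one root branch, found ", length(roots))
  if (!identical(roots, tree$root_id))
    stop("root_id '", tree$root_id, "' does not match the parentless branch '",
         roots, "'")
  for (b in brs) {
    if (is.null(b$parent_id)) next
    p <- brs[[b$parent_id]]
    if (is.null(p))
      stop("branch '", b$id, "': parent_id '", b$parent_id, "' does not resolve")
    if (is.null(b$attach_s))
      stop("branch '", b$id, "': non-root branch lacks attach_s")
    rng <- branch_range(p)
    if (b$attach_s < rng[1] - 1e-9 || b$attach_s > rng[2] + 1e-9)
      stop("branch '", b$id, "': attach_s ", b$attach_s,
           " outside parent '", p$id, "' range [", rng[1], ", ", rng[2], "]")
  }
  # connectivity / acyclicity: walk to root from every branch
  for (b in brs) {
    seen <- character()
    cur <- b
    while (!is.null(cur$parent_id)) {
      if (cur$id %in% seen)
        stop("cycle detected through branch '", cur$id, "'")
      seen <- c(seen, cur$id)
      cur <- brs[[cur$parent_id]]
    }
    if (cur$id != tree$root_id)
      stop("branch '", b$id, "': not connected to root")
  }
  invisible(tree)
}

#' A location on the tree
#'
#' @param branch_id Branch identifier.
#' @param s Arc length on that branch, mm.
#' @return An object of class `tree_location`.
#' @export
tree_location <- function(branch_id, s) {
  structure(list(branch_id = branch_id, s = as.numeric(s)),
            class = "tree_location")
}

children_of <- function(tree, id) {
  kids <- Filter(function(b) identical(b$parent_id, id), tree$branches)
  if (length(kids) == 0L) return(kids)
  kids[order(vapply(kids, `[[`, 0, "attach_s"))]
}

#' Path from the ostium to a tree location
#'
#' Returns the contiguous chain of branch segments traversed from the root
#' origin down to `loc`: on each ancestor, the interval from its origin to
#' the attachment point of the next branch in the chain; on the target
#' branch, the interval from its origin to `loc$s`.
#'
#' @param tree A `coronary_tree`.
#' @param loc A [tree_location()].
#' @return A data.frame with columns `branch_id`, `s_start`, `s_end`
#'   (mm), ordered root -> target. Interval lengths sum to the path length.
#' @export
path_to <- function(tree, loc) {
  b <- tree$branches[[loc$branch_id]]
  if (is.null(b)) stop("unknown branch id '", loc$branch_id, "'")
  rng <- branch_range(b)
  if (loc$s < rng[1] - 1e-9 || loc$s > rng[2] + 1e-9)
    stop("location s=", loc$s, " outside branch '", b$id, "' range")
  rows <- list(data.frame(branch_id = b$id, s_start = rng[1],
                          s_end = loc$s, stringsAsFactors = FALSE))
  while (!is.null(b$parent_id)) {
    att <- b$attach_s
    b <- tree$branches[[b$parent_id]]
    rows <- c(list(data.frame(branch_id = b$id, s_start = branch_range(b)[1],
                              s_end = att, stringsAsFactors = FALSE)), rows)
  }
  do.call(rbind, rows)
}

# Shape-preserving cubic Hermite interpolation (Fritsch--Butland slopes):
# harmonic-mean slopes where the data are locally monotone, zero slope at
# local extrema. On every interval the interpolant stays between the two
# bracketing data values, so resampling can never overshoot.
monotone_cubic_interp <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x); d <- diff(y) / h
  m <- numeric(n)
  m[1] <- d[1]; m[n] <- d[n - 1L]
  if (n > 2L) for (i in 2:(n - 1L)) {
    if (d[i - 1L] * d[i] <= 0) m[i] <- 0
    else m[i] <- 2 / (1 / d[i - 1L] + 1 / d[i])
  }
  # clamp endpoint slopes into the monotonicity region
  if (d[1] == 0) m[1] <- 0 else m[1] <- sign(d[1]) * min(abs(m[1]), 3 * abs(d[1]))
  if (d[n - 1L] == 0) m[n] <- 0 else
    m[n] <- sign(d[n - 1L]) * min(abs(m[n]), 3 * abs(d[n - 1L]))
  k <- pmin(pmax(findInterval(xout, x), 1L), n - 1L)
  t <- (xout - x[k]) / h[k]
  h00 <- (1 + 2 * t) * (1 - t)^2; h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t);       h11 <- t^2 * (t - 1)
  h00 * y[k] + h10 * h[k] * m[k] + h01 * y[k + 1L] + h11 * h[k] * m[k + 1L]
}

#' Resample a branch onto a uniform arc-length grid
#'
#' Monotone-cubic (shape-preserving Hermite) interpolation of the area
#' profile onto a uniform grid with spacing at most `step`; endpoints are
#' preserved exactly and interpolated areas never overshoot the bracketing
#' input areas, so resampling cannot create phantom stenoses. Optional 3D
#' coordinates are interpolated linearly.
#'
#' @param b A [branch()].
#' @param step Target grid spacing, mm (> 0).
#' @return A resampled `ffram_branch`. If `step` exceeds the branch length
#'   the result keeps only the two endpoints.
#' @export
resample_branch <- function(b, step) {
  stopifnot(step > 0)
  len <- branch_length(b)
  n <- max(1L, as.integer(ceiling(len / step)))
  s_out <- seq(b$s[1], b$s[length(b$s)], length.out = n + 1L)
  area_out <- monotone_cubic_interp(b$s, b$area, s_out)
  # guard endpoints against rounding
  area_out[1] <- b$area[1]
  area_out[length(area_out)] <- b$area[length(b$area)]
  xyz_out <- NULL
  if (!is.null(b$xyz))
    xyz_out <- vapply(1:3, function(j)
      stats::approx(b$s, b$xyz[, j], xout = s_out)$y, numeric(length(s_out)))
  branch(b$id, s_out, area_out, parent_id = b$parent_id,
         attach_s = b$attach_s, xyz = xyz_out, occluded = b$occluded)
}

#' Resample every branch of a tree
#'
#' @param tree A `coronary_tree`.
#' @param step Grid spacing, mm.
#' @return The tree with all branches resampled.
#' @export
resample_tree <- function(tree, step) {
  tree$branches <- lapply(tree$branches, resample_branch, step = step)
  validate_tree(tree)
  tree
}

# ---- CTREE-JSON I/O ---------------------------------------------------------

#' Read a coronary tree from a CTREE-JSON file
#'
#' The schema is `{"format": "ctree-json/1", "root_id": str, "branches":
#' [{"id", "parent_id", "attach_s_mm", "points": [{"s_mm", "area_mm2",
#' "x_mm"?, "y_mm"?, "z_mm"?}], "occluded"?}], "meta": {}}`. Lengths are mm,
#' areas mm^2; the original units are recorded in `meta$units`.
#'
#' @param path File path.
#' @return A validated `coronary_tree`.
#' @export
load_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed CTREE-JSON in '", path,
                                           "': ", conditionMessage(e)))
  if (!identical(raw$format, "ctree-json/1"))
    stop("malformed CTREE-JSON: key 'format' must be \"ctree-json/1\"")
  if (is.null(raw$root_id)) stop("malformed CTREE-JSON: missing key 'root_id'")
  if (is.null(raw$branches)) stop("malformed CTREE-JSON: missing key 'branches'")
  brs <- lapply(raw$branches, function(rb) {
    if (is.null(rb$id)) stop("malformed CTREE-JSON: branch missing key 'id'")
    if (is.null(rb$points)) stop("malformed CTREE-JSON: branch '", rb$id,
                                 "' missing key 'points'")
    s <- vapply(rb$points, function(p) {
      if (is.null(p$s_mm)) stop("malformed CTREE-JSON: branch '", rb$id,
                                "' point missing key 's_mm'")
      as.numeric(p$s_mm)
    }, 0)
    area <- vapply(rb$points, function(p) {
      if (is.null(p$area_mm2)) stop("malformed CTREE-JSON: branch '", rb$id,
                                    "' point missing key 'area_mm2'")
      as.numeric(p$area_mm2)
    }, 0)
    has_xyz <- all(vapply(rb$points, function(p)
      !is.null(p$x_mm) && !is.null(p$y_mm) && !is.null(p$z_mm), TRUE))
    xyz <- NULL
    if (has_xyz)
      xyz <- t(vapply(rb$points, function(p)
        c(as.numeric(p$x_mm), as.numeric(p$y_mm), as.numeric(p$z_mm)),
        numeric(3)))
    branch(rb$id, s, area,
           parent_id = if (is.null(rb$parent_id)) NULL else rb$parent_id,
           attach_s = if (is.null(rb$attach_s_mm)) NULL else rb$attach_s_mm,
           xyz = xyz, occluded = isTRUE(rb$occluded))
  })
  meta <- if (is.null(raw$meta)) list() else raw$meta
  if (is.null(meta$units)) meta$units <- list(length = "mm", area = "mm2")
  coronary_tree(brs, root_id = raw$root_id, meta = meta)
}

#' Write a coronary tree to a CTREE-JSON file
#'
#' Lossless for all fields up to numeric formatting; refuses trees with
#' non-finite areas.
#'
#' @param tree A valid `coronary_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_tree <- function(tree, path) {
  validate_tree(tree)
  if (is.null(tree$meta$units))
    tree$meta$units <- list(length = "mm", area = "mm2")
  enc <- list(
    format = "ctree-json/1",
    root_id = tree$root_id,
    branches = lapply(unname(tree$branches), function(b) {
      pts <- lapply(seq_along(b$s), function(i) {
        p <- list(s_mm = b$s[i], area_mm2 = b$area[i])
        if (!is.null(b$xyz)) {
          p$x_mm <- b$xyz[i, 1]; p$y_mm <- b$xyz[i, 2]; p$z_mm <- b$xyz[i, 3]
        }
        p
      })
      out <- list(id = b$id, parent_id = b$parent_id,
                  attach_s_mm = b$attach_s, points = pts)
      if (b$occluded) out$occluded <- TRUE
      out
    }),
    meta = tree$meta
  )
  txt <- jsonlite::toJSON(enc, auto_unbox = TRUE, digits = NA, null = "null",
                          pretty = TRUE)
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) stop("cannot write tree to '", path,
                                          "': ", conditionMessage(e)))
  invisible(path)
}

#' Export a tree as a per-branch CSV
#'
#' Columns: `branch_id`, `s_mm`, `area_mm2`.
#'
#' @param tree A `coronary_tree`.
#' @param path Output CSV path (optional).
#' @return The data.frame, invisibly if written.
#' @export
tree_to_csv <- function(tree, path = NULL) {
  df <- do.call(rbind, lapply(unname(tree$branches), function(b)
    data.frame(branch_id = b$id, s_mm = b$s, area_mm2 = b$area,
               stringsAsFactors = FALSE)))
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @export
print.coronary_tree <- function(x, ...) {
  npts <- sum(vapply(x$branches, function(b) length(b$s), 0L))
  cat("<coronary_tree> ", length(x$branches), " branch(es), ", npts,
      " points, root '", x$root_id, "'\n", sep = "")
  invisible(x)
}
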