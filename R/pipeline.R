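# End-to-end orchestration: geometry -> lesions -> flows -> FFR -> report,
# plus configuration, patient-file I/O, synthetic presets and provenance.
# All run parameters live in a single serializable config so any run can be
# pinned and reproduced exactly.

#' Run configuration
#'
#' Every tunable of the pipeline with its default. All values are
#' serializable to YAML ([write_config()] / [read_config()]) and echoed in
#' the provenance record of each run.
#'
#' @param grid_step Resampling grid spacing, mm.
#' @param smooth_window Area-smoothing window, mm.
#' @param ds_min Lesion-detection threshold (fraction).
#' @param throat_tol Throat area tolerance relative to the minimum.
#' @param q0 Resting perfusion, mL/min/g.
#' @param exponent Flow--diameter scaling-law exponent.
#' @param k_max,ds_lo,ds_hi,k_floor Hyperemic multiplier parameters.
#' @param mu,rho Blood viscosity (Pa s) and density (kg/m^3).
#' @param pa_offset Hyperemic aortic-pressure offset, mmHg.
#' @param ischemia_threshold FFR ischemia threshold.
#' @param include_bernoulli_net Loss-model flag (see
#'   [lesion_pressure_drop()]).
#' @param ffr_floor FFR clamp floor.
#' @param seed RNG seed for synthetic generation.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(grid_step = 0.25, smooth_window = 1, ds_min = 0.25,
                       throat_tol = 1.05, q0 = 0.8, exponent = 7 / 3,
                       k_max = 4, ds_lo = 0.3, ds_hi = 0.9, k_floor = 1,
                       mu = 3.5e-3, rho = 1060, pa_offset = 6.8,
                       ischemia_threshold = 0.8,
                       include_bernoulli_net = FALSE, ffr_floor = 0.01,
                       seed = 1L) {
  structure(list(grid_step = grid_step, smooth_window = smooth_window,
                 ds_min = ds_min, throat_tol = throat_tol, q0 = q0,
                 exponent = exponent, k_max = k_max, ds_lo = ds_lo,
                 ds_hi = ds_hi, k_floor = k_floor, mu = mu, rho = rho,
                 pa_offset = pa_offset,
                 ischemia_threshold = ischemia_threshold,
                 include_bernoulli_net = include_bernoulli_net,
                 ffr_floor = ffr_floor, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Read / write a patient JSON file
#'
#' Schema: `{"lvm_g": n, "sbp_mmHg": n, "dbp_mmHg": n, "hct"?: n,
#' "territory_fraction"?: n}`.
#'
#' @param path JSON file path.
#' @param config A `run_config` supplying physiology defaults.
#' @return A [patient_context()].
#' @export
load_patient <- function(path, config = run_config()) {
  raw <- jsonlite::fromJSON(path)
  for (key in c("lvm_g", "sbp_mmHg", "dbp_mmHg"))
    if (is.null(raw[[key]])) stop("patient file missing key '", key, "'")
  patient_context(lvm = raw$lvm_g, sbp = raw$sbp_mmHg, dbp = raw$dbp_mmHg,
                  hct = raw$hct, q0 = config$q0, mu = config$mu,
                  rho = config$rho, k_max = config$k_max,
                  ds_lo = config$ds_lo, ds_hi = config$ds_hi,
                  k_floor = config$k_floor,
                  territory_fraction =
                    if (is.null(raw$territory_fraction)) 1
                    else raw$territory_fraction)
}

#' @rdname load_patient
#' @param ctx A [patient_context()].
#' @export
save_patient <- function(ctx, path) {
  enc <- list(lvm_g = ctx$lvm, sbp_mmHg = ctx$sbp, dbp_mmHg = ctx$dbp)
  if (!is.null(ctx$hct)) enc$hct <- ctx$hct
  if (ctx$territory_fraction != 1)
    enc$territory_fraction <- ctx$territory_fraction
  writeLines(jsonlite::toJSON(enc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Compute FFR for a tree and patient
#'
#' The full analytical pipeline: resample the tree, smooth each branch,
#' detect and parameterize lesions, estimate resting flow from LV mass and
#' allocate it by the scaling law, apply the hyperemic multiplier, and
#' assemble the FFR profile with per-lesion pressure-drop breakdowns.
#'
#' @param tree A `coronary_tree`.
#' @param ctx A [patient_context()].
#' @param config A [run_config()].
#' @return List: `profile` ([ffr_profile()]), `lesions` (list of
#'   [lesion()]), `flows_rest`, `flows_hyper`, `pa` (mmHg), `q_total`
#'   (mL/s entering the tree), `config`.
#' @export
compute_ffr <- function(tree, ctx, config = run_config()) {
  rt <- resample_tree(tree, config$grid_step)
  rt$branches <- lapply(rt$branches, smooth_area_profile,
                        window = config$smooth_window)
  lesions <- find_lesions(rt, ds_min = config$ds_min,
                          window = 0)   # already smoothed
  pa <- mean_aortic_pressure(ctx$sbp, ctx$dbp, offset = config$pa_offset)
  q_total <- total_resting_flow(ctx) * ctx$territory_fraction
  rest <- allocate_branch_flows(rt, q_total, exponent = config$exponent)
  hyper <- hyperemic_flows(rest, rt, lesions, ctx)
  profile <- ffr_profile(rt, hyper, lesions, pa, mu = ctx$mu, rho = ctx$rho,
                         floor = config$ffr_floor,
                         include_bernoulli_net = config$include_bernoulli_net)
  list(profile = profile, lesions = lesions, flows_rest = rest,
       flows_hyper = hyper, pa = pa, q_total = q_total, config = config)
}

file_hash <- function(path) unname(tools::md5sum(path))

object_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  file_hash(tmp)
}

#' Run the pipeline on files and write a report
#'
#' Reads a CTREE-JSON tree and a patient JSON, runs [compute_ffr()], and
#' writes `ffr.csv` (per-point profile), `lesions.csv` (per-lesion
#' anatomy, pressure-drop breakdown, distal FFR, ischemia call) and
#' `provenance.json` (config, config hash, input hashes, package version)
#' into `out_dir`. Outputs carry no timestamps, so two runs with identical
#' inputs and config are byte-identical.
#'
#' @param tree_path,patient_path Input files.
#' @param out_dir Output directory (created if missing).
#' @param config A [run_config()].
#' @return The [compute_ffr()] result, invisibly.
#' @export
ffr_compute <- function(tree_path, patient_path, out_dir,
                        config = run_config()) {
  tree <- load_tree(tree_path)
  ctx <- load_patient(patient_path, config)
  res <- compute_ffr(tree, ctx, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prof_df <- do.call(rbind, lapply(names(res$profile$branches), function(id)
    cbind(branch_id = id, res$profile$branches[[id]],
          stringsAsFactors = FALSE)))
  utils::write.csv(prof_df, file.path(out_dir, "ffr.csv"), row.names = FALSE)
  ldf <- if (is.null(res$profile$lesions)) data.frame() else {
    anat <- lesion_table(res$lesions)
    cbind(anat, res$profile$lesions[, c("dp_ps_mmHg", "dp_ss_mmHg",
                                        "dp_sd_mmHg", "dp1_mmHg",
                                        "dp2_mmHg", "ffr_distal",
                                        "ischemic")])
  }
  utils::write.csv(ldf, file.path(out_dir, "lesions.csv"), row.names = FALSE)
  prov <- list(package = "ffram",
               version = as.character(utils::packageVersion("ffram")),
               config = unclass(config),
               config_hash = object_hash(unclass(config)),
               inputs = list(tree = file_hash(tree_path),
                             patient = file_hash(patient_path)),
               pa_mmHg = res$pa, q_total_ml_s = res$q_total,
               n_lesions = length(res$lesions))
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "provenance.json"))
  invisible(res)
}

#' Emit synthetic fixture files
#'
#' Presets: `"straight-tube"` (healthy 3 mm vessel), `"single-lad"` (one
#' stenosed vessel; severity via `ds`), `"left-tree"` (two-generation
#' bifurcating tree with a stenosis on one daughter), `"cohort"` (`n`
#' vessels with a manifest CSV).
#'
#' @param preset Preset name.
#' @param out_dir Output directory.
#' @param ds Diameter stenosis for lesion-bearing presets.
#' @param n,prevalence,seed Cohort parameters.
#' @param step Grid spacing, mm.
#' @return Invisibly, the written file paths.
#' @export
synth_preset <- function(preset, out_dir, ds = 0.5, n = 20,
                         prevalence = 0.43, seed = 1L, step = 0.25) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ctx <- patient_context()
  paths <- character(0)
  emit <- function(tree, ctx, stem) {
    tp <- file.path(out_dir, paste0(stem, ".ctree.json"))
    pp <- file.path(out_dir, paste0(stem, ".patient.json"))
    save_tree(tree, tp); save_patient(ctx, pp)
    c(tp, pp)
  }
  if (preset == "straight-tube") {
    paths <- emit(make_straight_tube(30, 1.5, step), ctx, "straight-tube")
  } else if (preset == "single-lad") {
    if (ds < 0 || ds >= 1) stop("ds must lie in [0, 1)")
    tree <- make_stenosed_vessel(stenosis_spec(ds_true = ds), step = step)
    paths <- emit(tree, ctx, "single-lad")
  } else if (preset == "left-tree") {
    if (ds < 0 || ds >= 1) stop("ds must lie in [0, 1)")
    tree <- make_bifurcating_tree(2, root_radius = 2, step = step)
    tree <- add_stenosis(tree, "rootL", ds_true = ds, center_s = 12)
    paths <- emit(tree, ctx, "left-tree")
  } else if (preset == "cohort") {
    cohort <- make_virtual_cohort(cohort_spec(n = n, prevalence = prevalence,
                                              seed = seed), step = step)
    rows <- lapply(cohort, function(e) {
      p <- emit(e$tree, e$ctx, e$vessel_id)
      paths <<- c(paths, p)
      data.frame(vessel_id = e$vessel_id, ds_true = e$ds_true,
                 tree_file = basename(p[1]), patient_file = basename(p[2]),
                 stringsAsFactors = FALSE)
    })
    mf <- file.path(out_dir, "manifest.csv")
    utils::write.csv(do.call(rbind, rows), mf, row.names = FALSE)
    paths <- c(paths, mf)
  } else {
    stop("unknown preset '", preset,
         "'; available: straight-tube, single-lad, left-tree, cohort")
  }
  invisible(paths)
}

#' Evaluate a paired per-vessel CSV
#'
#' Reads a CSV with columns `vessel_id`, `patient_id` (optional),
#' `ffr_invasive`, and any of `ffr_am`, `ffr_b`, `ds_ctca`, `ds_ica`
#' (fractions), runs [eval_report()], and writes `metrics.csv` and
#' `delong.csv` to `out_dir`.
#'
#' @param pairs_csv Input CSV path.
#' @param out_dir Output directory.
#' @param ... Passed to [eval_report()].
#' @return The report list, invisibly.
#' @export
ffr_eval <- function(pairs_csv, out_dir, ...) {
  records <- utils::read.csv(pairs_csv, stringsAsFactors = FALSE)
  need <- c("vessel_id", "ffr_invasive")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("input CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  rep <- eval_report(records, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rep$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(rep$delong))
    utils::write.csv(rep$delong, file.path(out_dir, "delong.csv"),
                     row.names = FALSE)
  invisible(rep)
}
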