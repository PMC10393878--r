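#' Default synthetic vessel cohort
#'
#' Draws a cohort of synthetic stenosed vessels emulating the usual
#' interventional case mix: percent diameter stenosis uniform in
#' [30, 90]%, reference diameter uniform in [2.5, 4.0] mm, 30 mm straight
#' vessels with a single mid-vessel lesion of 6-14 mm length. The default
#' size (40 vessels, seed 20230421) mirrors a 40-vessel paired analysis
#' set. The generator is deterministic given the seed.
#'
#' @param n Number of vessels.
#' @param seed RNG seed.
#' @param stenosis_range,diameter_range Uniform draw bounds.
#' @return List of [stenosis_spec()] objects (named case_01, ...).
#' @export
synthetic_cohort <- function(n = 40, seed = 20230421,
                             stenosis_range = c(30, 90),
                             diameter_range = c(2.5, 4.0)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  specs <- lapply(seq_len(n), function(i) {
    stenosis_spec(
      reference_diameter = stats::runif(1, diameter_range[1], diameter_range[2]),
      stenosis_pct = stats::runif(1, stenosis_range[1], stenosis_range[2]),
      lesion_length = stats::runif(1, 6, 14),
      lesion_center = stats::runif(1, 12, 18),
      eccentricity = 0,
      vessel_length = 30)
  })
  names(specs) <- sprintf("case_%02d", seq_len(n))
  specs
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Run the mesh-fidelity benchmarking sweep over a cohort
#'
#' Every vessel is solved (paired flows) at every fidelity plus a
#' finest-mesh reference arm (2x the 100%-fidelity cell target, same
#' solver), preserving the paired design. Cases whose solver fails at any
#' arm are excluded from the paired analyses and enumerated in the result.
#'
#' @param specs List of [stenosis_spec()] (or `vessel_geometry`) objects.
#' @param fidelities Fidelity percentages (default 10, 25, 50, 75, 100).
#' @param n_min,n_max Fidelity cell budget.
#' @param reference_factor Reference-arm cell target as a multiple of
#'   `n_max`.
#' @param fluid,controls,Pa,R_mv,flows Passed to [vffr_case()].
#' @param axial_samples,circumferential_samples Surface sampling used when
#'   specs are generated into geometries.
#' @param verbose Print per-case progress.
#' @return A `fidelity_sweep` with `records` (one row per case x arm:
#'   `case_id`, `method`, `fidelity_percent`, `n_cells`, `duration_s`,
#'   `vffr`, `converged`) and `excluded`.
#' @export
fidelity_sweep <- function(specs, fidelities = c(10, 25, 50, 75, 100),
                           n_min = 8000, n_max = 160000,
                           reference_factor = 2,
                           fluid = fluid_properties(),
                           controls = solver_controls(),
                           Pa = 100, R_mv = 25, flows = c(1, 3),
                           axial_samples = 96,
                           circumferential_samples = 32,
                           verbose = FALSE) {
  if (!length(specs)) .stopf("fidelity_sweep: empty cohort")
  ids <- names(specs) %||% sprintf("case_%02d", seq_along(specs))
  if (is.null(names(specs))) names(specs) <- ids
  ref_cells <- round(reference_factor * n_max)
  rows <- list()
  excluded <- character(0)
  for (id in ids) {
    sp <- specs[[id]]
    geom <- if (inherits(sp, "vessel_geometry")) sp
            else make_stenosed_vessel(sp, axial_samples,
                                      circumferential_samples)
    arms <- c(list(list(method = "reference", percent = NA_integer_,
                        fid = structure(list(percent = 100L,
                                             target_cells = ref_cells,
                                             n_min = n_min,
                                             n_max = ref_cells),
                                        class = "fidelity_level"))),
              lapply(fidelities, function(p)
                list(method = "fidelity_sweep", percent = as.integer(p),
                     fid = fidelity_level(p, n_min, n_max))))
    case_rows <- list()
    ok <- TRUE
    for (arm in arms) {
      res <- tryCatch(
        vffr_case(geom, arm$fid, flows = flows, fluid = fluid,
                  controls = controls, Pa = Pa, R_mv = R_mv),
        error = function(e) e)
      if (inherits(res, "error")) {
        ok <- FALSE
        if (verbose)
          message(sprintf("  %s @ %s: EXCLUDED (%s)", id,
                          arm$method, conditionMessage(res)))
        break
      }
      case_rows[[length(case_rows) + 1L]] <- data.frame(
        case_id = id, method = arm$method,
        fidelity_percent = arm$percent,
        n_cells = res$n_cells, duration_s = res$duration_s,
        vffr = res$vffr, converged = res$converged,
        stenosis_pct = if (!is.null(geom$spec)) geom$spec$stenosis_pct
                       else NA_real_)
    }
    if (!ok) { excluded <- c(excluded, id); next }
    rows <- c(rows, case_rows)
    if (verbose)
      message(sprintf("%s: vFFR(ref) %.4f [%s]", id,
                      case_rows[[1]]$vffr,
                      paste(sprintf("%.3f", vapply(case_rows[-1], `[[`,
                                                   numeric(1), "vffr")),
                            collapse = " ")))
  }
  records <- do.call(rbind, rows)
  structure(list(records = records, excluded = excluded,
                 fidelities = fidelities,
                 n_min = n_min, n_max = n_max,
                 reference_cells = ref_cells),
            class = "fidelity_sweep")
}

#' @export
print.fidelity_sweep <- function(x, ...) {
  cat(sprintf("<fidelity_sweep> %d cases x %d arms, %d excluded\n",
              length(unique(x$records$case_id)),
              length(x$fidelities) + 1L, length(x$excluded)))
  print(sweep_summary(x)$by_fidelity, row.names = FALSE)
  invisible(x)
}

#' Summarize a fidelity sweep (duration/accuracy tables)
#'
#' Produces the per-fidelity median/IQR of simulation duration and of
#' accuracy relative to the reference arm, paired Wilcoxon signed-rank
#' tests between adjacent fidelities (and against the reference),
#' Bland-Altman agreement per fidelity, threshold concordance, and the
#' per-fidelity regression of accuracy on reference vFFR with the ANCOVA
#' slope comparison. Quantiles use the type-7 (linear interpolation)
#' convention.
#'
#' @param sweep A [fidelity_sweep()] result.
#' @param conf_level Confidence level requested for the signed-rank CIs.
#' @param threshold Decision threshold for concordance.
#' @return A `sweep_summary` list: `by_fidelity`, `pairwise_duration`,
#'   `pairwise_accuracy`, `bland_altman`, `concordance`, `regression`.
#' @export
sweep_summary <- function(sweep, conf_level = 0.95, threshold = 0.80) {
  rec <- sweep$records
  ref <- rec[rec$method == "reference", c("case_id", "duration_s", "vffr")]
  names(ref)[2:3] <- c("ref_duration_s", "vffr_ref")
  fs <- rec[rec$method == "fidelity_sweep", ]
  fs <- merge(fs, ref, by = "case_id")
  fs$accuracy_pct <- accuracy_pct(fs$vffr, fs$vffr_ref)
  fs$difference <- fs$vffr_ref - fs$vffr
  fs$mean_vffr <- (fs$vffr_ref + fs$vffr) / 2

  qf <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), type = 7,
                                    names = FALSE)
  fids <- sort(unique(fs$fidelity_percent))
  by_fid <- do.call(rbind, lapply(fids, function(p) {
    sub <- fs[fs$fidelity_percent == p, ]
    qd <- qf(sub$duration_s); qa <- qf(sub$accuracy_pct)
    data.frame(fidelity_percent = p, n = nrow(sub),
               duration_median = qd[2], duration_iqr_low = qd[1],
               duration_iqr_high = qd[3],
               accuracy_median = qa[2], accuracy_iqr_low = qa[1],
               accuracy_iqr_high = qa[3],
               vffr_median = median(sub$vffr))
  }))

  pair_test <- function(col) {
    cmp <- list()
    for (i in seq_along(fids)[-1]) {
      a <- fs[fs$fidelity_percent == fids[i - 1], c("case_id", col)]
      b <- fs[fs$fidelity_percent == fids[i], c("case_id", col)]
      m <- merge(a, b, by = "case_id")
      d <- m[[paste0(col, ".y")]] - m[[paste0(col, ".x")]]
      w <- wilcoxon_signed_rank(d, conf_level = conf_level)
      cmp[[length(cmp) + 1L]] <- data.frame(
        comparison = sprintf("%d%% vs %d%%", fids[i], fids[i - 1]),
        median_difference = w$median_difference,
        ci_low = w$conf_int[1], ci_high = w$conf_int[2],
        achieved_level = w$achieved_level, p_value = w$p_value)
    }
    do.call(rbind, cmp)
  }

  ba <- lapply(setNames(fids, paste0("fidelity_", fids)), function(p) {
    sub <- fs[fs$fidelity_percent == p, ]
    bland_altman(sub$difference, means = sub$mean_vffr)
  })
  conc <- lapply(setNames(fids, paste0("fidelity_", fids)), function(p) {
    sub <- fs[fs$fidelity_percent == p, ]
    concordance_at_threshold(sub$vffr_ref, sub$vffr, threshold = threshold,
                             case_id = sub$case_id)
  })
  reg <- regression_with_slope_compare(fs$vffr_ref, fs$accuracy_pct,
                                       fs$fidelity_percent)
  structure(list(by_fidelity = by_fid,
                 pairwise_duration = pair_test("duration_s"),
                 pairwise_accuracy = pair_test("accuracy_pct"),
                 bland_altman = ba, concordance = conc, regression = reg,
                 pairs = fs),
            class = "sweep_summary")
}

#' Write / read benchmark records as CSV
#'
#' Documented schema: `case_id`, `method` (`reference` or
#' `fidelity_sweep`), `fidelity_percent` (empty for the reference arm),
#' `n_cells`, `duration_s`, `vffr`, `converged`, `stenosis_pct`.
#'
#' @param records The `records` data.frame of a [fidelity_sweep()].
#' @param path CSV path.
#' @return `path` (write) / the records data.frame (read).
#' @export
write_benchmark_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_benchmark_csv
#' @export
read_benchmark_csv <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "method", "fidelity_percent", "duration_s", "vffr",
            "converged")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    .stopf("read_benchmark_csv: missing columns: %s",
           paste(miss, collapse = ", "))
  rec
}
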