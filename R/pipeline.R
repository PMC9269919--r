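# Cohort-level orchestration: segmentation -> IIR quantification ->
# longitudinal change -> group summaries -> exact tests -> QC, mirroring
# the structure of a paired baseline / post-pacing animal study.

#' Simulate a synthetic cohort
#'
#' Generates paired baseline / post-pacing phantoms for `n_exp`
#' experimental animals (fibrosis increment `delta_f`) and `n_ctrl`
#' controls (no increment).  Per-timepoint biological variation of the
#' fibrosis fraction is drawn as Gaussian jitter with SD `f_jitter_sd`, so
#' repeated measurements differ slightly even in controls, as in any real
#' study.
#'
#' @param n_exp,n_ctrl group sizes (defaults 9 and 3).
#' @param f_baseline baseline fibrosis fraction of wall voxels.
#' @param delta_f post-pacing increment for the experimental group.
#' @param f_jitter_sd SD of per-timepoint fraction jitter (0 disables).
#' @param spec template [phantom_spec()]; its `fibrosis_fraction` and
#'   `seed` are overridden per animal/timepoint.
#' @param seed cohort seed; all per-animal seeds derive from it.
#' @return A list of class `study_cohort`; one element per animal with
#'   `id`, `group`, and `timepoints$baseline` / `timepoints$post` holding
#'   `la_phantom` objects.
#' @export
simulate_cohort <- function(n_exp = 9L, n_ctrl = 3L, f_baseline = 0.05,
                            delta_f = 0.02, f_jitter_sd = 0.002,
                            spec = phantom_spec(), seed = 1L) {
  n <- n_exp + n_ctrl
  groups <- c(rep("experimental", n_exp), rep("control", n_ctrl))
  params <- with_seed(seed, {
    data.frame(
      seed_b = sample.int(.Machine$integer.max - 1L, n),
      seed_p = sample.int(.Machine$integer.max - 1L, n),
      jit_b = stats::rnorm(n, 0, f_jitter_sd),
      jit_p = stats::rnorm(n, 0, f_jitter_sd))
  })
  animals <- vector("list", n)
  for (i in seq_len(n)) {
    f_b <- min(max(f_baseline + params$jit_b[i], 0.005), 0.15)
    f_p <- f_b + (if (groups[i] == "experimental") delta_f else 0) +
      params$jit_p[i]
    f_p <- min(max(f_p, 0.005), 0.18)
    spec_b <- spec; spec_b$fibrosis_fraction <- f_b
    spec_b$seed <- params$seed_b[i]
    spec_p <- spec; spec_p$fibrosis_fraction <- f_p
    spec_p$seed <- params$seed_p[i]
    animals[[i]] <- list(
      id = sprintf("%s_%d", if (groups[i] == "experimental") "dog" else
        "control", if (groups[i] == "experimental") i else i - n_exp),
      group = groups[i],
      timepoints = list(baseline = generate_la_phantom(spec_b),
                        post = generate_la_phantom(spec_p)))
  }
  structure(animals, class = "study_cohort")
}

#' Write a cohort to a directory tree
#'
#' One sub-directory per animal with `baseline.nrrd`, `post.nrrd`, the
#' blood-pool masks, landmark tables and a `truth.json` per timepoint.
#'
#' @param cohort a `study_cohort`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (an in cohort) {
    adir <- file.path(dir, an$id)
    dir.create(adir, showWarnings = FALSE)
    for (tp in names(an$timepoints)) {
      ph <- an$timepoints[[tp]]
      write_volume(ph$image, file.path(adir, paste0(tp, ".nrrd")))
      write_volume(ph$truth$blood_pool_mask,
                   file.path(adir, paste0(tp, "_pool.nrrd")))
      write_landmarks(ph$truth$landmarks,
                      file.path(adir, paste0(tp, "_landmarks.csv")))
      jsonlite::write_json(
        list(true_percent_mf = ph$truth$true_percent_mf, group = an$group),
        file.path(adir, paste0(tp, "_truth.json")), auto_unbox = TRUE,
        digits = NA)
    }
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return A `study_cohort` whose timepoints carry `image`,
#'   `blood_pool_mask` and `landmarks` (no ground-truth masks).
#' @export
read_cohort <- function(dir) {
  adirs <- list.dirs(dir, recursive = FALSE)
  animals <- lapply(adirs, function(adir) {
    tps <- list()
    for (tp in c("baseline", "post")) {
      ipath <- file.path(adir, paste0(tp, ".nrrd"))
      if (!file.exists(ipath)) next
      truth <- jsonlite::read_json(file.path(adir, paste0(tp, "_truth.json")))
      tps[[tp]] <- list(
        image = read_volume(ipath),
        truth = list(
          blood_pool_mask = {
            v <- read_volume(file.path(adir, paste0(tp, "_pool.nrrd")))
            label_map(v$data != 0, "blood_pool", v$spacing, v$origin)
          },
          landmarks = read_landmarks(
            file.path(adir, paste0(tp, "_landmarks.csv"))),
          true_percent_mf = truth$true_percent_mf))
    }
    grp <- jsonlite::read_json(
      file.path(adir, "baseline_truth.json"))$group
    list(id = basename(adir), group = grp, timepoints = tps)
  })
  structure(animals, class = "study_cohort")
}

# corner background boxes for NEMA-4 SNR on a phantom-like image
corner_noise_rois <- function(image, box = 5L) {
  d <- dim(image$data)
  k <- ceiling(d[3] / 2)
  mk <- function(is, js) {
    m <- array(FALSE, d)
    m[is, js, k] <- TRUE
    label_map(m, "generic", image$spacing, image$origin)
  }
  list(mk(1:box, 1:box), mk(1:box, (d[2] - box + 1):d[2]),
       mk((d[1] - box + 1):d[1], 1:box),
       mk((d[1] - box + 1):d[1], (d[2] - box + 1):d[2]))
}

#' Run the full fibrosis-progression study over a cohort
#'
#' For every animal and timepoint: extract the wall from the blood-pool
#' mask ([extract_wall()]), quantify fibrosis ([quantify_fibrosis()]);
#' then per animal the signed change [d_abs()] (volumetric and
#' slice-wise), per group [group_summary()] tables, paired
#' [wilcoxon_signed_rank_exact()] within each group and
#' [mann_whitney_u_exact()] between groups at the post timepoint, plus
#' per-image NEMA-4 SNR QC.  In-situ scans, if present in a cohort, are
#' never quantified.
#'
#' @param cohort a `study_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param k_sd threshold SD multiplier (default 2).
#' @param radius wall dilation radius in pixels (default 4).
#' @param compute_snr compute corner-ROI NEMA-4 SNR per image.
#' @return A list of class `study_report`: `per_animal` (data frame),
#'   `group_tables` (volumetric and slice-wise), `tests`, `qc`, `config`.
#' @export
run_study <- function(cohort, k_sd = 2, radius = 4, compute_snr = TRUE) {
  rows <- list()
  qc <- list()
  for (an in cohort) {
    meas <- list()
    for (tp in c("baseline", "post")) {
      obj <- an$timepoints[[tp]]
      if (is.null(obj)) stop("animal ", an$id, " lacks timepoint ", tp,
                             call. = FALSE)
      pool <- obj$truth$blood_pool_mask
      seg <- extract_wall(pool, radius = radius)
      m <- quantify_fibrosis(obj$image, pool, seg$wall, k_sd = k_sd,
                             timepoint = if (tp == "baseline") "baseline"
                             else "post_pacing")
      meas[[tp]] <- m
      if (compute_snr) {
        snr <- tryCatch(
          nema4_snr(obj$image, pool, corner_noise_rois(obj$image))$snr,
          error = function(e) NA_real_)
        qc[[length(qc) + 1L]] <- data.frame(animal = an$id, timepoint = tp,
                                            snr = snr)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      animal = an$id, group = an$group,
      v_b = meas$baseline$percent_mf_volumetric,
      v_p = meas$post$percent_mf_volumetric,
      d_abs = d_abs(meas$baseline$percent_mf_volumetric,
                    meas$post$percent_mf_volumetric),
      s_b = meas$baseline$percent_mf_slicewise,
      s_p = meas$post$percent_mf_slicewise,
      d_abs_slice = meas$post$percent_mf_slicewise -
        meas$baseline$percent_mf_slicewise,
      t_fib_b = meas$baseline$t_fib, t_fib_p = meas$post$t_fib)
  }
  per_animal <- do.call(rbind, rows)

  table_for <- function(cols) {
    out <- list()
    for (g in unique(per_animal$group)) {
      sub <- per_animal[per_animal$group == g, ]
      out[[g]] <- lapply(cols, function(cn) group_summary(sub[[cn]]))
    }
    out
  }
  group_tables <- list(
    volumetric = table_for(c(baseline = "v_b", post = "v_p",
                             d_abs = "d_abs")),
    slicewise = table_for(c(baseline = "s_b", post = "s_p",
                            d_abs = "d_abs_slice")))

  paired_test <- function(d) {
    tryCatch(wilcoxon_signed_rank_exact(d),
             error = function(e) list(p_two_sided = NA_real_,
                                      note = conditionMessage(e)))
  }
  exp_rows <- per_animal$group == "experimental"
  ctl_rows <- per_animal$group == "control"
  tests <- list(
    wilcoxon_experimental_volumetric =
      paired_test(per_animal$d_abs[exp_rows]),
    wilcoxon_control_volumetric = paired_test(per_animal$d_abs[ctl_rows]),
    wilcoxon_experimental_slicewise =
      paired_test(per_animal$d_abs_slice[exp_rows]),
    wilcoxon_control_slicewise =
      paired_test(per_animal$d_abs_slice[ctl_rows]),
    mann_whitney_post_volumetric = if (any(exp_rows) && any(ctl_rows))
      mann_whitney_u_exact(per_animal$v_p[exp_rows],
                           per_animal$v_p[ctl_rows]) else NULL,
    mann_whitney_post_slicewise = if (any(exp_rows) && any(ctl_rows))
      mann_whitney_u_exact(per_animal$s_p[exp_rows],
                           per_animal$s_p[ctl_rows]) else NULL)

  structure(list(per_animal = per_animal, group_tables = group_tables,
                 tests = tests,
                 qc = if (length(qc)) do.call(rbind, qc) else NULL,
                 config = list(k_sd = k_sd, radius = radius)),
            class = "study_report")
}

#' Write a study report as JSON plus CSV tables
#'
#' Emits `report.json` (full machine-readable report),
#' `per_animal.csv`, `table_volumetric.csv` and `table_slicewise.csv`
#' (group mean +/- SD and median +/- IQR rows for baseline, post and
#' D_abs, mirroring a paired-study summary table) and `qc_snr.csv`.
#'
#' @param report a `study_report`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_animal, file.path(dir, "per_animal.csv"),
                   row.names = FALSE)
  flatten_table <- function(tab) {
    do.call(rbind, lapply(names(tab), function(g) {
      do.call(rbind, lapply(names(tab[[g]]), function(m) {
        s <- tab[[g]][[m]]
        data.frame(group = g, measure = m, mean = s$mean, sd = s$sd,
                   median = s$median, iqr = s$iqr, n = s$n)
      }))
    }))
  }
  utils::write.csv(flatten_table(report$group_tables$volumetric),
                   file.path(dir, "table_volumetric.csv"), row.names = FALSE)
  utils::write.csv(flatten_table(report$group_tables$slicewise),
                   file.path(dir, "table_slicewise.csv"), row.names = FALSE)
  if (!is.null(report$qc))
    utils::write.csv(report$qc, file.path(dir, "qc_snr.csv"),
                     row.names = FALSE)
  json <- list(per_animal = report$per_animal,
               group_tables = report$group_tables,
               tests = lapply(report$tests, function(t)
                 if (is.null(t)) NULL else unclass(t)),
               qc = report$qc, config = report$config)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", nrow(x$per_animal), " animals; ",
      "experimental paired p = ",
      format(x$tests$wilcoxon_experimental_volumetric$p_two_sided,
             digits = 3), "\n", sep = "")
  invisible(x)
}
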