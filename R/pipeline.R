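#' @title Analysis pipeline and environment comparison
#' @description Orchestrates the full per-environment metric battery
#'   (RMSF, hybrid-sheet hydrogen bonds, water accessibility, helicity,
#'   active-site distances, tail order, area per lipid), aggregates
#'   replicates by SD of the mean, writes deterministic CSV/JSON outputs,
#'   and compares two environments with directional verdicts.
#' @name memdyn-pipeline
NULL

#' Write synthetic systems plus a ready-to-run analysis config
#'
#' Generates the protein and amphiphile replicate trajectories for a
#' spec, writes them in the package's file dialects (reference PDB +
#' xyz-table trajectories), the ground-truth sidecar JSON, and an
#' analysis config YAML pointing at everything.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return path of the written config YAML, invisibly.
#' @export
simulate_bundle <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reps <- generate_protein_trajectory(spec)
  write_pdb(reps[[1]]$topology, reps[[1]]$frames[[1]],
            file.path(dir, "protein_topology.pdb"))
  for (r in seq_along(reps)) {
    write_trajectory(reps[[r]], file.path(dir, sprintf("protein_rep%d.csv", r)),
                     dialect = "xyz-table")
  }
  lipids <- lapply(seq_len(spec$n_replicates), function(r) {
    generate_amphiphile_system(spec, replicate = r)
  })
  write_pdb(lipids[[1]]$topology, lipids[[1]]$frames[[1]],
            file.path(dir, "lipid_topology.pdb"))
  for (r in seq_along(lipids)) {
    write_trajectory(lipids[[r]], file.path(dir, sprintf("lipid_rep%d.csv", r)),
                     dialect = "xyz-table")
  }
  gt <- synthetic_ground_truth(spec)
  gt$leaflets <- attr(lipids[[1]], "leaflets")
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  fr <- spec$flexible_region
  cfg <- list(
    label = spec$mode,
    seed = spec$seed,
    mode = spec$mode,
    paths = list(
      topology = "protein_topology.pdb",
      trajectories = sprintf("protein_rep%d.csv", seq_len(spec$n_replicates)),
      lipid_topology = "lipid_topology.pdb",
      lipid_trajectories = sprintf("lipid_rep%d.csv", seq_len(spec$n_replicates))
    ),
    substrate_chains = "B",
    selections = list(
      fit = "chain A and backbone",
      protein_report = "chain A and backbone",
      substrate_report = "chain B and backbone",
      flexible_region = sprintf("chain A and resid %d-%d", fr[1], fr[2]),
      beta2 = "chain A and resid 213-217",
      beta3 = "chain B and resid 50-54",
      catalytic_a = sprintf("chain A and resid %d and name CG",
                            spec$catalytic_resids[1]),
      catalytic_b = sprintf("chain A and resid %d and name CG",
                            spec$catalytic_resids[2]),
      water_report = "chain B and resid 45-55",
      headgroups = "chain L and name P"
    ),
    parameters = list(
      window = 1 / 3,
      water_cutoff = 5.0,
      active_threshold = 7.0,
      hbond_criterion = "geometric",
      helicity_threshold = 0.5,
      min_dwell = 5,
      bin_width = 0.2,
      block_length = 50,
      tail_carbons = paste0("C", seq_len(spec$n_tail_carbons)),
      apl_max_frames = 25
    )
  )
  cfgpath <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfgpath)
  invisible(cfgpath)
}

#' Read an analysis config YAML
#'
#' Relative paths are resolved against the config file's directory.
#'
#' @param path config YAML path.
#' @return config list (class `AnalysisConfig`).
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  cfg$paths$topology <- rel(cfg$paths$topology)
  cfg$paths$trajectories <- rel(unlist(cfg$paths$trajectories))
  if (!is.null(cfg$paths$lipid_topology)) {
    cfg$paths$lipid_topology <- rel(cfg$paths$lipid_topology)
    cfg$paths$lipid_trajectories <- rel(unlist(cfg$paths$lipid_trajectories))
  }
  class(cfg) <- c("AnalysisConfig", "list")
  cfg
}

#' Run the full per-environment analysis
#'
#' Executes, per replicate: RMSD stability, the backbone RMSF profile
#' about the time-average reference, inter-strand hydrogen-bond counts
#' (both criteria), residue water accessibility, secondary-structure /
#' helicity of the flexible region, the catalytic distance series with
#' below-threshold fraction and histogram; and on the amphiphile system
#' the S_CH profile and (bilayer only) area per lipid. Replicates are
#' aggregated as mean and SD of the per-replicate means. Every table is
#' written as CSV plus a scalar `summary.json`; a failed stage is
#' recorded and the remaining stages continue.
#'
#' @param config an `AnalysisConfig` (or path to one).
#' @param out output directory.
#' @return result bundle (list), invisibly also written to `out`.
#' @export
run_analysis <- function(config, out) {
  if (is.character(config)) config <- read_analysis_config(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  par <- config$parameters
  log <- character(0)
  errors <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(expr, error = function(e) {
      errors <<- c(errors, paste0(name, ": ", conditionMessage(e)))
      structure(list(message = conditionMessage(e)), class = "stage_error")
    })
    log <<- c(log, sprintf("%-24s %7.2fs%s", name, proc.time()[3] - t0,
                           if (inherits(r, "stage_error")) "  FAILED" else ""))
    r
  }
  topo <- read_pdb(config$paths$topology,
                   substrate_chains = unlist(config$substrate_chains))
  trajs <- lapply(seq_along(config$paths$trajectories), function(r) {
    read_trajectory(config$paths$trajectories[r], topo$topology,
                    dialect = "xyz-table",
                    label = sprintf("%s_rep%d", config$label, r))
  })
  protein_sel <- setdiff(names(config$selections), "headgroups")
  sel <- lapply(config$selections[protein_sel], function(e) {
    resolve_selection(topo$topology, e)
  })
  res <- list(label = config$label, n_replicates = length(trajs))

  res$rmsd <- stage("rmsd_series", {
    lapply(trajs, function(tr) rmsd_series(tr, sel$fit)$values)
  })
  res$rmsf_protein <- stage("rmsf_protein", {
    lapply(trajs, function(tr) {
      rmsf_profile(tr, sel$fit, sel$protein_report, window = par$window)
    })
  })
  res$flexible_labels <- residue_labels(topo$topology)[
    selection_residues(topo$topology, sel$flexible_region)]
  res$rmsf_substrate <- stage("rmsf_substrate", {
    lapply(trajs, function(tr) {
      rmsf_profile(tr, sel$fit, sel$substrate_report, window = par$window)
    })
  })
  res$hbonds <- stage("hbond_count", {
    lapply(trajs, function(tr) {
      mean(hbond_count_series(tr, sel$beta2, sel$beta3,
                              criterion = par$hbond_criterion)$values)
    })
  })
  res$water <- stage("water_accessibility", {
    lapply(trajs, function(tr) {
      water_accessibility(tr, sel$water_report, cutoff = par$water_cutoff,
                          window = par$window)
    })
  })
  res$helicity <- stage("helicity", {
    lapply(trajs, function(tr) {
      ss <- assign_secondary_structure(tr, sel$flexible_region)
      helicity_series(ss, sel$flexible_region, top = tr$topology,
                      threshold = par$helicity_threshold,
                      min_dwell = par$min_dwell)
    })
  })
  res$active <- stage("active_site_distance", {
    spec <- distance_spec(config$selections$catalytic_a,
                          config$selections$catalytic_b,
                          threshold = par$active_threshold)
    lapply(seq_along(trajs), function(r) {
      ds <- distance_series(trajs[[r]], spec)
      fb <- fraction_below(ds, par$active_threshold,
                           block_length = par$block_length,
                           seed = config$seed + r)
      list(series = ds$values, fraction = fb$fraction, ci = fb$ci)
    })
  })
  # amphiphile stages
  if (!is.null(config$paths$lipid_topology)) {
    ltopo <- read_pdb(config$paths$lipid_topology)
    ltrajs <- lapply(seq_along(config$paths$lipid_trajectories), function(r) {
      read_trajectory(config$paths$lipid_trajectories[r], ltopo$topology,
                      dialect = "xyz-table",
                      label = sprintf("%s_lip%d", config$label, r))
    })
    tails <- tail_definition(unlist(par$tail_carbons), axis = "box_z")
    res$sch <- stage("order_parameter", {
      lapply(ltrajs, function(tr) order_parameter_profile(tr, tails))
    })
    res$apl <- stage("area_per_lipid", {
      hg <- resolve_selection(ltopo$topology, config$selections$headgroups)
      lapply(ltrajs, function(tr) {
        nf <- n_frames(tr)
        keep <- unique(round(seq(1, nf,
                                 length.out = min(nf, par$apl_max_frames))))
        vals <- vapply(keep, function(k) {
          part <- assign_leaflets(tr$frames[[k]], tr$topology, hg)
          area_per_lipid(tr$frames[[k]], part, method = "voronoi")$mean
        }, 0)
        mean(vals)
      })
    })
  }
  res$errors <- errors
  res$summary <- .bundle_summary(res)
  .write_bundle(res, out, log)
  invisible(res)
}

# scalar per-metric summaries: per-replicate means, replicate mean and
# SD of the mean
.bundle_summary <- function(res) {
  out <- list()
  scalar <- function(per_rep) {
    v <- unlist(per_rep)
    c(mean = mean(v), sd_of_mean = stats::sd(v))
  }
  if (!inherits(res$rmsd, "stage_error")) {
    out$rmsd_max <- scalar(lapply(res$rmsd, max))
  }
  if (!inherits(res$rmsf_protein, "stage_error")) {
    out$rmsf_protein_mean <- scalar(lapply(res$rmsf_protein,
                                           function(p) mean(p$values)))
    if (!is.null(res$flexible_labels)) {
      out$rmsf_flexible_region <- scalar(lapply(res$rmsf_protein, function(p) {
        mean(p$values[p$labels %in% res$flexible_labels])
      }))
    }
  }
  if (!inherits(res$hbonds, "stage_error")) {
    out$hbond_mean <- scalar(res$hbonds)
  }
  if (!inherits(res$helicity, "stage_error")) {
    out$helicity_mean <- scalar(lapply(res$helicity,
                                       function(h) mean(h$series$values)))
  }
  if (!inherits(res$active, "stage_error")) {
    out$active_fraction <- scalar(lapply(res$active, `[[`, "fraction"))
    pooled <- unlist(lapply(res$active, `[[`, "series"))
    out$active_fraction_pooled <- c(mean = mean(pooled < 7.0),
                                    sd_of_mean = NA_real_)
  }
  if (!is.null(res$sch) && !inherits(res$sch, "stage_error")) {
    out$mean_abs_sch <- scalar(lapply(res$sch, function(p) mean(p$abs_SCH)))
  }
  if (!is.null(res$apl) && !inherits(res$apl, "stage_error")) {
    out$area_per_lipid <- scalar(res$apl)
  }
  out
}

# flexible-region RMSF needs the residue labels; computed in compare and
# in the summary CSVs from the aggregated profile
.write_bundle <- function(res, out, log) {
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out, name), row.names = FALSE,
                     quote = FALSE)
  }
  if (!inherits(res$rmsf_protein, "stage_error")) {
    wcsv(aggregate_replicates(res$rmsf_protein), "rmsf_protein.csv")
  }
  if (!inherits(res$rmsf_substrate, "stage_error")) {
    wcsv(aggregate_replicates(res$rmsf_substrate), "rmsf_substrate.csv")
  }
  if (!inherits(res$water, "stage_error")) {
    profs <- lapply(res$water, function(w) {
      residue_profile(w$label, w$mean_waters, units = "waters")
    })
    wcsv(aggregate_replicates(profs), "water_accessibility.csv")
  }
  if (!inherits(res$helicity, "stage_error")) {
    hel <- do.call(cbind, lapply(res$helicity, function(h) h$series$values))
    colnames(hel) <- paste0("rep", seq_len(ncol(hel)))
    wcsv(data.frame(frame = seq_len(nrow(hel)), hel), "helicity.csv")
  }
  if (!inherits(res$active, "stage_error")) {
    pooled <- unlist(lapply(res$active, `[[`, "series"))
    wcsv(metric_histogram(pooled, 0.2), "distance_histogram.csv")
    wcsv(data.frame(replicate = seq_along(res$active),
                    fraction = vapply(res$active, `[[`, 0, "fraction"),
                    ci_lo = vapply(res$active, function(a) a$ci[1], 0),
                    ci_hi = vapply(res$active, function(a) a$ci[2], 0)),
         "active_fraction.csv")
  }
  if (!is.null(res$sch) && !inherits(res$sch, "stage_error")) {
    s <- res$sch[[1]]
    M <- vapply(res$sch, function(p) p$SCH, numeric(nrow(s)))
    wcsv(data.frame(carbon = s$carbon, SCH_mean = rowMeans(M),
                    SCH_sd_of_mean = apply(M, 1, stats::sd)),
         "sch_profile.csv")
  }
  if (!is.null(res$apl) && !inherits(res$apl, "stage_error")) {
    wcsv(data.frame(replicate = seq_along(res$apl),
                    area_per_lipid = unlist(res$apl)), "area_per_lipid.csv")
  }
  summ <- lapply(res$summary, function(s) {
    list(mean = unname(s["mean"]), sd_of_mean = unname(s["sd_of_mean"]))
  })
  jsonlite::write_json(list(label = res$label, metrics = summ,
                            errors = res$errors),
                       file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(log, file.path(out, "log.txt"))
  invisible(out)
}

#' Compare two analyzed environments
#'
#' Differences of replicate means (A minus B) with combined SD-of-mean
#' error propagation; a directional verdict is issued only when the
#' absolute difference exceeds the combined SD.
#'
#' @param bundle_a,bundle_b results of [run_analysis()] (or paths to
#'   their output directories' `summary.json`).
#' @return `ComparisonReport`: data.frame with per-metric means, SDs,
#'   delta, combined SD and verdict.
#' @export
compare_environments <- function(bundle_a, bundle_b) {
  getsum <- function(b) {
    if (is.character(b)) {
      j <- jsonlite::read_json(file.path(b, "summary.json"))
      list(label = j$label,
           summary = lapply(j$metrics, function(m) {
             c(mean = as.numeric(m$mean),
               sd_of_mean = if (is.null(m$sd_of_mean)) NA_real_ else
                 as.numeric(m$sd_of_mean))
           }))
    } else b
  }
  a <- getsum(bundle_a); b <- getsum(bundle_b)
  metrics <- intersect(names(a$summary), names(b$summary))
  if (!setequal(names(a$summary), names(b$summary))) {
    warning("bundles share only ", length(metrics), " metrics; comparing ",
            "on the intersection")
  }
  rows <- lapply(metrics, function(m) {
    ma <- a$summary[[m]]; mb <- b$summary[[m]]
    delta <- unname(ma["mean"] - mb["mean"])
    csd <- sqrt(sum(c(ma["sd_of_mean"], mb["sd_of_mean"])^2, na.rm = TRUE))
    verdict <- if (is.finite(csd) && csd > 0 && abs(delta) > csd) {
      sprintf("%s in %s", if (delta > 0) "higher" else "lower",
              if (is.null(a$label)) "A" else a$label)
    } else ""
    data.frame(metric = m, mean_a = unname(ma["mean"]),
               sd_a = unname(ma["sd_of_mean"]), mean_b = unname(mb["mean"]),
               sd_b = unname(mb["sd_of_mean"]), delta = delta,
               combined_sd = csd, verdict = verdict, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  class(rep) <- c("ComparisonReport", "data.frame")
  rep
}
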