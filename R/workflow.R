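#' Build a pipeline run configuration
#'
#' One flat key–value configuration holding the generator choice and every
#' analysis threshold (all defaults encode the standard calibration: 20-kb
#' track filter, 50% molecule filter, 40-kb / 5-origin cluster definition,
#' 200-kb/2-kb moving window, 300-kb velocity windows).
#'
#' @param generator One of `"clustered"`, `"uniform"`, `"rdna"`, `"sphase"`.
#' @param seed Integer seed recorded in every output.
#' @param n_molecules Cohort size (static generators).
#' @param n_origins Origins per genome (uniform generator).
#' @param replication_extent Extent or extent range (static generators).
#' @param f_sample Sampling fractions for the S-phase simulation.
#' @param chase_min Chase duration (min).
#' @param max_track_kb,max_fraction IOD eligibility filters.
#' @param d_max_kb,min_n Cluster definition.
#' @param window_kb,step_kb Moving-average profile parameters.
#' @param velocity_window_kb Velocity-vs-density window.
#' @param lilliefors_n_null Null draws for the exponentiality test.
#' @param fit_B Bootstrap replicates for model preference.
#' @param r0,r_mid,v Kinetic parameters for the S-phase simulation.
#' @param ... Additional overrides stored as-is.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(generator = c("clustered", "uniform", "rdna", "sphase"),
                       seed = 1, n_molecules = 131, n_origins = 900,
                       replication_extent = c(0.05, 0.5),
                       f_sample = c(0.2, 0.4, 0.6, 0.8), chase_min = 3,
                       max_track_kb = 20, max_fraction = 0.5,
                       d_max_kb = 40, min_n = 5,
                       window_kb = 200, step_kb = 2,
                       velocity_window_kb = 300,
                       lilliefors_n_null = 2000, fit_B = 199,
                       r0 = 2, r_mid = 8, v = 2.8, ...) {
  cfg <- list(generator = match.arg(generator), seed = seed,
              r0 = r0, r_mid = r_mid, v = v,
              n_molecules = n_molecules, n_origins = n_origins,
              replication_extent = replication_extent, f_sample = f_sample,
              chase_min = chase_min, max_track_kb = max_track_kb,
              max_fraction = max_fraction, d_max_kb = d_max_kb, min_n = min_n,
              window_kb = window_kb, step_kb = step_kb,
              velocity_window_kb = velocity_window_kb,
              lilliefors_n_null = lilliefors_n_null, fit_B = fit_B, ...)
  stop_if(any(vapply(cfg[c("max_track_kb", "max_fraction", "d_max_kb",
                           "min_n", "window_kb", "step_kb",
                           "velocity_window_kb")], function(x)
                             any(!is.numeric(x) | x <= 0), logical(1))),
          "all thresholds must be positive numbers")
  structure(cfg, class = "run_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value` (comments with `#`); values are parsed as
#' numeric vectors (comma separated) where possible. Parsed keys override
#' [run_config()] defaults.
#'
#' @param path Path to the file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- lapply(strsplit(lines, "="), function(p) {
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    list(key = key, value = if (all(!is.na(num))) num else val)
  })
  args <- stats::setNames(lapply(kv, `[[`, "value"),
                          vapply(kv, `[[`, character(1), "key"))
  do.call(run_config, args)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Seeded end-to-end run: generate (or simulate) molecules, measure IODs,
#' fit survival statistics, call clusters, and — for the S-phase simulator —
#' compute pulse/chase kinetics. All outputs are TSV tables plus a JSON
#' manifest recording the seed and parameters; runs are deterministic for a
#' fixed seed.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return The manifest (invisibly), as a list.
#' @export
run_pipeline <- function(config = run_config(), outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ..., "\n",
                            sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("replicomb run: generator=", config$generator, " seed=", config$seed)
  files <- character(0)
  genome <- genome_spec()

  mols <- switch(config$generator,
    clustered = generate_two_regime_molecules(
      replication_extent = config$replication_extent, seed = config$seed,
      n_molecules = config$n_molecules),
    uniform = generate_uniform_molecules(
      config$n_origins, replication_extent = config$replication_extent,
      seed = config$seed, n_molecules = config$n_molecules),
    rdna = generate_rdna_array(n_molecules = config$n_molecules,
                               seed = config$seed),
    sphase = {
      sim <- simulate_genome_sphase(
        genome, kinetic_profile(r0 = config$r0, r_mid = config$r_mid,
                                v = config$v, chase_min = config$chase_min),
        seed = config$seed)
      files <- c(files, write_tsv(sim$trajectory,
                                  file.path(outdir, "trajectory.tsv")))
      unlist(lapply(config$f_sample, function(ft) {
        lab <- label_at_fraction(sim, ft, chase = config$chase_min)
        fr <- fragment_and_stretch(lab$molecules, combing_noise(),
                                   seed = derive_seed(config$seed,
                                                      round(1000 * ft)))
        lapply(fr, function(m) { m$id <- sprintf("f%02.0f_%s", 100 * ft, m$id); m })
      }), recursive = FALSE)
    })
  logf(length(mols), " molecules")
  files <- c(files, write_molecules(mols, file.path(outdir, "molecules.tsv")))

  iods <- measure_iods(mols, config$max_track_kb, config$max_fraction)
  files <- c(files, write_tsv(iods, file.path(outdir, "iods.tsv")))
  x <- eligible_iods(iods)
  if (length(x) < 10) {
    warning("too few eligible IODs (", length(x), "); IOD statistics skipped")
    logf("WARNING: too few eligible IODs (", length(x), ")")
  } else {
    sc <- survival_curve(x)
    files <- c(files, write_tsv(data.frame(iod_kb = sc$x, exceedance = sc$surv),
                                file.path(outdir, "survival.tsv")))
    fit <- fit_exponential_regimes(x, B = config$fit_B,
                                   seed = derive_seed(config$seed, 21))
    lt <- lilliefors_exponential(x, n_null = config$lilliefors_n_null,
                                 seed = derive_seed(config$seed, 22))
    files <- c(files, write_tsv(data.frame(
      n = fit$n, single_median_kb = fit$single$median_kb,
      w = fit$mixture$w, median1_kb = fit$mixture$median1_kb,
      median2_kb = fit$mixture$median2_kb, breakpoint_kb = fit$breakpoint_kb,
      lrt = fit$lrt, p_boot = fit$p_boot, preferred = fit$preferred,
      lilliefors_D = unname(lt$statistic), lilliefors_p = lt$p.value),
      file.path(outdir, "fits.tsv")))
    logf("fit: preferred=", fit$preferred, " lilliefors p=", lt$p.value)
  }

  calls <- call_clusters(mols, cluster_params(config$d_max_kb, config$min_n))
  files <- c(files, write_tsv(calls$clusters,
                              file.path(outdir, "clusters.tsv")))
  logf(nrow(calls$clusters), " clusters")

  if (config$generator == "sphase") {
    prof <- firing_and_density_profiles(mols, genome, config$chase_min)
    files <- c(files, write_tsv(prof$per_molecule,
                                file.path(outdir, "kinetics.tsv")))
    recs <- do.call(rbind, lapply(mols, classify_replicons,
                                  chase_min = config$chase_min))
    ev <- estimate_fork_velocities(recs)
    files <- c(files, write_tsv(data.frame(velocity_kb_min = ev$velocities),
                                file.path(outdir, "velocities.tsv")))
    logf("mean fork velocity ", round(ev$mean_kb_min, 2), " kb/min (n=",
         ev$n, ")")
  }

  manifest <- list(package = "replicomb",
                   version = as.character(utils::packageVersion("replicomb")),
                   generator = config$generator, seed = config$seed,
                   parameters = unclass(config),
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("done; ", length(files), " tables written")
  invisible(manifest)
}

#' Regenerate report figures from a pipeline run directory
#'
#' Renders the standard panels (semilog survival curve, cluster-size
#' histogram, fork-velocity histogram, kinetic profiles) from the TSV tables
#' written by [run_pipeline()]; no computation happens in the plotting
#' layer, so re-rendering from the same tables is reproducible. Panels with
#' no underlying data are emitted as "no data" placeholders.
#'
#' @param rundir A [run_pipeline()] output directory.
#' @param format `"pdf"` or `"png"`.
#' @return Character vector of figure paths, invisibly.
#' @export
generate_report <- function(rundir, format = c("pdf", "png")) {
  format <- match.arg(format)
  stop_if(!dir.exists(rundir), "no such run directory: ", rundir)
  figs <- character(0)
  save_fig <- function(p, name) {
    path <- file.path(rundir, paste0(name, ".", format))
    ggplot2::ggsave(path, p, width = 5, height = 4,
                    device = if (format == "pdf") grDevices::pdf else "png")
    figs <<- c(figs, path)
  }
  placeholder <- function(msg) {
    ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0, label = msg) +
      ggplot2::theme_void()
  }
  tsv <- function(name) {
    path <- file.path(rundir, name)
    if (file.exists(path)) utils::read.delim(path) else NULL
  }

  surv <- tsv("survival.tsv")
  p <- if (!is.null(surv) && nrow(surv) > 1) {
    ggplot2::ggplot(surv[surv$exceedance > 0, ],
                    ggplot2::aes(x = iod_kb, y = exceedance)) +
      ggplot2::geom_step() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "IOD (kb)", y = "fraction of IODs > x") +
      ggplot2::theme_classic()
  } else placeholder("no IOD data")
  save_fig(p, "survival_semilog")

  cl <- tsv("clusters.tsv")
  p <- if (!is.null(cl) && nrow(cl) > 0) {
    ggplot2::ggplot(cl, ggplot2::aes(x = span_kb)) +
      ggplot2::geom_histogram(binwidth = 20, boundary = 0) +
      ggplot2::labs(x = "cluster size (kb)", y = "count") +
      ggplot2::theme_classic()
  } else placeholder("no clusters")
  save_fig(p, "cluster_sizes")

  vel <- tsv("velocities.tsv")
  if (!is.null(vel)) {
    p <- if (nrow(vel) > 0) {
      ggplot2::ggplot(vel, ggplot2::aes(x = velocity_kb_min)) +
        ggplot2::geom_histogram(binwidth = 0.25, boundary = 0) +
        ggplot2::labs(x = "fork velocity (kb/min)", y = "forks") +
        ggplot2::theme_classic()
    } else placeholder("no velocities")
    save_fig(p, "fork_velocities")
  }

  kin <- tsv("kinetics.tsv")
  if (!is.null(kin)) {
    p <- if (nrow(kin) > 0) {
      ggplot2::ggplot(kin, ggplot2::aes(x = 100 * f, y = active_per_genome)) +
        ggplot2::geom_point() +
        ggplot2::labs(x = "% DNA synthesis", y = "active replicons per genome") +
        ggplot2::theme_classic()
    } else placeholder("no kinetic data")
    save_fig(p, "active_replicons")
  }
  invisible(figs)
}
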