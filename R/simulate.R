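#' Configuration of a synthetic LC-MS experiment
#'
#' Describes a multi-run label-free experiment with known ground truth, built
#' to exercise every stage of the matcher: shared peptides whose elution
#' peaks have reproducible shapes, a smooth non-linear retention-time warp
#' between runs, Gaussian residual shifts around the warp, interfering decoy
#' peaks near the true peaks in the same mass window, baseline noise, large
#' intensity fold changes between runs, and partially sampled identification
#' tables with optional planted false positives.
#'
#' @param n_peptides Number of shared peptide ions.
#' @param n_runs Number of runs (2 for pairwise benchmarks, 3+ for coverage).
#' @param mz_range Monoisotopic m/z range (Th); peptides are spread evenly so
#'   their 10 ppm windows never overlap.
#' @param run_length Gradient length in seconds.
#' @param scan_interval MS1 scan spacing in seconds.
#' @param warp_coefficients List of per-run polynomial coefficients (highest
#'   first) mapping base (run 1) time into that run's time; `NULL` gives an
#'   identity first run and smooth mildly non-linear warps for runs 2 and 3.
#' @param at_sigma Standard deviation (s) of the Gaussian residual shift
#'   added around the warped base time.
#' @param shape_family `"emg"` (exponentially modified Gaussian, realistic
#'   tailing; default) or `"gaussian"` (for analytic checks).
#' @param peak_width_range Range of the per-peptide Gaussian width sigma (s).
#' @param peak_tail_range Range of the per-peptide EMG tail constant tau (s).
#' @param shape_noise Relative perturbation of width/tail per run plus
#'   multiplicative trace noise; controls how far the shape R-squared of
#'   corresponding peaks falls below 1.
#' @param shape_reproducible If `FALSE`, every run draws an independent peak
#'   shape, destroying the shape-correlation signal (the regime in which the
#'   shift statistic alone should suffice).
#' @param decoys_per_peptide Number of interfering peaks planted near each
#'   true peak, per run, in the same mass window.
#' @param decoy_offset_range Absolute offset range (s) of decoy apexes from
#'   the true apex; the sign is random per decoy.
#' @param fold_change_range Intensity ratio bounds across runs; per-run scale
#'   factors are drawn log-uniformly so the ratio between two runs can reach
#'   the upper bound (default up to 50-fold).
#' @param noise_level,noise_sigma Mean and SD (counts) of the Gaussian
#'   baseline noise added to every trace point (clipped at zero).
#' @param identified_fraction Per-run probability that a peptide appears in
#'   that run's identification table (Tandem-MS sampling).
#' @param id_false_positive_rate Fraction of emitted identifications whose RT
#'   is wrong (pointing at an interfering peak); scalar or one value per run.
#' @param base_intensity_meanlog,base_intensity_sdlog Log-normal parameters
#'   of the base apex intensity.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_peptides = 150,
                       n_runs = 2,
                       mz_range = c(400, 1000),
                       run_length = 900,
                       scan_interval = 1,
                       warp_coefficients = NULL,
                       at_sigma = 3,
                       shape_family = c("emg", "gaussian"),
                       peak_width_range = c(2, 4),
                       peak_tail_range = c(1, 3),
                       shape_noise = 0.08,
                       shape_reproducible = TRUE,
                       decoys_per_peptide = 3,
                       decoy_offset_range = c(30, 90),
                       fold_change_range = c(1, 50),
                       noise_level = 15,
                       noise_sigma = 5,
                       identified_fraction = 0.9,
                       id_false_positive_rate = 0,
                       base_intensity_meanlog = log(2000),
                       base_intensity_sdlog = 0.6) {
  shape_family <- match.arg(shape_family)
  stopifnot(n_peptides >= 1, n_runs >= 2, diff(mz_range) > 0,
            run_length > 0, scan_interval > 0, at_sigma >= 0,
            shape_noise >= 0, decoys_per_peptide >= 0,
            length(decoy_offset_range) == 2, diff(decoy_offset_range) >= 0,
            fold_change_range[1] >= 1, noise_level >= 0, noise_sigma >= 0,
            all(identified_fraction >= 0 & identified_fraction <= 1),
            all(id_false_positive_rate >= 0 & id_false_positive_rate <= 1))
  margin <- max(decoy_offset_range) + 12 * max(peak_width_range) +
    8 * max(peak_tail_range) + 4 * at_sigma
  if (2 * margin >= run_length)
    stop("infeasible geometry: decoy offsets and peak widths do not fit in ",
         "run_length = ", run_length, " s", call. = FALSE)
  if (is.null(warp_coefficients)) {
    warp_coefficients <- default_warps(n_runs)
  } else {
    stopifnot(length(warp_coefficients) == n_runs)
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Crowded-decoy benchmark configuration
#'
#' A [sim_config] preset emulating short-gradient, high-complexity runs where
#' interfering peaks sit close to the true one: narrow peaks (so nearby
#' intervals stay resolved at the detection threshold), a larger residual
#' shift, and two decoys per peptide planted within three residual-shift
#' standard deviations of the true apex. In this regime the warped time alone
#' is ambiguous and the peak-shape statistic must carry the discrimination.
#'
#' @param ... Overrides passed on to [sim_config].
#' @return A `sim_config`.
#' @export
sim_config_crowded <- function(...) {
  args <- list(n_peptides = 150, run_length = 700, scan_interval = 0.4,
               peak_width_range = c(0.8, 1.5), peak_tail_range = c(0.2, 0.6),
               at_sigma = 9, decoys_per_peptide = 2,
               decoy_offset_range = c(18, 26), identified_fraction = 0.95,
               fold_change_range = c(1, 8), base_intensity_sdlog = 0.3)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# identity first run; smooth monotone mildly non-linear warps afterwards
default_warps <- function(n_runs) {
  base <- list(c(1, 0),
               c(-4e-8, 6e-5, 1.02, 8),
               c(3e-8, -5e-5, 0.98, -6))
  lapply(seq_len(n_runs), function(r) {
    if (r <= 3L) base[[r]] else c(1, 4 * (r - 1))
  })
}

# stable EMG / Gaussian kernel, unnormalised, mu is the Gaussian centre
peak_shape <- function(t, mu, sigma, tau, family) {
  if (family == "gaussian" || tau <= 1e-9)
    return(exp(-((t - mu)^2) / (2 * sigma^2)))
  z <- sigma / tau - (t - mu) / sigma
  logf <- sigma^2 / (2 * tau^2) - (t - mu) / tau + log(2) +
    stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  exp(logf)
}

# A peptide's elution profile: a main EMG component plus an optional
# shoulder component (second EMG at a small offset with its own width and
# tail), giving the between-peptide shape diversity real chromatograms show.
# The Gaussian family stays a single clean component for analytic checks.
draw_shape <- function(cfg) {
  s <- stats::runif(1, cfg$peak_width_range[1], cfg$peak_width_range[2])
  tau <- stats::runif(1, cfg$peak_tail_range[1], cfg$peak_tail_range[2])
  if (cfg$shape_family == "gaussian")
    return(list(s = s, tau = tau, f2 = 0, off = 0, s2 = s, tau2 = tau))
  list(s = s, tau = tau,
       f2 = stats::runif(1, 0, 0.7),
       off = stats::runif(1, -2.5, 2.5) * s,
       s2 = s * stats::runif(1, 0.6, 1.6),
       tau2 = tau * stats::runif(1, 0.5, 2))
}

jitter_shape <- function(p, noise) {
  j <- function(v) v * max(1 + stats::rnorm(1, 0, noise), 0.2)
  p$s <- j(p$s); p$tau <- j(p$tau)
  p$s2 <- j(p$s2); p$tau2 <- j(p$tau2)
  p$f2 <- p$f2 * max(1 + stats::rnorm(1, 0, noise), 0)
  p$off <- j(p$off)
  p
}

eval_shape <- function(t, mu, p, family) {
  y <- peak_shape(t, mu, p$s, p$tau, family)
  if (p$f2 > 0) y <- y + p$f2 * peak_shape(t, mu + p$off, p$s2, p$tau2, family)
  y
}

# apex (mode) offset of the profile relative to the main component mu
shape_mode <- function(p, family) {
  ext <- 4 * max(p$s, p$s2) + 5 * max(p$tau, p$tau2) + abs(p$off)
  g <- seq(-ext, ext, by = p$s / 50)
  v <- eval_shape(g, 0, p, family)
  list(offset = g[which.max(v)], max = max(v))
}

#' Generate a synthetic multi-run LC-MS experiment
#'
#' Realises a [sim_config] into in-memory runs plus the ground truth needed
#' for evaluation. Everything is reproducible from `seed`.
#'
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return A list of class `sim_experiment` with `runs` (list of [run_data]),
#'   `truth` (data frame: one row per peptide per run with the planted
#'   interval, apex time and intensity), `ids` (list of per-run
#'   identification tables, with a logical `is_fp` column flagging planted
#'   false positives) and `config`.
#' @export
simulate_runs <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config
  n <- cfg$n_peptides
  scan_times <- seq(0, cfg$run_length, by = cfg$scan_interval)
  n_scan <- length(scan_times)

  spacing <- diff(cfg$mz_range) / n
  mz_mono <- cfg$mz_range[1] + spacing * (seq_len(n) - 0.5) +
    stats::runif(n, -0.1, 0.1) * min(spacing / 4, 0.1)
  charge <- sample(2:3, n, replace = TRUE)
  mz_iso <- first_isotope_mz(mz_mono, charge)
  sequence <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                 sample(8:15, 1), replace = TRUE), collapse = ""),
    character(1))
  # regenerate any duplicate sequences deterministically
  while (anyDuplicated(sequence)) {
    d <- which(duplicated(sequence))
    sequence[d] <- paste0(sequence[d], "K")
  }

  margin <- max(cfg$decoy_offset_range) + 12 * max(cfg$peak_width_range) +
    8 * max(cfg$peak_tail_range) + 4 * cfg$at_sigma
  t_base <- stats::runif(n, margin, cfg$run_length - margin)
  shape_base <- lapply(seq_len(n), function(i) draw_shape(cfg))
  a_base <- stats::rlnorm(n, cfg$base_intensity_meanlog,
                          cfg$base_intensity_sdlog)
  log_half_fold <- log(cfg$fold_change_range[2] / cfg$fold_change_range[1]) / 2

  idf <- rep_len(cfg$identified_fraction, cfg$n_runs)
  fpr <- rep_len(cfg$id_false_positive_rate, cfg$n_runs)

  runs <- vector("list", cfg$n_runs)
  truth <- list()
  ids <- vector("list", cfg$n_runs)

  for (r in seq_len(cfg$n_runs)) {
    wc <- cfg$warp_coefficients[[r]]
    mono_mat <- matrix(0, nrow = n, ncol = n_scan)
    decoy_apex <- vector("list", n)

    apex_time <- numeric(n); apex_int <- numeric(n)
    iv_start <- numeric(n); iv_end <- numeric(n)
    for (i in seq_len(n)) {
      target <- polyval_(wc, t_base[i]) + stats::rnorm(1, 0, cfg$at_sigma)
      p <- if (cfg$shape_reproducible)
        jitter_shape(shape_base[[i]], cfg$shape_noise)
      else draw_shape(cfg)
      amp <- a_base[i] * exp(stats::runif(1, -1, 1) * log_half_fold)
      md <- shape_mode(p, cfg$shape_family)
      mu <- target - md$offset
      y <- amp * eval_shape(scan_times, mu, p, cfg$shape_family) / md$max
      if (cfg$shape_noise > 0)
        y <- y * exp(stats::rnorm(n_scan, 0, cfg$shape_noise / 3))
      mono_mat[i, ] <- y
      apex_time[i] <- target
      apex_int[i] <- amp
      iv_start[i] <- mu - 3 * p$s - abs(p$off)
      iv_end[i] <- target + 3 * p$s + 4 * max(p$tau, p$tau2) + abs(p$off)

      dap <- numeric(0)
      if (cfg$decoys_per_peptide > 0) {
        for (d in seq_len(cfg$decoys_per_peptide)) {
          off <- sample(c(-1, 1), 1) *
            stats::runif(1, cfg$decoy_offset_range[1],
                         cfg$decoy_offset_range[2])
          dt <- target + off
          dp <- draw_shape(cfg)
          damp <- stats::rlnorm(1, cfg$base_intensity_meanlog,
                                cfg$base_intensity_sdlog)
          dmd <- shape_mode(dp, cfg$shape_family)
          mono_mat[i, ] <- mono_mat[i, ] + damp *
            eval_shape(scan_times, dt - dmd$offset, dp,
                       cfg$shape_family) / dmd$max
          dap <- c(dap, dt)
        }
      }
      decoy_apex[[i]] <- dap
    }

    iso_mat <- 0.65 * mono_mat
    mono_mat <- mono_mat +
      matrix(stats::rnorm(n * n_scan, cfg$noise_level, cfg$noise_sigma),
             nrow = n)
    iso_mat <- iso_mat +
      matrix(stats::rnorm(n * n_scan, cfg$noise_level, cfg$noise_sigma),
             nrow = n)
    mono_mat[mono_mat < 0] <- 0
    iso_mat[iso_mat < 0] <- 0

    ord <- order(c(mz_mono, mz_iso))
    all_mz <- c(mz_mono, mz_iso)[ord]
    scans <- lapply(seq_len(n_scan), function(j) {
      ints <- c(mono_mat[, j], iso_mat[, j])[ord]
      keep <- ints > 0
      cbind(mz = all_mz[keep], intensity = ints[keep])
    })
    run_id <- sprintf("run%02d", r)
    runs[[r]] <- run_data(run_id, scan_times, scans)

    truth[[r]] <- data.frame(
      sequence = sequence, charge = charge, run_id = run_id,
      mz_mono = mz_mono, base_time = t_base, apex_time = apex_time,
      apex_intensity = apex_int, start_time = iv_start, end_time = iv_end,
      stringsAsFactors = FALSE)

    sel <- stats::runif(n) < idf[r]
    fp <- sel & stats::runif(n) < fpr[r]
    rt_id <- apex_time
    for (i in which(fp)) {
      rt_id[i] <- if (length(decoy_apex[[i]]) > 0)
        decoy_apex[[i]][sample.int(length(decoy_apex[[i]]), 1)]
      else stats::runif(1, 0, cfg$run_length)
    }
    prob <- stats::rbeta(n, 60, 1.5)
    ids[[r]] <- data.frame(
      sequence = sequence[sel], charge = charge[sel], mz = mz_mono[sel],
      rt_sec = rt_id[sel], probability = prob[sel], run_id = run_id,
      is_fp = fp[sel], stringsAsFactors = FALSE)
  }

  structure(list(runs = runs, truth = do.call(rbind, truth), ids = ids,
                 config = cfg, seed = seed),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("Synthetic LC-MS experiment:", x$config$n_peptides, "peptides x",
      x$config$n_runs, "runs (seed", x$seed, ")\n")
  invisible(x)
}

#' Write a run to a centroided mzML file
#'
#' Emits the MS1 scans of a [run_data] object as a standards-conformant
#' centroided mzML file via \pkg{mzR}, readable by [read_mzml].
#'
#' @param run A [run_data] object with at least one scan.
#' @param path Output path (conventionally `.mzML`).
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "run_data"))
  n <- length(run$times)
  if (n == 0L) stop("cannot write an empty run", call. = FALSE)
  pks <- run$scans
  nP <- vapply(pks, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = rep(1L, n), polarity = rep(1L, n), peaksCount = nP,
    totIonCurrent = vapply(pks, function(p) sum(p[, 2L]), numeric(1)),
    retentionTime = run$times,
    basePeakMZ = vapply(pks, function(p)
      if (nrow(p)) p[which.max(p[, 2L]), 1L] else 0, numeric(1)),
    basePeakIntensity = vapply(pks, function(p)
      if (nrow(p)) max(p[, 2L]) else 0, numeric(1)),
    collisionEnergy = rep(0, n), ionisationEnergy = rep(0, n),
    lowMZ = vapply(pks, function(p) if (nrow(p)) min(p[, 1L]) else 0,
                   numeric(1)),
    highMZ = vapply(pks, function(p) if (nrow(p)) max(p[, 1L]) else 0,
                    numeric(1)),
    precursorScanNum = rep(0L, n), precursorMZ = rep(0, n),
    precursorCharge = rep(0L, n), precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = sprintf("scan=%d", seq_len(n)), centroided = rep(TRUE, n),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = rep(NA_real_, n),
    isolationWindowLowerOffset = rep(NA_real_, n),
    isolationWindowUpperOffset = rep(NA_real_, n),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE)
  mzR::writeMSData(pks, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Write a synthetic experiment to disk
#'
#' Writes one mzML file and one identification TSV per run plus a
#' `truth.json` with the planted features and the configuration; the layout
#' consumed by the command-line interface.
#'
#' @param experiment A [simulate_runs] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "sim_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (r in seq_along(experiment$runs)) {
    run <- experiment$runs[[r]]
    mz_path <- file.path(dir, paste0(run$run_id, ".mzML"))
    id_path <- file.path(dir, paste0(run$run_id, "_ids.tsv"))
    write_mzml(run, mz_path)
    write_peptide_table(experiment$ids[[r]], id_path)
    paths[paste0("mzml_", r)] <- mz_path
    paths[paste0("ids_", r)] <- id_path
  }
  tr_path <- file.path(dir, "truth.json")
  cfg <- experiment$config
  cfg$shape_family <- unclass(cfg$shape_family)
  jsonlite::write_json(
    list(truth = experiment$truth,
         ids = lapply(experiment$ids, identity),
         config = unclass(cfg), seed = experiment$seed),
    tr_path, digits = NA, auto_unbox = TRUE)
  paths["truth"] <- tr_path
  invisible(paths)
}
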