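# shared fixture builders -----------------------------------------------

make_iv <- function(times, intensities) {
  mbralign:::new_peak_interval(times, intensities)
}

make_xic <- function(times, intensities, mz = 500, ppm = 10, run = "r") {
  structure(list(run_id = run, target_mz = mz, ppm_window = ppm,
                 times = times, intensities = intensities), class = "xic")
}

# clean (noise-free) elution peak interval from an EMG(+shoulder) profile,
# truncated at `thr` like the detector would
emg_profile <- function(t, mu, sigma, tau) {
  z <- sigma / tau - (t - mu) / sigma
  exp(sigma^2 / (2 * tau^2) - (t - mu) / tau + log(2) +
        pnorm(z, lower.tail = FALSE, log.p = TRUE))
}

make_emg_iv <- function(sigma, tau, apex = 100, amp = 1000, dt = 1,
                        thr = 30, f2 = 0, off = 0, s2 = sigma, tau2 = tau) {
  t <- seq(apex - 6 * sigma - 3 * tau - abs(off),
           apex + 6 * sigma + 8 * tau + abs(off), by = dt)
  y <- emg_profile(t, apex, sigma, tau)
  if (f2 > 0) y <- y + f2 * emg_profile(t, apex + off, s2, tau2)
  y <- y / max(y) * amp
  keep <- range(which(y > thr))
  make_iv(t[keep[1]:keep[2]], y[keep[1]:keep[2]])
}

# hand-written minimal mzML (scan start times in MINUTES) ----------------

.b64 <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                endian = "little"))
}

.spec_xml <- function(i, rt_min, mz, int, level) {
  sprintf(paste0(
    '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '<scanList count="1"><scan>',
    '<cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%g" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/>',
    '</scan></scanList>',
    '<binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<binary>%s</binary></binaryDataArray>',
    '<binaryDataArray encodedLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<binary>%s</binary></binaryDataArray>',
    '</binaryDataArrayList></spectrum>'),
    i - 1L, i, length(mz), level, rt_min,
    nchar(.b64(mz)), .b64(mz), nchar(.b64(int)), .b64(int))
}

write_minute_mzml <- function(path, rts_min, levels,
                              mzs = NULL, ints = NULL) {
  if (is.null(mzs)) mzs <- rep(list(c(400, 500)), length(rts_min))
  if (is.null(ints)) ints <- lapply(seq_along(rts_min),
                                    function(i) c(10 * i, 20 * i))
  specs <- vapply(seq_along(rts_min), function(i)
    .spec_xml(i, rts_min[i], mzs[[i]], ints[[i]], levels[i]), character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="2">',
    '<cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="UO" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="sw" version="0">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="test"/>',
    '</software></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="ic"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="sw">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="r" defaultInstrumentConfigurationRef="ic">',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp">',
            length(rts_min)),
    paste(specs, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(xml, path)
  path
}

# cached default experiment + fit (several test files reuse it) ----------

.fixture_env <- new.env(parent = emptyenv())

default_experiment <- function() {
  if (is.null(.fixture_env$ex))
    .fixture_env$ex <- simulate_runs(sim_config(), seed = 42)
  .fixture_env$ex
}

default_fit <- function() {
  if (is.null(.fixture_env$fit))
    .fixture_env$fit <- suppressWarnings(mbr_fit(
      default_experiment()$runs[[1]], default_experiment()$runs[[2]],
      default_experiment()$ids[[1]], default_experiment()$ids[[2]],
      seed = 42))
  .fixture_env$fit
}

# ground-truth Q2 apex times for the testing entries of a fit
testing_truth <- function(fit, experiment, run = "run02") {
  tr <- experiment$truth[experiment$truth$run_id == run, ]
  out <- merge(fit$split$testing[, c("sequence", "charge")],
               data.frame(sequence = tr$sequence, charge = tr$charge,
                          rt_q2 = tr$apex_time))
  out
}

# crowded-decoy pairwise benchmark used by several acceptance checks
run_crowded_benchmark <- function(seed, ...) {
  cfg <- sim_config_crowded(...)
  ex <- simulate_runs(cfg, seed = seed)
  fit <- suppressWarnings(mbr_fit(ex$runs[[1]], ex$runs[[2]],
                                  ex$ids[[1]], ex$ids[[2]], seed = seed))
  te <- testing_truth(fit, ex)
  c(combined = as.numeric(match_accuracy(predict(fit), te)),
    shift_only = as.numeric(match_accuracy(
      predict(fit, statistic = "shift"), te)),
    nearest = as.numeric(match_accuracy(
      predict(fit, statistic = "nearest"), te)),
    mean_candidates = mean(vapply(fit$test_features,
                                  function(f) length(f$candidates), 1L)))
}
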