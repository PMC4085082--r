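# Seeded synthetic two-lead ECG generator. Beats are sums of three
# Gaussian bumps (P, QRS, T) on baseline noise — deliberately simpler than
# a dynamical ECG model, but expressing the two discriminative axes the
# classifier relies on: QRS width (wide for ventricular ectopy) and RR
# structure (premature beats arrive early; ventricular ones are followed
# by a compensatory pause).

#' Default beat morphology templates
#'
#' Per-class P/QRS/T Gaussian-bump parameters (amplitudes in arbitrary
#' units, widths as Gaussian sd in seconds). Ventricular beats have no P
#' wave, a QRS at least twice as wide as the normal template, and an
#' inverted T; supraventricular ectopic beats share the normal morphology
#' (their signature is rhythm, not shape); fusion beats are rendered as
#' 50/50 mixtures of the N and V waveforms. Unknown/paced beats (Q) are
#' not generated. Bump centers relative to the R peak: P at -0.16 s, QRS
#' at 0, T at +0.24 s.
#'
#' @param jitterSd relative per-beat jitter applied to every amplitude and
#'   width at render time, default 0.05.
#' @return named list of class templates.
#' @export
defaultTemplates <- function(jitterSd = 0.05) {
  n <- list(p_amp = 0.15, p_width_s = 0.020,
            qrs_amp = 1.00, qrs_width_s = 0.012,
            t_amp = 0.30, t_width_s = 0.060,
            jitter_sd = jitterSd)
  v <- list(p_amp = 0.00, p_width_s = 0.020,
            qrs_amp = 1.10, qrs_width_s = 0.030,
            t_amp = -0.35, t_width_s = 0.070,
            jitter_sd = jitterSd)
  stopifnot(v$qrs_width_s >= 2 * n$qrs_width_s, v$p_amp == 0)
  list(N = n, S = n, V = v, F = NULL)  # F rendered as an N/V mixture
}

#' Default rhythm model
#'
#' RR-interval generator parameters. Normal (and fusion) beats follow a
#' quasi-regular rhythm around `base_rr_s`; supraventricular ectopic
#' beats arrive at about `sveb_ratio_mean` of the base interval and
#' ventricular ones at about `veb_ratio_mean`, with the beat after a
#' ventricular ectopic delayed by `compensatory_pause_factor`. Class
#' prevalences default to values typical of ambulatory arrhythmia
#' recordings (ectopy a few percent, fusion rare). All intervals are
#' truncated below at `min_rr_s`.
#'
#' @return named list of rhythm parameters.
#' @export
defaultRhythm <- function() {
  list(base_rr_s = 0.8,
       rr_jitter_sd = 0.03,
       sveb_ratio_mean = 0.65, sveb_ratio_sd = 0.03,
       veb_ratio_mean = 0.60, veb_ratio_sd = 0.04,
       compensatory_pause_factor = 1.4,
       class_mix = c(N = 0.89, S = 0.04, V = 0.06, F = 0.01),
       min_rr_s = 0.2)
}

# Render one beat's waveform into `signal` around sample `rSample`.
.addBeat <- function(signal, rSample, tmpl, fs, ampScale = 1) {
  bumps <- rbind(
    c(tmpl$p_amp,   -0.16, tmpl$p_width_s),
    c(tmpl$qrs_amp,  0.00, tmpl$qrs_width_s),
    c(tmpl$t_amp,    0.24, tmpl$t_width_s))
  for (b in seq_len(nrow(bumps))) {
    amp <- bumps[b, 1L] * ampScale
    if (amp == 0) next
    center <- rSample + bumps[b, 2L] * fs
    halfWin <- ceiling(4 * bumps[b, 3L] * fs)
    lo <- max(1L, floor(center - halfWin))
    hi <- min(length(signal), ceiling(center + halfWin))
    if (lo > hi) next
    t <- (lo:hi - center) / fs
    signal[lo:hi] <- signal[lo:hi] + amp * exp(-t^2 / (2 * bumps[b, 3L]^2))
  }
  signal
}

# Per-beat jittered copy of a template.
.jitterTemplate <- function(tmpl) {
  js <- tmpl$jitter_sd
  jig <- function(x) x * (1 + stats::rnorm(1L, 0, js))
  list(p_amp = jig(tmpl$p_amp), p_width_s = abs(jig(tmpl$p_width_s)),
       qrs_amp = jig(tmpl$qrs_amp), qrs_width_s = abs(jig(tmpl$qrs_width_s)),
       t_amp = jig(tmpl$t_amp), t_width_s = abs(jig(tmpl$t_width_s)),
       jitter_sd = js)
}

#' Simulate one annotated two-lead recording
#'
#' Draws a beat class sequence from the rhythm model's class mix,
#' generates RR intervals per class (short before ectopic beats, a
#' compensatory pause after ventricular ones), renders each beat as
#' jittered Gaussian bumps at 360 Hz, and adds independent baseline noise
#' per lead; lead B is an amplitude-scaled copy of the lead-A waveform
#' with its own noise. Annotation symbols use MIT-BIH codes (N, A, V, F)
#' plus one leading rhythm marker `+` to exercise non-beat rejection.
#' Fully reproducible from `seed`.
#'
#' @param nBeats number of beats, >= 2.
#' @param templates see [defaultTemplates()].
#' @param rhythm see [defaultRhythm()].
#' @param noiseSd baseline noise sd per lead, default 0.03.
#' @param seed integer seed.
#' @param recordId record identifier.
#' @param fs sampling rate in Hz, default 360.
#' @param leadBScale lead-B amplitude factor, default 0.7.
#' @param ampScale global waveform amplitude factor, default 1.
#' @return an [EcgRecording-class] whose annotations carry the true beat
#'   classes.
#' @export
simulateRecording <- function(nBeats = 300L, templates = defaultTemplates(),
                              rhythm = defaultRhythm(), noiseSd = 0.03,
                              seed = 1L, recordId = "S001", fs = 360,
                              leadBScale = 0.7, ampScale = 1) {
  if (nBeats < 2L) stop("need at least 2 beats", call. = FALSE)
  mix <- rhythm$class_mix
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("class_mix must be non-negative probabilities summing to 1",
         call. = FALSE)
  withSeed(seed, {
    classes <- sample(names(mix), nBeats, replace = TRUE, prob = mix)
    rr <- numeric(nBeats)          # rr[i] = interval preceding beat i
    for (i in 2:nBeats) {
      cls <- classes[i]
      rr[i] <- switch(cls,
        S = rhythm$base_rr_s *
              stats::rnorm(1L, rhythm$sveb_ratio_mean, rhythm$sveb_ratio_sd),
        V = rhythm$base_rr_s *
              stats::rnorm(1L, rhythm$veb_ratio_mean, rhythm$veb_ratio_sd),
        rhythm$base_rr_s + stats::rnorm(1L, 0, rhythm$rr_jitter_sd))
      if (classes[i - 1L] == "V" && !cls %in% c("S", "V"))
        rr[i] <- rr[i] * rhythm$compensatory_pause_factor
      rr[i] <- max(rr[i], rhythm$min_rr_s)
    }
    rTimes <- 0.5 + cumsum(rr)     # first beat at 0.5 s
    nSamples <- ceiling((rTimes[nBeats] + 0.5) * fs)
    rSamples <- as.integer(round(rTimes * fs)) + 1L

    clean <- numeric(nSamples)
    for (i in seq_len(nBeats)) {
      cls <- classes[i]
      if (cls == "F") {
        clean <- .addBeat(clean, rSamples[i],
                          .jitterTemplate(templates$N), fs, 0.5 * ampScale)
        clean <- .addBeat(clean, rSamples[i],
                          .jitterTemplate(templates$V), fs, 0.5 * ampScale)
      } else {
        clean <- .addBeat(clean, rSamples[i],
                          .jitterTemplate(templates[[cls]]), fs, ampScale)
      }
    }
    leadA <- clean + stats::rnorm(nSamples, 0, noiseSd)
    leadB <- leadBScale * clean + stats::rnorm(nSamples, 0, noiseSd)
    sig <- cbind(A = leadA, B = leadB)

    symbols <- c(N = "N", S = "A", V = "V", F = "F")[classes]
    ann <- data.frame(sample = c(1L, rSamples),
                      symbol = c("+", unname(symbols)),
                      stringsAsFactors = FALSE)
    new("EcgRecording", recordId = recordId, signal = sig,
        samplingRate = fs, annotations = ann)
  })
}

#' Simulate an inter-patient dataset
#'
#' Generates `nRecordings` recordings whose template and rhythm parameters
#' are drawn per recording from mild hyper-distributions (base heart rate,
#' QRS width, waveform amplitude, lead-B gain), emulating between-patient
#' variation, then splits the record ids disjointly into a training and a
#' testing set.
#'
#' @param nRecordings total recordings, >= 2.
#' @param nBeats beats per recording, default 300.
#' @param seed integer master seed; each recording derives its own
#'   sub-seed.
#' @param trainIds how many recordings form the training set, default
#'   half.
#' @param variation per-recording hyper-parameters: `base_rr_range`
#'   (uniform, s), `qrs_width_sd` (relative log-scale sd; 0 makes all
#'   recordings share templates), `amp_range` and `lead_b_range`
#'   (uniform factors).
#' @param noiseSd baseline noise sd.
#' @return list with `ds1` and `ds2`, each a named list of
#'   [EcgRecording-class] objects with disjoint record ids.
#' @export
simulateDataset <- function(nRecordings = 6L, nBeats = 300L, seed = 1L,
                            trainIds = nRecordings %/% 2L,
                            variation = list(base_rr_range = c(0.70, 0.95),
                                             qrs_width_sd = 0.10,
                                             amp_range = c(0.85, 1.15),
                                             lead_b_range = c(0.5, 0.9)),
                            noiseSd = 0.03) {
  if (nRecordings < 2L) stop("need at least 2 recordings", call. = FALSE)
  if (trainIds < 1L || trainIds >= nRecordings)
    stop("trainIds must leave at least one test recording", call. = FALSE)
  params <- withSeed(seed, {
    lapply(seq_len(nRecordings), function(i)
      list(base_rr = stats::runif(1L, variation$base_rr_range[1L],
                                  variation$base_rr_range[2L]),
           qrsMul = exp(stats::rnorm(1L, 0, variation$qrs_width_sd)),
           amp = stats::runif(1L, variation$amp_range[1L],
                              variation$amp_range[2L]),
           leadB = stats::runif(1L, variation$lead_b_range[1L],
                                variation$lead_b_range[2L]),
           subSeed = sample.int(.Machine$integer.max - 1L, 1L)))
  })
  recs <- lapply(seq_len(nRecordings), function(i) {
    p <- params[[i]]
    tmpl <- defaultTemplates()
    for (cls in c("N", "S", "V"))
      tmpl[[cls]]$qrs_width_s <- tmpl[[cls]]$qrs_width_s * p$qrsMul
    rhythm <- defaultRhythm()
    rhythm$base_rr_s <- p$base_rr
    simulateRecording(nBeats = nBeats, templates = tmpl, rhythm = rhythm,
                      noiseSd = noiseSd, seed = p$subSeed,
                      recordId = sprintf("S%03d", i),
                      leadBScale = p$leadB, ampScale = p$amp)
  })
  names(recs) <- vapply(recs, recordId, character(1))
  list(ds1 = recs[seq_len(trainIds)],
       ds2 = recs[(trainIds + 1L):nRecordings])
}

#' Write a simulated dataset to disk
#'
#' Writes every recording as a plain-text triplet plus a `manifest.csv`
#' naming each record and its set; a rerun with the same seed reproduces
#' the files byte for byte.
#'
#' @param dataset list from [simulateDataset()].
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  for (set in c("ds1", "ds2")) {
    for (rec in dataset[[set]]) {
      writeRecording(rec, dir)
      rows[[length(rows) + 1L]] <- data.frame(record = recordId(rec),
                                              set = toupper(set))
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  invisible(manifest)
}
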