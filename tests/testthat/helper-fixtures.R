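# Shared fixture builders. Everything is generated in code at test time.

# A recording with hand-placed beats: a ramp signal (never flat) and
# annotations at chosen samples.
makeRampRecording <- function(rSamples = c(200L, 500L, 800L),
                              symbols = rep("N", length(rSamples)),
                              nSamples = 1000L, fs = 360,
                              id = "T001") {
  sig <- cbind(A = seq_len(nSamples) / nSamples + sin(seq_len(nSamples) / 7),
               B = cos(seq_len(nSamples) / 11))
  new("EcgRecording", recordId = id, signal = sig, samplingRate = fs,
      annotations = data.frame(sample = rSamples, symbol = symbols,
                               stringsAsFactors = FALSE))
}

# Two well-separated Gaussian clusters in feature space, replicated into
# M identical groups; labels N and V.
makeSeparableGroups <- function(n = 40L, p = 5L, M = 3L, gap = 10,
                                seed = 42L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * p), ncol = p),
             matrix(rnorm(n / 2 * p, mean = gap), ncol = p))
  labels <- factor(rep(c("N", "V"), each = n / 2),
                   levels = aamiClasses())
  list(groups = replicate(M, X, simplify = FALSE), labels = labels)
}

# Small synthetic train/test BeatSets for pipeline-level tests; modest
# sizes keep the suite quick while leaving the class structure intact.
makeSmallSplit <- function(nRecordings = 4L, nBeats = 120L, seed = 7L) {
  ds <- simulateDataset(nRecordings = nRecordings, nBeats = nBeats,
                        seed = seed)
  list(train = combineBeatSets(lapply(ds$ds1, extractBeats)),
       test  = combineBeatSets(lapply(ds$ds2, extractBeats)))
}
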