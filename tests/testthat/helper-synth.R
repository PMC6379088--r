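# Shared fixtures, all generated in code.

# Memoize expensive default-study bundles across tests within a file run.
.study_cache <- new.env(parent = emptyenv())

cachedStudy <- function(seed = 1, ...) {
  key <- paste0("s", seed, "_", paste(deparse(list(...)), collapse = ""))
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- generateStudy(syntheticStudyConfig(seed = seed),
                                         ...)
  }
  .study_cache[[key]]
}

# A deterministic hypnogram built from state run lengths (in epochs).
runsHyp <- function(states, lengths, protocol = ProtocolMeta(), ...) {
  Hypnogram(rep(states, lengths), protocol = protocol, ...)
}

# A 24-h repeating pattern padded to the protocol length: recovery days are
# then identical to baseline days by construction.
repeatingHyp <- function(dayStates, protocol = ProtocolMeta()) {
  stopifnot(length(dayStates) == 21600)
  Hypnogram(rep(dayStates, protocol@nDays), protocol = protocol)
}
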