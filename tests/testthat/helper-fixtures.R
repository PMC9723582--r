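# Shared fixtures, all generated in code. Construct and templates are small
# enough that a full segment+consensus round trip stays in test budget.

fixConstruct <- function() defaultConstruct()

# a short 16S-ITS template (primer-site layout intact) for fast round trips
fixTemplate <- function(seed = 101, coreLen = 1250L, itsLen = 400L) {
  makeTaxonTemplate(coreLen = coreLen, itsLen = itsLen, seed = seed)
}

# consensus-level sequences: n noisy replicates of each template at a small
# residual error, named <template>_<i>
fixConsensusSet <- function(templates, perTemplate, mismatch = 5e-5,
                            indel = 2.5e-5, seed = 1) {
  set.seed(seed)
  em <- errorModel(mismatch = mismatch, ins = indel, del = indel, jitter = 0)
  out <- character(0)
  for (t in seq_along(templates)) {
    for (i in seq_len(perTemplate)) {
      out[sprintf("t%02d_%03d", t, i)] <- rcaits:::.mutateSeq(templates[[t]], em)
    }
  }
  out
}

# quick per-base error rate between a sequence and its source template
editRate <- function(seq, template) {
  as.integer(utils::adist(seq, template)) / nchar(template)
}
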