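# small deterministic scenes used across tests
miniTruth <- function(len = 2e6, seed = 101) simulateReference(len, seed = seed)

noiseFreeModel <- function() errorModel(pDigest = 1, falseCutRate = 0,
                                        sizingVarPerBp = 0, minDetectable = 0)

# exact sub-map of a truth map between two interior cut indices
truthWindow <- function(truth, i, j, id = "win") {
  FragmentMap(id, fragments(truth)[i:j], kind = "rmap")
}
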