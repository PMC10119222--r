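# Cytogenetic comparator scheme (reconstruction).
# Low-risk membership by specific whole-chromosome aberrations
# (chromosome 11 loss or chromosome 17 gain); everything else standard.
# This file is an editable reconstruction of the published scheme, not a
# verbatim transcription; adjust against the source publication before
# applying it to real cohorts. Records need logical columns chr11_loss
# and chr17_gain.
id: shih_cytogenetic
labels: low, standard
default: standard
chr11_loss | chr17_gain -> low
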