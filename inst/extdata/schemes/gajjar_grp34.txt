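# Combined Group 3/4 comparator scheme (reconstruction).
# High risk on metastatic disease or MYC/MYCN amplification; low risk on
# whole-chromosome 11 loss; intermediate otherwise. This file is an
# editable reconstruction of the published scheme, not a verbatim
# transcription; adjust against the source publication before applying
# it to real cohorts. Records need m_stage, myc_amp, mycn_amp and a
# logical chr11_loss column.
id: gajjar_grp34
labels: low, intermediate, high
default: intermediate
m_stage == "M+" | myc_amp | mycn_amp -> high
chr11_loss -> low
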