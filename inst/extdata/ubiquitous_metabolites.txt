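# Currency/ubiquitous metabolite base identifiers, one per line.
# Expanded per model compartment as <base>_<compartment> by
# defaultUbiquitousIds(); override with any custom list.
atp
adp
amp
pi
ppi
h
h2o
co2
o2
nad
nadh
nadp
nadph
coa
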