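# Known class label sets
CULTIVARS <- c("Alto", "Bronsyn", "Maxsyn", "Trojan")
ENDOPHYTE_STATUSES <- c("E+", "E-")
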