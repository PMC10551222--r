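# reversible isomerisation, unit mass-action when K = kappa = 1
(1, 1) A <--> B
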