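# SERCA-type pump: six lumped conformations P1..P6
(1, 1) P1 + ATP <--> P2
(1, 1) P2 + 2 Cai <--> P3
(1, 1) P3 <--> P4 + ADP
(1, 1) P4 <--> P5 + 2 Casr
(1, 1) P5 <--> P6 + Pi
(1, 1) P6 <--> P1 + H
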