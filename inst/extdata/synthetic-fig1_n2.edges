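# Synthetic reconstruction; see synthetic-fig1_n1.edges. Differs from n1 in
# which height-1 nodes receive the extra root edges (both under H here,
# crossed under H and J in n1) - enough to break isomorphism while keeping
# first- and second-order indistinguishability of the pair.
edge R A
edge R C
edge R D
edge A H
edge A J
edge H C
edge H D
edge J E
edge J F
edge C 1
edge C 2
edge E 1
edge E 2
edge D 3
edge D 4
edge F 3
edge F 4
leaf 1 1
leaf 2 2
leaf 3 3
leaf 4 4
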