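# Synthetic reconstruction; see synthetic-fig2_n1.edges. 15 nodes, taxa 1-6;
# exactly R, B, E, F, K have no first-order equivalent node in the partner.
edge R B
edge R K
edge B F
edge B E
edge F E
edge F K
edge E G
edge E D
edge K A
edge K D
edge G A
edge G C
edge A 1
edge A 2
edge C 3
edge C 4
edge D 5
edge D 6
leaf 1 1
leaf 2 2
leaf 3 3
leaf 4 4
leaf 5 5
leaf 6 6
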