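# Synthetic reconstruction; see synthetic-fig3_n1.edges. 15 nodes on taxa
# {1..6}; exactly R, B, F, H and the leaf 6 have no first-order equivalent
# node in the partner.
edge R B
edge R H
edge B F
edge B D
edge F H
edge F G
edge H E
edge H 6
edge E G
edge E D
edge G A
edge G C
edge D C
edge D 5
edge A 1
edge A 2
edge C 3
edge C 4
leaf 1 1
leaf 2 2
leaf 3 3
leaf 4 4
leaf 5 5
leaf 6 6
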