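# Synthetic reconstruction of a published figure network: 13 nodes on taxa
# {1..5}; exactly R, B, F have no first-order equivalent in the partner
# (which is on the larger taxon set {1..6}).
edge R B
edge R E
edge B F
edge B G
edge F E
edge F C
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
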