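# Synthetic phylo-SCFG parameter set for hierfold (plain key/value format).
#
# PROVENANCE: this is a SYNTHETIC stand-in asset, not a published parameter
# file.  The grammar production probabilities are set at the magnitudes
# commonly cited for the lightweight structural grammar
#   S -> LS | L ,  L -> s | dFd ,  F -> dFd | LS
# trained on rRNA/tRNA consensus structures, and the stationary frequencies
# concentrate pair mass on the six canonical (Watson-Crick + GU wobble)
# dinucleotides as such models do.  Rate matrices are built by the loader as
# reversible GTR-style matrices from these stationary frequencies and the
# exchangeability scalars below, scaled to one expected substitution per
# unit branch length.  All operations take the loaded parameter set as an
# argument, so a user-supplied file in this same format replaces the asset.
#
# grammar <production> <probability>
grammar S->LS 0.868534
grammar S->L  0.131466
grammar L->s  0.894603
grammar L->dFd 0.105397
grammar F->dFd 0.787640
grammar F->LS  0.212360
#
# single_freq <nt> <stationary probability>  (sums to 1)
single_freq A 0.364097
single_freq C 0.151009
single_freq G 0.211881
single_freq U 0.273013
# single-nucleotide exchangeability (one scalar: F81-style dynamics)
single_exch 1.0
#
# pair_freq <dinucleotide> <stationary probability>  (sums to 1; the six
# canonical pairs carry the bulk of the mass)
pair_freq AU 0.175000
pair_freq UA 0.135000
pair_freq GC 0.230000
pair_freq CG 0.210000
pair_freq GU 0.100000
pair_freq UG 0.090000
pair_freq AA 0.006000
pair_freq AC 0.006000
pair_freq AG 0.006000
pair_freq CA 0.006000
pair_freq CC 0.006000
pair_freq CU 0.006000
pair_freq GA 0.006000
pair_freq GG 0.006000
pair_freq UC 0.006000
pair_freq UU 0.006000
# exchangeability for pair states differing in one / both nucleotides
pair_exch_single 1.0
pair_exch_double 0.3
# overall rate of the 16-state process in expected substitutions per unit
# branch length: a dinucleotide state covers two sites, and branch lengths
# are in substitutions per site, so the paired process runs at rate 2
pair_rate 2.0
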