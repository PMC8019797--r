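# Disable FP contraction so the spatial Wiener kernel reproduces, operation for
# operation, the arithmetic of an interpreted per-pixel reference computation.
PKG_CXXFLAGS = -ffp-contract=off
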