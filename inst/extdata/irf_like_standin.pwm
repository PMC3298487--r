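# Synthetic stand-in for an IRF-family binding-site matrix (the vendor
# matrix library is proprietary). Encodes the AANTGAAA-style IRF core;
# illustrative only -- all matrix-dependent results in this package are
# computed on synthetic promoter sequences, never asserted against
# published scan counts.
# Columns: A C G T (per-position probabilities).
>IRF_like_standin
0.85 0.05 0.05 0.05
0.85 0.05 0.05 0.05
0.25 0.25 0.25 0.25
0.05 0.05 0.05 0.85
0.05 0.05 0.85 0.05
0.90 0.03 0.04 0.03
0.90 0.03 0.04 0.03
0.85 0.05 0.05 0.05
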