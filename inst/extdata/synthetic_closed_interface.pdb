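REMARK   5 SYNTHETIC stand-in structure, not experimental data
REMARK   5 C-alpha triad built at interface angle 10.0 deg
ATOM      1  CA  PHE A 120      51.000  30.000  30.000  1.00  0.00           C
ATOM      2  CA  GLY B  52      44.280  32.518  30.000  1.00  0.00           C
ATOM      3  CA  TRP B 123      30.000  30.000  30.000  1.00  0.00           C
END
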