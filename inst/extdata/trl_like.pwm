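>Trl_like
0.0166667 0.0166667 0.9500000 0.0166667
0.9500000 0.0166667 0.0166667 0.0166667
0.0166667 0.0166667 0.9500000 0.0166667
0.9500000 0.0166667 0.0166667 0.0166667
0.0166667 0.0166667 0.9500000 0.0166667
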