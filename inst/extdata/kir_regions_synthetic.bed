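chr19	54724000	54734000	KIR3DL3
chr19	54734000	54744000	KIR2DL3
chr19	54744000	54754000	KIR2DL1
chr19	54754000	54764000	KIR2DL4
chr19	54764000	54774000	KIR3DL1
chr19	54774000	54784000	KIR2DS4
chr19	54784000	54794000	KIR3DL2
chr19	54794000	54804000	KIR2DL2
chr19	54804000	54814000	KIR2DL5A
chr19	54814000	54824000	KIR2DL5B
chr19	54824000	54834000	KIR2DS1
chr19	54834000	54844000	KIR2DS2
chr19	54844000	54854000	KIR2DS3
chr19	54854000	54864000	KIR2DS5
chr19	54864000	54874000	KIR3DS1
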