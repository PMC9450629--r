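# Total spiral-canal length per reference case (mm). Original comma-decimal
# strings: 23,00 19,00 23,50 22,00 26,50 17,00.
case_id,total_mm
case1,23.0
case2,19.0
case3,23.5
case4,22.0
case5,26.5
case6,17.0
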