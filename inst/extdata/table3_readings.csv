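# Per-ruler readings of the six reference temporal-bone cases, vestibule (R1)
# towards the apex (Rx). Dot-decimal normalization of the source table; rows
# the source marks "DNM" (no measurement recorded) are omitted here and
# reconstructed by render_fixture_report().
# Original comma-decimal row strings, for auditability:
#   R1..R6: 2,00 for every case
#   R7:  2,00 2,00 2,00 2,00 2,00 1,50
#   R8:  2,00 2,00 2,00 2,00 2,00 1,50
#   R9:  2,00 1,00 2,00 2,00 2,00 1,00
#   R10: 1,50 1,00 1,50 1,50 2,00 1,00
#   R11: 1,50 1,00 1,50 1,50 2,00 DNM
#   R12: 1,00 DNM  1,50 1,00 2,00 DNM
#   R13: 1,00 DNM  1,00 DNM  1,50 DNM
#   R14: DNM  DNM  DNM  DNM  1,00 DNM
case_id,label,length_mm
case1,R1,2.0
case1,R2,2.0
case1,R3,2.0
case1,R4,2.0
case1,R5,2.0
case1,R6,2.0
case1,R7,2.0
case1,R8,2.0
case1,R9,2.0
case1,R10,1.5
case1,R11,1.5
case1,R12,1.0
case1,R13,1.0
case2,R1,2.0
case2,R2,2.0
case2,R3,2.0
case2,R4,2.0
case2,R5,2.0
case2,R6,2.0
case2,R7,2.0
case2,R8,2.0
case2,R9,1.0
case2,R10,1.0
case2,R11,1.0
case3,R1,2.0
case3,R2,2.0
case3,R3,2.0
case3,R4,2.0
case3,R5,2.0
case3,R6,2.0
case3,R7,2.0
case3,R8,2.0
case3,R9,2.0
case3,R10,1.5
case3,R11,1.5
case3,R12,1.5
case3,R13,1.0
case4,R1,2.0
case4,R2,2.0
case4,R3,2.0
case4,R4,2.0
case4,R5,2.0
case4,R6,2.0
case4,R7,2.0
case4,R8,2.0
case4,R9,2.0
case4,R10,1.5
case4,R11,1.5
case4,R12,1.0
case5,R1,2.0
case5,R2,2.0
case5,R3,2.0
case5,R4,2.0
case5,R5,2.0
case5,R6,2.0
case5,R7,2.0
case5,R8,2.0
case5,R9,2.0
case5,R10,2.0
case5,R11,2.0
case5,R12,2.0
case5,R13,1.5
case5,R14,1.0
case6,R1,2.0
case6,R2,2.0
case6,R3,2.0
case6,R4,2.0
case6,R5,2.0
case6,R6,2.0
case6,R7,1.5
case6,R8,1.5
case6,R9,1.0
case6,R10,1.0
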