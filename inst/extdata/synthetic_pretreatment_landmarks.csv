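"name","x","y","z"
"incisal_mid_U1_R",-4.5,-0.972,0
"apex_U1_R",-4.5,-0.972,-13
"incisal_mid_U1_L",4.5,-0.972,0
"apex_U1_L",4.5,-0.972,-13
"incisal_mid_U2_R",-13,-8.112,0
"apex_U2_R",-13,-8.112,-13
"incisal_mid_U2_L",13,-8.112,0
"apex_U2_L",13,-8.112,-13
"cusp_tip_U3_R",-17.5,-14.7,0
"apex_U3_R",-17.5,-14.7,-16
"cusp_tip_U3_L",17.5,-14.7,0
"apex_U3_L",17.5,-14.7,-16
"buccal_cusp_U5_R",-23,-25.392,0
"apex_U5_R",-23,-25.392,-14
"buccal_cusp_U5_L",23,-25.392,0
"apex_U5_L",23,-25.392,-14
"MB_cusp_U6_R",-25,-30,0
"apex_U6_R",-25,-30,-13
"MB_cusp_U6_L",25,-30,0
"apex_U6_L",25,-30,-13
"MB_cusp_U7_R",-26.5,-33.708,0
"apex_U7_R",-26.5,-33.708,-12
"MB_cusp_U7_L",26.5,-33.708,0
"apex_U7_L",26.5,-33.708,-12
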