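feature_id,neutral_mass,mz,adduct,rt,parent_area,formula,mass_error_ppm,active_assay,n_candidates,n_active_total,n_active_top
F01,139.0633,140.07058,[M+H]+,9.71,3.9e7,C7H9NO2,-0.17,,2116,18,0
F02,186.0528,187.06011,[M+H]+,10.61,1.5e7,C8H10O5,0.05,,803,23,3
F03,214.0478,215.05504,[M+H]+,10.61,9.0e7,C9H10O6,0.14,,293,6,0
F04,246.0740,247.08126,[M+H]+,10.61,6.8e7,C10H14O7,0.08,,233,8,0
F05,232.0583,233.06561,[M+H]+,10.61,2.0e7,C9H12O7,0.12,,151,4,0
F06,200.0321,201.03933,[M+H]+,10.61,2.1e7,C8H8O6,-0.17,,293,8,1
F07,263.1005,264.10776,[M+H]+,10.81,6.3e6,C10H17NO7,-0.08,TOX21DT40ratioup,138,6,1
F08,280.0503,281.05753,[M+H]+,14.58,6.6e6,C14H13ClO4,0.05,,329,24,0
F09,246.0892,247.09648,[M+H]+,15.01,4.6e7,C14H14O4,-0.04,,2757,238,10
F10,210.0529,211.06016,[M+H]+,15.23,2.1e7,C10H10O5,0.21,,1283,41,1
F11,150.0318,151.03905,[M+H]+,15.23,1.4e7,C8H6O3,0.54,,311,10,6
F12,405.1788,406.18602,[M+H]+,15.39,3.0e7,C21H27NO7,-0.02,TOX21p53BLAup,356,20,2
F13,186.0681,187.07534,[M+H]+,15.39,2.3e7,C12H10O2,-0.07,TOX21DT40ratioup,1085,39,17
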