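cell_type,protein,copies_per_cell,provenance
human_platelet,Gq,6000,native
human_platelet,smG,50000,native
human_platelet,PLCb,10000,native
human_platelet,IP3ME,20000,native
human_platelet,DGK,10000,native
human_platelet,LPP,5000,native
human_platelet,CDIPT,8000,native
human_platelet,OCRL1,2000,native
human_platelet,PI4K,3000,native
human_platelet,PIP5K,5000,native
human_platelet,SAC1,4000,native
human_platelet,cPLA2,10000,native
mouse_platelet_synthetic,Gq,1007.94522377939,native
mouse_platelet_synthetic,smG,15623.861165496,native
mouse_platelet_synthetic,PLCb,3400.30457595449,native
mouse_platelet_synthetic,IP3ME,5281.99401901431,native
mouse_platelet_synthetic,DGK,1574.16139431552,native
mouse_platelet_synthetic,LPP,3576.04742368865,native
mouse_platelet_synthetic,CDIPT,729.436149082834,native
mouse_platelet_synthetic,OCRL1,279.532908802508,native
mouse_platelet_synthetic,PI4K,623.282652715163,native
mouse_platelet_synthetic,PIP5K,2033.05384810457,native
mouse_platelet_synthetic,SAC1,2264.38651094645,native
mouse_platelet_synthetic,cPLA2,5318.92555105155,native
HeLa_synthetic,Gq,68973.9588000543,native
HeLa_synthetic,smG,1649439.11035705,native
HeLa_synthetic,PLCb,75630.967649334,native
HeLa_synthetic,IP3ME,439737.06487568,native
HeLa_synthetic,DGK,246835.345721088,native
HeLa_synthetic,LPP,347724.605009786,native
HeLa_synthetic,CDIPT,285774.406896142,native
HeLa_synthetic,OCRL1,29697.9894108009,native
HeLa_synthetic,PI4K,153278.967803238,native
HeLa_synthetic,PIP5K,65022.9327322395,native
HeLa_synthetic,SAC1,127899.579879845,native
HeLa_synthetic,cPLA2,65495.7407986552,native
U2OS_synthetic,smG,1061774.73630331,native
U2OS_synthetic,PLCb,54026.0139293591,native
U2OS_synthetic,DGK,213298.812820265,native
U2OS_synthetic,LPP,83167.9011748972,native
U2OS_synthetic,CDIPT,131446.798338655,native
U2OS_synthetic,PIP5K,103896.178829284,native
U2OS_synthetic,SAC1,111364.137931406,native
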