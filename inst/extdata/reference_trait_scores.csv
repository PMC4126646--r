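species,stems,isv_dc,rar,rar_fine,tmax,rar_coarse,ei,eps_ult_mech,eps_ult_phys,nitrogen,cellulose
A. americana,1,2,3,1,2,3,3,3,2,1,2
A. codonocephala,2,2,2,3,3,1,2,3,2,3,3
A. hispidus,3,2,1,3,2,1,1,1,2,1,1
B. championii,1,3,2,2,2,2,2,1,2,2,1
C. anomala,3,1,1,3,3,1,1,3,2,1,3
F. tikoua,2,1,2,2,2,2,1,1,1,1,3
J. curcas,1,2,2,1,1,3,3,3,2,1,3
P. stricta,1,3,2,2,3,2,3,3,3,3,1
R. chinensis,2,2,2,1,1,3,3,1,2,2,1
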