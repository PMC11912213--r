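peptide,n_residues,method,dE_hyd_hartree,dE_hyd_kcal,dG_hyd_hartree,dG_hyd_kcal
Abeta28,28,GFN-FF,-0.3851056,-241.66,-0.3992255,-250.52
Abeta28,28,GFN2-xTB,-0.8219843,-515.80,-0.8549519,-536.49
Abeta40,40,GFN-FF,-0.3867420,-242.68,-0.4044057,-253.77
Abeta40,40,GFN2-xTB,-0.8687382,-545.14,-0.9117551,-572.14
Abeta42,42,GFN-FF,-0.4083824,-256.26,-0.4323021,-271.27
Abeta42,42,GFN2-xTB,-0.9814659,-615.88,-0.9790356,-614.35
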