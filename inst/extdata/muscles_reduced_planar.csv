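name,f_max,l_opt,l_slack,pennation_opt,tau_act,tau_deact,coords,arms
iliopsoas_r,2200,0.12,0.14,0.14,0.015,0.06,hip_r,0.05
glutmax_r,3500,0.16,0.125,0,0.015,0.06,hip_r,-0.06
hamstrings_r,3500,0.11,0.33,0,0.015,0.06,hip_r;knee_r,-0.055;0.035
rectfem_r,1800,0.09,0.34,0.05,0.015,0.06,hip_r;knee_r,0.045;-0.04
vasti_r,7000,0.09,0.22,0.05,0.015,0.06,knee_r,-0.045
gastroc_r,2500,0.06,0.38,0.17,0.015,0.06,knee_r;ankle_r,0.02;-0.04
soleus_r,5000,0.045,0.27,0.44,0.015,0.06,ankle_r,-0.045
tibant_r,1500,0.07,0.22,0.1,0.015,0.06,ankle_r,0.035
iliopsoas_l,2200,0.12,0.14,0.14,0.015,0.06,hip_l,0.05
glutmax_l,3500,0.16,0.125,0,0.015,0.06,hip_l,-0.06
hamstrings_l,3500,0.11,0.33,0,0.015,0.06,hip_l;knee_l,-0.055;0.035
rectfem_l,1800,0.09,0.34,0.05,0.015,0.06,hip_l;knee_l,0.045;-0.04
vasti_l,7000,0.09,0.22,0.05,0.015,0.06,knee_l,-0.045
gastroc_l,2500,0.06,0.38,0.17,0.015,0.06,knee_l;ankle_l,0.02;-0.04
soleus_l,5000,0.045,0.27,0.44,0.015,0.06,ankle_l,-0.045
tibant_l,1500,0.07,0.22,0.1,0.015,0.06,ankle_l,0.035
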