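name,f_max,l_opt,l_slack,pennation_opt,tau_act,tau_deact,coords,arms
addbrev_r,600,0.1,0.035,0.1,0.015,0.06,hip_r_add,0.035
addlong_r,900,0.11,0.12,0.14,0.015,0.06,hip_r_add;hip_r_flex,0.04;0.015
addmagDist_r,560,0.18,0.09,0.12,0.015,0.06,hip_r_add,0.045
addmagIsch_r,460,0.16,0.22,0.14,0.015,0.06,hip_r_add;hip_r_flex,0.04;-0.02
addmagMid_r,560,0.14,0.05,0.12,0.015,0.06,hip_r_add,0.04
addmagProx_r,490,0.11,0.04,0.19,0.015,0.06,hip_r_add,0.035
bflh_r,980,0.1,0.33,0.2,0.015,0.06,hip_r_flex;knee_r,-0.055;0.032
bfsh_r,560,0.11,0.11,0.25,0.015,0.06,knee_r,0.03
edl_r,510,0.07,0.37,0.19,0.015,0.06,ankle_r,0.032
ehl_r,160,0.08,0.33,0.16,0.015,0.06,ankle_r,0.030
fdl_r,310,0.045,0.38,0.24,0.015,0.06,ankle_r,-0.032
fhl_r,430,0.05,0.35,0.29,0.015,0.06,ankle_r,-0.035
gaslat_r,680,0.06,0.38,0.21,0.015,0.06,knee_r;ankle_r,0.018;-0.040
gasmed_r,1600,0.06,0.4,0.17,0.015,0.06,knee_r;ankle_r,0.020;-0.042
glmax1_r,980,0.15,0.05,0.38,0.015,0.06,hip_r_flex;hip_r_rot,-0.05;-0.02
glmax2_r,1400,0.16,0.07,0.38,0.015,0.06,hip_r_flex,-0.06
glmax3_r,950,0.17,0.06,0.38,0.015,0.06,hip_r_flex;hip_r_add,-0.055;0.015
glmed1_r,1100,0.07,0.06,0.35,0.015,0.06,hip_r_add;hip_r_flex,-0.045;0.01
glmed2_r,920,0.07,0.07,0.35,0.015,0.06,hip_r_add,-0.05
glmed3_r,600,0.07,0.05,0.35,0.015,0.06,hip_r_add;hip_r_flex,-0.045;-0.015
glmin1_r,270,0.07,0.02,0.17,0.015,0.06,hip_r_add,-0.035
glmin2_r,280,0.06,0.03,0.17,0.015,0.06,hip_r_add,-0.035
glmin3_r,320,0.04,0.05,0.17,0.015,0.06,hip_r_add;hip_r_rot,-0.03;-0.01
grac_r,280,0.23,0.17,0.14,0.015,0.06,hip_r_add;knee_r,0.035;0.02
iliacus_r,1100,0.11,0.1,0.25,0.015,0.06,hip_r_flex,0.045
perbrev_r,520,0.045,0.15,0.2,0.015,0.06,ankle_r,-0.02
perlong_r,1150,0.05,0.33,0.24,0.015,0.06,ankle_r,-0.025
piri_r,1030,0.03,0.11,0.17,0.015,0.06,hip_r_rot,-0.025
psoas_r,1200,0.1,0.16,0.19,0.015,0.06,hip_r_flex,0.045
recfem_r,1200,0.08,0.35,0.24,0.015,0.06,hip_r_flex;knee_r,0.04;-0.04
sart_r,250,0.4,0.11,0.02,0.015,0.06,hip_r_flex;knee_r,0.04;0.015
semimem_r,1300,0.07,0.35,0.26,0.015,0.06,hip_r_flex;knee_r,-0.055;0.035
semiten_r,410,0.19,0.25,0.22,0.015,0.06,hip_r_flex;knee_r,-0.06;0.04
soleus_r,3600,0.044,0.28,0.49,0.015,0.06,ankle_r,-0.045
tfl_r,230,0.1,0.42,0.05,0.015,0.06,hip_r_add;hip_r_flex,-0.04;0.02
tibant_r,1000,0.068,0.24,0.17,0.015,0.06,ankle_r,0.035
tibpost_r,1600,0.038,0.28,0.24,0.015,0.06,ankle_r,-0.03
vasint_r,1700,0.1,0.2,0.08,0.015,0.06,knee_r,-0.044
vaslat_r,2900,0.1,0.22,0.32,0.015,0.06,knee_r,-0.045
vasmed_r,1400,0.1,0.2,0.51,0.015,0.06,knee_r,-0.044
gemelli_r,160,0.024,0.04,0,0.015,0.06,hip_r_rot,-0.02
pectineus_r,180,0.13,0.003,0,0.015,0.06,hip_r_add;hip_r_flex,0.03;0.02
quadfem_r,270,0.054,0.02,0,0.015,0.06,hip_r_rot,-0.03
addbrev_l,600,0.1,0.035,0.1,0.015,0.06,hip_l_add,0.035
addlong_l,900,0.11,0.12,0.14,0.015,0.06,hip_l_add;hip_l_flex,0.04;0.015
addmagDist_l,560,0.18,0.09,0.12,0.015,0.06,hip_l_add,0.045
addmagIsch_l,460,0.16,0.22,0.14,0.015,0.06,hip_l_add;hip_l_flex,0.04;-0.02
addmagMid_l,560,0.14,0.05,0.12,0.015,0.06,hip_l_add,0.04
addmagProx_l,490,0.11,0.04,0.19,0.015,0.06,hip_l_add,0.035
bflh_l,980,0.1,0.33,0.2,0.015,0.06,hip_l_flex;knee_l,-0.055;0.032
bfsh_l,560,0.11,0.11,0.25,0.015,0.06,knee_l,0.03
edl_l,510,0.07,0.37,0.19,0.015,0.06,ankle_l,0.032
ehl_l,160,0.08,0.33,0.16,0.015,0.06,ankle_l,0.030
fdl_l,310,0.045,0.38,0.24,0.015,0.06,ankle_l,-0.032
fhl_l,430,0.05,0.35,0.29,0.015,0.06,ankle_l,-0.035
gaslat_l,680,0.06,0.38,0.21,0.015,0.06,knee_l;ankle_l,0.018;-0.040
gasmed_l,1600,0.06,0.4,0.17,0.015,0.06,knee_l;ankle_l,0.020;-0.042
glmax1_l,980,0.15,0.05,0.38,0.015,0.06,hip_l_flex;hip_l_rot,-0.05;-0.02
glmax2_l,1400,0.16,0.07,0.38,0.015,0.06,hip_l_flex,-0.06
glmax3_l,950,0.17,0.06,0.38,0.015,0.06,hip_l_flex;hip_l_add,-0.055;0.015
glmed1_l,1100,0.07,0.06,0.35,0.015,0.06,hip_l_add;hip_l_flex,-0.045;0.01
glmed2_l,920,0.07,0.07,0.35,0.015,0.06,hip_l_add,-0.05
glmed3_l,600,0.07,0.05,0.35,0.015,0.06,hip_l_add;hip_l_flex,-0.045;-0.015
glmin1_l,270,0.07,0.02,0.17,0.015,0.06,hip_l_add,-0.035
glmin2_l,280,0.06,0.03,0.17,0.015,0.06,hip_l_add,-0.035
glmin3_l,320,0.04,0.05,0.17,0.015,0.06,hip_l_add;hip_l_rot,-0.03;-0.01
grac_l,280,0.23,0.17,0.14,0.015,0.06,hip_l_add;knee_l,0.035;0.02
iliacus_l,1100,0.11,0.1,0.25,0.015,0.06,hip_l_flex,0.045
perbrev_l,520,0.045,0.15,0.2,0.015,0.06,ankle_l,-0.02
perlong_l,1150,0.05,0.33,0.24,0.015,0.06,ankle_l,-0.025
piri_l,1030,0.03,0.11,0.17,0.015,0.06,hip_l_rot,-0.025
psoas_l,1200,0.1,0.16,0.19,0.015,0.06,hip_l_flex,0.045
recfem_l,1200,0.08,0.35,0.24,0.015,0.06,hip_l_flex;knee_l,0.04;-0.04
sart_l,250,0.4,0.11,0.02,0.015,0.06,hip_l_flex;knee_l,0.04;0.015
semimem_l,1300,0.07,0.35,0.26,0.015,0.06,hip_l_flex;knee_l,-0.055;0.035
semiten_l,410,0.19,0.25,0.22,0.015,0.06,hip_l_flex;knee_l,-0.06;0.04
soleus_l,3600,0.044,0.28,0.49,0.015,0.06,ankle_l,-0.045
tfl_l,230,0.1,0.42,0.05,0.015,0.06,hip_l_add;hip_l_flex,-0.04;0.02
tibant_l,1000,0.068,0.24,0.17,0.015,0.06,ankle_l,0.035
tibpost_l,1600,0.038,0.28,0.24,0.015,0.06,ankle_l,-0.03
vasint_l,1700,0.1,0.2,0.08,0.015,0.06,knee_l,-0.044
vaslat_l,2900,0.1,0.22,0.32,0.015,0.06,knee_l,-0.045
vasmed_l,1400,0.1,0.2,0.51,0.015,0.06,knee_l,-0.044
gemelli_l,160,0.024,0.04,0,0.015,0.06,hip_l_rot,-0.02
pectineus_l,180,0.13,0.003,0,0.015,0.06,hip_l_add;hip_l_flex,0.03;0.02
quadfem_l,270,0.054,0.02,0,0.015,0.06,hip_l_rot,-0.03
ercspn_r,2500,0.12,0.1,0,0.015,0.06,lumbar_flex;lumbar_add,-0.055;-0.03
ercspn_l,2500,0.12,0.1,0,0.015,0.06,lumbar_flex;lumbar_add,-0.055;0.03
rectabd_r,1000,0.3,0.1,0,0.015,0.06,lumbar_flex,0.08
rectabd_l,1000,0.3,0.1,0,0.015,0.06,lumbar_flex,0.08
extobl_r,900,0.12,0.14,0,0.015,0.06,lumbar_flex;lumbar_add;lumbar_rot,0.045;-0.05;0.04
extobl_l,900,0.12,0.14,0,0.015,0.06,lumbar_flex;lumbar_add;lumbar_rot,0.045;0.05;-0.04
intobl_r,900,0.1,0.12,0,0.015,0.06,lumbar_flex;lumbar_add;lumbar_rot,0.04;-0.05;-0.04
intobl_l,900,0.1,0.12,0,0.015,0.06,lumbar_flex;lumbar_add;lumbar_rot,0.04;0.05;0.04
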