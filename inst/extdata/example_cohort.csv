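# symregpk-csv-v1
id,time_s,rate_ugps,conc_ugpl,age_y,wgt_kg,bmi,gender,site
S0001,                 0,3998.5763545545437,,51.468263084068894,59.978645318318158,32.857194036105646,M,V
S0001,                30,99.964408863863596,,51.468263084068894,59.978645318318158,32.857194036105646,M,V
S0001,              1815,49.982204431931798,,51.468263084068894,59.978645318318158,32.857194036105646,M,V
S0001,              3600,                 0,,51.468263084068894,59.978645318318158,32.857194036105646,M,V
S0001,                60,,293.37959754740353,51.468263084068894,59.978645318318158,32.857194036105646,M,V
S0001,               235,,349.58431776011952,51.468263084068894,59.978645318318158,32.857194036105646,M,V
S0001,               920,,335.76911831716626,51.468263084068894,59.978645318318158,32.857194036105646,M,V
S0001,              3600,,796.62612212965439,51.468263084068894,59.978645318318158,32.857194036105646,M,V
S0001,              3660,,658.57049787514268,51.468263084068894,59.978645318318158,32.857194036105646,M,V
S0001,              7200,,548.22384935837533,51.468263084068894,59.978645318318158,32.857194036105646,M,V
S0002,                 0,510.81130622513592,,29.345108615234494,7.6621695933770386,14.962964611458592,F,V
S0002,                30,12.770282655628398,,29.345108615234494,7.6621695933770386,14.962964611458592,F,V
S0002,              1815,6.3851413278141989,,29.345108615234494,7.6621695933770386,14.962964611458592,F,V
S0002,              3600,                 0,,29.345108615234494,7.6621695933770386,14.962964611458592,F,V
S0002,                60,,257.91040510861285,29.345108615234494,7.6621695933770386,14.962964611458592,F,V
S0002,               235,, 255.4394652972903,29.345108615234494,7.6621695933770386,14.962964611458592,F,V
S0002,               920,,355.01516019109118,29.345108615234494,7.6621695933770386,14.962964611458592,F,V
S0002,              3600,,625.76889645787173,29.345108615234494,7.6621695933770386,14.962964611458592,F,V
S0002,              3660,,543.78994094925349,29.345108615234494,7.6621695933770386,14.962964611458592,F,V
S0002,              7200,,361.62891184396318,29.345108615234494,7.6621695933770386,14.962964611458592,F,V
S0003,                 0,7583.1238528086496,, 54.73705280944705,113.74685779212975,25.909171229954804,F,A
S0003,                30,189.57809632021625,, 54.73705280944705,113.74685779212975,25.909171229954804,F,A
S0003,              1815,94.789048160108123,, 54.73705280944705,113.74685779212975,25.909171229954804,F,A
S0003,              3600,                 0,, 54.73705280944705,113.74685779212975,25.909171229954804,F,A
S0003,                60,,255.60979569649734, 54.73705280944705,113.74685779212975,25.909171229954804,F,A
S0003,               235,, 245.9003051279866, 54.73705280944705,113.74685779212975,25.909171229954804,F,A
S0003,               920,,356.09540178461867, 54.73705280944705,113.74685779212975,25.909171229954804,F,A
S0003,              3600,,448.69214931491206, 54.73705280944705,113.74685779212975,25.909171229954804,F,A
S0003,              3660,,310.49911582316275, 54.73705280944705,113.74685779212975,25.909171229954804,F,A
S0003,              7200,,466.13696006701042, 54.73705280944705,113.74685779212975,25.909171229954804,F,A
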