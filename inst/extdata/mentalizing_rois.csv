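name,x,y,z,radius_mm
dMPFC,-2,60,22,8
vMPFC,-2,48,-20,8
RTPJ,59,-55,27,8
LTPJ,-48,-55,26,8
PCC,2,-52,42,8
rATL,48,-6,-20,8
lATL,-52,6,-35,8
lTP,-40,21,-24,8
rCereb,29,-82,-39,8
mCereb,2,-52,-47,8
lCereb,-25,-78,-39,8
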