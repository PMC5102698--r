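name,x,y,z
rCereb,29,-82,-39
lCereb,-25,-78,-39
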