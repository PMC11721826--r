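# Clinical regrouping of the 23 significant disease clusters into 11 groups.
"D64": [D64]
"H16/H60": [H16, H60]
"J41/J45": [J41, J45]
"L01/L24": [L01, L24]
"M00": [M00]
"M41/M54": [M41, M54]
"M62/M65/M67": [M62, M65, M67]
"Q65": [Q65]
"Q66": [Q66]
"S30/S33/S70/S73": [S30, S33, S70, S73]
"S50/S80/S83/T00": [S50, S80, S83, T00]
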