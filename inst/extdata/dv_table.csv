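# Daily Value reference amounts used as denominators for reformulation thresholds.
# Transcribed from Health Canada's Table of Daily Values (2016 labelling regulations),
# adults and children >= 4 years. Energy uses the 2000 kcal reference intake that
# anchors the %DV footnote; protein has no Canadian %DV, so the 50 g reference
# standard (Codex/US) is used and recorded here as an editable input.
# version: hc-tdv-2016/transcription-1
nutrient,dv,unit
energy_kcal,2000,kcal
fat_g,75,g
satfat_g,20,g
carb_g,275,g
sugars_g,100,g
protein_g,50,g
sodium_mg,2300,mg
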