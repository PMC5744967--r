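{
  "registry_version": "1.0",
  "description": "Published hyperspectral vegetation indices for leaf chlorophyll, water and pigment status. Formulas use R<nm> for reflectance at the 1-nm grid point <nm>. 'core' entries form the 19-index comparison suite; non-core entries are supplementary variants.",
  "indices": [
    {"name": "SR1", "formula": "R750/R700", "target": "chlorophyll", "core": true},
    {"name": "DoubleDifference", "formula": "(R749-R720)-(R701-R672)", "target": "chlorophyll", "core": true,
     "note": "transcribed as printed in the source comparison table; the sign pattern differs from the original publication"},
    {"name": "Vogelmann1", "formula": "R740/R720", "target": "chlorophyll", "core": true},
    {"name": "mSR705", "formula": "(R750-R445)/(R705-R445)", "target": "chlorophyll", "core": true},
    {"name": "SRCarter", "formula": "R760/R695", "target": "stress", "core": true},
    {"name": "Maccioni", "formula": "(R780-R710)/(R780-R680)", "target": "chlorophyll", "core": true},
    {"name": "SR3", "formula": "R750/R550", "target": "chlorophyll", "core": true},
    {"name": "Gitelson", "formula": "1/R700", "target": "chlorophyll", "core": true},
    {"name": "NDVI_MODIS", "formula": "band_mean_ndvi", "target": "greenness", "core": true,
     "special": "modis", "note": "red band 620-670 nm, NIR band 841-876 nm, band-mean reflectance then the NDVI formula"},
    {"name": "Datt4", "formula": "R672/(R550*R708)", "target": "chlorophyll", "core": true},
    {"name": "SR4", "formula": "R700/R670", "target": "chlorophyll", "core": true},
    {"name": "SR2", "formula": "R752/R690", "target": "chlorophyll", "core": true},
    {"name": "NDVI", "formula": "(R860-R690)/(R860+R690)", "target": "greenness", "core": true},
    {"name": "Vogelmann2", "formula": "(R734-R747)-(R715+R726)", "target": "chlorophyll", "core": true,
     "note": "transcribed as printed in the source comparison table; the original publication uses a ratio form"},
    {"name": "mNDVI", "formula": "(R800-R680)/(R800+R680-2*R445)", "target": "chlorophyll", "core": true},
    {"name": "NDWI", "formula": "(R860-R1240)/(R860+R1240)", "target": "water", "core": true},
    {"name": "SIPI", "formula": "(R800-R445)", "target": "pigments", "core": true,
     "note": "as printed in the source comparison table (likely truncated); see SIPI_full for the conventional form"},
    {"name": "PRI", "formula": "(R531-R570)/(R531+R570)", "target": "light-use efficiency", "core": true},
    {"name": "mSRCHL", "formula": "(R800-R445)/(R680-R445)", "target": "chlorophyll", "core": true},
    {"name": "SIPI_full", "formula": "(R800-R445)/(R800-R680)", "target": "pigments", "core": false}
  ]
}
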