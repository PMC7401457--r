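{
  "_comment": "Healthy-control reference: per-metric [mean, SD] for women (F) and men (M). The default table is pooled across sexes (84 control eyes); both sexes therefore carry the same entry. vd_* in 1/mm, thicknesses in um, FAZ circularity dimensionless.",
  "metrics": {
    "vd_scp":          {"F": [21.1, 0.7],   "M": [21.1, 0.7]},
    "vd_dcp":          {"F": [16.1, 1.8],   "M": [16.1, 1.8]},
    "vd_fr":           {"F": [22.4, 0.6],   "M": [22.4, 0.6]},
    "rnfl_um":         {"F": [7.0, 3.4],    "M": [7.0, 3.4]},
    "gcl_ipl_um":      {"F": [82.7, 5.5],   "M": [82.7, 5.5]},
    "crt_um":          {"F": [260.6, 18.3], "M": [260.6, 18.3]},
    "faz_circularity": {"F": [0.65, 0.07],  "M": [0.65, 0.07]},
    "faz_area_mm2":    {"F": [0.24, 0.11],  "M": [0.24, 0.11]}
  }
}
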