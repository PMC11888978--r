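{
  "description": "Recipe for the bundled representative day-4 PHx+Gln section (rendered at run time by representativeSection()).",
  "profile": "PHx+Gln:D4",
  "width_mm": 1,
  "height_mm": 1,
  "pixel_size_um": 1,
  "landmarks": {"pt_count": 5, "cv_count": 2, "min_sep_um": 150, "seed": 4},
  "render_seed": 1004,
  "options": {"tissueMarginUm": 0, "saltCount": 0},
  "expected": {"pt_per_mm2": 5, "cv_per_mm2": 2},
  "synthetic": true
}
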