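# 50-gene demonstration run: wild type plus both Spn1-mutant presets.
seed: 42
outdir: mnassp_demo
simulation:
  n_genes: 50
  n_fragments: 20000
  spacing_bp: 165
  ndr_width_bp: 140
conditions:
  - name: WT
    preset: WT
  - name: K192N
    preset: K192N
  - name: d141-305
    preset: 141-305
bins:
  - {min: 0, max: 60, label: ndr-short}
  - {min: 142, max: 152, label: nucleosome}
flank: 800
vplot_max_offset: 500
alpha: 0.05
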