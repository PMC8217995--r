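intervals:
- name: non-echogenic
  lo: 0
  hi: 4
  band: non-echogenic
  tissue_tag: blood
- name: hypoechogenic I
  lo: 5
  hi: 18
  band: low echogenicity
  tissue_tag: unassigned
- name: hypoechogenic II
  lo: 19
  hi: 32
  band: low echogenicity
  tissue_tag: unassigned
- name: hypoechogenic III
  lo: 33
  hi: 46
  band: low echogenicity
  tissue_tag: unassigned
- name: hypoechogenic IV
  lo: 47
  hi: 60
  band: low echogenicity
  tissue_tag: muscle
- name: echogenic I
  lo: 61
  hi: 84
  band: echogenic
  tissue_tag: unassigned
- name: echogenic II
  lo: 85
  hi: 108
  band: echogenic
  tissue_tag: unassigned
- name: echogenic III
  lo: 109
  hi: 132
  band: echogenic
  tissue_tag: unassigned
- name: hyperechogenic I
  lo: 133
  hi: 148
  band: high echogenicity
  tissue_tag: fibrosis
- name: hyperechogenic II
  lo: 149
  hi: 164
  band: high echogenicity
  tissue_tag: fibrosis
- name: hyperechogenic III
  lo: 165
  hi: 180
  band: high echogenicity
  tissue_tag: fibrosis
- name: hyperechogenic IV
  lo: 181
  hi: 195
  band: high echogenicity
  tissue_tag: fibrosis
- name: hyperechogenic V
  lo: 196
  hi: 210
  band: high echogenicity
  tissue_tag: unassigned
- name: saturation
  lo: 211
  hi: 255
  band: saturation
  tissue_tag: calcium
color_bands:
- band: non-echogenic
  lo: 0
  hi: 4
  rgb:
  - 0
  - 0
  - 0
- band: low echogenicity
  lo: 5
  hi: 60
  rgb:
  - 0
  - 0
  - 255
- band: echogenic
  lo: 61
  hi: 132
  rgb:
  - 0
  - 200
  - 0
- band: high echogenicity
  lo: 133
  hi: 210
  rgb:
  - 255
  - 165
  - 0
- band: saturation
  lo: 211
  hi: 255
  rgb:
  - 255
  - 255
  - 255
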