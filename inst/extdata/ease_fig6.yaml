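category_boundaries:
- 3
- 7
missing_lasct_policy: refuse
bands:
  lasr:
  - lower: 23.0
    upper: .inf
    lower_inc: no
    upper_inc: no
    points: 0
  - lower: 15.0
    upper: 23.0
    lower_inc: yes
    upper_inc: yes
    points: 1
  - lower: 0.0
    upper: 15.0
    lower_inc: no
    upper_inc: no
    points: 2
  patdi:
  - lower: 0.0
    upper: 120.0
    lower_inc: no
    upper_inc: no
    points: 0
  - lower: 120.0
    upper: 150.0
    lower_inc: yes
    upper_inc: yes
    points: 1
  - lower: 150.0
    upper: .inf
    lower_inc: no
    upper_inc: no
    points: 2
  lavi:
  - lower: 0.0
    upper: 34.0
    lower_inc: no
    upper_inc: no
    points: 0
  - lower: 34.0
    upper: 48.0
    lower_inc: yes
    upper_inc: yes
    points: 1
  - lower: 48.0
    upper: .inf
    lower_inc: no
    upper_inc: no
    points: 2
  stiffness:
  - lower: 0.0
    upper: 0.5
    lower_inc: no
    upper_inc: yes
    points: 0
  - lower: 0.5
    upper: .inf
    lower_inc: no
    upper_inc: no
    points: 2
  ee:
  - lower: 0.0
    upper: 14.0
    lower_inc: no
    upper_inc: yes
    points: 0
  - lower: 14.0
    upper: .inf
    lower_inc: no
    upper_inc: no
    points: 2
  lasct:
  - lower: 6.0
    upper: .inf
    lower_inc: no
    upper_inc: no
    points: 0
  - lower: 0.0
    upper: 6.0
    lower_inc: no
    upper_inc: yes
    points: 2
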