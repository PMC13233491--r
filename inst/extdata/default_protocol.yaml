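ranges:
  4-6:
  - 4.0
  - 6.0
  6-8:
  - 6.0
  - 8.0
  8-10:
  - 8.0
  - 10.0
bands:
- direction: increase
  deviation:
  - 0.0
  - 1.0
  percent:
  - 0.1
  - 0.2
- direction: increase
  deviation:
  - 1.0
  - 2.0
  percent:
  - 0.2
  - 0.3
- direction: increase
  deviation:
  - 2.0
  - .inf
  percent:
  - 0.3
  - 0.4
- direction: decrease
  deviation:
  - 0.0
  - 1.0
  percent:
  - 0.1
  - 0.2
- direction: decrease
  deviation:
  - 1.0
  - 2.0
  percent:
  - 0.2
  - 0.3
- direction: decrease
  deviation:
  - 2.0
  - .inf
  percent:
  - 0.3
  - 0.4
hold_thresholds:
  4-6: 11.0
  6-8: 13.0
  8-10: 15.0
recheck_window:
- 24.0
- 48.0
dose_increment: 0.5
adherence_margin: 0.1
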