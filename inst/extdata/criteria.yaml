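tmax:
  direction: above
  advisory: 33.0
  warning: 35.0
  persistence_days: 2
  advisory_points: 1.0
  warning_points: 2.0
tmin:
  direction: below
  advisory: -12.0
  warning: -15.0
  persistence_days: 2
  advisory_points: 1.0
  warning_points: 2.0
humidity:
  direction: below
  advisory: 35.0
  warning: 25.0
  persistence_days: 2
  advisory_points: 1.0
  warning_points: 2.0
rainfall:
  direction: above
  advisory: 80.0
  warning: 150.0
  persistence_days: 1
  advisory_points: 1.0
  warning_points: 2.0
pm10:
  direction: above
  advisory: 150.0
  warning: 300.0
  persistence_days: 1
  advisory_points: 1.0
  warning_points: 2.0
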