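name: reference
ecg_divisor: 1.0
bp:
  high_sys: 145.0
  high_dia: 100.0
  low_sys: 100.0
  low_dia: 60.0
vitals:
- vital: room_temp
  low: 15.0
  high: 35.0
  unit: degC
  rule_low: R3
  rule_high: R2
  rule_normal: ~
  predicate_low: Room_Temperature_Status
  predicate_high: Room_Temperature_Status
  tell_low: no
  tell_high: no
- vital: spo2
  low: ~
  high: 90.0
  unit: '%'
  rule_low: ~
  rule_high: R4
  rule_normal: ~
  predicate_low: ~
  predicate_high: Current_BOS_Level
  tell_low: no
  tell_high: yes
- vital: body_temp
  low: 37.0
  high: 39.0
  unit: degC
  rule_low: R9
  rule_high: R7
  rule_normal: R11
  predicate_low: Has_Hypothermia
  predicate_high: Has_Fever
  tell_low: yes
  tell_high: yes
- vital: heart_rate
  low: 60.0
  high: 100.0
  unit: bpm
  rule_low: R14
  rule_high: R12
  rule_normal: R15
  predicate_low: Low_Heart_Rate
  predicate_high: High_Heart_Rate
  tell_low: no
  tell_high: yes
- vital: blood_sugar
  low: 70.0
  high: 150.0
  unit: mg/dL
  rule_low: R18
  rule_high: R16
  rule_normal: R19
  predicate_low: Low_Blood_Sugar
  predicate_high: High_Blood_Sugar
  tell_low: no
  tell_high: yes
- vital: ecg
  low: 0.6
  high: 1.2
  unit: ratio
  rule_low: R22
  rule_high: R20
  rule_normal: R23
  predicate_low: Low_Abnormal_ECG
  predicate_high: Abnormal_ECG
  tell_low: no
  tell_high: yes
- vital: bp
  low: ~
  high: ~
  unit: mmHg
  rule_low: R26
  rule_high: R24
  rule_normal: R27
  predicate_low: Low_Blood_Pressure
  predicate_high: High_Blood_Pressure
  tell_low: no
  tell_high: yes
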