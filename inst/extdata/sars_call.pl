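% Call-the-doctor reasoning for a monitored severe-respiratory-distress
% patient. Evidence strengths: white-blood-cell abnormality 0.5, tachypnea
% 0.6, fever 0.9, low blood-oxygen saturation 1.0 (certain).
0.5::wbc_abnormal.
0.6::tachypnea.
0.9::fever.
1.0::low_spo2.

% Distress is indicated when fever coincides with desaturation.
sars_indicators :- fever, low_spo2.

% The doctor is called when distress is corroborated by either
% laboratory (WBC) or respiratory-rate evidence.
call_doctor :- sars_indicators, wbc_abnormal.
call_doctor :- sars_indicators, tachypnea.
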