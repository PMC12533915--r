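name;label;formula;unit;comparator;threshold_m;threshold_f
sokolow_lyon;Sokolow-Lyon index;SV1 + max(RV5, RV6);mV;ge;3.5;3.5
sokolow_lyon_product;Sokolow-Lyon voltage-duration product;(SV1 + max(RV5, RV6)) * QRSd;mV.ms;ge;371;371
cornell_voltage;Cornell voltage;RaVL + SV3;mV;gt;2.8;2.0
cornell_product;Cornell voltage-duration product;(RaVL + SV3 + 0.8 * female) * QRSd;mV.ms;gt;244;244
peguero_lo_presti;Peguero-Lo Presti;SD + SV4;mV;ge;2.8;2.3
gubner_ungerleider;Gubner-Ungerleider;RI + SIII;mV;gt;2.5;2.5
lewis;Lewis index;(RI + SIII) - (RIII + SI);mV;ge;1.7;1.7
ravl_voltage;R wave in aVL;RaVL;mV;gt;1.1;1.1
ravf_voltage;R wave in aVF;RaVF;mV;gt;2.0;2.0
ri_voltage;R wave in lead I;RI;mV;gt;1.5;1.5
rv5_voltage;R wave in V5;RV5;mV;gt;2.6;2.6
rv6_voltage;R wave in V6;RV6;mV;gt;2.6;2.6
mcphie;McPhie (tallest precordial R + deepest precordial S);max(RV1, RV2, RV3, RV4, RV5, RV6) + max(SV1, SV2, SV3, SV4, SV5, SV6);mV;gt;4.5;4.5
total_qrs_voltage;Total 12-lead QRS voltage;RI+SI+RII+SII+RIII+SIII+RaVR+SaVR+RaVL+SaVL+RaVF+SaVF+RV1+SV1+RV2+SV2+RV3+SV3+RV4+SV4+RV5+SV5+RV6+SV6;mV;gt;17.5;17.5
limb_lead_voltage;Largest limb-lead R or S;max(RI, RII, RIII, RaVR, RaVL, RaVF, SI, SII, SIII, SaVR, SaVL, SaVF);mV;ge;2.0;2.0
deep_precordial_s;Deep right-precordial S;max(SV1, SV2);mV;ge;3.0;3.0
tall_precordial_r;Tall left-precordial R;max(RV5, RV6);mV;ge;3.0;3.0
modified_sokolow_lyon;Modified Sokolow-Lyon (SV2 + RV5/6);SV2 + max(RV5, RV6);mV;ge;4.5;4.5
rv6_over_rv5;R in V6 exceeding R in V5;RV6 - RV5;mV;gt;0;0
romhilt_estes_4;Romhilt-Estes score >= 4;RE;points;ge;4;4
romhilt_estes_5;Romhilt-Estes score >= 5;RE;points;ge;5;5
minnesota_3_1;Minnesota code 3.1 (any tall left R);max(RaVL / 1.2, max(RV5, RV6) / 2.6, RI / 1.5);ratio;gt;1;1
perugia;Perugia score (adjusted Cornell or strain or RE5);(RaVL + SV3 + 0.8 * female > 2.4) + strain + (RE >= 5);points;ge;1;1
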