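variable,mean_ed,sd_ed,n_ed,mean_hc,sd_hc,n_hc,printed_t
age,16.06,1.38,91,16.22,1.22,48,-0.68
education_years,9.38,1.43,91,9.56,1.56,48,-0.65
bmi,20.22,2.04,91,20.85,1.97,48,-1.77
cognitive_flexibility,108.45,8,91,106.79,8.08,48,1.15
cognitive_inhibition,100.62,8.28,91,100.98,7.74,48,-0.26
similarities,33.11,4.65,91,33.08,4.2,48,0.03
matrix_reasoning,22.14,2.61,91,22.02,2.71,48,0.26
vocabulary,41.7,4.84,91,40.21,3.6,48,2.06
block_design,43.78,10.51,91,46.83,9.43,48,-1.74
self_transcendence,13.77,7.18,91,11.09,4.94,48,2.59
cooperativeness,31.95,5.93,91,34.4,5.75,48,-2.37
self_directedness,22.13,8,91,33.19,7.65,48,-7.98
persistence,5.44,2.05,91,4.88,1.73,48,1.68
reward_dependence,16.03,3.53,91,16.29,3.39,48,-0.43
harm_avoidance,25.04,6.29,91,14.04,7.55,48,8.64
novelty_seeking,16.83,6.28,91,20.01,5.21,48,-3.18
inhibitory_control,4.39,0.86,91,4.46,0.84,48,-0.49
attentional_control,3.14,0.96,91,4.45,1.04,48,-7.26
activation_control,4.15,0.98,91,5,0.98,48,-4.89
effortful_control,3.97,0.76,91,4.66,0.76,48,-5.07
motivational_bias,-0.29,0.57,91,0.65,0.51,48,-9.84
behavioral_inhibition,25.12,2.87,91,19.98,3.16,48,9.41
reward_responsiveness,16.51,2.5,91,17.5,1.68,48,-2.79
trust,1.55,1.31,91,4.09,1,48,-12.79
body_listening,1.41,1.06,91,2.4,1.25,48,-4.65
self_regulation,1.73,1.06,91,3.09,1,48,-7.49
emotional_awareness,2.64,1.11,91,2.99,1.08,48,-1.80
attention_regulation,2.01,0.97,91,3.14,1.05,48,-6.16
not_worrying,2.42,1.03,91,3.19,0.92,48,-4.52
not_distracting,2.14,1.08,91,2.8,1.01,48,-3.57
noticing,2.91,1.01,91,3.05,1.08,48,-0.75
emotion_dysregulation,114.65,24.97,91,63.17,14.05,48,15.55
alexithymia,57.7,11.66,91,44.17,10.14,48,7.10
weight_concern,3.75,1.66,91,0.11,0.19,48,20.70
shape_concern,4.12,1.72,91,0.14,0.19,48,21.80
eating_concern,1.97,1.32,91,0.03,0.2,48,13.75
excessive_exercise,7.48,6.35,91,3.5,3.66,48,4.69
restricting,11.18,6.13,91,2.56,2.77,48,11.39
purging,3.08,4.45,91,0.04,0.29,48,6.48
binge_eating,5.96,6.48,91,5.1,4.26,48,0.93
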