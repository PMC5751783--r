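id,activity,role,report_count
model_tdp_01,1,model,NA
model_tdp_02,1,model,NA
model_tdp_03,1,model,NA
model_tdp_04,1,model,NA
model_tdp_05,1,model,NA
model_tdp_06,1,model,NA
model_tdp_07,1,model,NA
model_tdp_08,1,model,NA
model_tdp_09,1,model,NA
model_tdp_10,1,model,NA
model_tdp_11,1,model,NA
model_tdp_12,1,model,NA
model_tdp_13,1,model,NA
model_tdp_14,1,model,NA
model_tdp_15,1,model,NA
model_tdp_16,1,model,NA
model_tdp_17,1,model,NA
model_tdp_18,1,model,NA
model_tdp_19,1,model,NA
model_tdp_20,1,model,NA
model_tdp_21,1,model,NA
model_tdp_22,1,model,NA
model_tdp_23,1,model,NA
model_tdp_24,1,model,NA
model_tdp_25,1,model,NA
model_tdp_26,1,model,NA
model_tdp_27,1,model,NA
model_tdp_28,1,model,NA
model_tdp_29,1,model,NA
model_tdp_30,1,model,NA
model_tdp_31,1,model,NA
model_tdp_32,1,model,NA
model_safe_01,0,model,NA
model_safe_02,0,model,NA
model_safe_03,0,model,NA
model_safe_04,0,model,NA
model_safe_05,0,model,NA
model_safe_06,0,model,NA
model_safe_07,0,model,NA
model_safe_08,0,model,NA
model_safe_09,0,model,NA
model_safe_10,0,model,NA
model_safe_11,0,model,NA
model_safe_12,0,model,NA
model_safe_13,0,model,NA
model_safe_14,0,model,NA
model_safe_15,0,model,NA
model_safe_16,0,model,NA
model_safe_17,0,model,NA
model_safe_18,0,model,NA
model_safe_19,0,model,NA
model_safe_20,0,model,NA
model_safe_21,0,model,NA
model_safe_22,0,model,NA
model_safe_23,0,model,NA
external_tdp_01,1,external,32
external_tdp_02,1,external,39
external_tdp_03,1,external,46
external_tdp_04,1,external,53
external_tdp_05,1,external,60
external_tdp_06,1,external,67
external_tdp_07,1,external,74
external_tdp_08,1,external,81
external_tdp_09,1,external,88
external_tdp_10,1,external,95
external_tdp_11,1,external,102
external_tdp_12,1,external,109
external_tdp_13,1,external,116
external_tdp_14,1,external,123
external_tdp_15,1,external,130
external_tdp_16,1,external,137
external_tdp_17,1,external,144
external_tdp_18,1,external,151
external_tdp_19,1,external,158
external_tdp_20,1,external,165
external_tdp_21,1,external,172
external_tdp_22,1,external,179
external_tdp_23,1,external,186
external_tdp_24,1,external,193
external_tdp_25,1,external,200
external_tdp_26,1,external,207
external_tdp_27,1,external,214
external_tdp_28,1,external,221
external_tdp_29,1,external,228
external_tdp_30,1,external,235
external_tdp_31,1,external,242
external_tdp_32,1,external,249
external_tdp_33,1,external,256
external_tdp_34,1,external,263
external_tdp_35,1,external,270
external_tdp_36,1,external,277
external_tdp_37,1,external,284
external_safe_01,0,external,25
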